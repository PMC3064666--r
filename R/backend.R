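# MILP backend contract
#
# A backend is a function(problems, time_limit) taking a list of problems and
# returning a list of results.  Each problem is a list with ncol, nrow, obj,
# ai/aj/ax (1-based sparse triplets), clo/chi (row bounds, may be Inf), relax.
# Each result is a list with status ("optimal", "time_limit", "infeasible",
# ...), objective, x (variable values), bound, nodes and optionally lp_value.
# All variables are binary; bounds beyond [0, 1] are expressed as rows.

#' Solve a batch of 0/1 integer programs with HiGHS
#'
#' Default backend: serializes the problems to JSON, runs the bundled SciPy
#' helper (HiGHS is SciPy's MILP engine) in one Python subprocess, and reads
#' the results back. HiGHS is deterministic for a fixed model, so repeated
#' solves return the same objective.
#'
#' @param problems List of problems in the backend contract format.
#' @param time_limit Per-model time limit in seconds.
#' @return List of result lists.
#' @export
milp_highs <- function(problems, time_limit = 600) {
  script <- system.file("python", "milp_backend.py", package = "crmphase", mustWork = TRUE)
  python <- Sys.which(c("python3", "python"))
  python <- python[nzchar(python)][1L]
  if (is.na(python) || !nzchar(python)) {
    stop("no python interpreter found on PATH (needed for the HiGHS backend)", call. = FALSE)
  }
  payload <- lapply(unname(problems), function(p) {
    p$time_limit <- time_limit
    p$clo <- ifelse(is.infinite(p$clo), ifelse(p$clo > 0, "inf", "-inf"), p$clo)
    p$chi <- ifelse(is.infinite(p$chi), ifelse(p$chi > 0, "inf", "-inf"), p$chi)
    p
  })
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA, null = "null")
  code <- system2(python, c(shQuote(script), shQuote(infile), shQuote(outfile)),
    stdout = FALSE, stderr = ""
  )
  if (code != 0L || !file.exists(outfile)) {
    stop("MILP backend subprocess failed (exit code ", code, ")", call. = FALSE)
  }
  jsonlite::read_json(outfile, simplifyVector = TRUE, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}

resolve_backend <- function(backend) {
  if (is.function(backend)) {
    return(backend)
  }
  switch(backend,
    highs = milp_highs,
    stop("unknown backend '", backend, "'", call. = FALSE)
  )
}
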