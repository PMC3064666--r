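#' Read a plain-text matrix of single-digit symbols
#'
#' One row per non-blank line; symbols may be contiguous (`"2112"`) or
#' whitespace-separated (`"2 1 1 2"`). No header: the shape is inferred.
#'
#' @param path File path or connection.
#' @param alphabet Integer vector of permitted symbols.
#' @return Integer matrix.
#' @export
read_matrix <- function(path, alphabet = 0:2) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty matrix file", call. = FALSE)
  rows <- lapply(lines, function(l) {
    toks <- strsplit(gsub("[[:space:]]+", "", l), "")[[1L]]
    suppressWarnings(as.integer(toks))
  })
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    stop("ragged rows: widths ", paste(unique(widths), collapse = ", "), call. = FALSE)
  }
  m <- do.call(rbind, rows)
  if (anyNA(m) || !all(m %in% alphabet)) {
    stop(
      "symbol outside alphabet {", paste(alphabet, collapse = ", "), "}",
      call. = FALSE
    )
  }
  m
}

#' Write a matrix in the contiguous-symbol dialect
#'
#' @param x Integer matrix.
#' @param path File path or connection.
#' @export
write_matrix <- function(x, path) {
  if (!is.matrix(x) || nrow(x) == 0L || ncol(x) == 0L) {
    stop("cannot write an empty matrix", call. = FALSE)
  }
  writeLines(apply(x, 1L, paste0, collapse = ""), path)
  invisible(path)
}

#' @rdname read_matrix
#' @param validate Validate (and deduplicate) rows as genotypes.
#' @export
read_genotypes <- function(path, validate = TRUE) {
  g <- read_matrix(path, alphabet = 0:2)
  if (validate) g <- validate_genotypes(g)
  g
}

#' @rdname read_matrix
#' @export
read_mask <- function(path) {
  read_matrix(path, alphabet = 0:1)
}

#' Write a phasing solution to a sectioned ASCII file
#'
#' The layout is line-oriented: a header of `key value` lines (`n`, `m`,
#' `objective`, `corrections`, `status`), then a `HAPLOTYPES` block (one binary
#' string per line), an `ASSIGNMENT` block (`genotype hap_a hap_b`, 1-based
#' indices into the haplotype block) and a `CORRECTIONS` block
#' (`genotype snp original corrected`). `read_solution()` inverts it.
#'
#' @param sol A `pph_solution` object.
#' @param path File path or connection.
#' @export
write_solution <- function(sol, path) {
  stopifnot(inherits(sol, "pph_solution"))
  lines <- c(
    paste("n", sol$n),
    paste("m", sol$m),
    paste("objective", sol$objective),
    paste("corrections", nrow(sol$corrections)),
    paste("status", sol$status),
    "HAPLOTYPES",
    apply(sol$haplotypes, 1L, paste0, collapse = ""),
    "ASSIGNMENT",
    sprintf("%d %d %d", sol$assignment$genotype, sol$assignment$hap_a, sol$assignment$hap_b),
    "CORRECTIONS"
  )
  if (nrow(sol$corrections) > 0L) {
    lines <- c(lines, sprintf(
      "%d %d %d %d",
      sol$corrections$genotype, sol$corrections$snp,
      sol$corrections$original, sol$corrections$corrected
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_solution
#' @export
read_solution <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  sec <- match(c("HAPLOTYPES", "ASSIGNMENT", "CORRECTIONS"), lines)
  if (anyNA(sec) || is.unsorted(sec)) {
    stop("malformed solution file: missing or misordered section headers", call. = FALSE)
  }
  header <- lines[seq_len(sec[1L] - 1L)]
  kv <- strsplit(header, "[[:space:]]+")
  vals <- stats::setNames(
    vapply(kv, function(x) paste(x[-1L], collapse = " "), character(1)),
    vapply(kv, `[[`, character(1), 1L)
  )
  hap_lines <- lines[seq(sec[1L] + 1L, sec[2L] - 1L)]
  haps <- do.call(rbind, lapply(strsplit(hap_lines, ""), as.integer))
  asg_lines <- if (sec[3L] > sec[2L] + 1L) lines[seq(sec[2L] + 1L, sec[3L] - 1L)] else character(0)
  asg <- if (length(asg_lines)) {
    do.call(rbind, lapply(strsplit(asg_lines, "[[:space:]]+"), as.integer))
  } else {
    matrix(integer(0), 0L, 3L)
  }
  if (nrow(asg) > 0L && any(asg[, 2:3] < 1L | asg[, 2:3] > nrow(haps))) {
    stop("assignment references a haplotype index outside the haplotype block", call. = FALSE)
  }
  cor_lines <- if (sec[3L] < length(lines)) lines[seq(sec[3L] + 1L, length(lines))] else character(0)
  corm <- if (length(cor_lines)) {
    do.call(rbind, lapply(strsplit(cor_lines, "[[:space:]]+"), as.integer))
  } else {
    matrix(integer(0), 0L, 4L)
  }
  corrections <- tibble::tibble(
    genotype = as.integer(corm[, 1L]), snp = as.integer(corm[, 2L]),
    original = as.integer(corm[, 3L]), corrected = as.integer(corm[, 4L]),
    delta = as.integer(corm[, 4L]) - as.integer(corm[, 3L])
  )
  new_pph_solution(
    haplotypes = haps,
    assignment = tibble::tibble(
      genotype = as.integer(asg[, 1L]),
      hap_a = as.integer(asg[, 2L]), hap_b = as.integer(asg[, 3L])
    ),
    corrections = corrections,
    objective = as.integer(vals[["objective"]]),
    status = vals[["status"]],
    n = as.integer(vals[["n"]]),
    m = as.integer(vals[["m"]])
  )
}
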