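"""Batch 0/1 MILP solver used as the default backend.

Reads a JSON file holding a list of problems, solves each with HiGHS through
scipy.optimize.milp, and writes a JSON list of results.  Each problem is a
dict with: ncol, nrow, obj (dense list), ai/aj/ax (1-based constraint
triplets), clo/chi (row bounds, "inf"/"-inf" allowed), time_limit, and an
optional "relax" flag requesting the LP-relaxation value as well.
"""

import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

STATUS = {0: "optimal", 1: "iteration_limit", 2: "infeasible", 3: "unbounded", 4: "error"}


def _aslist(v):
    return v if isinstance(v, list) else [v]


def _num(v):
    if v == "inf":
        return np.inf
    if v == "-inf":
        return -np.inf
    return float(v)


def solve_one(p):
    ncol = int(p["ncol"])
    nrow = int(p["nrow"])
    c = np.atleast_1d(np.asarray(p["obj"], dtype=float))
    A = sparse.csr_matrix(
        (np.atleast_1d(np.asarray(p["ax"], dtype=float)),
         (np.atleast_1d(np.asarray(p["ai"], dtype=int)) - 1,
          np.atleast_1d(np.asarray(p["aj"], dtype=int)) - 1)),
        shape=(nrow, ncol),
    )
    clo = np.atleast_1d(np.asarray([_num(v) for v in _aslist(p["clo"])], dtype=float))
    chi = np.atleast_1d(np.asarray([_num(v) for v in _aslist(p["chi"])], dtype=float))
    bounds = Bounds(np.zeros(ncol), np.ones(ncol))
    constraints = LinearConstraint(A, clo, chi) if nrow > 0 else ()
    options = {"time_limit": float(p.get("time_limit", 600.0)), "mip_rel_gap": 0.0}

    res = milp(c=c, constraints=constraints, bounds=bounds,
               integrality=np.ones(ncol), options=options)
    out = {
        "status": STATUS.get(int(res.status), "error"),
        "success": bool(res.success),
        "objective": None if res.fun is None else float(res.fun),
        "x": None if res.x is None else [float(v) for v in res.x],
        "bound": None if res.mip_dual_bound is None else float(res.mip_dual_bound),
        "nodes": None if res.mip_node_count is None else int(res.mip_node_count),
    }
    # time-limit with an incumbent: scipy reports status 1 but success False
    if out["status"] == "iteration_limit" and out["x"] is not None:
        out["status"] = "time_limit"
    if p.get("relax"):
        lp = milp(c=c, constraints=constraints, bounds=bounds,
                  integrality=np.zeros(ncol), options=options)
        out["lp_value"] = None if lp.fun is None else float(lp.fun)
    return out


def main(infile, outfile):
    with open(infile) as fh:
        problems = json.load(fh)
    results = [solve_one(p) for p in problems]
    with open(outfile, "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
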