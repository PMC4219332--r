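"""Batch LP/MILP/QP back end.

Reads a JSON file with a list of problems, solves each with SciPy/HiGHS,
writes a JSON file with one result per problem.  Infinities are exchanged
with R as +/-1e30.

Problem schema (all arrays plain JSON lists):
  type        "milp" (also plain LP) or "qp" (box+row constrained least
              squares against a target vector, used for L2-MOMA)
  c           objective coefficients (milp only)
  target      reference vector for ||x - target||^2 (qp only)
  A           {"i": row idx (0-based), "j": col idx, "x": values,
               "nrow": n, "ncol": m}
  rlb, rub    row bounds
  lb, ub      variable bounds
  integrality 0/1 per variable (milp only; absent means all-continuous)
  options     {"mip_rel_gap": g, "time_limit": s}
"""

import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp, minimize

BIG = 1e30

_MILP_STATUS = {
    0: "optimal",
    1: "limit",
    2: "infeasible",
    3: "unbounded",
    4: "error",
}


def _inf(a):
    a = np.atleast_1d(np.asarray(a, dtype=float))
    a = np.where(a >= BIG, np.inf, a)
    a = np.where(a <= -BIG, -np.inf, a)
    return a


def _matrix(spec):
    return sparse.csc_matrix(
        (np.atleast_1d(np.asarray(spec["x"], dtype=float)),
         (np.atleast_1d(np.asarray(spec["i"], dtype=int)),
          np.atleast_1d(np.asarray(spec["j"], dtype=int)))),
        shape=(int(spec["nrow"]), int(spec["ncol"])),
    )


def _solve_milp(p):
    ncol = int(p["A"]["ncol"])
    A = _matrix(p["A"])
    c = np.atleast_1d(np.asarray(p["c"], dtype=float))
    lb, ub = _inf(p["lb"]), _inf(p["ub"])
    rlb, rub = _inf(p["rlb"]), _inf(p["rub"])
    integrality = np.atleast_1d(np.asarray(p.get("integrality", [0] * ncol), dtype=int))
    opts = p.get("options", {}) or {}
    options = {"presolve": True}
    if integrality.any():
        options["mip_rel_gap"] = float(opts.get("mip_rel_gap", 0.0))
    if "time_limit" in opts:
        options["time_limit"] = float(opts["time_limit"])
    cons = [LinearConstraint(A, rlb, rub)] if A.shape[0] else []
    res = milp(c=c, constraints=cons, bounds=Bounds(lb, ub),
               integrality=integrality, options=options)
    status = _MILP_STATUS.get(res.status, "error")
    out = {"status": status, "message": str(res.message)}
    if res.x is not None:
        out["x"] = [float(v) for v in res.x]
        out["objective"] = float(res.fun)
    return out


def _solve_qp(p):
    target = np.atleast_1d(np.asarray(p["target"], dtype=float))
    A = _matrix(p["A"])
    lb, ub = _inf(p["lb"]), _inf(p["ub"])
    rlb, rub = _inf(p["rlb"]), _inf(p["rub"])

    def fun(x):
        d = x - target
        return float(d @ d)

    def jac(x):
        return 2.0 * (x - target)

    def hess(x):
        return 2.0 * np.eye(len(target))

    cons = [LinearConstraint(A.toarray(), rlb, rub)] if A.shape[0] else []
    x0 = np.clip(target, lb, np.where(np.isfinite(ub), ub, np.abs(target) + 1.0))
    res = minimize(fun, x0, jac=jac, hess=hess, method="trust-constr",
                   bounds=Bounds(lb, ub), constraints=cons,
                   options={"maxiter": 2000, "gtol": 1e-12, "xtol": 1e-14})
    viol = 0.0
    if A.shape[0]:
        Ax = A @ res.x
        viol = float(max(np.max(np.maximum(Ax - rub, 0.0)),
                         np.max(np.maximum(rlb - Ax, 0.0))))
    ok = res.status in (1, 2) and viol < 1e-7
    return {"status": "optimal" if ok else "error",
            "message": str(res.message),
            "x": [float(v) for v in res.x],
            "objective": float(res.fun)}


def main(argv):
    infile, outfile = argv[1], argv[2]
    with open(infile) as fh:
        payload = json.load(fh)
    results = []
    for p in payload["problems"]:
        try:
            if p.get("type", "milp") == "qp":
                results.append(_solve_qp(p))
            else:
                results.append(_solve_milp(p))
        except Exception as exc:  # surfaced to R as status "error"
            results.append({"status": "error", "message": repr(exc)})
    with open(outfile, "w") as fh:
        json.dump({"results": results}, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
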