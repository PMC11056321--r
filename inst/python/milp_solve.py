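"""HiGHS bridge: solve a MILP described in JSON and write the result as JSON.

Input schema (all arrays parallel where applicable):
  n        int, number of variables
  obj      [float] objective coefficients (minimized)
  vtype    ["binary"|"integer"|"continuous"]
  lb, ub   [float] variable bounds (ub may be null/1e30 for +inf)
  rows, cols, vals  sparse constraint matrix triplets (1-based indices)
  sense    ["<="|">="|"=="] per constraint row
  rhs      [float]
  relax    bool, drop integrality
  time_limit  float seconds, < 0 means none

Output: {"status": ..., "x": [...], "message": ...}
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp


def as_array(x, n, dtype=float):
    if x is None:
        return np.zeros(n, dtype=dtype)
    a = np.asarray(x, dtype=dtype)
    if a.ndim == 0:
        a = a.reshape(1)
    return a


def main(fin, fout):
    with open(fin) as fh:
        m = json.load(fh)
    n = int(m["n"])
    obj = as_array(m["obj"], n)
    vtype = m["vtype"]
    if isinstance(vtype, str):
        vtype = [vtype]
    lb = as_array(m["lb"], n)
    ub = as_array(m["ub"], n)
    lb = np.where(np.isnan(lb) | (lb <= -1e30), -np.inf, lb)
    ub = np.where(np.isnan(ub) | (ub >= 1e30), np.inf, ub)
    integrality = np.array(
        [0 if t == "continuous" else 1 for t in vtype], dtype=int
    )
    if m.get("relax"):
        integrality = np.zeros(n, dtype=int)

    rows = as_array(m.get("rows"), 0, dtype=int)
    cols = as_array(m.get("cols"), 0, dtype=int)
    vals = as_array(m.get("vals"), 0)
    sense = m.get("sense") or []
    if isinstance(sense, str):
        sense = [sense]
    rhs = as_array(m.get("rhs"), len(sense))
    nc = len(sense)
    constraints = []
    if nc > 0:
        A = sparse.csc_matrix(
            (vals, (rows - 1, cols - 1)), shape=(nc, n)
        )
        clb = np.empty(nc)
        cub = np.empty(nc)
        for i, s in enumerate(sense):
            if s == "<=":
                clb[i], cub[i] = -np.inf, rhs[i]
            elif s == ">=":
                clb[i], cub[i] = rhs[i], np.inf
            else:
                clb[i] = cub[i] = rhs[i]
        constraints = [LinearConstraint(A, clb, cub)]

    options = {"mip_rel_gap": 0.0}
    tl = m.get("time_limit", -1)
    if tl is not None and tl > 0:
        options["time_limit"] = float(tl)

    res = milp(
        c=obj,
        constraints=constraints,
        integrality=integrality,
        bounds=Bounds(lb, ub),
        options=options,
    )
    # scipy status codes: 0 optimal, 1 iteration/time limit, 2 infeasible,
    # 3 unbounded, 4 other
    status_map = {0: "optimal", 1: "limit-reached", 2: "infeasible",
                  3: "unbounded"}
    status = status_map.get(res.status, "error")
    out = {
        "status": status,
        "message": res.message,
        "x": None if res.x is None else [float(v) for v in res.x],
    }
    with open(fout, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
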