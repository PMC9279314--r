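"""Mixed-integer program backend: reads a problem JSON, solves it with
scipy's HiGHS branch-and-cut interface, writes a solution JSON.

Problem JSON (all arrays dense unless noted): n_vars, n_rows, obj (minimize),
lb, ub, integrality (0/1), A_row/A_col/A_val (0-based triplets), row_lb,
row_ub, mip_rel_gap, time_limit. Bounds with |value| >= 1e30 are infinite.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

BIG = 1e30


def definf(a):
    a = np.asarray(a, dtype=float)
    a[a >= BIG] = np.inf
    a[a <= -BIG] = -np.inf
    return a


def main(fin, fout):
    with open(fin) as fh:
        spec = json.load(fh)
    n = int(spec["n_vars"])
    c = np.asarray(spec["obj"], dtype=float)
    bounds = Bounds(definf(spec["lb"]), definf(spec["ub"]))
    integrality = np.asarray(spec["integrality"], dtype=float)
    constraints = []
    if int(spec["n_rows"]) > 0:
        A = sparse.csr_matrix(
            (np.asarray(spec["A_val"], dtype=float),
             (np.asarray(spec["A_row"], dtype=int),
              np.asarray(spec["A_col"], dtype=int))),
            shape=(int(spec["n_rows"]), n))
        constraints = [LinearConstraint(A, definf(spec["row_lb"]),
                                        definf(spec["row_ub"]))]
    options = {"mip_rel_gap": float(spec.get("mip_rel_gap", 0.0)),
               "time_limit": float(spec.get("time_limit", 300.0)),
               "presolve": True}
    res = milp(c, constraints=constraints, integrality=integrality,
               bounds=bounds, options=options)

    def num(v):
        if v is None:
            return None
        v = float(v)
        return v if np.isfinite(v) else None

    out = {
        "status": int(res.status),
        "success": bool(res.success),
        "message": str(res.message),
        "x": None if res.x is None else [float(v) for v in res.x],
        "fun": num(res.fun),
        "mip_dual_bound": num(getattr(res, "mip_dual_bound", None)),
        "mip_gap": num(getattr(res, "mip_gap", None)),
    }
    with open(fout, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
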