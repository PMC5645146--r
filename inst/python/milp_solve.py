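"""Generic mixed-integer linear program solver bridge.

Reads a problem description from a JSON file and writes the solution to a
JSON file. The problem is solver-neutral: objective vector, sparse
constraint triplets with row bounds, variable bounds and integrality
flags. Solved with HiGHS via scipy.optimize.milp.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp


def main(fin, fout):
    with open(fin) as fh:
        prob = json.load(fh)
    n = int(prob["nvar"])
    ncon = int(prob["ncon"])
    c = np.asarray(prob["obj"], dtype=float)
    A = sparse.coo_matrix(
        (np.asarray(prob["a_val"], dtype=float),
         (np.asarray(prob["a_row"], dtype=int),
          np.asarray(prob["a_col"], dtype=int))),
        shape=(ncon, n),
    )
    con = LinearConstraint(
        A.tocsr(),
        np.asarray(prob["con_lb"], dtype=float),
        np.asarray(prob["con_ub"], dtype=float),
    )
    bounds = Bounds(
        np.asarray(prob["var_lb"], dtype=float),
        np.asarray(prob["var_ub"], dtype=float),
    )
    integrality = np.asarray(prob["integrality"], dtype=int)
    options = {"disp": False}
    if prob.get("time_limit"):
        options["time_limit"] = float(prob["time_limit"])
    res = milp(c=c, constraints=con, bounds=bounds,
               integrality=integrality, options=options)
    gap = getattr(res, "mip_gap", None)
    out = {
        "status": int(res.status),
        "success": bool(res.success),
        "message": str(res.message),
        "x": None if res.x is None else [float(v) for v in res.x],
        "objective": None if res.x is None else float(res.fun),
        "mip_gap": None if gap is None else float(gap),
    }
    with open(fout, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
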