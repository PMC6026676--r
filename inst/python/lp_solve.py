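"""One-shot LP solve for the 'scipy' backend: JSON in, JSON out.

Problem: min c'x  s.t.  A x = b,  lb <= x <= ub.
Bounds of magnitude >= 1e30 are treated as infinite.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def main(fin, fout):
    with open(fin) as fh:
        spec = json.load(fh)
    c = np.asarray(spec["c"], dtype=float)
    A = np.asarray(spec["A"], dtype=float)
    if A.ndim == 1:
        A = A.reshape(1, -1)
    b = np.asarray(spec["b"], dtype=float)
    lb = np.asarray(spec["lb"], dtype=float)
    ub = np.asarray(spec["ub"], dtype=float)
    lb[lb <= -1e30] = -np.inf
    ub[ub >= 1e30] = np.inf
    res = linprog(c, A_eq=A, b_eq=b, bounds=list(zip(lb, ub)),
                  method="highs")
    out = {"status": int(res.status),
           "objective": None if res.x is None else float(res.fun),
           "x": None if res.x is None else [float(v) for v in res.x]}
    with open(fout, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
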