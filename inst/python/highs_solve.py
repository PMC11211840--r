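"""Mixed-integer linear program backend.

Reads a model directory written by the R side (meta.json + arrays.bin of
little-endian float64 blocks), solves it with HiGHS via scipy.optimize.milp,
and writes solution.json plus x.bin. Kept dependency-minimal on purpose:
numpy + scipy only.

Usage: python highs_solve.py <model_dir>
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

INF = 1e30


def main(model_dir):
    with open(f"{model_dir}/meta.json") as fh:
        meta = json.load(fh)
    raw = np.fromfile(f"{model_dir}/arrays.bin", dtype="<f8")
    blocks = {}
    pos = 0
    for name, ln in zip(meta["block_names"], meta["block_lengths"]):
        blocks[name] = raw[pos:pos + ln]
        pos += ln
    assert pos == raw.size, "array file length mismatch"

    nv = int(meta["n_vars"])
    obj = blocks["obj"]
    lb = blocks["lb"].copy()
    ub = blocks["ub"].copy()
    lb[lb <= -INF] = -np.inf
    ub[ub >= INF] = np.inf
    integrality = blocks["integrality"].astype(np.int64)
    ai = blocks["a_row"].astype(np.int64)
    aj = blocks["a_col"].astype(np.int64)
    av = blocks["a_val"]
    rlo = blocks["row_lb"].copy()
    rhi = blocks["row_ub"].copy()
    rlo[rlo <= -INF] = -np.inf
    rhi[rhi >= INF] = np.inf
    nrow = int(meta["n_rows"])
    A = sparse.csr_matrix((av, (ai, aj)), shape=(nrow, nv))

    opts = {"presolve": True}
    if meta.get("time_limit") is not None:
        opts["time_limit"] = float(meta["time_limit"])
    opts["mip_rel_gap"] = float(meta.get("mip_rel_gap", 0.0))
    if meta.get("node_limit") is not None:
        opts["node_limit"] = int(meta["node_limit"])

    res = milp(c=obj, constraints=LinearConstraint(A, rlo, rhi),
               integrality=integrality, bounds=Bounds(lb, ub), options=opts)

    out = {
        "status_code": int(res.status),
        "status": {0: "optimal", 1: "limit_reached", 2: "infeasible",
                   3: "unbounded", 4: "error"}.get(int(res.status), "unknown"),
        "message": str(res.message),
        "objective": None if res.fun is None else float(res.fun),
        "mip_gap": None if getattr(res, "mip_gap", None) is None else float(res.mip_gap),
        "has_solution": res.x is not None,
    }
    with open(f"{model_dir}/solution.json", "w") as fh:
        json.dump(out, fh)
    if res.x is not None:
        np.asarray(res.x, dtype="<f8").tofile(f"{model_dir}/x.bin")


if __name__ == "__main__":
    main(sys.argv[1])
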