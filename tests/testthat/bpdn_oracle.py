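"""Independent basis-pursuit-denoising oracle.

Solves  min ||a||_1  s.t.  ||y - X a||_2 <= eps  for a batch of small
instances by sequential quadratic programming on the positive/negative
split a = p - q (p, q >= 0), which makes the objective linear and the
constraint smooth.  Reads a JSON list of instances on the path given as
argv[1], writes a JSON list of results to argv[2].
"""
import json
import sys

import numpy as np
from scipy.optimize import minimize


def solve(X, y, eps):
    X = np.asarray(X, dtype=float)
    y = np.asarray(y, dtype=float)
    d, n = X.shape
    if np.linalg.norm(y) <= eps:
        return np.zeros(n)

    # feasible start from the least-squares solution
    a0, *_ = np.linalg.lstsq(X, y, rcond=None)
    z0 = np.concatenate([np.clip(a0, 0, None), np.clip(-a0, 0, None)])

    def obj(z):
        return z.sum()

    def obj_grad(z):
        return np.ones(2 * n)

    def con(z):
        a = z[:n] - z[n:]
        r = y - X @ a
        return eps ** 2 - r @ r

    def con_grad(z):
        a = z[:n] - z[n:]
        r = y - X @ a
        g = 2.0 * X.T @ r
        return np.concatenate([g, -g])

    res = minimize(
        obj, z0, jac=obj_grad, method="SLSQP",
        bounds=[(0.0, None)] * (2 * n),
        constraints=[{"type": "ineq", "fun": con, "jac": con_grad}],
        options={"maxiter": 2000, "ftol": 1e-14},
    )
    z = res.x
    return z[:n] - z[n:]


def main(src, dst):
    with open(src) as fh:
        instances = json.load(fh)
    out = []
    for inst in instances:
        X = np.asarray(inst["X"], dtype=float)
        if X.ndim == 1:
            X = X.reshape(len(inst["y"]), -1)
        a = solve(X, inst["y"], inst["eps"])
        r = np.asarray(inst["y"]) - X @ a
        out.append({
            "alpha": a.tolist(),
            "l1": float(np.abs(a).sum()),
            "residual": float(np.linalg.norm(r)),
        })
    with open(dst, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
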