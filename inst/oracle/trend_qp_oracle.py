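"""Independent oracle for the piecewise-linear trend objective.

Reads JSON {"t": [...], "y": [...], "lam": ...} from stdin, solves

    minimize 0.5*||y - x||^2 + lam * sum_j |(D x)_j|

via the epigraph quadratic program over (x, s), s_j >= |(D x)_j|, using
scipy's trust-constr solver, and writes JSON {"objective": ..., "x": [...]}
to stdout.  Used only as a cross-check of the package's own solver.
"""
import json
import sys

import numpy as np
from scipy import optimize, sparse


def main():
    prob = json.load(sys.stdin)
    t = np.asarray(prob["t"], dtype=float)
    y = np.asarray(prob["y"], dtype=float)
    lam = float(prob["lam"])
    n = len(t)
    m = n - 2
    h = np.diff(t)
    rows, cols, vals = [], [], []
    for j in range(m):
        rows += [j, j, j]
        cols += [j, j + 1, j + 2]
        vals += [1.0 / h[j], -(1.0 / h[j] + 1.0 / h[j + 1]), 1.0 / h[j + 1]]
    D = sparse.csr_matrix((vals, (rows, cols)), shape=(m, n))

    # variables z = (x, s); constraints  -s <= D x <= s  i.e.
    #  D x - s <= 0  and  -D x - s <= 0
    A = sparse.vstack(
        [
            sparse.hstack([D, -sparse.identity(m)]),
            sparse.hstack([-D, -sparse.identity(m)]),
        ]
    ).tocsr()
    lc = optimize.LinearConstraint(A, -np.inf, 0.0)

    def fun(z):
        x, s = z[:n], z[n:]
        return 0.5 * np.sum((y - x) ** 2) + lam * np.sum(s)

    def grad(z):
        x = z[:n]
        return np.concatenate([x - y, np.full(m, lam)])

    H = sparse.block_diag([sparse.identity(n), sparse.csr_matrix((m, m))])

    x0 = y.copy()
    s0 = np.abs(D @ x0) + 1.0
    res = optimize.minimize(
        fun,
        np.concatenate([x0, s0]),
        jac=grad,
        hess=lambda z: H,
        constraints=[lc],
        method="trust-constr",
        options={
            "gtol": 1e-14,
            "xtol": 1e-16,
            "barrier_tol": 1e-14,
            "maxiter": 20000,
        },
    )
    x = res.x[:n]
    obj = 0.5 * np.sum((y - x) ** 2) + lam * np.sum(np.abs(D @ x))
    json.dump({"objective": float(obj), "x": x.tolist()}, sys.stdout)


if __name__ == "__main__":
    main()
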