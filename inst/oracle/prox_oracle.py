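"""Independent convex oracle for the row-wise lq proximal problem.

Solves  argmin_theta 0.5*||theta - v||^2 + lam*||theta||_q  with a
general-purpose constrained solver (scipy), via smooth reformulations:

  q = 1   : positive/negative splitting, bound-constrained L-BFGS-B
  q = inf : epigraph with linear constraints, SLSQP
  other q : splitting + epigraph of the q-norm, SLSQP and trust-constr,
            keeping whichever reaches the lower objective

Input : JSON file {"cases": [{"v": [...], "q": <number or "inf">,
                              "lam": <number>}, ...]}
Output: JSON file {"solutions": [[...], ...]}
"""
import json
import sys

import numpy as np
from scipy.optimize import minimize, LinearConstraint, NonlinearConstraint


def solve_l1(v, lam):
    n = len(v)

    def fun(w):
        tp, tn = w[:n], w[n:]
        r = tp - tn - v
        return 0.5 * r @ r + lam * (tp.sum() + tn.sum())

    def grad(w):
        tp, tn = w[:n], w[n:]
        r = tp - tn - v
        return np.concatenate([r + lam, -r + lam])

    x0 = np.concatenate([np.maximum(v, 0), np.maximum(-v, 0)])
    res = minimize(fun, x0, jac=grad, method="L-BFGS-B",
                   bounds=[(0, None)] * (2 * n),
                   options={"ftol": 1e-16, "gtol": 1e-12, "maxiter": 2000})
    return res.x[:n] - res.x[n:]


def solve_linf(v, lam):
    n = len(v)

    def fun(w):
        th, t = w[:n], w[n]
        r = th - v
        return 0.5 * r @ r + lam * t

    def grad(w):
        th = w[:n]
        return np.concatenate([th - v, [lam]])

    # t - theta_i >= 0, t + theta_i >= 0, t >= 0
    A = np.zeros((2 * n + 1, n + 1))
    for i in range(n):
        A[i, i] = -1.0
        A[i, n] = 1.0
        A[n + i, i] = 1.0
        A[n + i, n] = 1.0
    A[2 * n, n] = 1.0
    con = LinearConstraint(A, 0, np.inf)
    x0 = np.concatenate([v, [np.max(np.abs(v)) if n else 0.0]])
    res = minimize(fun, x0, jac=grad, method="SLSQP", constraints=[con],
                   options={"ftol": 1e-14, "maxiter": 1000})
    return res.x[:n]


def solve_lq(v, q, lam):
    n = len(v)

    def fun(w):
        tp, tn, t = w[:n], w[n:2 * n], w[2 * n]
        r = tp - tn - v
        return 0.5 * r @ r + lam * t

    def grad(w):
        tp, tn = w[:n], w[n:2 * n]
        r = tp - tn - v
        return np.concatenate([r, -r, [lam]])

    def confun(w):
        tp, tn, t = w[:n], w[n:2 * n], w[2 * n]
        return t ** q - np.sum((tp + tn) ** q)

    def congrad(w):
        tp, tn, t = w[:n], w[n:2 * n], w[2 * n]
        g = -q * (tp + tn) ** (q - 1)
        return np.concatenate([g, g, [q * t ** (q - 1)]])

    bounds = [(0, None)] * (2 * n) + [(1e-12, None)]
    nlc = NonlinearConstraint(confun, 0, np.inf, jac=congrad)

    def split_start(theta):
        t0 = np.sum(np.abs(theta) ** q) ** (1.0 / q) if n else 0.0
        return np.concatenate([np.maximum(theta, 0), np.maximum(-theta, 0),
                               [t0 + 1e-6]])

    # SLSQP from several starts (cheap); trust-constr once, from the
    # unshrunk start (expensive but robust to SLSQP stalls)
    attempts = [("SLSQP", split_start(v)), ("SLSQP", split_start(0.5 * v)),
                ("SLSQP", split_start(0.1 * v)),
                ("trust-constr", split_start(v))]
    best_x, best_f = None, np.inf
    for method, x0 in attempts:
        opts = ({"ftol": 1e-14, "maxiter": 1000} if method == "SLSQP"
                else {"gtol": 1e-12, "xtol": 1e-14, "maxiter": 3000})
        try:
            res = minimize(fun, x0, jac=grad, method=method,
                           bounds=bounds, constraints=[nlc], options=opts)
        except Exception:
            continue
        th = res.x[:n] - res.x[n:2 * n]
        f = (0.5 * np.sum((th - v) ** 2)
             + lam * np.sum(np.abs(th) ** q) ** (1.0 / q))
        if f < best_f:
            best_f, best_x = f, th

    # independent second formulation: the minimizer is sign-aligned with v
    # and coordinate-wise shrunk, so solve over the box 0 <= u <= |v| with
    # the norm written out (smooth away from u = 0); L-BFGS-B is much more
    # reliable here than the SLSQP epigraph when SLSQP stalls
    a = np.abs(v)
    sgn = np.sign(v)

    def bfun(u):
        s = np.sum(u ** q)
        return 0.5 * np.sum((u - a) ** 2) + lam * s ** (1.0 / q)

    def bgrad(u):
        s = np.sum(u ** q)
        if s <= 0:
            return u - a
        return (u - a) + lam * s ** (1.0 / q - 1.0) * u ** (q - 1.0)

    for u0 in (a, 0.5 * a, 0.05 * a):
        res = minimize(bfun, u0, jac=bgrad, method="L-BFGS-B",
                       bounds=[(0, ai) for ai in a],
                       options={"ftol": 1e-16, "gtol": 1e-12,
                                "maxiter": 5000})
        if res.fun < best_f:
            best_f, best_x = res.fun, sgn * res.x

    # the all-zero point is always feasible; keep it if it is better
    f0 = 0.5 * np.sum(v ** 2)
    if f0 < best_f:
        best_x = np.zeros(n)
    return best_x


def main(inp, outp):
    with open(inp) as fh:
        payload = json.load(fh)
    sols = []
    for case in payload["cases"]:
        v = np.asarray(case["v"], dtype=float)
        lam = float(case["lam"])
        q = case["q"]
        if lam == 0:
            sols.append(v.tolist())
            continue
        if q == "inf" or (isinstance(q, (int, float)) and np.isinf(q)):
            th = solve_linf(v, lam)
        elif float(q) == 1.0:
            th = solve_l1(v, lam)
        else:
            th = solve_lq(v, float(q), lam)
        sols.append(np.asarray(th).tolist())
    with open(outp, "w") as fh:
        json.dump({"solutions": sols}, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
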