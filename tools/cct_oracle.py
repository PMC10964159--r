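"""Independent reference implementation of the MSE-optimal (CCT-style)
plug-in bandwidth selector for the sharp RD estimator, used once to compute
frozen oracle constants for the R package's tests. Written from the
published formulas, independently of the R code.

h = ( V / (2 (p+1) (B^2 + R) n) )^(1/(2p+3))

V = v_K (sig2_above + sig2_below) / f(c)
B = b_K (coef_above - (-1)^(p+1) coef_below)   [coef = m^(p+1)(c)/(p+1)!]
R = 3 b_K^2 (var_coef_above + var_coef_below)

Pilot quantities: Gaussian KDE with Silverman bandwidth for f(c); residual
variance of side-wise local linear fits in a uniform pilot window
1.84 sd n^(-1/5); global side-wise polynomial fits of order p+2 for the
(p+1)-th derivative coefficient and its homoskedastic variance.
"""
import sys
import numpy as np


def kernel_constants(name, p):
    if name == "triangular":
        m1 = lambda j: 1.0 / ((j + 1) * (j + 2))
        m2 = lambda j: 2.0 / ((j + 1) * (j + 2) * (j + 3))
    else:
        m1 = lambda j: 1.0 / (j + 1)
        m2 = m1
    idx = np.arange(p + 1)
    G = np.array([[m1(i + j) for j in idx] for i in idx])
    th = np.array([m1(j + p + 1) for j in idx])
    Ps = np.array([[m2(i + j) for j in idx] for i in idx])
    Gi = np.linalg.inv(G)
    return (Gi @ th)[0], (Gi @ Ps @ Gi)[0, 0]


def pilot_variance(x, y, c, h_pilot):
    d = np.abs(x - c)
    inw = d < h_pilot
    if inw.sum() < 5:
        order = np.argsort(d, kind="stable")
        inw = np.zeros(len(x), bool)
        inw[order[:5]] = True
    xs = x[inw] - c
    ys = y[inw]
    X = np.column_stack([np.ones(len(xs)), xs])
    beta, *_ = np.linalg.lstsq(X, ys, rcond=None)
    e = ys - X @ beta
    return float(e @ e) / max(len(ys) - 2, 1)


def global_curvature(x, y, c, p):
    q = p + 2
    X = np.column_stack([(x - c) ** j for j in range(q + 1)])
    A = np.linalg.inv(X.T @ X)
    beta = A @ (X.T @ y)
    e = y - X @ beta
    sigma2 = float(e @ e) / max(len(y) - q - 1, 1)
    j = p + 1
    return beta[j], sigma2 * A[j, j]


def cct_bandwidth(x, y, c, kernel="triangular", p=1, regularization=True):
    n = len(x)
    below = x < c
    xb, yb = x[below], y[below]
    xa, ya = x[~below], y[~below]
    sd = x.std(ddof=1)
    q75, q25 = np.percentile(x, [75, 25])
    bw0 = 0.9 * min(sd, (q75 - q25) / 1.34) * n ** (-0.2)
    z = (x - c) / bw0
    f_c = np.mean(np.exp(-0.5 * z * z) / np.sqrt(2 * np.pi)) / bw0
    h_pilot = 1.84 * sd * n ** (-0.2)
    sig2_b = pilot_variance(xb, yb, c, h_pilot)
    sig2_a = pilot_variance(xa, ya, c, h_pilot)
    cb, vb = global_curvature(xb, yb, c, p)
    ca, va = global_curvature(xa, ya, c, p)
    bK, vK = kernel_constants(kernel, p)
    sgn = (-1.0) ** (p + 1)
    B = bK * (ca - sgn * cb)
    R = 3 * bK ** 2 * (va + vb) if regularization else 0.0
    V = vK * (sig2_a + sig2_b) / f_c
    return (V / (2 * (p + 1) * (B * B + R) * n)) ** (1.0 / (2 * p + 3))


if __name__ == "__main__":
    for path, p in [(a.split(":")[0], int(a.split(":")[1])) for a in sys.argv[1:]]:
        d = np.genfromtxt(path, delimiter=",", names=True)
        h = cct_bandwidth(d["x"], d["y"], 65.0, "triangular", p)
        print(f"{path} p={p} h={h:.10f}")
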