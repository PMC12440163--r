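"""Independent NumPy/SciPy oracle for the time-series feature catalogue.

Reimplements every pinned feature definition directly from its mathematical
statement, as a second code path in another language. Usage:

    python oracle_features.py <series.csv> <catalog.csv> <out.csv>

series.csv: one series per row, no header. catalog.csv: columns name,
feature_type,p1,p2,p3,s1,s2 (header). Output: matrix of feature values,
rows = series, columns = catalogue entries, no header.
"""
import csv
import sys

import numpy as np
from scipy import signal as ss
from scipy import stats as st


def agg(v, how):
    v = np.asarray(v, float)
    if v.size == 0:
        return 0.0
    return {
        "mean": np.mean, "var": lambda a: np.var(a), "median": np.median,
        "std": lambda a: np.std(a), "max": np.max, "min": np.min,
    }[how](v)


def linreg_idx(y):
    y = np.asarray(y, float)
    n = len(y)
    if n < 2:
        return 0.0, 0.0, 0.0, 1.0, 0.0
    if np.ptp(y) == 0.0:
        return 0.0, float(np.mean(y)), 0.0, 1.0, 0.0
    res = st.linregress(np.arange(n), y)
    return (res.slope, res.intercept, res.rvalue, res.pvalue, res.stderr)


def binned_entropy(v, bins):
    v = np.asarray(v, float)
    if np.ptp(v) == 0.0:
        return 0.0
    h, _ = np.histogram(v, bins=int(bins))
    p = h[h > 0] / len(v)
    return float(-np.sum(p * np.log(p)))


def sample_entropy(x):
    x = np.asarray(x, float)
    n = len(x)
    sd = np.std(x)
    if n < 4 or sd <= 0:
        return 0.0
    tol = 0.2 * sd
    def matches(m):
        nt = n - m + 1
    # pairwise Chebyshev over templates of length m
        tm = np.array([x[i:i + m] for i in range(nt)])
        cnt = 0
        for i in range(nt):
            d = np.max(np.abs(tm[i + 1:] - tm[i]), axis=1)
            cnt += int(np.sum(d <= tol))
        return cnt
    B = matches(2)
    # (m+1)-templates restricted to the n-m available
    nt = n - 2
    tm = np.array([x[i:i + 3] for i in range(nt)])
    A = 0
    for i in range(nt):
        d = np.max(np.abs(tm[i + 1:] - tm[i]), axis=1)
        A += int(np.sum(d <= tol))
    if A == 0 or B == 0:
        return 0.0
    return float(-np.log(A / B))


def approximate_entropy(x, m, rcoef):
    x = np.asarray(x, float)
    n = len(x)
    if n < m + 2:
        return 0.0
    r = rcoef * np.std(x)
    def phi(mm):
        cnt = n - mm + 1
        tm = np.array([x[i:i + mm] for i in range(cnt)])
        s = 0.0
        for i in range(cnt):
            d = np.max(np.abs(tm - tm[i]), axis=1)
            s += np.log(np.sum(d <= r) / cnt)
        return s / cnt
    return float(abs(phi(int(m)) - phi(int(m) + 1)))


def permutation_entropy(x, tau, dim):
    x = np.asarray(x, float)
    tau, dim = int(tau), int(dim)
    cnt = len(x) - (dim - 1) * tau
    if cnt < 1:
        return 0.0
    pats = {}
    for i in range(cnt):
        w = x[i:i + (dim - 1) * tau + 1:tau]
        key = tuple(np.argsort(w, kind="stable"))
        pats[key] = pats.get(key, 0) + 1
    p = np.array(list(pats.values())) / cnt
    return float(-np.sum(p * np.log(p)))


def fourier_entropy(x, bins):
    x = np.asarray(x, float)
    _, pxx = ss.welch(x, nperseg=min(len(x), 30), detrend="constant")
    mx = pxx.max()
    if mx <= 0:
        return 0.0
    return binned_entropy(pxx / mx, bins)


def benford(x):
    a = np.abs(np.asarray(x, float))
    a = a[np.isfinite(a) & (a > 0)]
    if a.size == 0:
        return 0.0
    d = (a / 10 ** np.floor(np.log10(a))).astype(int)
    f = np.array([np.mean(d == k) for k in range(1, 10)])
    if np.var(f) <= 0:
        return 0.0
    b = np.log10(1 + 1 / np.arange(1, 10))
    return float(np.corrcoef(f, b)[0, 1])


def number_peaks(x, support):
    x = np.asarray(x, float)
    n = len(x)
    support = int(support)
    cnt = 0
    for i in range(support, n - support):
        if all(x[i] > x[i - k] and x[i] > x[i + k]
               for k in range(1, support + 1)):
            cnt += 1
    return float(cnt)


def change_quantiles(x, ql, qh, isabs, how):
    x = np.asarray(x, float)
    if ql >= qh:
        return 0.0
    lo, hi = np.quantile(x, ql), np.quantile(x, qh)
    inside = (x >= lo) & (x <= hi)
    keep = inside[:-1] & inside[1:]
    d = np.diff(x)[keep]
    if isabs:
        d = np.abs(d)
    if d.size == 0:
        return 0.0
    return float(agg(d, how))


def autocorr(x, lag):
    x = np.asarray(x, float)
    lag = int(lag)
    n = len(x)
    if lag == 0:
        return 1.0
    v = np.var(x)
    if lag >= n or v <= 0:
        return 0.0
    m = np.mean(x)
    return float(np.sum((x[:n - lag] - m) * (x[lag:] - m)) / ((n - lag) * v))


def cwt_coef(x, coeff, width):
    x = np.asarray(x, float)
    n = len(x)
    coeff = int(coeff)
    if coeff >= n:
        return 0.0
    M = min(int(10 * width), n)
    t = np.arange(M) - (M - 1) / 2.0
    A = 2 / (np.sqrt(3 * width) * np.pi ** 0.25)
    w = A * (1 - (t / width) ** 2) * np.exp(-t ** 2 / (2 * width ** 2))
    return float(np.convolve(x, w, mode="same")[coeff])


def fft_aggregated(x, attr):
    S = np.abs(np.fft.rfft(x))
    tot = S.sum()
    if tot <= 0:
        return 0.0
    i = np.arange(len(S))
    mu = np.sum(i * S) / tot
    if attr == "centroid":
        return float(mu)
    m2 = np.sum((i - mu) ** 2 * S) / tot
    if attr == "variance":
        return float(m2)
    if m2 <= 0:
        return 0.0
    m3 = np.sum((i - mu) ** 3 * S) / tot
    m4 = np.sum((i - mu) ** 4 * S) / tot
    if attr == "skew":
        return float(m3 / m2 ** 1.5)
    return float(m4 / m2 ** 2)


def agg_linear_trend(x, chunk_len, how, attr):
    x = np.asarray(x, float)
    chunk_len = int(chunk_len)
    chunks = [x[i:i + chunk_len] for i in range(0, len(x), chunk_len)]
    if len(chunks) < 2:
        return 0.0
    a = [agg(c, how) for c in chunks]
    out = linreg_idx(a)
    return out[{"slope": 0, "intercept": 1, "rvalue": 2, "stderr": 4}[attr]]


def max_langevin(x, m, r):
    x = np.asarray(x, float)
    m, r = int(m), int(r)
    x0, dx = x[:-1], np.diff(x)
    n = len(x0)
    if n < m + 1:
        return 0.0
    edges = np.quantile(x0, np.arange(r + 1) / r)
    b = np.clip(np.searchsorted(edges, x0, side="right") - 1, 0, r - 1)
    mx, md = [], []
    for k in range(r):
        sel = b == k
        if sel.any():
            mx.append(x0[sel].mean())
            md.append(dx[sel].mean())
    if len(mx) < m + 1:
        return 0.0
    try:
        coef = np.polyfit(mx, md, m)
        rts = np.roots(coef)
    except Exception:
        return 0.0
    real = [z.real for z in rts
            if abs(z.imag) <= 1e-9 * (1 + abs(z.real))]
    if not real:
        return 0.0
    return float(max(real))


def evaluate(x, row):
    ft = row["feature_type"]
    p1 = float(row["p1"]) if row["p1"] != "" else 0.0
    p2 = float(row["p2"]) if row["p2"] != "" else 0.0
    p3 = float(row["p3"]) if row["p3"] != "" else 0.0
    s1, s2 = row["s1"], row["s2"]
    x = np.asarray(x, float)
    n = len(x)
    d = np.diff(x)
    if ft == "mean":
        return np.mean(x)
    if ft == "median":
        return np.median(x)
    if ft == "maximum":
        return np.max(x)
    if ft == "minimum":
        return np.min(x)
    if ft == "absolute_maximum":
        return np.max(np.abs(x))
    if ft == "standard_deviation":
        return np.std(x)
    if ft == "variance":
        return np.var(x)
    if ft == "variation_coefficient":
        m = np.mean(x)
        return np.std(x) / m if m != 0 else 0.0
    if ft == "root_mean_square":
        return np.sqrt(np.mean(x ** 2))
    if ft == "sum_values":
        return np.sum(x)
    if ft == "abs_energy":
        return np.sum(x ** 2)
    if ft == "mean_abs_change":
        return np.mean(np.abs(d))
    if ft == "absolute_sum_of_changes":
        return np.sum(np.abs(d))
    if ft == "sample_entropy":
        return sample_entropy(x)
    if ft == "benford_correlation":
        return benford(x)
    if ft == "binned_entropy":
        return binned_entropy(x, p1)
    if ft == "mean_n_absolute_max":
        k = int(p1)
        return 0.0 if k > n else float(np.mean(np.sort(np.abs(x))[::-1][:k]))
    if ft == "approximate_entropy":
        return approximate_entropy(x, p1, p2)
    if ft == "permutation_entropy":
        return permutation_entropy(x, p1, p2)
    if ft == "fourier_entropy":
        return fourier_entropy(x, p1)
    if ft == "cid_ce":
        if p1 != 0:
            sd = np.std(x)
            if sd <= 0:
                return 0.0
            x = (x - np.mean(x)) / sd
        return np.sqrt(np.sum(np.diff(x) ** 2))
    if ft == "number_crossing_m":
        pos = x > p1
        return float(np.sum(pos[:-1] != pos[1:]))
    if ft == "number_peaks":
        return number_peaks(x, p1)
    if ft == "count_above":
        return float(np.mean(x >= p1))
    if ft == "count_below":
        return float(np.mean(x <= p1))
    if ft == "range_count":
        return float(np.sum((x >= p1) & (x < p2)))
    if ft == "quantile":
        return float(np.quantile(x, p1))
    if ft == "change_quantiles":
        return change_quantiles(x, p1, p2, p3 != 0, s1)
    if ft == "autocorrelation":
        return autocorr(x, p1)
    if ft == "agg_autocorrelation":
        if np.var(x) <= 0:
            return 0.0
        maxlag = min(int(p1), n - 1)
        return float(agg([autocorr(x, l) for l in range(1, maxlag + 1)], s1))
    if ft == "c3":
        lag = int(p1)
        if n <= 2 * lag:
            return 0.0
        return float(np.mean(x[2 * lag:] * x[lag:n - lag] * x[:n - 2 * lag]))
    if ft == "cwt_coefficients":
        return cwt_coef(x, p1, p2)
    if ft == "fft_coefficient":
        v = np.fft.rfft(x)[int(p1)]
        return {"real": v.real, "imag": v.imag, "abs": abs(v),
                "angle": np.angle(v, deg=True)}[s1]
    if ft == "fft_aggregated":
        return fft_aggregated(x, s1)
    if ft == "linear_trend":
        out = linreg_idx(x)
        return out[{"slope": 0, "intercept": 1, "rvalue": 2, "pvalue": 3,
                    "stderr": 4}[s1]]
    if ft == "agg_linear_trend":
        return agg_linear_trend(x, p1, s2, s1)
    if ft == "max_langevin_fixed_point":
        return max_langevin(x, p1, p2)
    raise ValueError("unknown feature type: " + ft)


def main():
    series_csv, catalog_csv, out_csv = sys.argv[1:4]
    series = np.loadtxt(series_csv, delimiter=",", ndmin=2)
    with open(catalog_csv) as fh:
        cat = list(csv.DictReader(fh))
    out = np.zeros((series.shape[0], len(cat)))
    for i in range(series.shape[0]):
        for j, row in enumerate(cat):
            v = evaluate(series[i], row)
            out[i, j] = v if np.isfinite(v) else 0.0
    np.savetxt(out_csv, out, delimiter=",", fmt="%.17g")


if __name__ == "__main__":
    main()
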