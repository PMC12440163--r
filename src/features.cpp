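// Time-series feature engine.
//
// Evaluates the pinned feature catalogue on every keypoint-channel series of
// every analysis window. Feature types are dispatched on integer opcodes
// prepared on the R side; string parameters (aggregators, regression
// attributes) arrive as integer enums. Non-finite results are replaced by 0
// and counted, so the feature matrix is always finite.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>
using namespace Rcpp;

// opcodes (kept in sync with .feature_opcode() in R/features.R)
enum Op {
  OP_MEAN = 1, OP_MEDIAN, OP_MAX, OP_MIN, OP_ABSMAX, OP_STD, OP_VAR,
  OP_VARCOEF, OP_RMS, OP_SUM, OP_ABSENERGY, OP_MEANABSCHANGE,
  OP_ABSSUMCHANGES, OP_SAMPEN, OP_BENFORD, OP_BINNEDENT, OP_MEANNABSMAX,
  OP_APEN, OP_PERMENT, OP_FOURIERENT, OP_CIDCE, OP_NCROSS, OP_NPEAKS,
  OP_COUNTABOVE, OP_COUNTBELOW, OP_RANGECOUNT, OP_QUANTILE, OP_CHANGEQ,
  OP_AUTOCORR, OP_AGGAUTOCORR, OP_C3, OP_CWT, OP_FFTCOEF, OP_FFTAGG,
  OP_LINTREND, OP_AGGLINTREND, OP_LANGEVIN
};

// aggregator enum: mean=0 var=1 median=2 std=3 max=4 min=5
// linear-trend attr enum: slope=0 intercept=1 rvalue=2 pvalue=3 stderr=4
// fft attr enum: real=0 imag=1 abs=2 angle=3
// fft_aggregated enum: centroid=0 variance=1 skew=2 kurtosis=3

static double vec_mean(const arma::vec& v) {
  return v.n_elem ? arma::mean(v) : 0.0;
}

static double pop_var(const arma::vec& v) {
  if (v.n_elem == 0) return 0.0;
  double m = arma::mean(v);
  double s = 0.0;
  for (arma::uword i = 0; i < v.n_elem; ++i) s += (v[i] - m) * (v[i] - m);
  return s / v.n_elem;
}

static double quantile7(const arma::vec& sorted, double q) {
  int n = sorted.n_elem;
  if (n == 1) return sorted[0];
  double h = (n - 1) * q;
  int lo = (int)std::floor(h);
  if (lo >= n - 1) return sorted[n - 1];
  double frac = h - lo;
  return sorted[lo] + frac * (sorted[lo + 1] - sorted[lo]);
}

static double agg_apply(const arma::vec& v, int code) {
  if (v.n_elem == 0) return 0.0;
  switch (code) {
  case 0: return arma::mean(v);
  case 1: return pop_var(v);
  case 2: { arma::vec s = arma::sort(v); return quantile7(s, 0.5); }
  case 3: return std::sqrt(pop_var(v));
  case 4: return v.max();
  case 5: return v.min();
  }
  return 0.0;
}

// OLS of y against 0..n-1; out = {slope, intercept, rvalue, pvalue, stderr}
static void linreg_idx(const arma::vec& y, double* out) {
  int n = y.n_elem;
  if (n < 2) { out[0] = out[1] = out[2] = out[4] = 0.0; out[3] = 1.0; return; }
  double tm = (n - 1) / 2.0, ym = arma::mean(y);
  double sxx = 0.0, sxy = 0.0, syy = 0.0;
  for (int i = 0; i < n; ++i) {
    double dt = i - tm, dy = y[i] - ym;
    sxx += dt * dt; sxy += dt * dy; syy += dy * dy;
  }
  if (syy <= 0.0) {
    out[0] = 0.0; out[1] = ym; out[2] = 0.0; out[3] = 1.0; out[4] = 0.0;
    return;
  }
  double slope = sxy / sxx;
  double intercept = ym - slope * tm;
  double r = sxy / std::sqrt(sxx * syy);
  if (r > 1.0) r = 1.0; if (r < -1.0) r = -1.0;
  double p = 1.0, se = 0.0;
  if (n > 2) {
    double sse = syy - slope * sxy;
    if (sse < 0) sse = 0;
    se = std::sqrt(sse / (n - 2) / sxx);
    if (se > 0) {
      double t = slope / se;
      p = 2.0 * R::pt(-std::fabs(t), n - 2, 1, 0);
    } else {
      p = (slope == 0.0) ? 1.0 : 0.0;
    }
  }
  out[0] = slope; out[1] = intercept; out[2] = r; out[3] = p; out[4] = se;
}

// per-series context with lazy caches
struct Ctx {
  arma::vec x;
  int n;
  double mean, var, sd;
  arma::vec sorted, dif;
  bool has_fft = false;
  arma::cx_vec fft;
  void init(const arma::vec& xi) {
    x = xi; n = x.n_elem;
    mean = arma::mean(x);
    var = pop_var(x);
    sd = std::sqrt(var);
    sorted = arma::sort(x);
    dif = arma::diff(x);
    has_fft = false;
  }
  const arma::cx_vec& get_fft() {
    if (!has_fft) { fft = arma::fft(x); has_fft = true; }
    return fft;
  }
};

static double autocorr_lag(const Ctx& c, int lag) {
  if (lag == 0) return 1.0;
  if (lag >= c.n || c.var <= 0.0) return 0.0;
  double s = 0.0;
  for (int i = 0; i < c.n - lag; ++i)
    s += (c.x[i] - c.mean) * (c.x[i + lag] - c.mean);
  return s / ((c.n - lag) * c.var);
}

static double binned_entropy_vec(const arma::vec& v, int bins) {
  int n = v.n_elem;
  if (n == 0) return 0.0;
  double lo = v.min(), hi = v.max();
  if (hi - lo <= 0.0) return 0.0;
  std::vector<int> cnt(bins, 0);
  double w = (hi - lo) / bins;
  for (int i = 0; i < n; ++i) {
    int b = (int)((v[i] - lo) / w);
    if (b >= bins) b = bins - 1;
    if (b < 0) b = 0;
    cnt[b]++;
  }
  double e = 0.0;
  for (int b = 0; b < bins; ++b) {
    if (cnt[b] > 0) {
      double p = (double)cnt[b] / n;
      e -= p * std::log(p);
    }
  }
  return e;
}

static double sample_entropy(const Ctx& c) {
  int n = c.n, m = 2;
  double tol = 0.2 * c.sd;
  if (n < m + 2 || c.sd <= 0.0) return 0.0;
  long B = 0, A = 0;
  int nm = n - m + 1, nm1 = n - m;
  for (int i = 0; i < nm; ++i)
    for (int j = i + 1; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k)
        d = std::max(d, std::fabs(c.x[i + k] - c.x[j + k]));
      if (d <= tol) B++;
    }
  for (int i = 0; i < nm1; ++i)
    for (int j = i + 1; j < nm1; ++j) {
      double d = 0.0;
      for (int k = 0; k < m + 1; ++k)
        d = std::max(d, std::fabs(c.x[i + k] - c.x[j + k]));
      if (d <= tol) A++;
    }
  if (A == 0 || B == 0) return 0.0;
  return -std::log((double)A / (double)B);
}

static double approx_entropy(const Ctx& c, int m, double rcoef) {
  int n = c.n;
  if (n < m + 2) return 0.0;
  double r = rcoef * c.sd;
  auto phi = [&](int mm) {
    int cnt = n - mm + 1;
    double s = 0.0;
    for (int i = 0; i < cnt; ++i) {
      int match = 0;
      for (int j = 0; j < cnt; ++j) {
        double d = 0.0;
        for (int k = 0; k < mm; ++k)
          d = std::max(d, std::fabs(c.x[i + k] - c.x[j + k]));
        if (d <= r) match++;
      }
      s += std::log((double)match / cnt);
    }
    return s / cnt;
  };
  return std::fabs(phi(m) - phi(m + 1));
}

static double perm_entropy(const Ctx& c, int tau, int dim) {
  int n = c.n;
  int cnt = n - (dim - 1) * tau;
  if (cnt < 1) return 0.0;
  std::map<std::vector<int>, int> tab;
  std::vector<int> idx(dim);
  for (int i = 0; i < cnt; ++i) {
    for (int k = 0; k < dim; ++k) idx[k] = k;
    // stable argsort of the embedded vector
    std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
      return c.x[i + a * tau] < c.x[i + b * tau];
    });
    tab[idx]++;
  }
  double e = 0.0;
  for (auto& kv : tab) {
    double p = (double)kv.second / cnt;
    e -= p * std::log(p);
  }
  return e;
}

static double fourier_entropy(Ctx& c, int bins) {
  // single-segment Welch PSD: constant detrend, periodic Hann window;
  // scaling cancels under max-normalisation except for the one-sided
  // doubling of interior bins
  int n = c.n;
  arma::vec y(n);
  for (int i = 0; i < n; ++i) {
    double w = 0.5 - 0.5 * std::cos(2.0 * M_PI * i / n);
    y[i] = (c.x[i] - c.mean) * w;
  }
  arma::cx_vec F = arma::fft(y);
  int nb = n / 2 + 1;
  arma::vec p(nb);
  for (int k = 0; k < nb; ++k) {
    p[k] = std::norm(F[k]);
    bool interior = (k > 0) && !(n % 2 == 0 && k == nb - 1);
    if (interior) p[k] *= 2.0;
  }
  double mx = p.max();
  if (mx <= 0.0) return 0.0;
  return binned_entropy_vec(p / mx, bins);
}

static double benford_corr(const Ctx& c) {
  int cnt[9] = {0};
  int tot = 0;
  for (int i = 0; i < c.n; ++i) {
    double a = std::fabs(c.x[i]);
    if (!std::isfinite(a) || a <= 0.0) continue;
    int d = (int)(a / std::pow(10.0, std::floor(std::log10(a))));
    if (d >= 1 && d <= 9) { cnt[d - 1]++; tot++; }
  }
  if (tot == 0) return 0.0;
  arma::vec f(9), b(9);
  for (int d = 0; d < 9; ++d) {
    f[d] = (double)cnt[d] / tot;
    b[d] = std::log10(1.0 + 1.0 / (d + 1));
  }
  if (pop_var(f) <= 0.0) return 0.0;
  return arma::as_scalar(arma::cor(f, b));
}

static double number_peaks(const Ctx& c, int support) {
  int n = c.n, cnt = 0;
  for (int i = support; i < n - support; ++i) {
    bool ok = true;
    for (int k = 1; k <= support && ok; ++k)
      ok = (c.x[i] > c.x[i - k]) && (c.x[i] > c.x[i + k]);
    if (ok) cnt++;
  }
  return cnt;
}

static double change_quantiles(const Ctx& c, double ql, double qh, bool isabs,
                               int agg) {
  if (ql >= qh) return 0.0;
  double lo = quantile7(c.sorted, ql), hi = quantile7(c.sorted, qh);
  std::vector<double> d;
  for (int i = 0; i + 1 < c.n; ++i) {
    bool in0 = c.x[i] >= lo && c.x[i] <= hi;
    bool in1 = c.x[i + 1] >= lo && c.x[i + 1] <= hi;
    if (in0 && in1) {
      double v = c.x[i + 1] - c.x[i];
      d.push_back(isabs ? std::fabs(v) : v);
    }
  }
  if (d.empty()) return 0.0;
  return agg_apply(arma::vec(d), agg);
}

static double cwt_coef(const Ctx& c, int coeff, double width) {
  int n = c.n;
  int M = std::min((int)(10 * width), n);
  if (coeff >= n) return 0.0;
  arma::vec w(M);
  double A = 2.0 / (std::sqrt(3.0 * width) * std::pow(M_PI, 0.25));
  for (int k = 0; k < M; ++k) {
    double t = k - (M - 1) / 2.0;
    double q = t / width;
    w[k] = A * (1.0 - q * q) * std::exp(-t * t / (2.0 * width * width));
  }
  // 'same'-mode convolution value at index `coeff`
  int off = (M - 1) / 2;
  int k = coeff + off;        // index in the full convolution
  double s = 0.0;
  for (int j = 0; j < n; ++j) {
    int wi = k - j;
    if (wi >= 0 && wi < M) s += c.x[j] * w[wi];
  }
  return s;
}

static double fft_aggregated(Ctx& c, int attr) {
  const arma::cx_vec& F = c.get_fft();
  int nb = c.n / 2 + 1;
  double tot = 0.0, mu = 0.0;
  arma::vec S(nb);
  for (int k = 0; k < nb; ++k) { S[k] = std::abs(F[k]); tot += S[k]; }
  if (tot <= 0.0) return 0.0;
  for (int k = 0; k < nb; ++k) mu += k * S[k] / tot;
  if (attr == 0) return mu;
  double m2 = 0.0, m3 = 0.0, m4 = 0.0;
  for (int k = 0; k < nb; ++k) {
    double d = k - mu, wk = S[k] / tot;
    m2 += d * d * wk; m3 += d * d * d * wk; m4 += d * d * d * d * wk;
  }
  if (attr == 1) return m2;
  if (m2 <= 0.0) return 0.0;
  if (attr == 2) return m3 / std::pow(m2, 1.5);
  return m4 / (m2 * m2);
}

static double agg_linear_trend(const Ctx& c, int chunk_len, int agg,
                               int attr) {
  int n = c.n;
  int nch = (n + chunk_len - 1) / chunk_len;
  if (nch < 2) return 0.0;
  arma::vec a(nch);
  for (int i = 0; i < nch; ++i) {
    int s = i * chunk_len, e = std::min(n, s + chunk_len);
    a[i] = agg_apply(c.x.subvec(s, e - 1), agg);
  }
  double out[5];
  linreg_idx(a, out);
  return out[attr];
}

static double max_langevin(const Ctx& c, int m, int r) {
  int n = c.n - 1;
  if (n < m + 1) return 0.0;
  arma::vec x0 = c.x.subvec(0, n - 1);
  arma::vec dx = c.dif;
  arma::vec s = arma::sort(x0);
  // quantile-edge binning into r bins
  std::vector<double> edges(r + 1);
  for (int j = 0; j <= r; ++j) edges[j] = quantile7(s, (double)j / r);
  std::vector<double> sx(r, 0.0), sdx(r, 0.0);
  std::vector<int> cnt(r, 0);
  for (int i = 0; i < n; ++i) {
    int b = (int)(std::upper_bound(edges.begin(), edges.end(), x0[i]) -
                  edges.begin()) - 1;
    if (b >= r) b = r - 1;
    if (b < 0) b = 0;
    cnt[b]++; sx[b] += x0[i]; sdx[b] += dx[i];
  }
  std::vector<double> mx, md;
  for (int b = 0; b < r; ++b)
    if (cnt[b] > 0) { mx.push_back(sx[b] / cnt[b]); md.push_back(sdx[b] / cnt[b]); }
  int k = mx.size();
  if (k < m + 1) return 0.0;
  // least-squares polynomial fit of degree m (columns: descending powers)
  arma::mat V(k, m + 1);
  arma::vec y(k);
  for (int i = 0; i < k; ++i) {
    y[i] = md[i];
    double p = 1.0;
    for (int j = m; j >= 0; --j) { V(i, j) = p; p *= mx[i]; }
  }
  arma::vec coef;
  bool ok = arma::solve(coef, V, y);
  if (!ok) return 0.0;
  arma::cx_vec rts;
  try { rts = arma::roots(coef); } catch (...) { return 0.0; }
  double best = -std::numeric_limits<double>::infinity();
  for (arma::uword i = 0; i < rts.n_elem; ++i) {
    if (std::fabs(rts[i].imag()) <= 1e-9 * (1.0 + std::fabs(rts[i].real())))
      best = std::max(best, rts[i].real());
  }
  if (!std::isfinite(best)) return 0.0;
  return best;
}

static double eval_feature(Ctx& c, int op, double p1, double p2, double p3,
                           int e1, int e2) {
  const int n = c.n;
  switch (op) {
  case OP_MEAN: return c.mean;
  case OP_MEDIAN: return quantile7(c.sorted, 0.5);
  case OP_MAX: return c.x.max();
  case OP_MIN: return c.x.min();
  case OP_ABSMAX: return arma::abs(c.x).max();
  case OP_STD: return c.sd;
  case OP_VAR: return c.var;
  case OP_VARCOEF: return c.mean != 0.0 ? c.sd / c.mean : 0.0;
  case OP_RMS: return std::sqrt(arma::mean(arma::square(c.x)));
  case OP_SUM: return arma::sum(c.x);
  case OP_ABSENERGY: return arma::sum(arma::square(c.x));
  case OP_MEANABSCHANGE:
    return n > 1 ? arma::mean(arma::abs(c.dif)) : 0.0;
  case OP_ABSSUMCHANGES:
    return n > 1 ? arma::sum(arma::abs(c.dif)) : 0.0;
  case OP_SAMPEN: return sample_entropy(c);
  case OP_BENFORD: return benford_corr(c);
  case OP_BINNEDENT: return binned_entropy_vec(c.x, (int)p1);
  case OP_MEANNABSMAX: {
    int k = (int)p1;
    if (k > n) return 0.0;
    arma::vec a = arma::sort(arma::abs(c.x), "descend");
    return arma::mean(a.subvec(0, k - 1));
  }
  case OP_APEN: return approx_entropy(c, (int)p1, p2);
  case OP_PERMENT: return perm_entropy(c, (int)p1, (int)p2);
  case OP_FOURIERENT: return fourier_entropy(c, (int)p1);
  case OP_CIDCE: {
    if (n < 2) return 0.0;
    if (p1 != 0.0) {
      if (c.sd <= 0.0) return 0.0;
      double s = 0.0;
      for (int i = 0; i + 1 < n; ++i) {
        double d = (c.x[i + 1] - c.x[i]) / c.sd;
        s += d * d;
      }
      return std::sqrt(s);
    }
    return std::sqrt(arma::sum(arma::square(c.dif)));
  }
  case OP_NCROSS: {
    int cnt = 0;
    for (int i = 0; i + 1 < n; ++i)
      if ((c.x[i] > p1) != (c.x[i + 1] > p1)) cnt++;
    return cnt;
  }
  case OP_NPEAKS: return number_peaks(c, (int)p1);
  case OP_COUNTABOVE: {
    int cnt = 0;
    for (int i = 0; i < n; ++i) if (c.x[i] >= p1) cnt++;
    return (double)cnt / n;
  }
  case OP_COUNTBELOW: {
    int cnt = 0;
    for (int i = 0; i < n; ++i) if (c.x[i] <= p1) cnt++;
    return (double)cnt / n;
  }
  case OP_RANGECOUNT: {
    int cnt = 0;
    for (int i = 0; i < n; ++i) if (c.x[i] >= p1 && c.x[i] < p2) cnt++;
    return cnt;
  }
  case OP_QUANTILE: return quantile7(c.sorted, p1);
  case OP_CHANGEQ: return change_quantiles(c, p1, p2, p3 != 0.0, e1);
  case OP_AUTOCORR: return autocorr_lag(c, (int)p1);
  case OP_AGGAUTOCORR: {
    if (c.var <= 0.0) return 0.0;
    int maxlag = std::min((int)p1, n - 1);
    if (maxlag < 1) return 0.0;
    arma::vec a(maxlag);
    for (int l = 1; l <= maxlag; ++l) a[l - 1] = autocorr_lag(c, l);
    return agg_apply(a, e1);
  }
  case OP_C3: {
    int lag = (int)p1;
    if (n <= 2 * lag) return 0.0;
    double s = 0.0;
    for (int i = 0; i < n - 2 * lag; ++i)
      s += c.x[i + 2 * lag] * c.x[i + lag] * c.x[i];
    return s / (n - 2 * lag);
  }
  case OP_CWT: return cwt_coef(c, (int)p1, p2);
  case OP_FFTCOEF: {
    int k = (int)p1;
    if (k > n / 2) return NA_REAL;     // guarded on the R side
    const arma::cx_vec& F = c.get_fft();
    std::complex<double> v = F[k];
    switch (e1) {
    case 0: return v.real();
    case 1: return v.imag();
    case 2: return std::abs(v);
    case 3: return std::arg(v) * 180.0 / M_PI;
    }
    return 0.0;
  }
  case OP_FFTAGG: return fft_aggregated(c, e1);
  case OP_LINTREND: {
    double out[5];
    linreg_idx(c.x, out);
    return out[e1];
  }
  case OP_AGGLINTREND: return agg_linear_trend(c, (int)p1, e2, e1);
  case OP_LANGEVIN: return max_langevin(c, (int)p1, (int)p2);
  }
  return 0.0;
}

// windows: list of T x C matrices (same shape); catalog opcode/param vectors.
// Returns (n_windows) x (C * K) matrix, channel-major blocks, with the count
// of non-finite replacements in attribute "n_nonfinite".
// [[Rcpp::export]]
NumericMatrix compute_features_engine(List windows, IntegerVector op,
                                      NumericVector p1, NumericVector p2,
                                      NumericVector p3, IntegerVector e1,
                                      IntegerVector e2) {
  int nw = windows.size();
  int K = op.size();
  if (nw == 0) stop("no windows");
  NumericMatrix w0 = windows[0];
  int C = w0.ncol();
  NumericMatrix out(nw, C * K);
  long nonfinite = 0;
  Ctx ctx;
  for (int wi = 0; wi < nw; ++wi) {
    NumericMatrix wm = windows[wi];
    if (wm.ncol() != C || wm.nrow() != w0.nrow())
      stop("window shape mismatch at window %d", wi + 1);
    for (int ci = 0; ci < C; ++ci) {
      arma::vec x(wm.nrow());
      for (int t = 0; t < wm.nrow(); ++t) x[t] = wm(t, ci);
      ctx.init(x);
      for (int k = 0; k < K; ++k) {
        double v = eval_feature(ctx, op[k], p1[k], p2[k], p3[k], e1[k], e2[k]);
        if (!std::isfinite(v)) { v = 0.0; nonfinite++; }
        out(wi, ci * K + k) = v;
      }
    }
    if (wi % 64 == 0) Rcpp::checkUserInterrupt();
  }
  out.attr("n_nonfinite") = (double)nonfinite;
  return out;
}

// Column-wise midranks plus tie corrections for the Mann-Whitney tests:
// returns the rank matrix with attributes "tie_term" (sum of t^3 - t over
// tie groups, per column) and "is_const" (logical per column).
// [[Rcpp::export]]
NumericMatrix col_midranks(NumericMatrix x) {
  int n = x.nrow(), p = x.ncol();
  NumericMatrix out(n, p);
  NumericVector tie_term(p);
  LogicalVector is_const(p);
  std::vector<int> idx(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    NumericMatrix::Column col = x(_, j);
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      return col[a] < col[b];
    });
    double tt = 0.0;
    int i = 0;
    while (i < n) {
      int k = i;
      while (k + 1 < n && col[idx[k + 1]] == col[idx[i]]) ++k;
      double r = (i + k) / 2.0 + 1.0;     // midrank (1-based)
      for (int m = i; m <= k; ++m) out(idx[m], j) = r;
      double t = k - i + 1;
      if (t > 1) tt += t * t * t - t;
      i = k + 1;
    }
    tie_term[j] = tt;
    is_const[j] = (col[idx[n - 1]] == col[idx[0]]);
  }
  out.attr("tie_term") = tie_term;
  out.attr("is_const") = is_const;
  return out;
}
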