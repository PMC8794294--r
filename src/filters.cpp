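#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial state zi (length n-1),
// a[0] assumed 1. In-place over x.
static void lfilter(const std::vector<double>& b, const std::vector<double>& a,
                    std::vector<double>& x, const std::vector<double>& zi,
                    double scale) {
  const int n = (int)b.size();          // b and a padded to equal length
  std::vector<double> z(n - 1);
  for (int i = 0; i < n - 1; ++i) z[i] = zi[i] * scale;
  const int N = (int)x.size();
  for (int i = 0; i < N; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (int j = 0; j < n - 2; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    z[n - 2] = b[n - 1] * xi - a[n - 1] * yi;
    x[i] = yi;
  }
}

// Zero-phase (forward-backward) filtering of every column of X, with
// odd-reflection padding of length padlen and step-matched initial
// conditions zi (computed in R once per filter design).
// [[Rcpp::export(name = ".cpp_filtfilt_mat")]]
NumericMatrix cpp_filtfilt_mat(NumericVector b_, NumericVector a_,
                               NumericVector zi_, NumericMatrix X,
                               int padlen) {
  const int n = std::max(b_.size(), a_.size());
  std::vector<double> b(n, 0.0), a(n, 0.0), zi(n - 1);
  for (int i = 0; i < b_.size(); ++i) b[i] = b_[i];
  for (int i = 0; i < a_.size(); ++i) a[i] = a_[i];
  for (int i = 0; i < n - 1; ++i) zi[i] = zi_[i];

  const int N = X.nrow(), C = X.ncol();
  if (N <= padlen)
    stop("series too short for zero-phase filtering (need > %d samples)",
         padlen);
  NumericMatrix out(N, C);
  std::vector<double> w(N + 2 * padlen);
  for (int c = 0; c < C; ++c) {
    // odd (anti-symmetric) reflection about the end samples
    for (int i = 0; i < padlen; ++i)
      w[i] = 2.0 * X(0, c) - X(padlen - i, c);
    for (int i = 0; i < N; ++i) w[padlen + i] = X(i, c);
    for (int i = 0; i < padlen; ++i)
      w[padlen + N + i] = 2.0 * X(N - 1, c) - X(N - 2 - i, c);

    lfilter(b, a, w, zi, w[0]);
    std::reverse(w.begin(), w.end());
    lfilter(b, a, w, zi, w[0]);
    std::reverse(w.begin(), w.end());
    for (int i = 0; i < N; ++i) out(i, c) = w[padlen + i];
  }
  return out;
}

// ---- periodized orthogonal DWT despiking -------------------------------
// Analysis: a[k] = sum_m h0[m] x[(2k+m) mod N]; d[k] likewise with h1.
// For an orthonormal filter bank the synthesis operator is the transpose,
// so reconstruction scatters h0[m]*a[k] + h1[m]*d[k] back to (2k+m) mod N.

static void dwt_step(const std::vector<double>& x, int N,
                     const std::vector<double>& h0,
                     const std::vector<double>& h1,
                     std::vector<double>& approx, std::vector<double>& detail) {
  const int L = (int)h0.size(), half = N / 2;
  for (int k = 0; k < half; ++k) {
    double a = 0.0, d = 0.0;
    for (int m = 0; m < L; ++m) {
      int idx = (2 * k + m) % N;
      a += h0[m] * x[idx];
      d += h1[m] * x[idx];
    }
    approx[k] = a;
    detail[k] = d;
  }
}

static void idwt_step(const std::vector<double>& approx,
                      const std::vector<double>& detail, int half,
                      const std::vector<double>& h0,
                      const std::vector<double>& h1,
                      std::vector<double>& x) {
  const int L = (int)h0.size(), N = 2 * half;
  std::fill(x.begin(), x.begin() + N, 0.0);
  for (int k = 0; k < half; ++k) {
    for (int m = 0; m < L; ++m) {
      int idx = (2 * k + m) % N;
      x[idx] += h0[m] * approx[k] + h1[m] * detail[k];
    }
  }
}

static double mad_scale(const std::vector<double>& d, int n) {
  std::vector<double> tmp(d.begin(), d.begin() + n);
  std::vector<double> absdev(n);
  std::nth_element(tmp.begin(), tmp.begin() + n / 2, tmp.begin() + n);
  double med;
  if (n % 2 == 1) med = tmp[n / 2];
  else {
    double hi = tmp[n / 2];
    double lo = *std::max_element(tmp.begin(), tmp.begin() + n / 2);
    med = 0.5 * (lo + hi);
  }
  for (int i = 0; i < n; ++i) absdev[i] = std::fabs(d[i] - med);
  std::nth_element(absdev.begin(), absdev.begin() + n / 2, absdev.end());
  double mad;
  if (n % 2 == 1) mad = absdev[n / 2];
  else {
    double hi = absdev[n / 2];
    double lo = *std::max_element(absdev.begin(), absdev.begin() + n / 2);
    mad = 0.5 * (lo + hi);
  }
  return 1.4826 * mad;  // consistent with stats::mad
}

// Columns of X must have length divisible by 2^levels (the R wrapper pads).
// Detail coefficients with |c| > k * (1.4826 * MAD) per level are set to
// zero (hard thresholding of outlying coefficients only); k <= 0 or
// non-finite k disables thresholding (pure analysis/synthesis round trip).
// [[Rcpp::export(name = ".cpp_dwt_despike")]]
NumericMatrix cpp_dwt_despike(NumericMatrix X, NumericVector h0_,
                              NumericVector h1_, int levels, double k) {
  const int N = X.nrow(), C = X.ncol();
  if (N % (1 << levels) != 0)
    stop("series length must be divisible by 2^levels");
  std::vector<double> h0(h0_.begin(), h0_.end());
  std::vector<double> h1(h1_.begin(), h1_.end());
  NumericMatrix out(N, C);
  std::vector<double> cur(N), approx(N / 2), buf(N);
  std::vector<std::vector<double>> details(levels);
  for (int lev = 0; lev < levels; ++lev)
    details[lev].assign(N >> (lev + 1), 0.0);
  for (int c = 0; c < C; ++c) {
    for (int i = 0; i < N; ++i) cur[i] = X(i, c);
    int n = N;
    for (int lev = 0; lev < levels; ++lev) {
      dwt_step(cur, n, h0, h1, approx, details[lev]);
      n /= 2;
      std::copy(approx.begin(), approx.begin() + n, cur.begin());
    }
    if (R_finite(k) && k > 0) {
      int m = N;
      for (int lev = 0; lev < levels; ++lev) {
        m /= 2;
        double s = mad_scale(details[lev], m);
        if (s > 0) {
          double thr = k * s;
          for (int i = 0; i < m; ++i)
            if (std::fabs(details[lev][i]) > thr) details[lev][i] = 0.0;
        }
      }
    }
    // reconstruct from the deepest approximation upward
    for (int lev = levels - 1; lev >= 0; --lev) {
      int half = N >> (lev + 1);
      std::copy(cur.begin(), cur.begin() + half, approx.begin());
      idwt_step(approx, details[lev], half, h0, h1, buf);
      std::copy(buf.begin(), buf.begin() + 2 * half, cur.begin());
    }
    for (int i = 0; i < N; ++i) out(i, c) = cur[i];
  }
  return out;
}
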