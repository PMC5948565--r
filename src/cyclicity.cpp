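#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double EPS = 1e-12;

// Sakoe-Chiba radius used by the DTW estimator: max(2, round(N/10)).
static int band_for(int N) {
  int b = (int)std::lround(N / 10.0);
  return b < 2 ? 2 : b;
}

// Banded DTW cost between equal-length sequences, |.| local cost.
// Cells outside |i - j| <= band are unreachable.
static double dtw_cost(const double *a, const double *b, int n, int band) {
  std::vector<double> prev(n + 1, R_PosInf), cur(n + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), R_PosInf);
    int jlo = std::max(1, i - band), jhi = std::min(n, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      double c = std::fabs(a[i - 1] - b[j - 1]);
      double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// [[Rcpp::export]]
double dtw_banded_(NumericVector a, NumericVector b, int band) {
  if (a.size() != b.size())
    stop("dtw_banded_: sequences must have equal length");
  if (a.size() == 0) stop("dtw_banded_: empty sequences");
  if (band < 0) stop("dtw_banded_: band must be >= 0");
  return dtw_cost(REAL(a), REAL(b), (int)a.size(), band);
}

// Raw cyclicity scores for one window channel.
// w: window values for lags -K..K; zero_idx: 0-based index of lag 0.
// Returns (Nmax - Nmin + 1) x 4 matrix; columns are estimators 1..4,
// unselected estimators filled with NA.
// [[Rcpp::export]]
NumericMatrix score_window_(NumericVector w, int zero_idx, int Nmin, int Nmax,
                            IntegerVector estimators, int dtw_band) {
  int len = w.size();
  if (Nmin < 1 || Nmin > Nmax) stop("score_window_: invalid N range");
  if (zero_idx - Nmax < 0 || zero_idx + Nmax - 1 >= len)
    stop("score_window_: window too short for Nmax");

  bool use[5] = {false, false, false, false, false};
  for (int i = 0; i < estimators.size(); ++i) {
    int e = estimators[i];
    if (e < 1 || e > 4) stop("score_window_: estimator labels must be 1..4");
    use[e] = true;
  }

  int nN = Nmax - Nmin + 1;
  NumericMatrix out(nN, 4);
  std::fill(out.begin(), out.end(), NA_REAL);
  const double *x = REAL(w);
  const double *z = x + zero_idx;  // z[v] = w(lag v)

  for (int r = 0; r < nN; ++r) {
    int N = Nmin + r;
    if (use[1]) {
      double s = 0.0;
      for (int v = 0; v < N; ++v) s += z[v] * z[v - N];
      out(r, 0) = s / N;
    }
    if (use[2]) {
      double s = 0.0;
      for (int v = 0; v < N; ++v) s += std::fabs(z[v] - z[v - N]);
      out(r, 1) = 1.0 / (EPS + s / N);
    }
    if (use[3]) {
      double m = R_NegInf;
      for (int v = 0; v < N; ++v) {
        double p = z[v] + z[v - N];
        if (p > m) m = p;
      }
      out(r, 2) = m;
    }
    if (use[4]) {
      int band = dtw_band >= 0 ? dtw_band : band_for(N);
      double c = dtw_cost(z - N, z, N, band);
      out(r, 3) = 1.0 / (EPS + c);
    }
  }
  return out;
}
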