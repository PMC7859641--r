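#include <Rcpp.h>
using namespace Rcpp;

// Exact DTW: minimum summed Euclidean point-pair distance over all monotone
// alignments anchored at both endpoint pairs. Two-row dynamic program; the
// first row/column are peeled off to keep the hot loop branch-free.
// [[Rcpp::export]]
double dtw_cost_cpp(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  const double *ax = &A(0, 0), *ay = &A(0, 1);
  const double *bx = &B(0, 0), *by = &B(0, 1);
  std::vector<double> prev(m), cur(m);
  double acc = 0.0;
  for (int j = 0; j < m; ++j) {
    double dx = ax[0] - bx[j], dy = ay[0] - by[j];
    acc += std::sqrt(dx * dx + dy * dy);
    prev[j] = acc;
  }
  for (int i = 1; i < n; ++i) {
    double dx = ax[i] - bx[0], dy = ay[i] - by[0];
    cur[0] = prev[0] + std::sqrt(dx * dx + dy * dy);
    for (int j = 1; j < m; ++j) {
      dx = ax[i] - bx[j];
      dy = ay[i] - by[j];
      double best = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
      cur[j] = std::sqrt(dx * dx + dy * dy) + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// Discrete Frechet distance: minimax coupling dynamic program.
// [[Rcpp::export]]
double frechet_cost_cpp(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  const double *ax = &A(0, 0), *ay = &A(0, 1);
  const double *bx = &B(0, 0), *by = &B(0, 1);
  std::vector<double> prev(m), cur(m);
  for (int j = 0; j < m; ++j) {
    double dx = ax[0] - bx[j], dy = ay[0] - by[j];
    double d = std::sqrt(dx * dx + dy * dy);
    prev[j] = (j == 0) ? d : std::max(prev[j - 1], d);
  }
  for (int i = 1; i < n; ++i) {
    double dx = ax[i] - bx[0], dy = ay[i] - by[0];
    cur[0] = std::max(prev[0], std::sqrt(dx * dx + dy * dy));
    for (int j = 1; j < m; ++j) {
      dx = ax[i] - bx[j];
      dy = ay[i] - by[j];
      double d = std::sqrt(dx * dx + dy * dy);
      double best = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
      cur[j] = std::max(best, d);
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// All-pairs upper-triangle driver. measure: 0 = dtw, 1 = frechet.
// [[Rcpp::export]]
NumericMatrix pairwise_cost_cpp(List paths, int measure) {
  int n = paths.size();
  NumericMatrix out(n, n);
  std::vector<NumericMatrix> mats(n);
  for (int i = 0; i < n; ++i) mats[i] = as<NumericMatrix>(paths[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = (measure == 0) ? dtw_cost_cpp(mats[i], mats[j])
                                : frechet_cost_cpp(mats[i], mats[j]);
      out(i, j) = d;
      out(j, i) = d;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
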