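// Scaled-probability dynamic programming kernels for the conditional
// memoryless edit transducer. Lattices are (nx+1) x (ny+1); each alpha/beta
// row is rescaled by its maximum so that strings at the 1020-character cap
// stay inside double range, with per-row log scale factors carried
// alongside. Letters arrive as 1-based indices into the alphabet.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Fill scaled forward lattice. A has (nx+1)*(ny+1) entries, row-major
// (index i * (ny+1) + j). rowlog[i] is the log of the cumulative scale of
// row i: alpha_true[i][j] = A[i][j] * exp(rowlog[i]).
// Returns log p(y|x) (may be -inf).
static double fill_forward(const std::vector<int>& x, const std::vector<int>& y,
                           const NumericVector& ins, const NumericMatrix& sub,
                           const NumericVector& del, double gamma,
                           std::vector<double>& A, std::vector<double>& rowlog) {
  int nx = x.size(), ny = y.size();
  int W = ny + 1;
  A.assign((nx + 1) * W, 0.0);
  rowlog.assign(nx + 1, 0.0);

  // row 0: only insertions
  A[0] = 1.0;
  for (int j = 1; j <= ny; ++j) A[j] = ins[y[j - 1] - 1] * A[j - 1];
  double m0 = 0.0;
  for (int j = 0; j <= ny; ++j) if (A[j] > m0) m0 = A[j];
  if (m0 > 0.0 && m0 != 1.0) {
    for (int j = 0; j <= ny; ++j) A[j] /= m0;
    rowlog[0] = std::log(m0);
  }

  for (int i = 1; i <= nx; ++i) {
    double* cur = &A[i * W];
    const double* prev = &A[(i - 1) * W];
    int xi = x[i - 1] - 1;
    double d = del[xi];
    // relative to row i-1's scale
    cur[0] = d * prev[0];
    for (int j = 1; j <= ny; ++j) {
      int yj = y[j - 1] - 1;
      cur[j] = ins[yj] * cur[j - 1] + d * prev[j] + sub(xi, yj) * prev[j - 1];
    }
    double m = 0.0;
    for (int j = 0; j <= ny; ++j) if (cur[j] > m) m = cur[j];
    if (m > 0.0) {
      for (int j = 0; j <= ny; ++j) cur[j] /= m;
      rowlog[i] = rowlog[i - 1] + std::log(m);
    } else {
      rowlog[i] = rowlog[i - 1];  // row is all zero; values stay 0
    }
  }
  double aend = A[nx * W + ny];
  if (aend <= 0.0 || gamma <= 0.0) return NEG_INF;
  return std::log(gamma) + std::log(aend) + rowlog[nx];
}

// Fill scaled backward lattice: beta_true[i][j] = B[i][j] * exp(rowlog[i]).
static void fill_backward(const std::vector<int>& x, const std::vector<int>& y,
                          const NumericVector& ins, const NumericMatrix& sub,
                          const NumericVector& del, double gamma,
                          std::vector<double>& B, std::vector<double>& rowlog) {
  int nx = x.size(), ny = y.size();
  int W = ny + 1;
  B.assign((nx + 1) * W, 0.0);
  rowlog.assign(nx + 1, 0.0);

  // row nx: input exhausted, only insertions then stop
  double* last = &B[nx * W];
  last[ny] = gamma;
  for (int j = ny - 1; j >= 0; --j) last[j] = ins[y[j] - 1] * last[j + 1];
  double m0 = 0.0;
  for (int j = 0; j <= ny; ++j) if (last[j] > m0) m0 = last[j];
  if (m0 > 0.0) {
    for (int j = 0; j <= ny; ++j) last[j] /= m0;
    rowlog[nx] = std::log(m0);
  }

  for (int i = nx - 1; i >= 0; --i) {
    double* cur = &B[i * W];
    const double* next = &B[(i + 1) * W];
    int xi = x[i] - 1;  // next input letter from state (i, j)
    double d = del[xi];
    cur[ny] = d * next[ny];
    for (int j = ny - 1; j >= 0; --j) {
      int yj = y[j] - 1;
      cur[j] = ins[yj] * cur[j + 1] + d * next[j] + sub(xi, yj) * next[j + 1];
    }
    double m = 0.0;
    for (int j = 0; j <= ny; ++j) if (cur[j] > m) m = cur[j];
    if (m > 0.0) {
      for (int j = 0; j <= ny; ++j) cur[j] /= m;
      rowlog[i] = rowlog[i + 1] + std::log(m);
    } else {
      rowlog[i] = rowlog[i + 1];
    }
  }
}

static std::vector<int> as_idx(SEXP v) {
  IntegerVector iv(v);
  return std::vector<int>(iv.begin(), iv.end());
}

// [[Rcpp::export]]
NumericVector sed_loglik_cpp(List xs, List ys, NumericVector ins,
                             NumericMatrix sub, NumericVector del,
                             double gamma) {
  int n = xs.size();
  NumericVector out(n);
  std::vector<double> A, rl;
  for (int k = 0; k < n; ++k) {
    std::vector<int> x = as_idx(xs[k]), y = as_idx(ys[k]);
    out[k] = fill_forward(x, y, ins, sub, del, gamma, A, rl);
  }
  return out;
}

// Accumulated posterior expected operation counts plus total loglik over a
// list of pairs. pair_loglik reports each pair's log p(y|x) so callers can
// identify unexplainable pairs.
// [[Rcpp::export]]
List sed_counts_cpp(List xs, List ys, NumericVector ins, NumericMatrix sub,
                    NumericVector del, double gamma) {
  int n = xs.size();
  int Az = ins.size();
  NumericVector n_ins(Az), n_del(Az);
  NumericMatrix n_sub(Az, Az);
  NumericVector pair_ll(n);
  double total_ll = 0.0;
  std::vector<double> A, B, ra, rb;

  for (int k = 0; k < n; ++k) {
    std::vector<int> x = as_idx(xs[k]), y = as_idx(ys[k]);
    int nx = x.size(), ny = y.size();
    int W = ny + 1;
    double lp = fill_forward(x, y, ins, sub, del, gamma, A, ra);
    pair_ll[k] = lp;
    if (!std::isfinite(lp)) { total_ll = NEG_INF; continue; }
    total_ll += lp;
    fill_backward(x, y, ins, sub, del, gamma, B, rb);

    // deletions and substitutions: consume x[i-1] moving into row i
    for (int i = 1; i <= nx; ++i) {
      int xi = x[i - 1] - 1;
      double lf = ra[i - 1] + rb[i] - lp;
      const double* ap = &A[(i - 1) * W];
      const double* bp = &B[i * W];
      double d = del[xi];
      if (lf < 700.0) {
        double F = std::exp(lf);
        double acc_d = 0.0;
        for (int j = 0; j <= ny; ++j) acc_d += ap[j] * bp[j];
        n_del[xi] += F * d * acc_d;
        for (int j = 1; j <= ny; ++j) {
          int yj = y[j - 1] - 1;
          double t = ap[j - 1] * bp[j];
          if (t > 0.0) n_sub(xi, yj) += F * sub(xi, yj) * t;
        }
      } else {
        // rare overflow-guard path: per-cell log-space accumulation
        for (int j = 0; j <= ny; ++j) {
          double t = ap[j] * bp[j];
          if (t > 0.0 && d > 0.0)
            n_del[xi] += std::exp(lf + std::log(d * t));
          if (j >= 1) {
            int yj = y[j - 1] - 1;
            double s = sub(xi, yj) * ap[j - 1] * bp[j];
            if (s > 0.0) n_sub(xi, yj) += std::exp(lf + std::log(s));
          }
        }
      }
    }
    // insertions: emit y[j-1] within row i
    for (int i = 0; i <= nx; ++i) {
      double lf = ra[i] + rb[i] - lp;
      const double* ap = &A[i * W];
      const double* bp = &B[i * W];
      if (lf < 700.0) {
        double F = std::exp(lf);
        for (int j = 1; j <= ny; ++j) {
          int yj = y[j - 1] - 1;
          double t = ap[j - 1] * bp[j];
          if (t > 0.0) n_ins[yj] += F * ins[yj] * t;
        }
      } else {
        for (int j = 1; j <= ny; ++j) {
          int yj = y[j - 1] - 1;
          double s = ins[yj] * ap[j - 1] * bp[j];
          if (s > 0.0) n_ins[yj] += std::exp(lf + std::log(s));
        }
      }
    }
  }

  return List::create(_["n_ins"] = n_ins, _["n_sub"] = n_sub,
                      _["n_del"] = n_del, _["n_end"] = (double)n,
                      _["loglik"] = total_ll, _["pair_loglik"] = pair_ll);
}
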