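// Sequential minimal optimization solver for soft-margin kernel SVMs,
// plus a one-vs-one cross-validation driver used as the genetic
// algorithm's fitness engine. The wrapper GA evaluates thousands of
// candidate feature subsets, each with a full 10-fold CV of a cubic-kernel
// SVM; the kernel Gram matrix is computed once per candidate and shared
// across folds and class pairs, which is what makes the wrapper tractable.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

const double TAU = 1e-12;

// Two-variable SMO with maximal-violating-pair working-set selection on a
// precomputed kernel. `rows` maps local indices to rows of K. Labels are
// +/-1. Returns alpha (local order) and the bias b of the decision
// function f(x) = sum_i alpha_i y_i K(x_i, x) + b.
struct BinarySvm {
  std::vector<double> alpha;
  double b;
  int iter;
};

BinarySvm solve_binary(const NumericMatrix& K,
                       const std::vector<int>& rows,
                       const std::vector<double>& yv,
                       double C, double eps, int max_iter) {
  const int n = (int)rows.size();
  BinarySvm out;
  out.alpha.assign(n, 0.0);
  out.b = 0.0;
  out.iter = 0;

  // contiguous copy of the subproblem kernel: the SMO loop is memory bound
  std::vector<double> Ks((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) Ks[(size_t)i * n + j] = K(rows[i], rows[j]);
  }

  // grad_t = (Q alpha)_t - 1 with Q_ij = y_i y_j K_ij; alpha = 0 initially.
  std::vector<double> grad(n, -1.0);

  int it = 0;
  for (; it < max_iter; ++it) {
    // second-order working-set selection (libsvm WSS2): i maximizes the
    // KKT violation -y g over I_up; j in I_low maximizes the decrease of
    // the dual objective when paired with i
    int i = -1, j = -1;
    double gmax = -INFINITY, gmin = INFINITY;
    for (int t = 0; t < n; ++t) {
      double v = -yv[t] * grad[t];
      bool in_up = (yv[t] > 0) ? (out.alpha[t] < C - TAU) : (out.alpha[t] > TAU);
      if (in_up && v > gmax) { gmax = v; i = t; }
    }
    if (i < 0) break;
    const double* Ki = &Ks[(size_t)i * n];
    double best_obj = -INFINITY;
    for (int t = 0; t < n; ++t) {
      double v = -yv[t] * grad[t];
      bool in_low = (yv[t] > 0) ? (out.alpha[t] > TAU) : (out.alpha[t] < C - TAU);
      if (!in_low) continue;
      if (v < gmin) gmin = v;
      double b_it = gmax - v;
      if (b_it > TAU) {
        double a_it = Ki[i] + Ks[(size_t)t * n + t] - 2.0 * yv[i] * yv[t] * Ki[t];
        if (a_it <= 0) a_it = TAU;
        double obj = b_it * b_it / a_it;
        if (obj > best_obj) { best_obj = obj; j = t; }
      }
    }
    if (j < 0 || gmax - gmin < eps) break;

    const double* Kj = &Ks[(size_t)j * n];
    double Kii = Ki[i];
    double Kjj = Kj[j];
    double Kij = Ki[j];
    double ai_old = out.alpha[i], aj_old = out.alpha[j];

    if (yv[i] != yv[j]) {
      double quad = Kii + Kjj + 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      double delta = (-grad[i] - grad[j]) / quad;
      double diff = out.alpha[i] - out.alpha[j];
      out.alpha[i] += delta;
      out.alpha[j] += delta;
      if (diff > 0) {
        if (out.alpha[j] < 0) { out.alpha[j] = 0; out.alpha[i] = diff; }
      } else {
        if (out.alpha[i] < 0) { out.alpha[i] = 0; out.alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (out.alpha[i] > C) { out.alpha[i] = C; out.alpha[j] = C - diff; }
      } else {
        if (out.alpha[j] > C) { out.alpha[j] = C; out.alpha[i] = C + diff; }
      }
    } else {
      double quad = Kii + Kjj - 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      double delta = (grad[i] - grad[j]) / quad;
      double sum = out.alpha[i] + out.alpha[j];
      out.alpha[i] -= delta;
      out.alpha[j] += delta;
      if (sum > C) {
        if (out.alpha[i] > C) { out.alpha[i] = C; out.alpha[j] = sum - C; }
      } else {
        if (out.alpha[j] < 0) { out.alpha[j] = 0; out.alpha[i] = sum; }
      }
      if (sum > C) {
        if (out.alpha[j] > C) { out.alpha[j] = C; out.alpha[i] = sum - C; }
      } else {
        if (out.alpha[i] < 0) { out.alpha[i] = 0; out.alpha[j] = sum; }
      }
    }

    double di = out.alpha[i] - ai_old;
    double dj = out.alpha[j] - aj_old;
    if (di == 0.0 && dj == 0.0) break;
    const double wi = yv[i] * di, wj = yv[j] * dj;
    for (int t = 0; t < n; ++t) {
      grad[t] += yv[t] * (wi * Ki[t] + wj * Kj[t]);
    }
  }
  out.iter = it;

  // bias: average y_t - s_t over free SVs, midpoint of KKT bounds otherwise
  double bsum = 0.0; int bn = 0;
  double up = -INFINITY, low = INFINITY;
  for (int t = 0; t < n; ++t) {
    double v = -yv[t] * grad[t];  // equals y_t - s_t
    bool in_up = (yv[t] > 0) ? (out.alpha[t] < C - TAU) : (out.alpha[t] > TAU);
    bool in_low = (yv[t] > 0) ? (out.alpha[t] > TAU) : (out.alpha[t] < C - TAU);
    if (out.alpha[t] > TAU && out.alpha[t] < C - TAU) { bsum += v; bn++; }
    if (in_up && v > up) up = v;
    if (in_low && v < low) low = v;
  }
  out.b = bn > 0 ? bsum / bn : (up + low) / 2.0;
  return out;
}

}  // namespace

//' @name cpp_smo_binary
//' @keywords internal
// [[Rcpp::export(name = "cpp_smo_binary")]]
List cpp_smo_binary(NumericMatrix K, IntegerVector y, double cost,
                    double eps = 1e-3, int max_iter = 100000) {
  int n = K.nrow();
  if (y.size() != n) stop("label length must match kernel size");
  std::vector<int> rows(n);
  std::vector<double> yv(n);
  for (int t = 0; t < n; ++t) {
    rows[t] = t;
    if (y[t] != 1 && y[t] != -1) stop("labels must be +1/-1");
    yv[t] = y[t];
  }
  BinarySvm m = solve_binary(K, rows, yv, cost, eps, max_iter);
  return List::create(_["alpha"] = NumericVector(m.alpha.begin(), m.alpha.end()),
                      _["b"] = m.b, _["iterations"] = m.iter);
}

//' @name cpp_svm_ovo_cv
//' @keywords internal
// [[Rcpp::export(name = "cpp_svm_ovo_cv")]]
double cpp_svm_ovo_cv(NumericMatrix Z, IntegerVector y, IntegerVector fold,
                      int n_class, double cost, int degree,
                      double gamma = 0.0, double eps = 1e-3,
                      int max_iter = 100000) {
  const int n = Z.nrow(), m = Z.ncol();
  if (y.size() != n || fold.size() != n) stop("length mismatch");
  if (m < 1) return 0.0;
  if (gamma <= 0.0) gamma = 1.0 / m;  // library-default kernel scaling

  // polynomial kernel (1 + gamma x.y)^degree on the selected, standardized
  // columns; computed once, shared by all folds and class pairs
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j <= i; ++j) {
      double dot = 0.0;
      for (int c = 0; c < m; ++c) dot += Z(i, c) * Z(j, c);
      double k = std::pow(1.0 + gamma * dot, (double)degree);
      K(i, j) = k;
      K(j, i) = k;
    }
  }

  int n_fold = 0;
  for (int t = 0; t < n; ++t) if (fold[t] > n_fold) n_fold = fold[t];

  double acc_sum = 0.0;
  int folds_used = 0;
  for (int f = 1; f <= n_fold; ++f) {
    std::vector<int> test_idx;
    for (int t = 0; t < n; ++t) if (fold[t] == f) test_idx.push_back(t);
    if (test_idx.empty()) continue;
    std::vector<std::vector<int> > votes(test_idx.size(),
                                         std::vector<int>(n_class, 0));

    for (int a = 1; a <= n_class; ++a) {
      for (int b = a + 1; b <= n_class; ++b) {
        std::vector<int> rows;
        std::vector<double> yv;
        for (int t = 0; t < n; ++t) {
          if (fold[t] != f && (y[t] == a || y[t] == b)) {
            rows.push_back(t);
            yv.push_back(y[t] == a ? 1.0 : -1.0);
          }
        }
        if (rows.empty()) continue;
        bool both = false;
        for (size_t t = 1; t < yv.size(); ++t) if (yv[t] != yv[0]) { both = true; break; }
        if (!both) {  // degenerate fold: every training row in one class
          int winner = yv[0] > 0 ? a : b;
          for (size_t ti = 0; ti < test_idx.size(); ++ti) votes[ti][winner - 1]++;
          continue;
        }
        BinarySvm mdl = solve_binary(K, rows, yv, cost, eps, max_iter);
        for (size_t ti = 0; ti < test_idx.size(); ++ti) {
          double fx = mdl.b;
          for (size_t t = 0; t < rows.size(); ++t) {
            if (mdl.alpha[t] > TAU) {
              fx += mdl.alpha[t] * yv[t] * K(rows[t], test_idx[ti]);
            }
          }
          // tie (fx == 0) goes to the lower class index
          votes[ti][(fx >= 0 ? a : b) - 1]++;
        }
      }
    }

    int correct = 0;
    for (size_t ti = 0; ti < test_idx.size(); ++ti) {
      int best = 0;
      for (int c = 1; c < n_class; ++c) {
        if (votes[ti][c] > votes[ti][best]) best = c;  // tie -> lowest index
      }
      if (best + 1 == y[test_idx[ti]]) correct++;
    }
    acc_sum += (double)correct / (double)test_idx.size();
    folds_used++;
  }
  return folds_used ? 100.0 * acc_sum / folds_used : 0.0;
}
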