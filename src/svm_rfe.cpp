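// Linear soft-margin SVM (dual SMO) and recursive feature elimination.
//
// The dual is min_a 0.5 a'Qa - e'a, 0 <= a_i <= C, y'a = 0 with
// Q_ij = y_i y_j K_ij and K the linear kernel. Solved by sequential
// minimal optimization with maximal-violating-pair working-set selection;
// deterministic given (K, y, C, tol), no randomized steps.
//
// The RFE loop keeps the n x n kernel of the surviving genes and downdates
// it by a rank-1 subtraction when a gene is removed, so each elimination
// costs O(n^2) for the kernel plus one SMO solve on n <= a few dozen
// samples; weight recomputation is O(n * surviving).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double SMO_TAU = 1e-12;
static const double ALPHA_EPS = 1e-10;

// SMO on a precomputed kernel. alpha and bias are outputs.
static void smo_solve(const arma::mat &K, const arma::vec &y, double C,
                      double tol, int max_iter, arma::vec &alpha, double &bias) {
  const int n = K.n_rows;
  alpha.zeros(n);
  arma::vec grad(n);
  grad.fill(-1.0); // gradient of 0.5 a'Qa - e'a at a = 0

  for (int it = 0; it < max_iter; ++it) {
    // maximal violating pair over I_up / I_low
    int i = -1, j = -1;
    double gmax = -std::numeric_limits<double>::infinity();
    double gmin = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * grad[t];
      const bool up = (y[t] > 0) ? (alpha[t] < C - ALPHA_EPS) : (alpha[t] > ALPHA_EPS);
      const bool low = (y[t] > 0) ? (alpha[t] > ALPHA_EPS) : (alpha[t] < C - ALPHA_EPS);
      if (up && v > gmax) { gmax = v; i = t; }
      if (low && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) break;

    const double old_ai = alpha[i], old_aj = alpha[j];
    // quad coefficient is ||x_i - x_j||^2 in kernel space in both branches
    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = SMO_TAU;
      const double delta = (-grad[i] - grad[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = SMO_TAU;
      const double delta = (grad[i] - grad[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    const double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai == 0 && daj == 0) break; // numerically stuck at optimum
    for (int t = 0; t < n; ++t)
      grad[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
  }

  // bias from KKT: free SVs give y_i - f_i exactly; otherwise midpoint of
  // the feasible interval implied by the bound constraints.
  arma::vec f = K * (alpha % y);
  double acc = 0; int nfree = 0;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > ALPHA_EPS && alpha[t] < C - ALPHA_EPS) { acc += y[t] - f[t]; ++nfree; }
  if (nfree > 0) {
    bias = acc / nfree;
  } else {
    double lo = -std::numeric_limits<double>::infinity();
    double hi = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const double v = y[t] - f[t];
      const bool at_zero = alpha[t] <= ALPHA_EPS;
      if ((at_zero && y[t] > 0) || (!at_zero && y[t] < 0)) lo = std::max(lo, v);
      else hi = std::min(hi, v);
    }
    bias = (std::isfinite(lo) && std::isfinite(hi)) ? (lo + hi) / 2.0
         : (std::isfinite(lo) ? lo : (std::isfinite(hi) ? hi : 0.0));
  }
}

// [[Rcpp::export(name = ".smo_train")]]
List smo_train(const arma::mat &X, const arma::vec &y, double C,
               double tol, int max_iter) {
  if (X.n_rows != y.n_elem) stop("nrow(X) must equal length(y)");
  arma::mat K = X * X.t();
  arma::vec alpha; double bias = 0;
  smo_solve(K, y, C, tol, max_iter, alpha, bias);
  arma::vec w = X.t() * (alpha % y);
  return List::create(_["alpha"] = alpha, _["bias"] = bias, _["weights"] = w);
}

// Full RFE: X is samples x genes. Returns, per gene (column), the
// elimination step (1 = first eliminated) and the squared-weight criterion
// at the step it was removed. chunk >= 1 genes removed per iteration.
// Tie rule: among equal minimum criteria, the gene later in the current
// surviving order is eliminated first.
// [[Rcpp::export(name = ".rfe_rank")]]
List rfe_rank(const arma::mat &X, const arma::vec &y, double C,
              double tol, int max_iter, int chunk) {
  const int n = X.n_rows, G = X.n_cols;
  if ((int)y.n_elem != n) stop("nrow(X) must equal length(y)");
  if (G < 1) stop("need at least one gene");
  if (chunk < 1) stop("chunk must be >= 1");

  std::vector<int> active(G);
  for (int g = 0; g < G; ++g) active[g] = g;

  arma::mat K = X * X.t();
  arma::vec elim_step(G), criterion(G);
  arma::vec alpha; double bias = 0;
  int step = 0;

  while (!active.empty()) {
    const int m = (int)active.size();
    smo_solve(K, y, C, tol, max_iter, alpha, bias);
    arma::vec beta = alpha % y;

    arma::vec crit(m);
    for (int t = 0; t < m; ++t) {
      const double w = arma::dot(X.col(active[t]), beta);
      crit[t] = w * w;
    }

    const int k = std::min(chunk, m);
    // order of removal inside the chunk: ascending criterion, ties by
    // later current position first (matches the single-gene tie rule)
    std::vector<int> idx(m);
    for (int t = 0; t < m; ++t) idx[t] = t;
    std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
      if (crit[a] != crit[b]) return crit[a] < crit[b];
      return a > b;
    });
    std::vector<int> drop(idx.begin(), idx.begin() + k);
    for (int d : drop) {
      const int g = active[d];
      elim_step[g] = ++step;
      criterion[g] = crit[d];
      K -= X.col(g) * X.col(g).t();
    }
    std::sort(drop.begin(), drop.end(), std::greater<int>());
    for (int d : drop) active.erase(active.begin() + d);
  }

  return List::create(_["elimination_step"] = elim_step,
                      _["criterion"] = criterion);
}
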