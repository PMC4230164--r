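// Searchlight decoding core: a C-support-vector classifier trained on a
// precomputed Gram matrix (SMO with maximal-violating-pair working-set
// selection), and the roaming-sphere map loop that applies it with
// leave-one-run-out cross-validation at every in-mask voxel.
//
// Problems here are tiny (typically 14 training vectors), so a direct SMO
// on the dual with an explicit Gram matrix is both exact and fast.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct SvmModel {
  std::vector<double> alpha;
  double b;
};

// Solve: min 1/2 a' Q a - e' a, s.t. y'a = 0, 0 <= a <= C, Q_ij = y_i y_j K_ij
SvmModel smo_train(const std::vector<double>& K, const std::vector<int>& y,
                   int n, double C, double eps = 1e-8, int max_iter = 100000) {
  std::vector<double> alpha(n, 0.0), grad(n, -1.0);
  double m_up = 0, m_low = 0;
  for (int iter = 0; iter < max_iter; ++iter) {
    int i = -1, j = -1;
    m_up = -std::numeric_limits<double>::infinity();
    m_low = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * grad[t];
      bool in_up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool in_low = (y[t] < 0 && alpha[t] < C) || (y[t] > 0 && alpha[t] > 0);
      if (in_up && v > m_up) { m_up = v; i = t; }
      if (in_low && v < m_low) { m_low = v; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low < eps) break;
    double quad = K[i * n + i] + K[j * n + j] - 2.0 * K[i * n + j];
    if (quad < 1e-12) quad = 1e-12;
    double delta = (m_up - m_low) / quad;
    // keep both variables inside the box while preserving y'a = 0
    double lo = -std::numeric_limits<double>::infinity();
    double hi = std::numeric_limits<double>::infinity();
    if (y[i] > 0) { lo = std::max(lo, -alpha[i]); hi = std::min(hi, C - alpha[i]); }
    else          { lo = std::max(lo, alpha[i] - C); hi = std::min(hi, alpha[i]); }
    if (y[j] > 0) { lo = std::max(lo, alpha[j] - C); hi = std::min(hi, alpha[j]); }
    else          { lo = std::max(lo, -alpha[j]); hi = std::min(hi, C - alpha[j]); }
    delta = std::min(std::max(delta, lo), hi);
    if (delta == 0) break;
    double dai = y[i] * delta, daj = -y[j] * delta;
    alpha[i] += dai;
    alpha[j] += daj;
    for (int t = 0; t < n; ++t) {
      grad[t] += y[t] * (y[i] * K[t * n + i] * dai + y[j] * K[t * n + j] * daj);
    }
  }
  SvmModel mod;
  mod.alpha = alpha;
  mod.b = (std::isfinite(m_up) && std::isfinite(m_low)) ? (m_up + m_low) / 2.0 : 0.0;
  return mod;
}

// Leave-one-run-out CV accuracy from a full Gram matrix over all samples.
// y in {-1,+1}; ties on the decision boundary go to class +1 (the caller maps
// the lexicographically first category to +1).
double cv_accuracy_gram(const double* G, int n, const std::vector<int>& y,
                        const std::vector<int>& run, double C) {
  std::vector<int> uruns;
  for (int t = 0; t < n; ++t) {
    bool seen = false;
    for (int u : uruns) if (u == run[t]) { seen = true; break; }
    if (!seen) uruns.push_back(run[t]);
  }
  std::sort(uruns.begin(), uruns.end());
  double acc_sum = 0.0;
  for (int fr : uruns) {
    std::vector<int> tr, te;
    for (int t = 0; t < n; ++t) (run[t] == fr ? te : tr).push_back(t);
    int m = (int)tr.size();
    std::vector<double> K(m * m);
    std::vector<int> yt(m);
    for (int a = 0; a < m; ++a) {
      yt[a] = y[tr[a]];
      for (int b = 0; b < m; ++b) K[a * m + b] = G[tr[a] * n + tr[b]];
    }
    SvmModel mod = smo_train(K, yt, m, C);
    int correct = 0;
    for (int s : te) {
      double f = mod.b;
      for (int a = 0; a < m; ++a) {
        if (mod.alpha[a] > 0) f += mod.alpha[a] * yt[a] * G[tr[a] * n + s];
      }
      int pred = (f < 0) ? -1 : 1;
      if (pred == y[s]) ++correct;
    }
    acc_sum += (double)correct / (double)te.size();
  }
  return acc_sum / (double)uruns.size();
}

} // namespace

// [[Rcpp::export(name = ".svm_train_gram_cpp")]]
List svm_train_gram_cpp(NumericMatrix G, IntegerVector y, double cost) {
  int n = G.nrow();
  std::vector<double> K(n * n);
  std::vector<int> yy(n);
  for (int i = 0; i < n; ++i) {
    yy[i] = y[i];
    for (int j = 0; j < n; ++j) K[i * n + j] = G(i, j);
  }
  SvmModel mod = smo_train(K, yy, n, cost);
  return List::create(_["alpha"] = NumericVector(mod.alpha.begin(), mod.alpha.end()),
                      _["b"] = mod.b);
}

// [[Rcpp::export(name = ".svm_cv_gram_cpp")]]
double svm_cv_gram_cpp(NumericMatrix G, IntegerVector y, IntegerVector run,
                       double cost) {
  int n = G.nrow();
  std::vector<int> yy(y.begin(), y.end()), rr(run.begin(), run.end());
  return cv_accuracy_gram(REAL(G), n, yy, rr, cost);
}

// B: n_maps x n_inmask feature matrix (column v = beta vector at in-mask
// voxel v); vox2col: full-grid linear index -> 0-based column (or -1);
// offsets: K x 3 integer voxel offsets of the sphere.
// [[Rcpp::export(name = ".sl_map_cpp")]]
NumericVector sl_map_cpp(NumericMatrix B, IntegerVector y, IntegerVector run,
                         IntegerVector vox2col, IntegerVector dims,
                         IntegerMatrix offsets, IntegerVector center_vox,
                         double cost, int min_sphere_voxels) {
  int n = B.nrow();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n_off = offsets.nrow();
  int n_centers = center_vox.size();
  std::vector<int> yy(y.begin(), y.end()), rr(run.begin(), run.end());
  NumericVector out(n_centers, NA_REAL);
  std::vector<int> cols;
  std::vector<double> G(n * n);
  const double* Bp = REAL(B);
  for (int c = 0; c < n_centers; ++c) {
    int lin = center_vox[c];               // 0-based full-grid linear index
    int cx = lin % nx, cy = (lin / nx) % ny, cz = lin / (nx * ny);
    cols.clear();
    for (int o = 0; o < n_off; ++o) {
      int x = cx + offsets(o, 0), yv = cy + offsets(o, 1), z = cz + offsets(o, 2);
      if (x < 0 || x >= nx || yv < 0 || yv >= ny || z < 0 || z >= nz) continue;
      int col = vox2col[x + nx * (yv + ny * z)];
      if (col >= 0) cols.push_back(col);
    }
    if ((int)cols.size() < min_sphere_voxels) continue;
    std::fill(G.begin(), G.end(), 0.0);
    for (int col : cols) {
      const double* bv = Bp + (size_t)col * n;
      for (int i = 0; i < n; ++i) {
        double bi = bv[i];
        if (bi == 0.0) continue;
        const double* row = bv;
        double* Gi = &G[(size_t)i * n];
        for (int j = 0; j <= i; ++j) Gi[j] += bi * row[j];
      }
    }
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) G[(size_t)i * n + j] = G[(size_t)j * n + i];
    out[c] = cv_accuracy_gram(G.data(), n, yy, rr, cost);
  }
  return out;
}
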