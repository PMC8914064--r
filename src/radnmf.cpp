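#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Multiplicative updates for the Frobenius NMF objective ||V - WH||_F^2.
// Alternates H <- H .* (W'V) ./ (W'WH + eps), W <- W .* (VH') ./ (WHH' + eps)
// and records the residual sum of squares after every sweep; stops when the
// relative RSS change drops below tol.
// [[Rcpp::export]]
List nmf_mu_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                int max_iter, double tol, double eps) {
  std::vector<double> rss_hist;
  double rss_prev = arma::accu(arma::square(V - W * H));
  rss_hist.push_back(rss_prev);
  bool converged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    H %= (W.t() * V) / (W.t() * W * H + eps);
    W %= (V * H.t()) / (W * H * H.t() + eps);
    double rss = arma::accu(arma::square(V - W * H));
    rss_hist.push_back(rss);
    if (std::fabs(rss_prev - rss) < tol * std::max(rss_prev, 1e-300)) {
      converged = true;
      break;
    }
    rss_prev = rss;
  }
  return List::create(_["W"] = W, _["H"] = H,
                      _["rss_history"] = rss_hist,
                      _["n_iter"] = std::min(it, max_iter),
                      _["converged"] = converged);
}

// Largest pairwise Euclidean distance between points (rows of P).
// [[Rcpp::export]]
double max_pairwise_dist_cpp(const arma::mat& P) {
  const arma::uword n = P.n_rows;
  double best = 0.0;
  for (arma::uword i = 0; i + 1 < n; ++i) {
    for (arma::uword j = i + 1; j < n; ++j) {
      double d = 0.0;
      for (arma::uword c = 0; c < P.n_cols; ++c) {
        double t = P(i, c) - P(j, c);
        d += t * t;
      }
      if (d > best) best = d;
    }
  }
  return std::sqrt(best);
}

// Largest pairwise distance restricted to pairs sharing a group label
// (rows of P must be sorted by g).
// [[Rcpp::export]]
double max_pairwise_dist_grouped_cpp(const arma::mat& P, const arma::vec& g) {
  const arma::uword n = P.n_rows;
  double best = 0.0;
  arma::uword start = 0;
  while (start < n) {
    arma::uword end = start;
    while (end + 1 < n && g(end + 1) == g(start)) ++end;
    for (arma::uword i = start; i < end; ++i) {
      for (arma::uword j = i + 1; j <= end; ++j) {
        double d = 0.0;
        for (arma::uword c = 0; c < P.n_cols; ++c) {
          double t = P(i, c) - P(j, c);
          d += t * t;
        }
        if (d > best) best = d;
      }
    }
    start = end + 1;
  }
  return std::sqrt(best);
}

// Connected zones of equal grey level under 26-connectivity.
// `levels` is a flattened 3D integer array (column-major, NA outside the
// ROI); returns a matrix with one row per zone: (grey level, zone size).
// [[Rcpp::export]]
IntegerMatrix glszm_zones_cpp(IntegerVector levels, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<bool> seen(n, false);
  std::vector<int> zl, zs;
  std::vector<int> stack;
  for (int v0 = 0; v0 < n; ++v0) {
    if (seen[v0] || levels[v0] == NA_INTEGER) continue;
    int lev = levels[v0];
    int size = 0;
    stack.clear();
    stack.push_back(v0);
    seen[v0] = true;
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      ++size;
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
              continue;
            int w = X + nx * (Y + ny * Z);
            if (!seen[w] && levels[w] != NA_INTEGER && levels[w] == lev) {
              seen[w] = true;
              stack.push_back(w);
            }
          }
    }
    zl.push_back(lev);
    zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t i = 0; i < zl.size(); ++i) {
    out(i, 0) = zl[i];
    out(i, 1) = zs[i];
  }
  return out;
}
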