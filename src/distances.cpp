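#include <Rcpp.h>
using namespace Rcpp;

// Nearest-neighbour distance within one planar point set (brute force).
// [[Rcpp::export]]
NumericVector nn_dist(NumericVector x, NumericVector y) {
  const int n = x.size();
  NumericVector out(n, R_PosInf);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      const double dx = x[i] - x[j], dy = y[i] - y[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Distance from each query location to the nearest event.
// [[Rcpp::export]]
NumericVector cross_min_dist(NumericVector qx, NumericVector qy,
                             NumericVector px, NumericVector py) {
  const int m = qx.size(), n = px.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < n; ++j) {
      const double dx = qx[i] - px[j], dy = qy[i] - py[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Weighted isotropic Gaussian kernel sum evaluated at grid cells:
// sum_j w_j * exp(-d^2/(2 sigma^2)) / (2 pi sigma^2)
// [[Rcpp::export]]
NumericVector gauss_sum(NumericVector cx, NumericVector cy,
                        NumericVector px, NumericVector py,
                        NumericVector w, double sigma) {
  const int m = cx.size(), n = px.size();
  const double s2 = sigma * sigma;
  const double norm = 1.0 / (2.0 * M_PI * s2);
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double acc = 0.0;
    for (int j = 0; j < n; ++j) {
      const double dx = cx[i] - px[j], dy = cy[i] - py[j];
      acc += w[j] * std::exp(-(dx * dx + dy * dy) / (2.0 * s2));
    }
    out[i] = acc * norm;
  }
  return out;
}

// Route rows through a single regression tree (ranger treeInfo layout:
// 0-based child ids, NA/-1 children at terminals, numeric splits with
// "value <= splitval goes left").
// [[Rcpp::export]]
NumericVector tree_traverse(IntegerVector left, IntegerVector right,
                            IntegerVector splitvar, NumericVector splitval,
                            NumericVector value, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (left[node] != NA_INTEGER && left[node] >= 0) {
      const double v = X(i, splitvar[node]);
      node = (v <= splitval[node]) ? left[node] : right[node];
    }
    out[i] = value[node];
  }
  return out;
}

// Sum over distinct ordered pairs of f(d) for the bandwidth criterion:
// returns sum_{i != j} [ k_{sigma*sqrt2}(d_ij) - 2 k_sigma(d_ij) ] for each
// sigma, where k_s(d) = exp(-d^2/(2 s^2)) / (2 pi s^2).
// [[Rcpp::export]]
NumericVector pair_kernel_contrast(NumericVector x, NumericVector y,
                                   NumericVector sigmas) {
  const int n = x.size(), m = sigmas.size();
  std::vector<double> d2;
  d2.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j], dy = y[i] - y[j];
      d2.push_back(dx * dx + dy * dy);
    }
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    const double s2 = sigmas[k] * sigmas[k];
    double acc = 0.0;
    for (size_t t = 0; t < d2.size(); ++t) {
      const double kconv = std::exp(-d2[t] / (4.0 * s2)) / (4.0 * M_PI * s2);
      const double ksig  = std::exp(-d2[t] / (2.0 * s2)) / (2.0 * M_PI * s2);
      acc += kconv - 2.0 * ksig;
    }
    out[k] = 2.0 * acc; // ordered pairs
  }
  return out;
}
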