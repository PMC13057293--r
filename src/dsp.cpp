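#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial state zi (length max(na,nb)-1).
// a[0] must be 1 (normalised by the caller).
// [[Rcpp::export]]
NumericVector cpp_iir_filter(NumericVector b, NumericVector a, NumericVector x,
                             NumericVector zi) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nf = std::max(na, nb);
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0), z(nf - 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  for (int i = 0; i < nf - 1 && i < zi.size(); ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nf - 2; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    z[nf - 2] = bb[nf - 1] * xi - aa[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}

// One level of the periodized DWT. g: analysis low-pass, h: analysis high-pass.
// approx[k] = sum_m g[m] x[(2k+m) mod n]; detail analogous. n must be even.
// [[Rcpp::export]]
List cpp_dwt_step(NumericVector x, NumericVector g, NumericVector h) {
  int n = x.size(), L = g.size(), half = n / 2;
  NumericVector a(half), d(half);
  for (int k = 0; k < half; ++k) {
    double sa = 0.0, sd = 0.0;
    int base = 2 * k;
    for (int m = 0; m < L; ++m) {
      double xv = x[(base + m) % n];
      sa += g[m] * xv;
      sd += h[m] * xv;
    }
    a[k] = sa;
    d[k] = sd;
  }
  return List::create(_["approx"] = a, _["detail"] = d);
}

// Inverse of cpp_dwt_step (transpose of the orthogonal analysis operator).
// [[Rcpp::export]]
NumericVector cpp_idwt_step(NumericVector a, NumericVector d, NumericVector g,
                            NumericVector h) {
  int half = a.size(), n = 2 * half, L = g.size();
  NumericVector x(n);
  for (int k = 0; k < half; ++k) {
    int base = 2 * k;
    for (int m = 0; m < L; ++m) {
      int j = (base + m) % n;
      x[j] += a[k] * g[m] + d[k] * h[m];
    }
  }
  return x;
}

// Full-pass / sampled ReliefF weight update for binary labels.
// X: n x p matrix already range-scaled to [0,1]; y: 0/1 integer labels;
// idx: 0-based indices of the sampled instances R; k: neighbours per class.
// Manhattan distance; ties broken by lower index. Binary prior factor for the
// miss class is P(miss)/(1-P(hit)) = 1.
// [[Rcpp::export]]
NumericVector cpp_relieff(NumericMatrix X, IntegerVector y, IntegerVector idx,
                          int k) {
  int n = X.nrow(), p = X.ncol(), m = idx.size();
  // row-major copy so per-instance feature vectors are contiguous
  std::vector<double> Xr((size_t)n * p);
  for (int f = 0; f < p; ++f)
    for (int j = 0; j < n; ++j) Xr[(size_t)j * p + f] = X(j, f);
  NumericVector w(p);
  std::vector<double> dist(n);
  std::vector<int> hits, misses;
  hits.reserve(n); misses.reserve(n);
  for (int s = 0; s < m; ++s) {
    int i = idx[s];
    const double *xi = &Xr[(size_t)i * p];
    for (int j = 0; j < n; ++j) {
      if (j == i) { dist[j] = R_PosInf; continue; }
      const double *xj = &Xr[(size_t)j * p];
      double dsum = 0.0;
      for (int f = 0; f < p; ++f) dsum += std::fabs(xi[f] - xj[f]);
      dist[j] = dsum;
    }
    hits.clear(); misses.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (y[j] == y[i]) hits.push_back(j); else misses.push_back(j);
    }
    auto cmp = [&dist](int u, int v) {
      if (dist[u] != dist[v]) return dist[u] < dist[v];
      return u < v;
    };
    std::partial_sort(hits.begin(), hits.begin() + k, hits.end(), cmp);
    std::partial_sort(misses.begin(), misses.begin() + k, misses.end(), cmp);
    double norm = (double)m * (double)k;
    for (int t = 0; t < k; ++t) {
      const double *xh = &Xr[(size_t)hits[t] * p];
      const double *xm = &Xr[(size_t)misses[t] * p];
      for (int f = 0; f < p; ++f) {
        w[f] -= std::fabs(xi[f] - xh[f]) / norm;
        w[f] += std::fabs(xi[f] - xm[f]) / norm;
      }
    }
  }
  return w;
}
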