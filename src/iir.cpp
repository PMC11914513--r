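#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with explicit initial state.
// a[0] must be 1 (caller normalizes). State zi has length
// max(len(a), len(b)) - 1. Orders 2 and 4 (the notch biquads and the
// Butterworth low-pass) use specialized loops; anything else falls back
// to a generic loop.
// [[Rcpp::export(name = ".iirFilterCpp")]]
NumericVector iirFilterCpp(NumericVector b, NumericVector a,
                           NumericVector x, NumericVector zi) {
  const int n = x.size();
  const int nb = b.size(), na = a.size();
  const int order = std::max(na, nb) - 1;
  std::vector<double> bb(order + 1, 0.0), aa(order + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(std::max(order, 1), 0.0);
  for (int i = 0; i < (int)zi.size() && i < order; ++i) z[i] = zi[i];

  NumericVector y(n);
  const double *xp = REAL(x);
  double *yp = REAL(y);

  if (order == 2) {
    const double b0 = bb[0], b1 = bb[1], b2 = bb[2];
    const double a1 = aa[1], a2 = aa[2];
    double z0 = z[0], z1 = z[1];
    for (int i = 0; i < n; ++i) {
      const double xi = xp[i];
      const double yi = b0 * xi + z0;
      z0 = b1 * xi + z1 - a1 * yi;
      z1 = b2 * xi - a2 * yi;
      yp[i] = yi;
    }
  } else if (order == 4) {
    const double b0 = bb[0], b1 = bb[1], b2 = bb[2], b3 = bb[3], b4 = bb[4];
    const double a1 = aa[1], a2 = aa[2], a3 = aa[3], a4 = aa[4];
    double z0 = z[0], z1 = z[1], z2 = z[2], z3 = z[3];
    for (int i = 0; i < n; ++i) {
      const double xi = xp[i];
      const double yi = b0 * xi + z0;
      z0 = b1 * xi + z1 - a1 * yi;
      z1 = b2 * xi + z2 - a2 * yi;
      z2 = b3 * xi + z3 - a3 * yi;
      z3 = b4 * xi - a4 * yi;
      yp[i] = yi;
    }
  } else {
    for (int i = 0; i < n; ++i) {
      const double xi = xp[i];
      const double yi = bb[0] * xi + (order > 0 ? z[0] : 0.0);
      for (int k = 0; k < order - 1; ++k)
        z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
      if (order > 0)
        z[order - 1] = bb[order] * xi - aa[order] * yi;
      yp[i] = yi;
    }
  }
  return y;
}

// Cascade of K first-order pole/zero sections applied column-wise:
// per section H(z) = (1 - zz z^-1) / (1 - zp z^-1). Used to shape white
// noise into 1/f (pink) noise; states reset at each column.
// [[Rcpp::export(name = ".pinkCascadeCpp")]]
NumericMatrix pinkCascadeCpp(NumericMatrix x, NumericVector zz,
                             NumericVector zp) {
  const int n = x.nrow(), m = x.ncol(), K = zz.size();
  NumericMatrix y(n, m);
  std::vector<double> xprev(K), yprev(K);
  for (int j = 0; j < m; ++j) {
    std::fill(xprev.begin(), xprev.end(), 0.0);
    std::fill(yprev.begin(), yprev.end(), 0.0);
    const double *xj = &x(0, j);
    double *yj = &y(0, j);
    for (int i = 0; i < n; ++i) {
      double v = xj[i];
      for (int k = 0; k < K; ++k) {
        const double w = v - zz[k] * xprev[k] + zp[k] * yprev[k];
        xprev[k] = v;
        yprev[k] = w;
        v = w;
      }
      yj[i] = v;
    }
  }
  return y;
}
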