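#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Online Kohonen training loop.
//
// w0:    npts x nnodes initial node weights (nnodes = side*side, row-major
//        node order: node j sits at grid (j / side, j % side))
// x:     npts x N reference spectra
// order: 1-based member index presented at each step (length n_steps)
// alpha decays exponentially alpha0 -> alpha_end, sigma likewise; the
// neighbourhood is a Gaussian in map-grid distance about the BMU.
// Returns the trained weights; qe_trace (mean BMU distance over the
// reference members, recorded every trace_every steps) is attached as an
// attribute for convergence diagnostics.
// [[Rcpp::export]]
NumericMatrix som_train_cpp(NumericMatrix w0, NumericMatrix x,
                            IntegerVector order, int side,
                            double alpha0, double alpha_end,
                            double sigma0, double sigma_end,
                            int trace_every) {
  NumericMatrix w = clone(w0);
  const int npts = w.nrow(), nn = w.ncol(), nsteps = order.size();
  const int nref = x.ncol();
  double *wp = REAL(w);
  double *xp = REAL(x);
  std::vector<int> row(nn), col(nn);
  for (int j = 0; j < nn; ++j) { row[j] = j / side; col[j] = j % side; }
  std::vector<double> trace;

  for (int t = 0; t < nsteps; ++t) {
    double frac = (nsteps > 1) ? (double)t / (double)(nsteps - 1) : 0.0;
    double alpha = alpha0 * std::pow(alpha_end / alpha0, frac);
    double sigma = sigma0 * std::pow(sigma_end / sigma0, frac);
    const double *xi = xp + (size_t)(order[t] - 1) * npts;

    // best matching unit (ties -> lowest row-major index via strict <)
    int best = 0; double bestd = R_PosInf;
    for (int j = 0; j < nn; ++j) {
      const double *wj = wp + (size_t)j * npts;
      double d = 0.0;
      for (int p = 0; p < npts; ++p) {
        double e = wj[p] - xi[p];
        d += e * e;
      }
      if (d < bestd) { bestd = d; best = j; }
    }

    double s2 = 2.0 * sigma * sigma;
    for (int j = 0; j < nn; ++j) {
      double dr = row[j] - row[best], dc = col[j] - col[best];
      double ah = alpha * std::exp(-(dr * dr + dc * dc) / s2);
      if (ah < 1e-12) continue;
      double *wj = wp + (size_t)j * npts;
      for (int p = 0; p < npts; ++p)
        wj[p] += ah * (xi[p] - wj[p]);
    }

    if (trace_every > 0 && ((t + 1) % trace_every == 0 || t == nsteps - 1)) {
      double qe = 0.0;
      for (int m = 0; m < nref; ++m) {
        const double *xm = xp + (size_t)m * npts;
        double dmin = R_PosInf;
        for (int j = 0; j < nn; ++j) {
          const double *wj = wp + (size_t)j * npts;
          double d = 0.0;
          for (int p = 0; p < npts; ++p) {
            double e = wj[p] - xm[p];
            d += e * e;
          }
          if (d < dmin) dmin = d;
        }
        qe += std::sqrt(dmin);
      }
      trace.push_back(qe / nref);
    }
  }
  w.attr("qe_trace") = NumericVector(trace.begin(), trace.end());
  return w;
}

// Squared Euclidean distances between each column of a and each column of b.
// [[Rcpp::export]]
NumericMatrix cross_dist2_cpp(NumericMatrix a, NumericMatrix b) {
  const int npts = a.nrow(), na = a.ncol(), nb = b.ncol();
  NumericMatrix out(na, nb);
  const double *ap = REAL(a), *bp = REAL(b);
  for (int j = 0; j < nb; ++j) {
    const double *bj = bp + (size_t)j * npts;
    for (int i = 0; i < na; ++i) {
      const double *ai = ap + (size_t)i * npts;
      double d = 0.0;
      for (int p = 0; p < npts; ++p) {
        double e = ai[p] - bj[p];
        d += e * e;
      }
      out(i, j) = d;
    }
  }
  return out;
}
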