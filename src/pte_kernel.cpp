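#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Plug-in transfer entropy (bits) between all ordered pairs of binned phase
// sequences. sym is n x C with integer symbols in [0, nbins); delay is the
// prediction lag in samples. Entry (i, j) of the result is TE(i -> j):
//   TE = sum p(yf, yp, x) * log2[ p(yf | yp, x) / p(yf | yp) ]
// over the empirical joint histogram of (y_{t+delay}, y_t, x_t); cells with
// zero probability contribute nothing. The y-marginals are shared across all
// sources x, so they are accumulated once per target.
// [[Rcpp::export]]
NumericMatrix pteMatrixCpp(IntegerMatrix sym, int delay, int nbins) {
  const int n = sym.nrow(), C = sym.ncol();
  const int m = n - delay;
  if (delay < 1) stop("delay must be >= 1 sample");
  if (m < 2) stop("sequence too short for the requested delay");
  if (nbins < 2) stop("nbins must be >= 2");
  for (int j = 0; j < C; ++j)
    for (int t = 0; t < n; ++t) {
      int s = sym(t, j);
      if (s < 0 || s >= nbins) stop("symbols must lie in [0, nbins)");
    }

  NumericMatrix te(C, C);
  std::vector<int> c3((size_t)nbins * nbins * nbins), cyx(nbins * nbins),
      cyy(nbins * nbins), cy(nbins);

  for (int j = 0; j < C; ++j) {
    std::fill(cy.begin(), cy.end(), 0);
    std::fill(cyy.begin(), cyy.end(), 0);
    for (int t = 0; t < m; ++t) {
      int yp = sym(t, j), yf = sym(t + delay, j);
      ++cy[yp];
      ++cyy[yf * nbins + yp];
    }
    for (int i = 0; i < C; ++i) {
      if (i == j) continue;
      std::fill(c3.begin(), c3.end(), 0);
      std::fill(cyx.begin(), cyx.end(), 0);
      for (int t = 0; t < m; ++t) {
        int x = sym(t, i), yp = sym(t, j), yf = sym(t + delay, j);
        ++c3[((size_t)yf * nbins + yp) * nbins + x];
        ++cyx[yp * nbins + x];
      }
      double s = 0.0;
      for (int yf = 0; yf < nbins; ++yf) {
        for (int yp = 0; yp < nbins; ++yp) {
          const int nyy = cyy[yf * nbins + yp];
          if (!nyy) continue;
          const size_t base = ((size_t)yf * nbins + yp) * nbins;
          for (int x = 0; x < nbins; ++x) {
            const int c = c3[base + x];
            if (!c) continue;
            const double num = (double)c * (double)cy[yp];
            const double den = (double)cyx[yp * nbins + x] * (double)nyy;
            s += ((double)c / m) * std::log2(num / den);
          }
        }
      }
      te(i, j) = s > 0.0 ? s : 0.0;  // clamp -0.0 / rounding dust
    }
  }
  return te;
}
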