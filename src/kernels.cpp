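#include <Rcpp.h>
using namespace Rcpp;

// Sum-of-squared-differences between a trimmed template core and every
// contiguous slice of the test neurogram. Both matrices are units x bins
// (column-major); the core spans whole columns, so each slice is one
// contiguous block and the scan reduces to flat dot products.
//
// Returns a vector of length ncol(test) - ncol(core) + 1, one distance per
// slice offset i = 0, 1, ... (relative lag = i - maxLagBins).
// [[Rcpp::export(name = ".cppLagDistances")]]
NumericVector cppLagDistances(const NumericMatrix& core,
                              const NumericMatrix& test) {
  const int m = core.nrow();
  const int nc = core.ncol();
  const int nt = test.ncol();
  if (test.nrow() != m) stop("template and test must have the same unit rows");
  const int noff = nt - nc + 1;
  if (noff < 1) stop("test must be at least as wide as the template core");

  NumericVector out(noff);
  const double* pc = core.begin();
  const double* pt = test.begin();
  const R_xlen_t len = static_cast<R_xlen_t>(m) * nc;

  for (int i = 0; i < noff; ++i) {
    const double* ts = pt + static_cast<R_xlen_t>(i) * m;
    double acc = 0.0;
    for (R_xlen_t k = 0; k < len; ++k) {
      const double d = pc[k] - ts[k];
      acc += d * d;
    }
    out[i] = acc;
  }
  return out;
}
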