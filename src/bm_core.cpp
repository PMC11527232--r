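#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Matrix exponentials of the Bloch-McConnell generator for a set of event
// durations. G is the (3*np+1)-dimensional homogeneous generator (affine
// recovery terms in the last column).
// [[Rcpp::export]]
arma::cube bm_propagators(const arma::mat& G, const arma::vec& durations) {
  const arma::uword n = G.n_rows;
  arma::cube out(n, n, durations.n_elem);
  for (arma::uword k = 0; k < durations.n_elem; ++k) {
    out.slice(k) = arma::expmat(G * durations(k));
  }
  return out;
}

// Event walk: apply a precomputed sequence of state-space matrices to the
// magnetization vector, recording the complex transverse signal at sample
// events. ops > 0 index slices of the per-parameter cube `matsA` (1-based),
// ops < 0 index slices of the shared cube `matsB` (rotations, preparations,
// crusher; -1-based), ops == 0 records a sample. demod is
// (n_samples x n_pools): per-sample, per-pool complex demodulation
// coefficients; pool p occupies state entries 3p, 3p+1, 3p+2 (0-based) as
// (Mx, My, Mz).
// [[Rcpp::export]]
arma::cx_vec bm_walk(const arma::cube& matsA, const arma::cube& matsB,
                     const arma::ivec& ops,
                     const arma::cx_mat& demod, const arma::vec& m0) {
  arma::vec M = m0;
  const arma::uword ns = demod.n_rows;
  const arma::uword np = demod.n_cols;
  arma::cx_vec out(ns);
  arma::uword si = 0;
  for (arma::uword i = 0; i < ops.n_elem; ++i) {
    const int op = ops(i);
    if (op > 0) {
      M = matsA.slice(op - 1) * M;
    } else if (op < 0) {
      M = matsB.slice(-op - 1) * M;
    } else {
      if (si >= ns) Rcpp::stop("more sample events than demod rows");
      std::complex<double> s(0.0, 0.0);
      for (arma::uword p = 0; p < np; ++p) {
        s += demod(si, p) * std::complex<double>(M(3 * p), M(3 * p + 1));
      }
      out(si) = s;
      ++si;
    }
  }
  if (si != ns) Rcpp::stop("sample count mismatch: got %d, expected %d",
                           (int)si, (int)ns);
  return out;
}
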