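#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Pairwise minimum (Kabsch-optimal, proper rotations only) RMSD between all
// frame pairs over the given atom subset, via the SVD of the 3x3 covariance:
// rmsd^2 = (G_i + G_j - 2 * (s1 + s2 + sign(det) * s3)) / N.
// coords: n_atoms x 3 x n_frames cube; subset: 1-based atom indices.
// [[Rcpp::export(name = ".pairwise_rmsd_cpp")]]
arma::mat pairwise_rmsd_cpp(const arma::cube& coords, const arma::uvec& subset) {
  const arma::uword nf = coords.n_slices, ns = subset.n_elem;
  arma::uvec idx = subset - 1;
  std::vector<arma::mat> X(nf);
  arma::vec G(nf);
  for (arma::uword f = 0; f < nf; ++f) {
    arma::mat m = coords.slice(f);
    arma::mat xs = m.rows(idx);                 // ns x 3
    xs.each_row() -= arma::mean(xs, 0);
    X[f] = xs;
    G(f) = arma::accu(xs % xs);
  }
  arma::mat out(nf, nf, arma::fill::zeros);
  arma::mat U, V, C;
  arma::vec s;
  for (arma::uword i = 0; i < nf; ++i) {
    for (arma::uword j = i + 1; j < nf; ++j) {
      C = X[i].t() * X[j];                      // 3 x 3
      arma::svd(U, s, V, C);
      double d = arma::det(U) * arma::det(V) < 0 ? -1.0 : 1.0;
      double tr = s(0) + s(1) + d * s(2);
      double r2 = (G(i) + G(j) - 2.0 * tr) / ns;
      double r = std::sqrt(std::max(0.0, r2));
      out(i, j) = r;
      out(j, i) = r;
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
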