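// Stochastic gradient descent inner loop for the factored miRNA
// similarity model. One call = one pass over a prepared sample order
// (positives plus sampled negatives). P, Q, bd, bm are updated in place;
// the caller owns freshly allocated copies.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Per-sample update at (d, m) with target r:
//   rhat = bd[d] + bm[m] + c * sum_{j in S} p_j . q_m,
//   S = R_d+ \ {m}, c = |S|^-alpha (0 when S is empty),
//   e = r - rhat,
// gradient-descent step with per-sample regularization on the touched
// parameters (beta on q_m and each p_j, lambda on bd, gamma on bm).
// [[Rcpp::export]]
void fmsm_sgd_epoch(NumericMatrix P_, NumericMatrix Q_,
                    NumericVector bd_, NumericVector bm_,
                    IntegerVector d_idx, IntegerVector m_idx,
                    NumericVector r, List pos_sets,
                    double alpha, double eta,
                    double beta, double lambda, double gamma) {
  arma::mat P(P_.begin(), P_.nrow(), P_.ncol(), false);
  arma::mat Q(Q_.begin(), Q_.nrow(), Q_.ncol(), false);
  arma::vec bd(bd_.begin(), bd_.size(), false);
  arma::vec bm(bm_.begin(), bm_.size(), false);

  const int nd = pos_sets.size();
  std::vector<arma::uvec> rpos(nd);
  for (int d = 0; d < nd; ++d) {
    IntegerVector v = pos_sets[d];
    arma::uvec u(v.size());
    for (int k = 0; k < v.size(); ++k) u[k] = (arma::uword) v[k]; // 0-based
    rpos[d] = u;
  }

  const int n = d_idx.size();
  const arma::uword dl = P.n_cols;
  arma::rowvec t(dl), q_old(dl);

  for (int k = 0; k < n; ++k) {
    const int d = d_idx[k];
    const arma::uword m = (arma::uword) m_idx[k];
    const arma::uvec &full = rpos[d];

    // S = R_d+ \ {m}; accumulate t = sum_{j in S} p_j
    t.zeros();
    arma::uword ns = 0;
    for (arma::uword a = 0; a < full.n_elem; ++a) {
      if (full[a] == m) continue;
      t += P.row(full[a]);
      ++ns;
    }
    const double c = (ns > 0) ? std::pow((double) ns, -alpha) : 0.0;
    const double rhat = bd[d] + bm[m] + c * arma::dot(t, Q.row(m));
    const double e = r[k] - rhat;

    bd[d] += eta * (e - lambda * bd[d]);
    bm[m] += eta * (e - gamma * bm[m]);
    q_old = Q.row(m);
    Q.row(m) += eta * (e * c * t - beta * q_old);
    if (ns > 0) {
      const arma::rowvec gp = eta * e * c * q_old;
      const double shrink = 1.0 - eta * beta;
      for (arma::uword a = 0; a < full.n_elem; ++a) {
        if (full[a] == m) continue;
        P.row(full[a]) = shrink * P.row(full[a]) + gp;
      }
    }
  }
}
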