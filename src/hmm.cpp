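// Gaussian hidden Markov model: EM (Baum-Welch), forward log-likelihood,
// and Viterbi decoding. Full covariance emissions; covariance diagonals are
// floored for numerical stability. Observations are T x d, states K.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// log N(x; mu_k, Sigma_k) for all t, k  -> T x K
static mat log_emission(const mat& X, const mat& mu, const cube& Sigma) {
  const uword T = X.n_rows, d = X.n_cols, K = mu.n_rows;
  mat logB(T, K);
  const double c0 = -0.5 * (double)d * std::log(2.0 * M_PI);
  for (uword k = 0; k < K; ++k) {
    mat L;
    bool ok = chol(L, Sigma.slice(k), "lower");
    if (!ok) {
      mat S = Sigma.slice(k);
      S.diag() += 1e-8 * (trace(S) / d + 1e-12);
      ok = chol(L, S, "lower");
      if (!ok) Rcpp::stop("emission covariance not positive definite");
    }
    double logdet = 2.0 * accu(log(L.diag()));
    mat Xc = X.each_row() - mu.row(k);
    mat Z = solve(trimatl(L), Xc.t());      // d x T
    logB.col(k) = (c0 - 0.5 * logdet - 0.5 * sum(square(Z), 0).t());
  }
  return logB;
}

// scaled forward pass; returns log-likelihood, fills alpha (T x K) and c (T)
static double forward_pass(const mat& B, const rowvec& pi, const mat& A,
                           mat& alpha, vec& cvec) {
  const uword T = B.n_rows, K = B.n_cols;
  alpha.set_size(T, K); cvec.set_size(T);
  rowvec a = pi % B.row(0);
  double c = accu(a);
  if (c <= 0 || !std::isfinite(c)) Rcpp::stop("forward pass underflow");
  a /= c; cvec(0) = c; alpha.row(0) = a;
  for (uword t = 1; t < T; ++t) {
    a = (a * A) % B.row(t);
    c = accu(a);
    if (c <= 0 || !std::isfinite(c)) Rcpp::stop("forward pass underflow");
    a /= c; cvec(t) = c; alpha.row(t) = a;
  }
  return accu(log(cvec));
}

// [[Rcpp::export]]
double cpp_hmm_loglik(const arma::mat& X, const arma::rowvec& pi,
                      const arma::mat& A, const arma::mat& mu,
                      const arma::cube& Sigma) {
  mat logB = log_emission(X, mu, Sigma);
  vec mx = max(logB, 1);
  mat B = exp(logB.each_col() - mx);
  mat alpha; vec cvec;
  double ll = forward_pass(B, pi, A, alpha, cvec);
  return ll + accu(mx);
}

// [[Rcpp::export]]
Rcpp::List cpp_hmm_em(const arma::mat& X, arma::rowvec pi, arma::mat A,
                      arma::mat mu, arma::cube Sigma,
                      int max_iter, double tol, double var_floor) {
  const uword T = X.n_rows, d = X.n_cols, K = mu.n_rows;
  std::vector<double> ll_trace;
  double ll_prev = -datum::inf;
  bool converged = false, degenerate = false;
  mat alpha, beta, gamma;
  for (int iter = 0; iter < max_iter; ++iter) {
    mat logB = log_emission(X, mu, Sigma);
    vec mx = max(logB, 1);
    mat B = exp(logB.each_col() - mx);
    vec cvec;
    double ll = forward_pass(B, pi, A, alpha, cvec) + accu(mx);
    ll_trace.push_back(ll);
    // backward (scaled with the forward constants)
    beta.set_size(T, K);
    beta.row(T - 1).ones();
    for (uword t = T - 1; t-- > 0; ) {
      beta.row(t) = ((beta.row(t + 1) % B.row(t + 1)) * A.t()) / cvec(t + 1);
    }
    gamma = alpha % beta;
    gamma.each_col() /= sum(gamma, 1);  // guard tiny drift
    // transition counts
    mat xi(K, K, fill::zeros);
    for (uword t = 0; t + 1 < T; ++t) {
      mat m = (alpha.row(t).t() * (B.row(t + 1) % beta.row(t + 1))) % A;
      xi += m / cvec(t + 1);
    }
    // M step
    rowvec Nk = sum(gamma, 0);
    if (Nk.min() < (double)d + 2.0) { degenerate = true; break; }
    pi = gamma.row(0);
    pi /= accu(pi);
    A = xi.each_col() / sum(xi, 1);
    for (uword k = 0; k < K; ++k) {
      vec g = gamma.col(k);
      rowvec mk = (g.t() * X) / Nk(k);
      mat Xc = X.each_row() - mk;
      mat S = (Xc.each_col() % g).t() * Xc / Nk(k);
      S = 0.5 * (S + S.t());
      for (uword j = 0; j < d; ++j)
        if (S(j, j) < var_floor) S(j, j) = var_floor;
      mu.row(k) = mk;
      Sigma.slice(k) = S;
    }
    if (iter > 0 && std::abs(ll - ll_prev) <
        tol * (std::abs(ll_prev) + 1.0)) { converged = true; break; }
    ll_prev = ll;
  }
  // final log-likelihood under the updated parameters
  double ll_final = degenerate && ll_trace.empty() ? -datum::inf
    : cpp_hmm_loglik(X, pi, A, mu, Sigma);
  return Rcpp::List::create(
    Rcpp::Named("initial_probs") = pi,
    Rcpp::Named("transition_matrix") = A,
    Rcpp::Named("state_means") = mu,
    Rcpp::Named("state_covariances") = Sigma,
    Rcpp::Named("log_likelihood") = ll_final,
    Rcpp::Named("ll_trace") = ll_trace,
    Rcpp::Named("degenerate") = degenerate,
    Rcpp::Named("converged") = converged);
}

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_hmm_viterbi(const arma::mat& X, const arma::rowvec& pi,
                                    const arma::mat& A, const arma::mat& mu,
                                    const arma::cube& Sigma) {
  const uword T = X.n_rows, K = mu.n_rows;
  mat logB = log_emission(X, mu, Sigma);
  mat logA = log(A + 1e-300);
  rowvec logpi = log(pi + 1e-300);
  mat delta(T, K);
  umat psi(T, K, fill::zeros);
  delta.row(0) = logpi + logB.row(0);
  for (uword t = 1; t < T; ++t) {
    for (uword k = 0; k < K; ++k) {
      vec cand = delta.row(t - 1).t() + logA.col(k);
      uword best = cand.index_max();
      psi(t, k) = best;
      delta(t, k) = cand(best) + logB(t, k);
    }
  }
  Rcpp::IntegerVector path(T);
  uword s = delta.row(T - 1).index_max();
  path[T - 1] = (int)s + 1;
  for (uword t = T - 1; t-- > 0; ) {
    s = psi(t + 1, s);
    path[t] = (int)s + 1;
  }
  return path;
}
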