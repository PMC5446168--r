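#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Profiled likelihood machinery for the hierarchical yield model
//
//   y_c = X_c beta + X_c b_c + eps_c,  b_c ~ N(0, sigma^2 * diag(lambda)),
//   eps_c ~ N(0, sigma^2 * phi_c * I),   phi_1 = 1.
//
// Random-effect variances are parameterized relative to sigma^2
// (lambda = D/sigma^2) so that beta (GLS) and sigma^2 profile out in
// closed form. All quantities are computed from per-region sufficient
// statistics A_c = X_c'X_c, u_c = X_c'y_c, s_c = y_c'y_c via the
// Woodbury identity: with S = diag(sqrt(lambda)) and
// M_c = phi_c I + S A_c S,
//   X_c' W_c^{-1} X_c = (A_c - A_c S M_c^{-1} S A_c) / phi_c
//   log|W_c| = (n_c - q) log phi_c + log|M_c|
// where W_c = phi_c I + X_c diag(lambda) X_c'.

struct MMState {
  mat H;        // sum_c X'W^{-1}X
  vec g;        // sum_c X'W^{-1}y
  double yy;    // sum_c y'W^{-1}y
  double ldet;  // sum_c log|W_c|
  double n;
  bool ok;
};

static MMState mm_accumulate(const cube& A, const mat& U, const vec& s,
                             const vec& nv, const vec& lambda,
                             const vec& phi) {
  const int C = A.n_slices;
  const int q = A.n_rows;
  MMState st;
  st.H.zeros(q, q);
  st.g.zeros(q);
  st.yy = 0.0;
  st.ldet = 0.0;
  st.n = accu(nv);
  st.ok = true;
  vec sl = sqrt(lambda);
  mat SS = sl * sl.t();
  for (int c = 0; c < C; ++c) {
    const mat& Ac = A.slice(c);
    vec uc = U.col(c);
    mat M = Ac % SS;
    M.diag() += phi(c);
    mat R;
    if (!chol(R, M)) { st.ok = false; return st; }
    st.ldet += (nv(c) - q) * std::log(phi(c)) + 2.0 * accu(log(R.diag()));
    // SA = S * A (rows scaled), Su = S u
    mat SA = Ac.each_col() % sl;
    vec Su = uc % sl;
    mat Mi_SA = solve(trimatu(R), solve(trimatl(R.t()), SA));
    vec Mi_Su = solve(trimatu(R), solve(trimatl(R.t()), Su));
    st.H += (Ac - SA.t() * Mi_SA) / phi(c);
    st.g += (uc - SA.t() * Mi_Su) / phi(c);
    st.yy += (s(c) - dot(Su, Mi_Su)) / phi(c);
  }
  return st;
}

static void theta_to_par(const vec& theta, int q, int C, bool random_eff,
                         bool het, vec& lambda, vec& phi) {
  lambda.zeros(q);
  phi.ones(C);
  int k = 0;
  if (random_eff)
    for (int j = 0; j < q; ++j) lambda(j) = std::exp(theta(k++));
  if (het)
    for (int c = 1; c < C; ++c) phi(c) = std::exp(theta(k++));
}

// Negative profiled log-likelihood (ML or REML) as a function of theta =
// (log lambda[active], log phi[2..C]).
// [[Rcpp::export]]
double mm_nll_cpp(const arma::vec& theta, const arma::cube& A,
                  const arma::mat& U, const arma::vec& s,
                  const arma::vec& nv, bool random_eff, bool het,
                  bool reml) {
  const int q = A.n_rows;
  const int C = A.n_slices;
  vec lambda, phi;
  theta_to_par(theta, q, C, random_eff, het, lambda, phi);
  MMState st = mm_accumulate(A, U, s, nv, lambda, phi);
  if (!st.ok) return 1e10;
  vec beta;
  if (!solve(beta, st.H, st.g, solve_opts::no_approx)) return 1e10;
  double Q = st.yy - dot(beta, st.g);
  if (!(Q > 1e-300)) return 1e10;
  double nll;
  if (!reml) {
    double sig2 = Q / st.n;
    nll = 0.5 * (st.n * std::log(2.0 * M_PI * sig2) + st.ldet + st.n);
  } else {
    double sig2 = Q / (st.n - q);
    double lh, sign;
    if (!log_det(lh, sign, st.H) || sign <= 0) return 1e10;
    nll = 0.5 * ((st.n - q) * std::log(2.0 * M_PI * sig2) + st.ldet + lh +
                 (st.n - q));
  }
  if (!std::isfinite(nll)) return 1e10;
  return nll;
}

// Full evaluation at given variance parameters: GLS beta, its unscaled
// covariance H^{-1}, profiled sigma^2, log-likelihood and per-region
// BLUPs b_c = lambda * S... = diag(lambda) X'W^{-1}(y - X beta).
// [[Rcpp::export]]
Rcpp::List mm_eval_cpp(const arma::cube& A, const arma::mat& U,
                       const arma::vec& s, const arma::vec& nv,
                       const arma::vec& lambda, const arma::vec& phi,
                       bool reml, bool blups) {
  const int q = A.n_rows;
  const int C = A.n_slices;
  MMState st = mm_accumulate(A, U, s, nv, lambda, phi);
  if (!st.ok) Rcpp::stop("covariance factorization failed (non-PD block)");
  vec beta = solve(st.H, st.g, solve_opts::no_approx);
  double Q = st.yy - dot(beta, st.g);
  if (Q < 0 && Q > -1e-8) Q = 0.0;
  double sig2 = reml ? Q / (st.n - q) : Q / st.n;
  double ll;
  if (!reml) {
    ll = (sig2 > 0) ? -0.5 * (st.n * std::log(2.0 * M_PI * sig2) + st.ldet +
                              st.n)
                    : datum::inf;
  } else {
    double lh, sign;
    log_det(lh, sign, st.H);
    ll = (sig2 > 0) ? -0.5 * ((st.n - q) * std::log(2.0 * M_PI * sig2) +
                              st.ldet + lh + (st.n - q))
                    : datum::inf;
  }
  mat B;
  if (blups) {
    B.zeros(q, C);
    vec sl = sqrt(lambda);
    mat SS = sl * sl.t();
    for (int c = 0; c < C; ++c) {
      const mat& Ac = A.slice(c);
      vec tc = U.col(c) - Ac * beta;  // X'(y - X beta)
      mat M = Ac % SS;
      M.diag() += phi(c);
      vec w = solve(M, sl % tc, solve_opts::likely_sympd);
      B.col(c) = lambda % ((tc - (Ac.each_col() % sl).t() * w) / phi(c));
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("beta") = beta, Rcpp::Named("H") = st.H,
      Rcpp::Named("sigma2") = sig2, Rcpp::Named("loglik") = ll,
      Rcpp::Named("ldet") = st.ldet, Rcpp::Named("Q") = Q,
      Rcpp::Named("blup") = B);
}
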