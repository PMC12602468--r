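// Dual-Kalman time-varying MVAR estimation and band-averaged PDC.
// Hot path: called once per surrogate inside the bootstrap, so it has to be
// cheap.  The parameter filter is run as N independent row filters (dimension
// N*p each); with isotropic prior/process noise and a diagonal observation
// noise this decouples exactly from the joint vec-form filter.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// OLS fit of a stationary VAR(p): X is T x N, returns A (N x N*p, blocks
// A_1..A_p left to right) and innovation covariance Sigma.
static void ols_var(const mat& X, const int p, mat& A, mat& Sigma) {
  const int T = X.n_rows, N = X.n_cols;
  const int Te = T - p;
  mat Z(Te, N * p);
  for (int k = 1; k <= p; ++k)
    Z.cols((k - 1) * N, k * N - 1) = X.rows(p - k, T - k - 1);
  const mat Y = X.rows(p, T - 1);
  mat B;
  if (!solve(B, Z, Y, solve_opts::no_approx))
    Rcpp::stop("rank-deficient regressor matrix in stationary VAR fit");
  A = B.t();
  const mat E = Y - Z * B;
  const int dof = std::max(Te - N * p, 1);
  Sigma = E.t() * E / dof;
}

// [[Rcpp::export(name = ".ols_var_cpp")]]
Rcpp::List ols_var_cpp(const arma::mat& X, const int p) {
  mat A, Sigma;
  ols_var(X, p, A, Sigma);
  return Rcpp::List::create(Rcpp::Named("A") = A, Rcpp::Named("Sigma") = Sigma);
}

// Dual extended Kalman filter for time-varying VAR(p) coefficients.
//   X             T x N observed series
//   process_noise q, random-walk variance of each coefficient
//   init_param_cov  initial diagonal covariance of the coefficient filters
//   state_noise   observation noise variance of the state filter
//   cov_cap       divergence guard on trace of any row filter covariance
// Returns coefficient cube (N x N*p x T-p), the OLS initializer and Sigma.
// [[Rcpp::export(name = ".dekf_cpp")]]
Rcpp::List dekf_cpp(const arma::mat& X, const int p,
                    const double process_noise, const double init_param_cov,
                    const double state_noise, const double cov_cap) {
  const int T = X.n_rows, N = X.n_cols, Np = N * p;

  mat A0, Sigma;
  ols_var(X, p, A0, Sigma);

  // Parameter filters: one per target row i, state = row i of [A_1..A_p].
  mat theta = A0;                       // N x Np, row i = filter i state
  cube C(Np, Np, N);
  for (int i = 0; i < N; ++i) C.slice(i) = init_param_cov * eye(Np, Np);
  vec r_param = Sigma.diag();
  r_param.transform([](double v) { return std::max(v, 1e-12); });

  // State filter in companion form, state s = [x_t; x_{t-1}; ...].
  vec s(Np);
  for (int k = 1; k <= p; ++k) s.subvec((k - 1) * N, k * N - 1) = X.row(p - k).t();
  mat Ps = kron(eye(p, p), Sigma);
  const mat Qs = Sigma;                 // innovation feeds the top block only

  cube coeffs(N, Np, T - p);

  for (int t = p; t < T; ++t) {
    const vec z = s;                    // filtered lags x_{t-1},...,x_{t-p}

    // --- parameter filters: predict (random walk) then update with y_t
    for (int i = 0; i < N; ++i) {
      mat& Ci = C.slice(i);
      Ci.diag() += process_noise;
      const vec g = Ci * z;
      const double S = dot(z, g) + r_param(i);
      const double e = X(t, i) - dot(theta.row(i), z);
      const vec K = g / S;
      theta.row(i) += (K * e).t();
      Ci -= K * g.t();
      Ci = 0.5 * (Ci + Ci.t());
      if (trace(Ci) > cov_cap)
        Rcpp::stop("parameter filter covariance diverged at time index %d (row %d)",
                   t + 1, i + 1);
    }
    coeffs.slice(t - p) = theta;

    // --- state filter with the freshly updated coefficients
    vec s_pred(Np);
    s_pred.head(N) = theta * z;
    if (p > 1) s_pred.subvec(N, Np - 1) = s.head(Np - N);
    // companion transition F: top block rows = theta, sub-identity below
    mat F(Np, Np, fill::zeros);
    F.rows(0, N - 1) = theta;
    if (p > 1) F.submat(N, 0, Np - 1, Np - N - 1) = eye(Np - N, Np - N);
    mat Pp = F * Ps * F.t();
    Pp.submat(0, 0, N - 1, N - 1) += Qs;
    mat Sobs = Pp.submat(0, 0, N - 1, N - 1) + state_noise * eye(N, N);
    mat Ks = solve(Sobs, Pp.rows(0, N - 1), solve_opts::likely_sympd).t(); // Np x N
    const vec innov = X.row(t).t() - s_pred.head(N);
    s = s_pred + Ks * innov;
    Ps = Pp - Ks * Pp.rows(0, N - 1);
    Ps = 0.5 * (Ps + Ps.t());
  }

  return Rcpp::List::create(Rcpp::Named("coeffs") = coeffs,
                            Rcpp::Named("A0") = A0,
                            Rcpp::Named("Sigma") = Sigma);
}

// Band- and time-averaged PDC from a coefficient cube.
//   coeffs  N x N*p x Tt cube of time-varying coefficients
//   freqs   frequencies (Hz) to evaluate (already restricted to the band)
//   burn    number of leading time points of the cube to skip
// [[Rcpp::export(name = ".tpdc_band_cpp")]]
arma::mat tpdc_band_cpp(const arma::cube& coeffs, const arma::vec& freqs,
                        const double TR, const int burn) {
  const int N = coeffs.n_rows, Np = coeffs.n_cols, Tt = coeffs.n_slices;
  const int p = Np / N, nf = freqs.n_elem;
  if (burn >= Tt) Rcpp::stop("burn-in leaves no time points");

  // phase factors e^{-i 2 pi f k TR}, per frequency and lag
  cx_mat phase(nf, p);
  for (int f = 0; f < nf; ++f)
    for (int k = 1; k <= p; ++k)
      phase(f, k - 1) = std::exp(std::complex<double>(0.0, -2.0 * M_PI * freqs(f) * k * TR));

  mat acc(N, N, fill::zeros);
  long n_terms = 0;

  if (p == 1) {
    // Closed form for order 1: |I - A e^{-iw}| has off-diagonal magnitudes
    // |a_ij| independent of frequency; only the diagonal term and hence the
    // column norm depend on f through cos(w).
    vec cosw(nf);
    for (int f = 0; f < nf; ++f) cosw(f) = std::cos(2.0 * M_PI * freqs(f) * TR);
    for (int t = burn; t < Tt; ++t) {
      const mat& At = coeffs.slice(t);
      const rowvec S = sum(square(At), 0);   // column sums of a_ij^2
      for (int f = 0; f < nf; ++f) {
        for (int j = 0; j < N; ++j) {
          const double cn2 = S(j) + 1.0 - 2.0 * At(j, j) * cosw(f);
          if (cn2 <= 0.0)
            Rcpp::stop("degenerate transfer column %d at frequency %g Hz",
                       j + 1, freqs(f));
          const double inv_cn = 1.0 / std::sqrt(cn2);
          for (int i = 0; i < N; ++i) {
            const double m = (i == j)
              ? std::sqrt(std::max(cn2 - S(j) + At(j, j) * At(j, j), 0.0))
              : std::abs(At(i, j));
            acc(i, j) += m * inv_cn;
          }
        }
      }
      ++n_terms;
    }
    return acc / (static_cast<double>(n_terms) * nf);
  }

  cx_mat Abar(N, N);
  for (int t = burn; t < Tt; ++t) {
    const mat& At = coeffs.slice(t);
    for (int f = 0; f < nf; ++f) {
      Abar.eye(N, N);
      for (int k = 0; k < p; ++k)
        Abar -= cx_mat(At.cols(k * N, (k + 1) * N - 1), mat(N, N, fill::zeros)) * phase(f, k);
      const mat mag = abs(Abar);
      const rowvec cn = sqrt(sum(square(mag), 0));
      for (int j = 0; j < N; ++j) {
        if (cn(j) <= 0.0)
          Rcpp::stop("degenerate transfer column %d at frequency %g Hz", j + 1, freqs(f));
        acc.col(j) += mag.col(j) / cn(j);
      }
    }
    ++n_terms;
  }
  return acc / (static_cast<double>(n_terms) * nf);
}
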