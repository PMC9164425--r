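// Data-augmentation Gibbs sampler for the two-study random-effect
// Mendelian-randomization model.  Each sweep imputes the Study-B exposures
// from their conditional normals, updates the regression coefficient blocks
// of the four structural equations, the residual standard deviations (slice
// step; inverse-gamma prior is on the sd, not the variance) and the latent
// per-individual confounders.  Uses R's RNG so set.seed() in R governs
// reproducibility.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static vec rnorm_vec(unsigned int n) {
  vec z(n);
  for (unsigned int i = 0; i < n; ++i) z(i) = R::norm_rand();
  return z;
}

// one draw from N(P^{-1} b, P^{-1}) given precision matrix P
static vec mvn_prec(const mat& P, const vec& b) {
  mat U = chol(P);  // P = U' U
  vec mu = solve(trimatu(U), solve(trimatl(U.t()), b));
  return mu + solve(trimatu(U), rnorm_vec(b.n_elem));
}

// slice sampler on t = log(sigma); target
//   f(t) = -(n + shape) t - SS/2 * exp(-2t) - scale * exp(-t)
// (normal likelihood with residual sum of squares SS over n observations,
//  Inv-Gamma(shape, scale) prior on sigma)
static double slice_logsigma(double t0, double n, double SS,
                             double shape, double scale) {
  const double w = 0.25;
  auto logf = [&](double t) {
    return -(n + shape) * t - 0.5 * SS * std::exp(-2.0 * t)
           - scale * std::exp(-t);
  };
  double y = logf(t0) + std::log(R::unif_rand());
  double L = t0 - w * R::unif_rand();
  double Rr = L + w;
  int m = 200;
  while (m-- > 0 && logf(L) > y) L -= w;
  m = 200;
  while (m-- > 0 && logf(Rr) > y) Rr += w;
  for (int k = 0; k < 200; ++k) {
    double t1 = L + (Rr - L) * R::unif_rand();
    if (logf(t1) >= y) return t1;
    if (t1 < t0) L = t1; else Rr = t1;
  }
  return t0;
}

// slice sampler on u = log(s) for the scale group move (U, delta) ->
// (sU, delta/s); with Haar measure ds/s and Jacobian s^{nU-4} the target is
//   f(u) = npow*u - a/2 * exp(2u) - b/2 * exp(-2u),  npow = nU - 4,
// a = sum(U^2), b = sum(delta^2)/delta_sd^2 (likelihood is invariant)
static double slice_logscale(double a, double b, double npow) {
  const double w = 0.05;
  auto logf = [&](double u) {
    return npow * u - 0.5 * a * std::exp(2.0 * u)
           - 0.5 * b * std::exp(-2.0 * u);
  };
  double u0 = 0.0;
  double y = logf(u0) + std::log(R::unif_rand());
  double L = u0 - w * R::unif_rand();
  double Rr = L + w;
  int m = 200;
  while (m-- > 0 && logf(L) > y) L -= w;
  m = 200;
  while (m-- > 0 && logf(Rr) > y) Rr += w;
  for (int k = 0; k < 200; ++k) {
    double u1 = L + (Rr - L) * R::unif_rand();
    if (logf(u1) >= y) return u1;
    if (u1 < u0) L = u1; else Rr = u1;
  }
  return u0;
}

// slice sampler on u = log s for the joint rescale of a latent-exposure
// residual vector and its residual sd, sigma' = s*sigma, X* = m + s*(X*-m);
// all Jacobian and normalisation powers of s cancel, leaving
//   f(u) = -(sh+1) u - (sc/sig) exp(-u) + A1 exp(u) - A2 exp(2u)
// with A1, A2 from the outcome-equation quadratic in the rescaled X*
static double slice_sigscale(double sig, double sh, double sc,
                             double A1, double A2) {
  const double w = 0.5;
  auto logf = [&](double u) {
    return -(sh + 1.0) * u - (sc / sig) * std::exp(-u)
           + A1 * std::exp(u) - A2 * std::exp(2.0 * u);
  };
  double u0 = 0.0;
  double y = logf(u0) + std::log(R::unif_rand());
  double L = u0 - w * R::unif_rand();
  double Rr = L + w;
  int m = 200;
  while (m-- > 0 && logf(L) > y) L -= w;
  m = 200;
  while (m-- > 0 && logf(Rr) > y) Rr += w;
  for (int k = 0; k < 200; ++k) {
    double u1 = L + (Rr - L) * R::unif_rand();
    if (logf(u1) >= y) return u1;
    if (u1 < u0) L = u1; else Rr = u1;
  }
  return u0;
}

// coefficient block of one structural equation across the two studies:
// response yA ~ N(WA c, s2A I), yB ~ N(WB c, s2B I), c ~ N(0, prior_prec^-1)
static vec reg_update(const mat& WA, const vec& yA, double s2A,
                      const mat& WB, const vec& yB, double s2B,
                      const vec& prior_prec) {
  mat P = WA.t() * WA / s2A + WB.t() * WB / s2B + diagmat(prior_prec);
  vec b = WA.t() * yA / s2A + WB.t() * yB / s2B;
  return mvn_prec(P, b);
}

// [[Rcpp::export]]
Rcpp::List gibbs_chain(const arma::mat& Z1A, const arma::mat& Z2A,
                       const arma::mat& Z3A,
                       const arma::vec& X1A, const arma::vec& X2A,
                       const arma::vec& Y1A, const arma::vec& Y2A,
                       const arma::mat& Z1B, const arma::mat& Z2B,
                       const arma::mat& Z3B,
                       const arma::vec& Y1B, const arma::vec& Y2B,
                       Rcpp::List priors, Rcpp::List init,
                       int iter, int warmup, int thin,
                       bool include_V, bool keep_latent) {
  const unsigned int nA = Z1A.n_rows, nB = Z1B.n_rows;
  const unsigned int L = Z1A.n_cols, K = Z2A.n_cols, M = Z3A.n_cols;
  const double a_sd = priors["alpha_sd"], b_sd = priors["beta_sd"],
               d_sd = priors["delta_sd"], V_sd = priors["V_sd"],
               sh = priors["sigma_shape"], sc = priors["sigma_scale"];
  const double V_prec = include_V ? 1.0 / (V_sd * V_sd) : 1e12;

  // state
  vec a1 = init["alpha1"], a2 = init["alpha2"],
      a31 = init["alpha31"], a32 = init["alpha32"];
  double b1 = init["beta1"], b2 = init["beta2"];
  vec d = init["delta"];    // X1, X2, Y1, Y2
  vec V = init["V"];        // X1, X2, Y1, Y2 (Study B only)
  vec s = init["sigma"];    // X1A, X2A, Y1A, Y2A, X1B, X2B, Y1B, Y2B (sds)
  vec UA = init["UA"], UB = init["UB"];
  vec X1B = init["X1B"], X2B = init["X2B"];
  if (!include_V) V.zeros();

  const unsigned int p1 = L + M, p2 = K + M;
  // persistent designs for the exposure equations: [Z block | Z3 | U | V]
  mat WX1A(nA, p1 + 2, fill::zeros), WX1B(nB, p1 + 2, fill::zeros);
  if (p1 > 0) {
    WX1A.cols(0, p1 - 1) = join_rows(Z1A, Z3A);
    WX1B.cols(0, p1 - 1) = join_rows(Z1B, Z3B);
  }
  WX1B.col(p1 + 1).ones();
  mat WX2A(nA, p2 + 2, fill::zeros), WX2B(nB, p2 + 2, fill::zeros);
  if (p2 > 0) {
    WX2A.cols(0, p2 - 1) = join_rows(Z2A, Z3A);
    WX2B.cols(0, p2 - 1) = join_rows(Z2B, Z3B);
  }
  WX2B.col(p2 + 1).ones();
  mat WYA(nA, 3, fill::zeros), WYB(nB, 3, fill::zeros);
  WYB.col(2).ones();

  vec ppX1(p1 + 2), ppX2(p2 + 2), ppY(3);
  ppX1.fill(1.0 / (a_sd * a_sd)); ppX1(p1) = 1.0 / (d_sd * d_sd);
  ppX1(p1 + 1) = V_prec;
  ppX2.fill(1.0 / (a_sd * a_sd)); ppX2(p2) = 1.0 / (d_sd * d_sd);
  ppX2(p2 + 1) = V_prec;
  ppY(0) = 1.0 / (b_sd * b_sd); ppY(1) = 1.0 / (d_sd * d_sd); ppY(2) = V_prec;

  const unsigned int npar = L + K + 2 * M + 18;
  const unsigned int nkeep = iter / thin;
  mat draws(nkeep, npar);
  vec sumUA(nA, fill::zeros), sumUB(nB, fill::zeros),
      sumX1B(nB, fill::zeros), sumX2B(nB, fill::zeros);
  mat keepUA, keepUB, keepX1B, keepX2B;
  if (keep_latent) {
    keepUA.set_size(nkeep, nA); keepUB.set_size(nkeep, nB);
    keepX1B.set_size(nkeep, nB); keepX2B.set_size(nkeep, nB);
  }

  unsigned int stored = 0;
  for (int it = 0; it < warmup + iter; ++it) {
    // --- impute the Study-B exposures from their conditional normals
    vec gX1B = V(0) + Z1B * a1 + Z3B * a31;   // mean without the U term
    vec gX2B = V(1) + Z2B * a2 + Z3B * a32;
    {
      double s2x = s(4) * s(4), s2y = s(6) * s(6);
      double prec = 1.0 / s2x + b1 * b1 / s2y;
      vec m = ((gX1B + d(0) * UB) / s2x
               + b1 * (Y1B - V(2) - d(2) * UB) / s2y) / prec;
      X1B = m + rnorm_vec(nB) / std::sqrt(prec);
    }
    {
      double s2x = s(5) * s(5), s2y = s(7) * s(7);
      double prec = 1.0 / s2x + b2 * b2 / s2y;
      vec m = ((gX2B + d(1) * UB) / s2x
               + b2 * (Y2B - V(3) - d(3) * UB) / s2y) / prec;
      X2B = m + rnorm_vec(nB) / std::sqrt(prec);
    }

    // --- coefficient blocks of the four structural equations
    WX1A.col(p1) = UA; WX1B.col(p1) = UB;
    vec c = reg_update(WX1A, X1A, s(0) * s(0), WX1B, X1B, s(4) * s(4), ppX1);
    if (L) a1 = c.subvec(0, L - 1);
    if (M) a31 = c.subvec(L, L + M - 1);
    d(0) = c(p1); V(0) = include_V ? c(p1 + 1) : 0.0;

    WX2A.col(p2) = UA; WX2B.col(p2) = UB;
    c = reg_update(WX2A, X2A, s(1) * s(1), WX2B, X2B, s(5) * s(5), ppX2);
    if (K) a2 = c.subvec(0, K - 1);
    if (M) a32 = c.subvec(K, K + M - 1);
    d(1) = c(p2); V(1) = include_V ? c(p2 + 1) : 0.0;

    WYA.col(0) = X1A; WYA.col(1) = UA;
    WYB.col(0) = X1B; WYB.col(1) = UB;
    c = reg_update(WYA, Y1A, s(2) * s(2), WYB, Y1B, s(6) * s(6), ppY);
    b1 = c(0); d(2) = c(1); V(2) = include_V ? c(2) : 0.0;

    WYA.col(0) = X2A; WYB.col(0) = X2B;
    c = reg_update(WYA, Y2A, s(3) * s(3), WYB, Y2B, s(7) * s(7), ppY);
    b2 = c(0); d(3) = c(1); V(3) = include_V ? c(2) : 0.0;

    // --- translation move along the imputation ridge: the likelihood is
    // invariant under (X1B + c, V_X1 + c, V_Y1 - b1 c); only the V priors
    // constrain c, so sample c from its exact Gaussian conditional to make
    // the random-effect intercepts mix (same for the second pair)
    if (include_V) {
      double v2 = V_sd * V_sd;
      {
        double m = (b1 * V(2) - V(0)) / (1.0 + b1 * b1);
        double c1 = m + std::sqrt(v2 / (1.0 + b1 * b1)) * R::norm_rand();
        X1B += c1; V(0) += c1; V(2) -= b1 * c1;
      }
      {
        double m = (b2 * V(3) - V(1)) / (1.0 + b2 * b2);
        double c2 = m + std::sqrt(v2 / (1.0 + b2 * b2)) * R::norm_rand();
        X2B += c2; V(1) += c2; V(3) -= b2 * c2;
      }
    }

    // --- scale group move on the (U, delta) ridge
    {
      double a = dot(UA, UA) + dot(UB, UB);
      double b = dot(d, d) / (d_sd * d_sd);
      double sfac = std::exp(slice_logscale(a, b, (double)(nA + nB) - 4.0));
      UA *= sfac; UB *= sfac; d /= sfac;
    }

    // --- residual standard deviations (slice step on log sigma)
    vec gX1A = Z1A * a1 + Z3A * a31;          // means without the U term
    vec gX2A = Z2A * a2 + Z3A * a32;
    gX1B = V(0) + Z1B * a1 + Z3B * a31;
    gX2B = V(1) + Z2B * a2 + Z3B * a32;
    vec gY1A = b1 * X1A, gY2A = b2 * X2A;
    vec gY1B = V(2) + b1 * X1B, gY2B = V(3) + b2 * X2B;
    vec rX1A = X1A - gX1A - d(0) * UA, rX2A = X2A - gX2A - d(1) * UA;
    vec rY1A = Y1A - gY1A - d(2) * UA, rY2A = Y2A - gY2A - d(3) * UA;
    vec rX1B = X1B - gX1B - d(0) * UB, rX2B = X2B - gX2B - d(1) * UB;
    vec rY1B = Y1B - gY1B - d(2) * UB, rY2B = Y2B - gY2B - d(3) * UB;
    const vec* res[8] = { &rX1A, &rX2A, &rY1A, &rY2A,
                          &rX1B, &rX2B, &rY1B, &rY2B };
    for (int j = 0; j < 8; ++j) {
      double n_j = (j < 4) ? (double)nA : (double)nB;
      double SS = dot(*res[j], *res[j]);
      s(j) = std::exp(slice_logsigma(std::log(s(j)), n_j, SS, sh, sc));
    }

    // --- joint rescale of each Study-B residual sd with its latent
    // exposures, X* -> m + s (X* - m): frees sigma_X1B/sigma_X2B from the
    // self-reinforcing random walk they perform when the causal effect is
    // near zero (the outcome equation then carries little information)
    {
      vec r = X1B - gX1B - d(0) * UB;
      vec dd = (Y1B - gY1B - d(2) * UB) + b1 * r;
      double s2Y = s(6) * s(6);
      double A1 = b1 * dot(dd, r) / s2Y;
      double A2 = b1 * b1 * dot(r, r) / (2.0 * s2Y);
      double sf = std::exp(slice_sigscale(s(4), sh, sc, A1, A2));
      s(4) *= sf;
      X1B += (sf - 1.0) * r;
      gY1B = V(2) + b1 * X1B;
    }
    {
      vec r = X2B - gX2B - d(1) * UB;
      vec dd = (Y2B - gY2B - d(3) * UB) + b2 * r;
      double s2Y = s(7) * s(7);
      double A1 = b2 * dot(dd, r) / s2Y;
      double A2 = b2 * b2 * dot(r, r) / (2.0 * s2Y);
      double sf = std::exp(slice_sigscale(s(5), sh, sc, A1, A2));
      s(5) *= sf;
      X2B += (sf - 1.0) * r;
      gY2B = V(3) + b2 * X2B;
    }

    // --- latent confounders
    {
      double precU = 1.0
        + d(0) * d(0) / (s(0) * s(0)) + d(1) * d(1) / (s(1) * s(1))
        + d(2) * d(2) / (s(2) * s(2)) + d(3) * d(3) / (s(3) * s(3));
      vec m = (d(0) * (X1A - gX1A) / (s(0) * s(0))
               + d(1) * (X2A - gX2A) / (s(1) * s(1))
               + d(2) * (Y1A - gY1A) / (s(2) * s(2))
               + d(3) * (Y2A - gY2A) / (s(3) * s(3))) / precU;
      UA = m + rnorm_vec(nA) / std::sqrt(precU);
    }
    {
      double precU = 1.0
        + d(0) * d(0) / (s(4) * s(4)) + d(1) * d(1) / (s(5) * s(5))
        + d(2) * d(2) / (s(6) * s(6)) + d(3) * d(3) / (s(7) * s(7));
      vec m = (d(0) * (X1B - gX1B) / (s(4) * s(4))
               + d(1) * (X2B - gX2B) / (s(5) * s(5))
               + d(2) * (Y1B - gY1B) / (s(6) * s(6))
               + d(3) * (Y2B - gY2B) / (s(7) * s(7))) / precU;
      UB = m + rnorm_vec(nB) / std::sqrt(precU);
    }

    // --- translation move along the (U_B, V) ridge: U_B + c with each
    // V_k - delta_k c leaves the Study-B likelihood invariant; c is pinned
    // only by the U prior and the V priors, so refresh it exactly
    if (include_V) {
      double v2 = V_sd * V_sd;
      double P = (double)nB + dot(d, d) / v2;
      double mc = (dot(d, V) / v2 - accu(UB)) / P;
      double cc = mc + R::norm_rand() / std::sqrt(P);
      UB += cc;
      V -= d * cc;
    }

    // --- store
    if (it >= warmup && (it - warmup) % thin == 0) {
      unsigned int pos = 0;
      rowvec row(npar);
      for (unsigned int j = 0; j < L; ++j) row(pos++) = a1(j);
      for (unsigned int j = 0; j < K; ++j) row(pos++) = a2(j);
      for (unsigned int j = 0; j < M; ++j) row(pos++) = a31(j);
      for (unsigned int j = 0; j < M; ++j) row(pos++) = a32(j);
      row(pos++) = b1; row(pos++) = b2;
      for (int j = 0; j < 4; ++j) row(pos++) = d(j);
      for (int j = 0; j < 4; ++j) row(pos++) = V(j);
      for (int j = 0; j < 8; ++j) row(pos++) = s(j);
      draws.row(stored) = row;
      sumUA += UA; sumUB += UB; sumX1B += X1B; sumX2B += X2B;
      if (keep_latent) {
        keepUA.row(stored) = UA.t(); keepUB.row(stored) = UB.t();
        keepX1B.row(stored) = X1B.t(); keepX2B.row(stored) = X2B.t();
      }
      ++stored;
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  Rcpp::List latent = Rcpp::List::create(
    Rcpp::Named("UA") = sumUA / stored,
    Rcpp::Named("UB") = sumUB / stored,
    Rcpp::Named("X1B") = sumX1B / stored,
    Rcpp::Named("X2B") = sumX2B / stored);
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("draws") = draws,
    Rcpp::Named("latent_mean") = latent);
  if (keep_latent) {
    out["latent_draws"] = Rcpp::List::create(
      Rcpp::Named("UA") = keepUA, Rcpp::Named("UB") = keepUB,
      Rcpp::Named("X1B") = keepX1B, Rcpp::Named("X2B") = keepX2B);
  }
  return out;
}
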