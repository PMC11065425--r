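// Photon-by-photon hidden Markov model core.
//
// The hidden chain evolves on the sync clock (one transition matrix A per
// tick); photons are observed at integer tick times with a 3-category
// emission per state. Between consecutive photons separated by `delta`
// ticks the transition operator is A^delta, evaluated through the spectral
// decomposition A = R diag(lambda) R^-1. The E-step uses exact
// interval-resolved expected transition counts: for a gap of delta ticks the
// sum over all unobserved tick positions of the pairwise posteriors has the
// closed form
//   xi_ij = A_ij * sum_{p,q} (uR)_p Rinv_{p,i} R_{j,q} (Rinv v)_q S_pq,
//   S_pq  = (lambda_p^delta - lambda_q^delta) / (lambda_p - lambda_q)
//           (or delta * lambda_p^(delta-1) when the eigenvalues coincide),
// where u is the scaled forward vector at the left photon and v the
// emission-weighted, rescaled backward vector at the right photon.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double FLOOR = 1e-300;

struct Spectral {
  cx_vec lambda;
  cx_mat R;
  cx_mat Rinv;
  // real fast path (transition matrices of near-identity chains have real
  // spectra in practice)
  bool real_ok;
  vec rlambda;
  mat rR;
  mat rRinv;
  bool ok;
};

static Spectral decompose(const mat& A) {
  Spectral s;
  s.real_ok = false;
  cx_vec eval;
  cx_mat evec;
  s.ok = eig_gen(eval, evec, A);
  if (s.ok) {
    s.lambda = eval;
    s.R = evec;
    s.ok = inv(s.Rinv, evec);
  }
  if (s.ok) {
    // nearly defective eigenbases reconstruct A poorly; then fall back to
    // repeated squaring (and the one-transition-per-gap E-step)
    double err = norm(real(s.R * diagmat(s.lambda) * s.Rinv) - A, "fro");
    if (!(err < 1e-10 * (1.0 + norm(A, "fro")))) s.ok = false;
  }
  if (s.ok && norm(imag(s.lambda), "inf") < 1e-14 &&
      norm(imag(s.R), "fro") < 1e-12 && all(real(s.lambda) > 0)) {
    s.real_ok = true;
    s.rlambda = real(s.lambda);
    s.rR = real(s.R);
    s.rRinv = real(s.Rinv);
  }
  return s;
}

static mat matpow_square(const mat& A, double n) {
  uword K = A.n_rows;
  mat result = eye(K, K);
  mat base = A;
  unsigned long long e = (unsigned long long)n;
  while (e > 0) {
    if (e & 1ULL) result = result * base;
    base = base * base;
    e >>= 1;
  }
  return result;
}

static mat matpow(const mat& A, double n, const Spectral& s) {
  uword K = A.n_rows;
  if (n == 0) return eye(K, K);
  if (n == 1) return A;
  mat P;
  if (s.real_ok) {
    vec lp(K);
    for (uword p = 0; p < K; ++p) lp(p) = std::pow(s.rlambda(p), n);
    P = s.rR * diagmat(lp) * s.rRinv;
  } else if (s.ok) {
    cx_vec lp(K);
    for (uword p = 0; p < K; ++p) lp(p) = std::pow(s.lambda(p), n);
    P = real(s.R * diagmat(lp) * s.Rinv);
  } else {
    P = matpow_square(A, n);
  }
  P.transform([](double x) { return x < 0 ? 0.0 : x; });
  return P;
}

// [[Rcpp::export]]
arma::mat cpp_matpow(const arma::mat& A, double n) {
  Spectral s = decompose(A);
  return matpow(A, n, s);
}

// Forward pass over one burst; returns log-likelihood, fills alpha (K x T)
// and scaling factors c (T).
static double forward_burst(const vec& pi, const mat& B,
                            const std::vector<mat>& P,
                            const ivec& obs, mat& alpha, vec& c) {
  uword T = obs.n_elem;
  double ll = 0;
  vec a = pi % B.col(obs(0));
  c(0) = accu(a);
  if (c(0) < FLOOR) c(0) = FLOOR;
  alpha.col(0) = a / c(0);
  ll += std::log(c(0));
  for (uword t = 1; t < T; ++t) {
    vec a2 = (P[t - 1].t() * alpha.col(t - 1)) % B.col(obs(t));
    c(t) = accu(a2);
    if (c(t) < FLOOR) c(t) = FLOOR;
    alpha.col(t) = a2 / c(t);
    ll += std::log(c(t));
  }
  return ll;
}

static void backward_burst(const mat& B, const std::vector<mat>& P,
                           const ivec& obs, const vec& c, mat& beta) {
  uword T = obs.n_elem;
  beta.col(T - 1).ones();
  for (uword t = T - 1; t >= 1; --t) {
    vec v = (B.col(obs(t)) % beta.col(t)) / c(t);
    beta.col(t - 1) = P[t - 1] * v;
  }
}

// Gap operators for one burst: P[t-1] = A^delta_t between photons t-1 and t.
static std::vector<mat> gap_ops(const mat& A, const Spectral& s,
                                const vec& delta, uword lo, uword hi) {
  std::vector<mat> P;
  P.reserve(hi - lo);
  for (uword t = lo + 1; t < hi; ++t) P.push_back(matpow(A, delta(t), s));
  return P;
}

// [[Rcpp::export]]
double cpp_h2mm_loglik(const arma::vec& pi, const arma::mat& A,
                       const arma::mat& B, const arma::vec& delta,
                       const arma::ivec& obs, const arma::ivec& offsets) {
  Spectral s = decompose(A);
  uword nb = offsets.n_elem - 1;
  double ll = 0;
  for (uword b = 0; b < nb; ++b) {
    uword lo = offsets(b), hi = offsets(b + 1), T = hi - lo;
    std::vector<mat> P = gap_ops(A, s, delta, lo, hi);
    mat alpha(pi.n_elem, T);
    vec c(T);
    ll += forward_burst(pi, B, P, obs.subvec(lo, hi - 1), alpha, c);
    if (!std::isfinite(ll))
      Rcpp::stop("non-finite log-likelihood in burst %d", (int)b + 1);
  }
  return ll;
}

// [[Rcpp::export]]
Rcpp::List cpp_h2mm_posteriors(const arma::vec& pi, const arma::mat& A,
                               const arma::mat& B, const arma::vec& delta,
                               const arma::ivec& obs,
                               const arma::ivec& offsets) {
  Spectral s = decompose(A);
  uword K = pi.n_elem, N = obs.n_elem, nb = offsets.n_elem - 1;
  mat gamma(K, N);
  double ll = 0;
  for (uword b = 0; b < nb; ++b) {
    uword lo = offsets(b), hi = offsets(b + 1), T = hi - lo;
    std::vector<mat> P = gap_ops(A, s, delta, lo, hi);
    ivec o = obs.subvec(lo, hi - 1);
    mat alpha(K, T), beta(K, T);
    vec c(T);
    ll += forward_burst(pi, B, P, o, alpha, c);
    backward_burst(B, P, o, c, beta);
    for (uword t = 0; t < T; ++t) {
      vec g = alpha.col(t) % beta.col(t);
      gamma.col(lo + t) = g / accu(g);
    }
  }
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("gamma") = gamma.t());
}

// [[Rcpp::export]]
Rcpp::List cpp_h2mm_em_step(const arma::vec& pi, const arma::mat& A,
                            const arma::mat& B, const arma::vec& delta,
                            const arma::ivec& obs,
                            const arma::ivec& offsets) {
  Spectral s = decompose(A);
  uword K = pi.n_elem, nb = offsets.n_elem - 1;
  vec pi_acc(K, fill::zeros);
  mat B_acc(K, 3, fill::zeros);
  mat Xi_acc(K, K, fill::zeros);
  double ll = 0;

  cx_mat Rst, Rinvst;
  if (s.ok) {
    Rst = strans(s.R);
    Rinvst = strans(s.Rinv);
  }

  for (uword b = 0; b < nb; ++b) {
    uword lo = offsets(b), hi = offsets(b + 1), T = hi - lo;
    std::vector<mat> P = gap_ops(A, s, delta, lo, hi);
    ivec o = obs.subvec(lo, hi - 1);
    mat alpha(K, T), beta(K, T);
    vec c(T);
    ll += forward_burst(pi, B, P, o, alpha, c);
    if (!std::isfinite(ll))
      Rcpp::stop("non-finite log-likelihood in burst %d", (int)b + 1);
    backward_burst(B, P, o, c, beta);

    for (uword t = 0; t < T; ++t) {
      vec g = alpha.col(t) % beta.col(t);
      g /= accu(g);
      if (t == 0) pi_acc += g;
      B_acc.col(o(t)) += g;
    }

    for (uword t = 0; t + 1 < T; ++t) {
      double d = delta(lo + t + 1);
      if (d < 1) continue;
      vec u = alpha.col(t);
      vec v = (B.col(o(t + 1)) % beta.col(t + 1)) / c(t + 1);
      if (s.real_ok) {
        rowvec uR = u.t() * s.rR;
        vec rv = s.rRinv * v;
        mat W(K, K);
        for (uword p = 0; p < K; ++p) {
          double lpd = std::pow(s.rlambda(p), d);
          for (uword q = 0; q < K; ++q) {
            double diffl = s.rlambda(p) - s.rlambda(q);
            double S;
            if (std::abs(diffl) > 1e-12) {
              S = (lpd - std::pow(s.rlambda(q), d)) / diffl;
            } else {
              S = d * std::pow(s.rlambda(p), d - 1);
            }
            W(p, q) = uR(p) * rv(q) * S;
          }
        }
        mat xi = A % (s.rRinv.t() * W * s.rR.t());
        xi.transform([](double x) { return x < 0 ? 0.0 : x; });
        Xi_acc += xi;
      } else if (s.ok) {
        cx_rowvec uR = conv_to<cx_rowvec>::from(u.t()) * s.R;
        cx_vec rv = s.Rinv * conv_to<cx_vec>::from(v);
        cx_mat W(K, K);
        for (uword p = 0; p < K; ++p) {
          cx_double lpd = std::pow(s.lambda(p), d);
          for (uword q = 0; q < K; ++q) {
            cx_double diff = s.lambda(p) - s.lambda(q);
            cx_double S;
            if (std::abs(diff) > 1e-12) {
              S = (lpd - std::pow(s.lambda(q), d)) / diff;
            } else {
              S = d * std::pow(s.lambda(p), d - 1);
            }
            W(p, q) = uR(p) * rv(q) * S;
          }
        }
        mat xi = A % real(Rinvst * W * Rst);
        xi.transform([](double x) { return x < 0 ? 0.0 : x; });
        Xi_acc += xi;
      } else {
        // conditioning fallback: treat the whole gap as a single step with
        // operator A^delta (one effective transition per gap)
        mat xi = (u * v.t()) % P[t];
        Xi_acc += xi;
      }
    }
  }

  vec pi_new = pi_acc / accu(pi_acc);
  mat A_new(K, K);
  for (uword i = 0; i < K; ++i) {
    double rs = accu(Xi_acc.row(i));
    if (rs > 0) {
      A_new.row(i) = Xi_acc.row(i) / rs;
    } else {
      A_new.row(i).zeros();
      A_new(i, i) = 1.0;
    }
  }
  mat B_new(K, 3);
  for (uword i = 0; i < K; ++i) {
    rowvec r = B_acc.row(i) + 1e-12;
    B_new.row(i) = r / accu(r);
  }
  return Rcpp::List::create(
      Rcpp::Named("loglik") = ll, Rcpp::Named("prior") = pi_new,
      Rcpp::Named("trans") = A_new, Rcpp::Named("emit") = B_new,
      Rcpp::Named("spectral_ok") = s.ok);
}

// [[Rcpp::export]]
Rcpp::List cpp_h2mm_viterbi(const arma::vec& pi, const arma::mat& A,
                            const arma::mat& B, const arma::vec& delta,
                            const arma::ivec& obs,
                            const arma::ivec& offsets) {
  Spectral s = decompose(A);
  uword K = pi.n_elem, N = obs.n_elem, nb = offsets.n_elem - 1;
  ivec states(N);
  vec logprob(nb);
  vec lpi = log(clamp(pi, FLOOR, 1.0));
  mat lB = log(clamp(B, FLOOR, 1.0));

  for (uword b = 0; b < nb; ++b) {
    uword lo = offsets(b), hi = offsets(b + 1), T = hi - lo;
    ivec o = obs.subvec(lo, hi - 1);
    mat dp(K, T);
    imat bp(K, T);
    dp.col(0) = lpi + lB.col(o(0));
    for (uword t = 1; t < T; ++t) {
      mat lP = log(clamp(matpow(A, delta(lo + t), s), FLOOR, 1.0));
      for (uword j = 0; j < K; ++j) {
        double best = -datum::inf;
        uword arg = 0;
        for (uword i = 0; i < K; ++i) {
          double v = dp(i, t - 1) + lP(i, j);
          if (v > best) {  // strict >: ties resolve to the lower state index
            best = v;
            arg = i;
          }
        }
        dp(j, t) = best + lB(j, o(t));
        bp(j, t) = arg;
      }
    }
    uword last = dp.col(T - 1).index_max();
    logprob(b) = dp(last, T - 1);
    states(lo + T - 1) = (int)last;
    for (uword t = T - 1; t >= 1; --t) {
      last = bp(last, t);
      states(lo + t - 1) = (int)last;
    }
  }
  return Rcpp::List::create(Rcpp::Named("states") = states + 1,
                            Rcpp::Named("logprob") = logprob);
}
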