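// Numerical kernels for the switching linear dynamical system:
// Kalman forward pass, RTS smoother, simulation smoother (Carter-Kohn
// backward sampling), forward-filter backward-sample for the discrete
// mode chain, and per-mode regression sufficient statistics.
//
// All random draws go through R's RNG (norm_rand / unif_rand) so that
// set.seed() in R controls every stochastic path deterministically.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// symmetrize in place
static inline void symm(arma::mat &A) { A = 0.5 * (A + A.t()); }

// Cholesky with escalating diagonal jitter; throws with a caller-supplied tag.
static arma::mat safe_chol(arma::mat A, const char *tag) {
  symm(A);
  double jit = 0.0;
  double scale = arma::trace(A) / A.n_rows;
  if (scale <= 0 || !std::isfinite(scale)) scale = 1.0;
  for (int k = 0; k < 6; ++k) {
    arma::mat L;
    bool ok = arma::chol(L, A + jit * arma::eye(A.n_rows, A.n_cols), "lower");
    if (ok) return L;
    jit = (jit == 0.0) ? 1e-12 * scale : jit * 100.0;
  }
  stop("Cholesky factorization failed for %s (matrix not positive definite)", tag);
  return A; // unreachable
}

static arma::vec draw_std_normal(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z(i) = norm_rand();
  return z;
}

// Fixed-size forward pass for selector observation matrices with small
// state dimension (the trajectory models are d <= 3): identical recursions
// to the generic path below, but with stack-allocated matrices so the
// per-step 2x2/3x3 algebra inlines.
template <arma::uword D, arma::uword P>
static double kf_core_fixed(const arma::mat &psi, const arma::ivec &z,
                            const arma::mat &mu, const arma::cube &Fm,
                            const arma::cube &Sg, const arma::uvec &sel,
                            const arma::mat &R,
                            const arma::vec &m0, const arma::mat &P0,
                            arma::mat &mp, arma::cube &Pp,
                            arma::mat &mf, arma::cube &Pf) {
  const int T = psi.n_rows;
  arma::vec::fixed<D> m;
  arma::mat::fixed<D, D> Pm, A, Id;
  arma::mat::fixed<P, P> S, Sl, Rf;
  arma::mat::fixed<D, P> PHt, K;
  arma::mat::fixed<P, D> tmp;
  arma::vec::fixed<P> innov, alpha;
  Id.eye();
  Rf = R;
  m = m0;
  Pm = P0;
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    if (t > 0) {
      int k = z(t - 1) - 1;
      if (k < 0 || k >= (int)Fm.n_slices)
        stop("mode index out of range at step %d", t);
      m = mu.col(k) + Fm.slice(k) * m;
      Pm = Fm.slice(k) * Pm * Fm.slice(k).t() + Sg.slice(k);
      Pm = 0.5 * (Pm + Pm.t());
    }
    mp.col(t) = m;
    Pp.slice(t) = Pm;

    for (arma::uword i = 0; i < P; ++i) {
      innov(i) = psi(t, i) - m(sel(i));
      PHt.col(i) = Pm.col(sel(i));
    }
    for (arma::uword i = 0; i < P; ++i)
      for (arma::uword j = 0; j < P; ++j)
        S(i, j) = PHt(sel(i), j) + Rf(i, j);
    S = 0.5 * (S + S.t());
    if (!arma::chol(Sl, S, "lower")) {
      S.diag() += 1e-9 * (arma::trace(S) / P + 1e-30);
      if (!arma::chol(Sl, S, "lower"))
        stop("singular innovation covariance at step %d; add measurement-noise jitter", t + 1);
    }
    alpha = arma::solve(arma::trimatl(Sl), innov);
    ll += -0.5 * (P * LOG2PI + arma::dot(alpha, alpha)) -
          arma::accu(arma::log(Sl.diag()));

    tmp = arma::solve(arma::trimatl(Sl), PHt.t());
    K = arma::solve(arma::trimatu(Sl.t()), tmp).t();

    m += K * innov;
    A = Id;
    for (arma::uword i = 0; i < P; ++i) A.col(sel(i)) -= K.col(i);
    Pm = A * Pm * A.t() + K * Rf * K.t();
    Pm = 0.5 * (Pm + Pm.t());
    mf.col(t) = m;
    Pf.slice(t) = Pm;
  }
  return ll;
}

// Forward Kalman pass over T measurements.
// z: integer vector length T, 1-based; z[t-1] indexes the mode whose
//    (mu, F, Sigma) govern the transition from time t to t+1 (z[T-1] unused).
// Returns loglik and (optionally) predicted/filtered moments.
// [[Rcpp::export(name = ".kf_forward")]]
List kf_forward(const arma::mat &psi, const arma::ivec &z,
                const arma::mat &mu, const arma::cube &Fm, const arma::cube &Sg,
                const arma::mat &H, const arma::mat &R,
                const arma::vec &m0, const arma::mat &P0,
                bool store_moments) {
  const int T = psi.n_rows;
  const int d = m0.n_elem;
  const int p = psi.n_cols;
  if ((int)H.n_rows != p || (int)H.n_cols != d)
    stop("observation matrix H has incompatible dimensions");
  if ((int)z.n_elem != T) stop("mode index vector must have one entry per time point");

  arma::mat mp(d, T), mf(d, T);
  arma::cube Pp, Pf;
  Pp.set_size(d, d, T); Pf.set_size(d, d, T);

  // selector fast path: every row of H picks out one coordinate
  bool selector = true;
  arma::uvec sel(p);
  for (int i = 0; i < p && selector; ++i) {
    arma::uvec nz = arma::find(arma::abs(H.row(i)) > 0);
    if (nz.n_elem == 1 && std::abs(H(i, nz(0)) - 1.0) < 1e-14) sel(i) = nz(0);
    else selector = false;
  }

  if (selector) {
    double ll = NA_REAL;
    if (d == 3 && p == 3)
      ll = kf_core_fixed<3, 3>(psi, z, mu, Fm, Sg, sel, R, m0, P0, mp, Pp, mf, Pf);
    else if (d == 3 && p == 2)
      ll = kf_core_fixed<3, 2>(psi, z, mu, Fm, Sg, sel, R, m0, P0, mp, Pp, mf, Pf);
    else if (d == 2 && p == 2)
      ll = kf_core_fixed<2, 2>(psi, z, mu, Fm, Sg, sel, R, m0, P0, mp, Pp, mf, Pf);
    else if (d == 2 && p == 1)
      ll = kf_core_fixed<2, 1>(psi, z, mu, Fm, Sg, sel, R, m0, P0, mp, Pp, mf, Pf);
    else if (d == 3 && p == 1)
      ll = kf_core_fixed<3, 1>(psi, z, mu, Fm, Sg, sel, R, m0, P0, mp, Pp, mf, Pf);
    if (!ISNA(ll)) {
      if (!std::isfinite(ll))
        stop("non-finite Kalman log-likelihood (parameter blow-up)");
      if (store_moments)
        return List::create(_["loglik"] = ll, _["mp"] = mp, _["Pp"] = Pp,
                            _["mf"] = mf, _["Pf"] = Pf);
      return List::create(_["loglik"] = ll);
    }
  }

  arma::vec m = m0;
  arma::mat P = P0;
  double loglik = 0.0;
  arma::mat Id = arma::eye(d, d);
  arma::mat S(p, p), Sl(p, p), K(d, p), PHt(d, p), A(d, d);
  arma::vec innov(p), alpha(p);

  for (int t = 0; t < T; ++t) {
    if (t > 0) {
      int k = z(t - 1) - 1;
      if (k < 0 || k >= (int)Fm.n_slices) stop("mode index out of range at step %d", t);
      m = mu.col(k) + Fm.slice(k) * m;
      P = Fm.slice(k) * P * Fm.slice(k).t() + Sg.slice(k);
      symm(P);
    }
    mp.col(t) = m; Pp.slice(t) = P;

    // measurement update
    if (selector) {
      innov = psi.row(t).t() - m(sel);
      PHt = P.cols(sel);
      S = PHt.rows(sel) + R;
    } else {
      innov = psi.row(t).t() - H * m;
      PHt = P * H.t();
      S = H * PHt + R;
    }
    symm(S);
    if (!arma::chol(Sl, S, "lower")) {
      // near-singular innovation: relative diagonal jitter, then retry
      S.diag() += 1e-9 * (arma::trace(S) / p + 1e-30);
      if (!arma::chol(Sl, S, "lower"))
        stop("singular innovation covariance at step %d; add measurement-noise jitter", t + 1);
    }
    alpha = arma::solve(arma::trimatl(Sl), innov);
    loglik += -0.5 * (p * LOG2PI + arma::dot(alpha, alpha)) -
              arma::accu(arma::log(Sl.diag()));

    // K <- P H' S^{-1} via chol solves
    K = arma::solve(arma::trimatu(Sl.t()),
                    arma::solve(arma::trimatl(Sl), PHt.t())).t();

    m += K * innov;
    // Joseph-form update for numerical symmetry/PSD
    if (selector) {
      A = Id;
      A.cols(sel) -= K;
    } else {
      A = Id - K * H;
    }
    P = A * P * A.t() + K * R * K.t();
    symm(P);
    mf.col(t) = m; Pf.slice(t) = P;
  }

  if (!std::isfinite(loglik))
    stop("non-finite Kalman log-likelihood (parameter blow-up)");

  if (store_moments)
    return List::create(_["loglik"] = loglik,
                        _["mp"] = mp, _["Pp"] = Pp,
                        _["mf"] = mf, _["Pf"] = Pf);
  return List::create(_["loglik"] = loglik);
}

// RTS backward smoothing from stored forward moments.
// [[Rcpp::export(name = ".rts_backward")]]
List rts_backward(const arma::ivec &z, const arma::mat &mu, const arma::cube &Fm,
                  const arma::mat &mp, const arma::cube &Pp,
                  const arma::mat &mf, const arma::cube &Pf) {
  const int T = mf.n_cols;
  const int d = mf.n_rows;
  arma::mat ms(d, T);
  arma::cube Ps(d, d, T);
  ms.col(T - 1) = mf.col(T - 1);
  Ps.slice(T - 1) = Pf.slice(T - 1);
  for (int t = T - 2; t >= 0; --t) {
    int k = z(t) - 1;
    arma::mat J = arma::solve(Pp.slice(t + 1), Fm.slice(k) * Pf.slice(t),
                              arma::solve_opts::likely_sympd).t();
    ms.col(t) = mf.col(t) + J * (ms.col(t + 1) - mp.col(t + 1));
    arma::mat P = Pf.slice(t) + J * (Ps.slice(t + 1) - Pp.slice(t + 1)) * J.t();
    symm(P);
    Ps.slice(t) = P;
  }
  return List::create(_["ms"] = ms, _["Ps"] = Ps);
}

// Fixed-size Carter-Kohn backward pass (same recursion as the generic
// code below; stack matrices for the d <= 3 trajectory models).
template <arma::uword D>
static void backward_fixed(const arma::ivec &z, const arma::cube &Fm,
                           const arma::mat &mp, const arma::cube &Pp,
                           const arma::mat &mf, const arma::cube &Pf,
                           arma::mat &r) {
  const int T = mf.n_cols;
  arma::vec::fixed<D> x, cm, zdraw;
  arma::mat::fixed<D, D> J, cP, Lc, Pfin;
  Pfin = Pf.slice(T - 1);
  Pfin = 0.5 * (Pfin + Pfin.t());
  {
    arma::mat Lg = safe_chol(Pfin, "filtered covariance (final step)");
    Lc = Lg;
  }
  for (arma::uword i = 0; i < D; ++i) zdraw(i) = norm_rand();
  x = mf.col(T - 1) + Lc * zdraw;
  r.row(T - 1) = x.t();
  for (int t = T - 2; t >= 0; --t) {
    int k = z(t) - 1;
    arma::mat::fixed<D, D> Ppn = Pp.slice(t + 1);
    J = (arma::inv(Ppn) * (Fm.slice(k) * Pf.slice(t)));
    J = J.t();
    cm = mf.col(t) + J * (x - mp.col(t + 1));
    cP = Pf.slice(t) - J * Ppn * J.t();
    cP = 0.5 * (cP + cP.t());
    if (!arma::chol(Lc, cP + 1e-14 * arma::eye(D, D), "lower")) {
      arma::vec ev; arma::mat V;
      arma::eig_sym(ev, V, arma::mat(cP));
      ev.transform([](double e) { return e > 0 ? std::sqrt(e) : 0.0; });
      Lc = V * arma::diagmat(ev);
    }
    for (arma::uword i = 0; i < D; ++i) zdraw(i) = norm_rand();
    x = cm + Lc * zdraw;
    r.row(t) = x.t();
  }
}

// Simulation smoother: one exact joint draw of the latent path given
// measurements and the per-step mode assignment (forward filter,
// Carter-Kohn backward sampling). Uses R's RNG.
// [[Rcpp::export(name = ".sim_smoother_draw")]]
List sim_smoother_draw(const arma::mat &psi, const arma::ivec &z,
                       const arma::mat &mu, const arma::cube &Fm, const arma::cube &Sg,
                       const arma::mat &H, const arma::mat &R,
                       const arma::vec &m0, const arma::mat &P0) {
  RNGScope scope;
  List fw = kf_forward(psi, z, mu, Fm, Sg, H, R, m0, P0, true);
  arma::mat mp = fw["mp"], mf = fw["mf"];
  arma::cube Pp = fw["Pp"], Pf = fw["Pf"];
  const int T = mf.n_cols;
  const int d = mf.n_rows;
  arma::mat r(T, d);

  if (d == 3) {
    backward_fixed<3>(z, Fm, mp, Pp, mf, Pf, r);
    return List::create(_["r"] = r, _["loglik"] = as<double>(fw["loglik"]));
  }
  if (d == 2) {
    backward_fixed<2>(z, Fm, mp, Pp, mf, Pf, r);
    return List::create(_["r"] = r, _["loglik"] = as<double>(fw["loglik"]));
  }

  arma::mat L = safe_chol(Pf.slice(T - 1), "filtered covariance (final step)");
  arma::vec x = mf.col(T - 1) + L * draw_std_normal(d);
  r.row(T - 1) = x.t();
  for (int t = T - 2; t >= 0; --t) {
    int k = z(t) - 1;
    arma::mat J = arma::solve(Pp.slice(t + 1), Fm.slice(k) * Pf.slice(t),
                              arma::solve_opts::likely_sympd).t();
    arma::vec cm = mf.col(t) + J * (x - mp.col(t + 1));
    arma::mat cP = Pf.slice(t) - J * Pp.slice(t + 1) * J.t();
    symm(cP);
    // clamp tiny negative eigenvalues from cancellation
    arma::mat Lc;
    if (!arma::chol(Lc, cP + 1e-14 * arma::eye(d, d), "lower")) {
      arma::vec ev; arma::mat V;
      arma::eig_sym(ev, V, cP);
      ev.transform([](double e) { return e > 0 ? std::sqrt(e) : 0.0; });
      Lc = V * arma::diagmat(ev);
    }
    x = cm + Lc * draw_std_normal(d);
    r.row(t) = x.t();
  }
  return List::create(_["r"] = r, _["loglik"] = as<double>(fw["loglik"]));
}

// Per-mode log transition densities: ll(k, t) = log N(r_{t+1}; mu_k + F_k r_t, Sg_k)
static arma::mat mode_loglik_matrix(const arma::mat &r, const arma::mat &mu, const arma::cube &Fm,
                              const arma::cube &Sg) {
  const int T = r.n_rows, d = r.n_cols, L = mu.n_cols;
  arma::mat ll(L, T - 1);
  for (int k = 0; k < L; ++k) {
    arma::mat Lk = safe_chol(Sg.slice(k), "mode process covariance");
    double ldet = 2.0 * arma::accu(arma::log(Lk.diag()));
    arma::mat pred = Fm.slice(k) * r.rows(0, T - 2).t();       // d x (T-1)
    pred.each_col() += mu.col(k);
    arma::mat e = r.rows(1, T - 1).t() - pred;                  // d x (T-1)
    arma::mat a = arma::solve(arma::trimatl(Lk), e);
    ll.row(k) = -0.5 * (d * LOG2PI + ldet + arma::sum(a % a, 0));
  }
  return ll;
}

// Forward-filter backward-sample of the discrete mode chain given the
// continuous path. Emission for mode at time t (t < T) is the transition
// density r_t -> r_{t+1}; the final time point carries no emission.
// Computations are in log space throughout. Returns T x ndraws labels.
// [[Rcpp::export(name = ".mode_ffbs")]]
arma::imat mode_ffbs(const arma::mat &r, const arma::mat &mu, const arma::cube &Fm,
                     const arma::cube &Sg, const arma::mat &Pi, const arma::vec &pi0,
                     int ndraws) {
  RNGScope scope;
  const int T = r.n_rows, L = mu.n_cols;
  arma::mat ll = mode_loglik_matrix(r, mu, Fm, Sg);
  if (!ll.is_finite()) stop("non-finite mode emission log-likelihood (NaN)");

  arma::mat logPi = arma::log(Pi + 1e-300);
  arma::vec logpi0 = arma::log(pi0 + 1e-300);

  // forward messages alpha(k, t) = log p(s_t = k, r_{1:t+1})
  arma::mat alpha(L, T);
  alpha.col(0) = logpi0 + ll.col(0);
  for (int t = 1; t < T; ++t) {
    arma::vec prev = alpha.col(t - 1);
    double mx = prev.max();
    arma::vec w = arma::exp(prev - mx);
    arma::vec acc = arma::log(Pi.t() * w + 1e-300) + mx;
    if (t < T - 1) acc += ll.col(t);
    alpha.col(t) = acc;
  }

  arma::imat out(T, ndraws);
  for (int s = 0; s < ndraws; ++s) {
    // sample s_T
    arma::vec lw = alpha.col(T - 1);
    lw -= lw.max();
    arma::vec w = arma::exp(lw); w /= arma::accu(w);
    double u = unif_rand(); int k = 0; double c = w(0);
    while (u > c && k < L - 1) { ++k; c += w(k); }
    out(T - 1, s) = k + 1;
    for (int t = T - 2; t >= 0; --t) {
      arma::vec lv = alpha.col(t) + logPi.col(k);
      lv -= lv.max();
      arma::vec v = arma::exp(lv); v /= arma::accu(v);
      u = unif_rand(); k = 0; c = v(0);
      while (u > c && k < L - 1) { ++k; c += v(k); }
      out(t, s) = k + 1;
    }
  }
  return out;
}

// Regression sufficient statistics per mode for steps t -> t+1 with
// regressor x_t = (r_t, 1). Step t belongs to mode z[t].
// [[Rcpp::export(name = ".mode_suffstats")]]
List mode_suffstats(const arma::mat &r, const arma::ivec &z, int L) {
  const int T = r.n_rows, d = r.n_cols;
  arma::cube Sxx(d + 1, d + 1, L, arma::fill::zeros);
  arma::cube Sxy(d + 1, d, L, arma::fill::zeros);
  arma::cube Syy(d, d, L, arma::fill::zeros);
  arma::ivec n(L, arma::fill::zeros);
  arma::vec x(d + 1);
  for (int t = 0; t < T - 1; ++t) {
    int k = z(t) - 1;
    if (k < 0 || k >= L) stop("mode label out of range at step %d", t + 1);
    x.subvec(0, d - 1) = r.row(t).t();
    x(d) = 1.0;
    arma::vec y = r.row(t + 1).t();
    Sxx.slice(k) += x * x.t();
    Sxy.slice(k) += x * y.t();
    Syy.slice(k) += y * y.t();
    n(k) += 1;
  }
  return List::create(_["Sxx"] = Sxx, _["Sxy"] = Sxy, _["Syy"] = Syy,
                      _["n"] = n);
}

// Matrix exponential / logarithm helpers (continuize needs a real logm).
// [[Rcpp::export(name = ".expm_arma")]]
arma::mat expm_arma(const arma::mat &A) { return arma::expmat(A); }

// [[Rcpp::export(name = ".logm_arma")]]
arma::mat logm_arma(const arma::mat &A) {
  arma::cx_mat Lc;
  bool ok = arma::logmat(Lc, A);
  if (!ok) stop("matrix logarithm failed: the discrete propagator has no real continuous embedding at this time step");
  double imnorm = arma::norm(arma::imag(Lc), "fro");
  double renorm = arma::norm(arma::real(Lc), "fro") + 1e-300;
  if (imnorm > 1e-8 * (1.0 + renorm))
    stop("matrix logarithm is complex: the discrete propagator has no real continuous embedding at this time step");
  return arma::real(Lc);
}
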