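#' Hyperparameter configuration of the sticky HDP prior
#'
#' Weak-limit truncation of the sticky hierarchical Dirichlet process over
#' the mode-transition structure. The shared stick weights `beta` follow a
#' finite Dirichlet approximation to GEM(`gamma`); each transition row is
#' `pi_j ~ Dirichlet(alpha beta + kappa delta_j)`, where `kappa` adds
#' extra prior mass on self-transitions. Hyperpriors: `gamma ~
#' Gamma(a_gamma, b_gamma)` (shape/rate), `alpha + kappa ~ Gamma(a_ak,
#' b_ak)`, and the self-transition fraction `rho = kappa / (kappa +
#' alpha) ~ Beta(c_rho, d_rho)`. Concentrations are stored via
#' `(alpha + kappa, rho)` so the identity `rho = kappa/(kappa+alpha)`
#' holds exactly at every sweep.
#'
#' @param L truncation level (maximum number of modes), >= 2.
#' @param a_gamma,b_gamma Gamma shape/rate hyperprior on `gamma`.
#' @param a_ak,b_ak Gamma shape/rate hyperprior on `alpha + kappa`.
#' @param c_rho,d_rho Beta hyperprior on `rho`.
#' @param n_sweeps number of Gibbs sweeps.
#' @param burn_in sweeps discarded before summarizing (default half).
#' @param seed integer seed for the whole chain.
#' @return an object of class `hdp_config`.
#' @export
hdp_config <- function(L = 10, a_gamma = 1, b_gamma = 0.01,
                       a_ak = 1, b_ak = 0.01, c_rho = 25, d_rho = 1,
                       n_sweeps = 2000, burn_in = floor(n_sweeps / 2),
                       seed = 1) {
  stopifnot(L >= 2, a_gamma > 0, b_gamma > 0, a_ak > 0, b_ak > 0,
            c_rho > 0, d_rho > 0, n_sweeps >= 2, burn_in >= 0,
            burn_in < n_sweeps)
  structure(list(L = as.integer(L), a_gamma = a_gamma, b_gamma = b_gamma,
                 a_ak = a_ak, b_ak = b_ak, c_rho = c_rho, d_rho = d_rho,
                 n_sweeps = as.integer(n_sweeps),
                 burn_in = as.integer(burn_in), seed = as.integer(seed)),
            class = "hdp_config")
}

#' Translate concentration-scenario labels to hyperprior constants
#'
#' The prior-sensitivity sweeps vary two knobs: `gamma_b`, the Gamma rate
#' on both `gamma` and `alpha + kappa` (shapes fixed at 1), and `rho_c`,
#' the Beta `c` parameter on `rho` (with `d` fixed at 1). The baseline is
#' `gamma_b = 0.01`, `rho_c = 25`. This is the single place where that
#' mapping lives.
#'
#' @param gamma_b Gamma rate on the concentrations.
#' @param rho_c Beta first parameter on the self-transition fraction.
#' @param ... further arguments passed to [hdp_config()].
#' @return an [hdp_config()] object.
#' @export
concentration_scenario <- function(gamma_b = 0.01, rho_c = 25, ...) {
  hdp_config(a_gamma = 1, b_gamma = gamma_b, a_ak = 1, b_ak = gamma_b,
             c_rho = rho_c, d_rho = 1, ...)
}

#' Matrix-normal inverse-Wishart base measure of the mode parameters
#'
#' The base measure `lambda` over one mode's discrete parameters: the
#' regression `r_{i+1} = A [r_i; 1] + eta`, `A = [F mu]`, carries a
#' matrix-normal prior `A | Sigma ~ MN(A0, Sigma, V0)` and `Sigma ~
#' IW(nu_Sigma, S_Sigma)`; the shared measurement covariance has `R ~
#' IW(nu_R, S_R)`. Degrees of freedom default to dimension + 2, the
#' vaguest choice with a defined mean, so `E[Sigma] = S_Sigma` and
#' `E[R] = S_R`.
#'
#' @param S_Sigma d x d inverse-Wishart scale = prior mean of `Sigma`.
#' @param S_R d_obs x d_obs inverse-Wishart scale = prior mean of `R`.
#' @param nu_Sigma,nu_R degrees of freedom (> dim + 1).
#' @param A0 prior mean of `[F mu]` (default `[I 0]`).
#' @param V0 (d+1) x (d+1) column covariance of the matrix-normal
#'   (default `10 I`, weak).
#' @return an object of class `slds_prior`.
#' @export
slds_prior <- function(S_Sigma, S_R, nu_Sigma = nrow(S_Sigma) + 2,
                       nu_R = nrow(S_R) + 2, A0 = NULL, V0 = NULL) {
  S_Sigma <- as.matrix(S_Sigma); S_R <- as.matrix(S_R)
  d <- nrow(S_Sigma); p <- nrow(S_R)
  check_psd(S_Sigma, "S_Sigma"); check_psd(S_R, "S_R")
  if (min(eigen(S_Sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("degenerate base measure: prior mean of Sigma must be positive definite")
  if (min(eigen(S_R, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("degenerate base measure: prior mean of R must be positive definite")
  if (nu_Sigma <= d + 1 || nu_R <= p + 1)
    stop("inverse-Wishart dfs must exceed dimension + 1 so the prior mean exists")
  if (is.null(A0)) A0 <- cbind(diag(d), rep(0, d))
  if (is.null(V0)) V0 <- diag(10, d + 1)
  structure(list(S_Sigma = S_Sigma, nu_Sigma = nu_Sigma,
                 S_R = S_R, nu_R = nu_R,
                 A0 = as.matrix(A0), V0 = as.matrix(V0), d = d, p = p),
            class = "slds_prior")
}

# ---- conditional draws ------------------------------------------------------

rinvwish <- function(nu, S) {
  # S is the IW scale; draw via Wishart on solve(S)
  W <- stats::rWishart(1, nu, solve(S))[, , 1]
  V <- solve(W)
  (V + t(V)) / 2
}

rmatnorm <- function(M, U, V) {
  # row covariance U, column covariance V
  Z <- matrix(stats::rnorm(length(M)), nrow(M), ncol(M))
  M + t(chol(U)) %*% Z %*% chol(V)
}

rdirichlet1 <- function(a) {
  g <- stats::rgamma(length(a), shape = a, rate = 1)
  if (sum(g) <= 0) { g <- rep(1e-12, length(a)); g[which.max(a)] <- 1 }
  g / sum(g)
}

#' Sample the mode sequence given the continuous path
#'
#' Forward-filter backward-sample over the discrete chain: the emission of
#' mode `k` at step `i < T` is the Gaussian transition density
#' `N(r_{i+1}; mu_k + F_k r_i, Sigma_k)`; the last time point carries no
#' emission. All messages are computed in log space. An exact joint draw
#' from the conditional posterior of the label chain.
#'
#' @param r T x d matrix of (sampled or true) positions.
#' @param theta list of L mode parameter lists, each with `mu`, `F`,
#'   `Sigma`.
#' @param pi L x L transition matrix (rows on the simplex).
#' @param pi0 initial mode distribution (default the shared weights
#'   `beta`; uniform if omitted).
#' @param ndraws number of independent draws to return.
#' @param seed optional integer seed.
#' @return integer vector of length T (or a T x `ndraws` matrix).
#' @export
sample_mode_sequence <- function(r, theta, pi, pi0 = NULL, ndraws = 1,
                                 seed = NULL) {
  r <- as.matrix(r)
  L <- length(theta); d <- ncol(r)
  mu <- vapply(theta, function(th) th$mu, numeric(d))
  mu <- matrix(mu, d, L)
  Fm <- array(0, c(d, d, L)); Sg <- array(0, c(d, d, L))
  for (k in seq_len(L)) { Fm[, , k] <- theta[[k]]$F; Sg[, , k] <- theta[[k]]$Sigma }
  if (is.null(pi0)) pi0 <- rep(1 / L, L)
  if (!is.null(seed)) set.seed(seed)
  out <- .mode_ffbs(r, mu, Fm, Sg, as.matrix(pi), pi0, as.integer(ndraws))
  if (ndraws == 1) as.integer(out[, 1]) else out
}

# chinese-restaurant table counts: number of tables serving dish k in
# restaurant j, given n customers and concentration a
crt_draw <- function(n, a) {
  if (n <= 0) return(0L)
  # the first customer always opens a table; as a -> 0 no further tables
  # open (guards against underflowed stick weights giving 0/0)
  if (a <= 0) return(1L)
  sum(stats::runif(n) < a / (a + seq_len(n) - 1))
}

transition_counts <- function(z, L) {
  T <- length(z)
  if (T < 2) return(matrix(0, L, L))
  matrix(tabulate((z[-T] - 1L) * L + z[-1], nbins = L * L), L, L, byrow = TRUE)
}

#' Sample the transition structure (beta, pi) given the mode sequence
#'
#' Weak-limit conjugate updates of the sticky HDP: auxiliary
#' Chinese-restaurant table counts are drawn for every (row, dish) pair,
#' sticky self-transition tables are thinned by the override step, the
#' shared weights are refreshed as `beta ~ Dirichlet(gamma/L + mbar_.k)`,
#' and each transition row as `pi_j ~ Dirichlet(alpha beta + kappa delta_j
#' + n_j.)` with `alpha = (1-rho)(alpha+kappa)`, `kappa =
#' rho (alpha+kappa)`.
#'
#' @param z integer mode labels (length T) — or, alternatively, supply
#'   `counts`, an L x L transition-count matrix.
#' @param beta current shared weights (length L).
#' @param gamma GEM concentration.
#' @param alpha_plus_kappa total concentration of the row DPs.
#' @param rho self-transition fraction in `[0, 1]`.
#' @param L truncation level.
#' @param counts optional transition-count matrix overriding `z`.
#' @param seed optional integer seed.
#' @return list with `beta`, `pi`, and the auxiliary `m_bar` (override-
#'   corrected table counts) and `w_total` (override count) used by the
#'   hyperparameter step.
#' @export
sample_transition_params <- function(z = NULL, beta, gamma, alpha_plus_kappa,
                                     rho, L = length(beta), counts = NULL,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(gamma > 0, alpha_plus_kappa > 0, rho >= 0, rho <= 1)
  alpha <- (1 - rho) * alpha_plus_kappa
  kappa <- rho * alpha_plus_kappa
  if (is.null(counts)) counts <- transition_counts(as.integer(z), L)
  stopifnot(all(dim(counts) == c(L, L)))

  m <- matrix(0L, L, L)
  for (j in seq_len(L)) for (k in seq_len(L)) {
    a <- alpha * beta[k] + if (j == k) kappa else 0
    m[j, k] <- crt_draw(counts[j, k], a)
  }
  # override: some self-transition tables are due to the sticky kappa mass
  w <- integer(L)
  for (j in seq_len(L)) {
    if (m[j, j] > 0) {
      pr <- rho / (rho + beta[j] * (1 - rho))
      w[j] <- stats::rbinom(1, m[j, j], pr)
    }
  }
  m_bar <- m
  diag(m_bar) <- diag(m) - w
  beta_new <- rdirichlet1(gamma / L + colSums(m_bar))
  pi <- matrix(0, L, L)
  for (j in seq_len(L)) {
    a <- alpha * beta_new + counts[j, ]
    a[j] <- a[j] + kappa
    pi[j, ] <- rdirichlet1(a)
  }
  list(beta = beta_new, pi = pi, m_bar = m_bar, w_total = sum(w),
       m_total = sum(m))
}

#' Sample per-mode dynamics and the shared measurement covariance
#'
#' Conjugate matrix-normal inverse-Wishart updates: each mode's `(mu, F)`
#' is the Bayesian multivariate regression of `r_{i+1}` on `[r_i; 1]` over
#' the steps assigned to that mode, `Sigma` its inverse-Wishart
#' conditional; modes with no assigned steps are refreshed from the base
#' measure. `R` is inverse-Wishart pooled over all time points using the
#' residuals `psi - H r`.
#'
#' @param r T x d sampled (or known) position path.
#' @param z integer mode labels, length T (step `i` belongs to `z[i]`).
#' @param prior an [slds_prior()].
#' @param L truncation level.
#' @param psi optional T x d_obs measurements (with `H`) to update `R`;
#'   omitted in tests that only target the dynamics update.
#' @param H observation selector matching `psi`.
#' @param seed optional integer seed.
#' @return list with `theta` (length-L list of `mu`, `F`, `Sigma`) and `R`
#'   (or `NULL` when `psi` is not supplied).
#' @export
sample_mode_params <- function(r, z, prior, L, psi = NULL, H = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- as.matrix(r)
  d <- ncol(r)
  stopifnot(inherits(prior, "slds_prior"), prior$d == d)
  ss <- .mode_suffstats(r, as.integer(z), as.integer(L))
  V0inv <- solve(prior$V0)
  A0V0inv <- prior$A0 %*% V0inv
  theta <- vector("list", L)
  for (k in seq_len(L)) {
    n_k <- ss$n[k]
    if (n_k == 0) {
      Sigma <- rinvwish(prior$nu_Sigma, prior$S_Sigma)
      A <- rmatnorm(prior$A0, Sigma, prior$V0)
    } else {
      Sxx <- ss$Sxx[, , k]; Sxy <- ss$Sxy[, , k]; Syy <- ss$Syy[, , k]
      Vn_inv <- V0inv + Sxx
      Vn <- solve(Vn_inv)
      Vn <- (Vn + t(Vn)) / 2
      An <- (A0V0inv + t(Sxy)) %*% Vn
      Sn <- prior$S_Sigma + Syy + prior$A0 %*% V0inv %*% t(prior$A0) -
        An %*% Vn_inv %*% t(An)
      Sn <- (Sn + t(Sn)) / 2
      ev <- eigen(Sn, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0) {
        warning("degenerate posterior scale for mode ", k,
                "; falling back to a prior draw")
        Sigma <- rinvwish(prior$nu_Sigma, prior$S_Sigma)
        A <- rmatnorm(prior$A0, Sigma, prior$V0)
      } else {
        Sigma <- rinvwish(prior$nu_Sigma + n_k, Sn)
        A <- rmatnorm(An, Sigma, Vn)
      }
    }
    theta[[k]] <- list(mu = as.numeric(A[, d + 1]),
                       F = A[, 1:d, drop = FALSE],
                       Sigma = Sigma)
  }
  Rdraw <- NULL
  if (!is.null(psi)) {
    psi <- as.matrix(psi)
    if (is.null(H)) H <- diag(d)
    resid <- psi - r %*% t(H)
    Sn_R <- prior$S_R + crossprod(resid)
    Rdraw <- rinvwish(prior$nu_R + nrow(psi), (Sn_R + t(Sn_R)) / 2)
  }
  list(theta = theta, R = Rdraw)
}

# Escobar-West style auxiliary draw for a DP concentration with likelihood
# prod_j Gamma(c)/Gamma(c + n_j) * c^{t_j}; groups = rows with n_j > 0.
sample_dp_concentration <- function(cur, a, b, n_groups_counts, n_tables_total) {
  nj <- n_groups_counts[n_groups_counts > 0]
  if (length(nj) == 0 || n_tables_total == 0) {
    return(stats::rgamma(1, shape = a, rate = b))
  }
  rj <- stats::rbeta(length(nj), cur + 1, nj)
  sj <- stats::rbinom(length(nj), 1, nj / (nj + cur))
  stats::rgamma(1, shape = a + n_tables_total - sum(sj),
                rate = b - sum(log(pmax(rj, 1e-300))))
}

#' Sample the concentration and stickiness hyperparameters
#'
#' Standard auxiliary-variable Gibbs steps: `gamma` from its conditional
#' given the (override-corrected) total table count and the number of
#' active dishes; `alpha + kappa` given per-row transition totals and
#' table totals; `rho` from its Beta conditional given the override
#' counts. Outputs are positive with `rho` in (0, 1).
#'
#' @param beta current shared weights (used for the active-dish count).
#' @param z mode labels (or supply `counts`).
#' @param cfg an [hdp_config()].
#' @param gamma,alpha_plus_kappa,rho current values.
#' @param aux optional auxiliary statistics from
#'   [sample_transition_params()] (`m_bar`, `w_total`, `m_total`); drawn
#'   afresh internally when omitted.
#' @param counts optional transition-count matrix.
#' @param seed optional integer seed.
#' @return list with `gamma`, `alpha_plus_kappa`, `rho`.
#' @export
sample_hyperparameters <- function(beta, z = NULL, cfg, gamma,
                                   alpha_plus_kappa, rho, aux = NULL,
                                   counts = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(cfg, "hdp_config"))
  L <- cfg$L
  if (is.null(counts)) counts <- transition_counts(as.integer(z), L)
  if (is.null(aux)) {
    aux <- sample_transition_params(beta = beta, gamma = gamma,
                                    alpha_plus_kappa = alpha_plus_kappa,
                                    rho = rho, L = L, counts = counts)
  }
  m_bar <- aux$m_bar
  mbar_total <- sum(m_bar)
  K_active <- sum(colSums(m_bar) > 0)
  gamma_new <- sample_dp_concentration(gamma, cfg$a_gamma, cfg$b_gamma,
                                       mbar_total, K_active)
  ak_new <- sample_dp_concentration(alpha_plus_kappa, cfg$a_ak, cfg$b_ak,
                                    rowSums(counts), aux$m_total)
  rho_new <- stats::rbeta(1, cfg$c_rho + aux$w_total,
                          cfg$d_rho + aux$m_total - aux$w_total)
  rho_new <- min(max(rho_new, 1e-8), 1 - 1e-8)
  list(gamma = max(gamma_new, 1e-8),
       alpha_plus_kappa = max(ak_new, 1e-8),
       rho = rho_new)
}

# ---- the blocked Gibbs sampler ---------------------------------------------

#' Run the sticky HDP-SLDS blocked Gibbs sampler on one trajectory
#'
#' One sweep draws, in order: the continuous path given the modes
#' (simulation smoother), the mode sequence given the path (FFBS), the
#' per-mode dynamics and shared measurement covariance (matrix-normal
#' inverse-Wishart), the transition structure `(beta, pi)`, and the
#' concentration/stickiness hyperparameters. Fully reproducible from
#' `cfg$seed`. Initialization assigns all steps to one mode with the base
#' measure's prior means, hyperparameters at their prior means.
#'
#' This is the engine behind [hdpslds()]; call it directly when you want
#' the raw chain.
#'
#' @param psi T x d_obs measurement matrix.
#' @param dt sampling interval.
#' @param obs an [observation_model()] giving `H` and the initial `R`.
#' @param prior an [slds_prior()].
#' @param cfg an [hdp_config()].
#' @param d state dimension (default `ncol(obs$H)`).
#' @param verbose print progress every `verbose` sweeps (0 = silent).
#' @return an object of class `hdpslds_chain`: per-sweep mode sequences
#'   (`z`, n_sweeps x T), data log-likelihood and joint log-density
#'   traces, hyperparameter traces, `beta` draws, per-sweep `theta` and
#'   `R` arrays, the accumulated posterior-mean path `r_mean`
#'   (post-burn-in), and the configuration.
#' @export
run_mcmc <- function(psi, dt, obs, prior, cfg, d = ncol(obs$H),
                     verbose = 0) {
  psi <- as.matrix(psi)
  stopifnot(inherits(obs, "obs_model"), inherits(prior, "slds_prior"),
            inherits(cfg, "hdp_config"), prior$d == d)
  T <- nrow(psi); L <- cfg$L; p <- ncol(psi)
  set.seed(cfg$seed)

  # initialization at prior means
  gamma <- cfg$a_gamma / cfg$b_gamma
  ak <- cfg$a_ak / cfg$b_ak
  rho <- cfg$c_rho / (cfg$c_rho + cfg$d_rho)
  beta <- rep(1 / L, L)
  alpha <- (1 - rho) * ak; kappa <- rho * ak
  pi <- matrix(rep(alpha * beta, each = L), L, L) + kappa * diag(L)
  pi <- pi / rowSums(pi)
  theta <- replicate(L, list(mu = as.numeric(prior$A0[, d + 1]),
                             F = prior$A0[, 1:d, drop = FALSE],
                             Sigma = prior$S_Sigma), simplify = FALSE)
  R <- prior$S_R
  z <- rep.int(1L, T)

  mu_c <- matrix(0, d, L)
  Fm <- array(0, c(d, d, L)); Sg <- array(0, c(d, d, L))
  refresh_stacks <- function(theta) {
    for (k in seq_len(L)) {
      mu_c[, k] <<- theta[[k]]$mu
      Fm[, , k] <<- theta[[k]]$F
      Sg[, , k] <<- theta[[k]]$Sigma
    }
  }
  refresh_stacks(theta)

  init <- default_init(psi, observation_model(obs$H, R), prior$S_Sigma)

  S <- cfg$n_sweeps
  z_draws <- matrix(NA_integer_, S, T)
  loglik <- numeric(S); joint_ld <- numeric(S)
  hyper <- matrix(NA_real_, S, 3,
                  dimnames = list(NULL, c("gamma", "alpha_plus_kappa", "rho")))
  beta_draws <- matrix(NA_real_, S, L)
  n_active <- integer(S)
  theta_mu <- array(NA_real_, c(S, d, L))
  theta_F <- array(NA_real_, c(S, d, d, L))
  theta_Sigma <- array(NA_real_, c(S, d, d, L))
  R_draws <- array(NA_real_, c(S, p, p))
  r_mean <- matrix(0, T, d); n_acc <- 0L

  for (s in seq_len(S)) {
    # 1. continuous path | modes, theta, R
    sm <- tryCatch(
      .sim_smoother_draw(psi, z, mu_c, Fm, Sg, obs$H, R, init$m0, init$P0),
      error = function(e)
        stop("sampler failed at sweep ", s, ": ", conditionMessage(e)))
    r <- sm$r
    loglik[s] <- sm$loglik

    # 2. modes | path
    z <- as.integer(.mode_ffbs(r, mu_c, Fm, Sg, pi, beta, 1L)[, 1])

    # 3. per-mode dynamics + shared R
    mp <- sample_mode_params(r, z, prior, L, psi = psi, H = obs$H)
    theta <- mp$theta; R <- mp$R
    refresh_stacks(theta)

    # 4. transition structure
    tp <- sample_transition_params(z = z, beta = beta, gamma = gamma,
                                   alpha_plus_kappa = ak, rho = rho, L = L)
    beta <- tp$beta; pi <- tp$pi

    # 5. hyperparameters
    hp <- sample_hyperparameters(beta = beta, z = z, cfg = cfg,
                                 gamma = gamma, alpha_plus_kappa = ak,
                                 rho = rho, aux = tp)
    gamma <- hp$gamma; ak <- hp$alpha_plus_kappa; rho <- hp$rho

    z_draws[s, ] <- z
    hyper[s, ] <- c(gamma, ak, rho)
    beta_draws[s, ] <- beta
    occ <- tabulate(z, L)
    n_active[s] <- sum(occ > 0)
    # joint log-density trace: data term + mode-chain prior term
    lpz <- sum(log(pmax(pi[cbind(z[-T], z[-1])], 1e-300))) +
      log(pmax(beta[z[1]], 1e-300))
    joint_ld[s] <- loglik[s] + lpz
    theta_mu[s, , ] <- mu_c
    theta_F[s, , , ] <- Fm
    theta_Sigma[s, , , ] <- Sg
    R_draws[s, , ] <- R
    if (s > cfg$burn_in) { r_mean <- r_mean + r; n_acc <- n_acc + 1L }
    if (verbose > 0 && s %% verbose == 0)
      message(sprintf("sweep %d/%d: loglik %.1f, joint %.1f, %d active modes",
                      s, S, loglik[s], joint_ld[s], n_active[s]))
  }

  structure(list(z = z_draws, loglik = loglik, joint_logdensity = joint_ld,
                 hyper = hyper, beta = beta_draws, n_active = n_active,
                 theta_mu = theta_mu, theta_F = theta_F,
                 theta_Sigma = theta_Sigma, R = R_draws,
                 r_mean = r_mean / max(n_acc, 1L),
                 dt = dt, obs = obs, prior = prior, cfg = cfg,
                 d = d, T = T),
            class = "hdpslds_chain")
}

#' Point estimate of the segmentation from a chain
#'
#' Aligns every post-burn-in sweep's labels to the final sweep via the
#' optimal (minimum-mismatch) assignment, then reports the per-time-point
#' majority label and the full per-time marginal probabilities.
#'
#' @param chain an `hdpslds_chain` from [run_mcmc()].
#' @param burn_in override of the chain's burn-in.
#' @return object of class `hdpslds_segmentation`: list with `labels`
#'   (length T), `prob` (T x L marginal matrix, rows sum to 1), and
#'   `n_sweeps_used`.
#' @export
point_estimate <- function(chain, burn_in = chain$cfg$burn_in) {
  stopifnot(inherits(chain, "hdpslds_chain"))
  S <- nrow(chain$z); T <- ncol(chain$z); L <- chain$cfg$L
  if (burn_in + 2L > S)
    stop("empty (or single-sweep) post-burn-in window")
  keep <- seq.int(burn_in + 1L, S)
  ref <- chain$z[S, ]
  counts <- matrix(0, T, L)
  for (s in keep) {
    zs <- chain$z[s, ]
    map <- align_labels(ref, zs)
    mapped <- map[as.character(zs)]
    # unmatched estimated labels keep their own identity (they are real
    # modes in this sweep, just absent from the reference)
    mapped[is.na(mapped)] <- zs[is.na(mapped)]
    counts[cbind(seq_len(T), mapped)] <- counts[cbind(seq_len(T), mapped)] + 1
  }
  prob <- counts / length(keep)
  labels <- max.col(prob, ties.method = "first")
  structure(list(labels = as.integer(labels), prob = prob,
                 n_sweeps_used = length(keep)),
            class = "hdpslds_segmentation")
}

#' @export
print.hdpslds_chain <- function(x, ...) {
  cat("Sticky HDP-SLDS chain:", nrow(x$z), "sweeps,", x$T, "time points,",
      "truncation L =", x$cfg$L, "\n")
  keep <- seq.int(x$cfg$burn_in + 1L, nrow(x$z))
  cat("  post-burn-in active modes (median):",
      stats::median(x$n_active[keep]), "\n")
  cat("  mean data log-likelihood:", format(mean(x$loglik[keep]), digits = 6),
      "\n")
  invisible(x)
}

#' @export
print.hdpslds_segmentation <- function(x, ...) {
  occ <- table(x$labels)
  cat("Segmentation point estimate over", length(x$labels), "time points\n")
  cat("  label occupancy:",
      paste(names(occ), "=", as.integer(occ), collapse = ", "), "\n")
  invisible(x)
}
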