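#' Observation model of a partially observed trajectory
#'
#' `H` selects which coordinates of the latent position are measured
#' (identity for full 3D observation, `cbind(diag(2), 0)` for the
#' hidden-z model); `R` is the localization-noise covariance of the
#' measured coordinates.
#'
#' @param H d_obs x d selector matrix with full row rank.
#' @param R d_obs x d_obs symmetric PSD covariance.
#' @return an object of class `obs_model`.
#' @export
observation_model <- function(H, R) {
  H <- as.matrix(H); R <- as.matrix(R)
  if (qr(H)$rank < nrow(H)) stop("H must have full row rank")
  check_psd(R, "R")
  stopifnot(nrow(R) == nrow(H))
  structure(list(H = H, R = R), class = "obs_model")
}

# Normalize per-step parameters: either a single disc_params shared by all
# steps or a list of length T-1. Returns mu (d x L), F and Sigma cubes and
# a per-time mode index (length T; last entry padding).
prep_step_params <- function(params, T) {
  if (inherits(params, "disc_params")) params <- list(params)
  stopifnot(is.list(params), length(params) >= 1)
  if (length(params) == 1) {
    z <- rep.int(1L, T)
  } else {
    if (length(params) != T - 1)
      stop("params_per_step must be a single disc_params or a list of length T-1")
    z <- c(seq_len(T - 1), 1L)
  }
  d <- length(params[[1]]$mu)
  L <- length(params)
  mu <- vapply(params, function(p) p$mu, numeric(d))
  mu <- matrix(mu, d, L)
  Fm <- array(0, c(d, d, L)); Sg <- array(0, c(d, d, L))
  for (k in seq_len(L)) {
    Fm[, , k] <- params[[k]]$F
    Sg[, , k] <- params[[k]]$Sigma
  }
  list(mu = mu, Fm = Fm, Sg = Sg, z = as.integer(z), d = d)
}

# Default diffuse initialization: first measurement lifted through the
# pseudoinverse of H (zero on hidden axes), covariance 1e3 x a scale built
# from the process and measurement covariances.
default_init <- function(psi, obs, Sg1) {
  H <- obs$H
  m0 <- as.numeric(t(H) %*% solve(H %*% t(H), psi[1, ]))
  scale <- mean(diag(Sg1)) + mean(diag(obs$R))
  P0 <- diag(1e3 * scale, ncol(H))
  list(m0 = m0, P0 = P0)
}

#' Kalman filter for a (mode-varying) linear-Gaussian trajectory model
#'
#' Exact forward filtering of `r_{i+1} = mu_i + F_i r_i + eta_i`,
#' `psi_i = H r_i + eps_i`, returning the log-likelihood
#' `sum_i log N(psi_i; predictive mean, predictive cov)` and the
#' predicted/filtered moments. Covariances are propagated in Joseph form
#' and symmetrized; innovation covariances carry a relative 1e-9 diagonal
#' jitter (long chains of near-unit-root states).
#'
#' @param psi T x d_obs measurement matrix (rows are time points).
#' @param params a single [disc_params()] shared by all steps, or a list of
#'   `T-1` of them (parameters of step `i -> i+1`).
#' @param obs an [observation_model()].
#' @param init optional list with `m0`, `P0`; default diffuse (see Details).
#' @return object of class `kalman_filter` with elements `loglik`,
#'   `mp`/`Pp` (predicted), `mf`/`Pf` (filtered).
#' @export
kalman_filter <- function(psi, params, obs, init = NULL) {
  psi <- as.matrix(psi)
  stopifnot(inherits(obs, "obs_model"))
  pp <- prep_step_params(params, nrow(psi))
  if (is.null(init)) init <- default_init(psi, obs, pp$Sg[, , 1])
  out <- .kf_forward(psi, pp$z, pp$mu, pp$Fm, pp$Sg, obs$H, obs$R,
                     init$m0, init$P0, TRUE)
  out$z <- pp$z; out$pp <- pp; out$init <- init
  class(out) <- "kalman_filter"
  out
}

#' Rauch-Tung-Striebel smoother
#'
#' Backward recursion over the moments of a [kalman_filter()] result; the
#' smoothed covariance never exceeds the filtered covariance in the
#' Loewner order.
#'
#' @param filter a [kalman_filter()] result.
#' @return list with `ms` (d x T smoothed means) and `Ps` (d x d x T).
#' @export
rts_smoother <- function(filter) {
  stopifnot(inherits(filter, "kalman_filter"))
  .rts_backward(filter$z, filter$pp$mu, filter$pp$Fm,
                filter$mp, filter$Pp, filter$mf, filter$Pf)
}

#' Simulation smoother (one exact posterior draw of the latent path)
#'
#' Forward Kalman filter followed by Carter-Kohn backward sampling: the
#' returned path is one exact draw from `p(r_{1:T} | psi, modes, theta)`.
#' Reproducible via `set.seed()` (or the `seed` argument).
#'
#' @inheritParams kalman_filter
#' @param seed optional integer seed.
#' @return list with `r` (T x d sampled path) and `loglik` of the filter.
#' @export
simulation_smoother <- function(psi, params, obs, init = NULL, seed = NULL) {
  psi <- as.matrix(psi)
  stopifnot(inherits(obs, "obs_model"))
  pp <- prep_step_params(params, nrow(psi))
  if (is.null(init)) init <- default_init(psi, obs, pp$Sg[, , 1])
  if (!is.null(seed)) set.seed(seed)
  .sim_smoother_draw(psi, pp$z, pp$mu, pp$Fm, pp$Sg, obs$H, obs$R,
                     init$m0, init$P0)
}
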