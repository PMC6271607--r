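#' Fit a sticky HDP-SLDS segmentation to one trajectory
#'
#' The main entry point of the package. Given a time-ordered matrix of
#' noisy position measurements at uniform spacing `dt`, runs the blocked
#' Gibbs sampler ([run_mcmc()]) of the sticky HDP switching linear
#' dynamical system and returns a fitted-model object: the number of
#' kinetic states, the segmentation, and per-state kinetic parameters are
#' all inferred jointly, without fixing the number of states in advance.
#'
#' Each hidden state is a discretized overdamped-Langevin diffusion
#' (`r_{i+1} = mu_k + F_k r_i + eta`, `eta ~ N(0, Sigma_k)`) observed
#' through Gaussian localization noise with shared covariance `R`
#' (`psi_i = H r_i + eps`). Switching follows a sticky hierarchical
#' Dirichlet process prior truncated at `L` modes.
#'
#' @param psi T x d_obs matrix (or data frame) of measurements; rows are
#'   time points.
#' @param dt sampling interval (seconds).
#' @param prior an [slds_prior()]; when `NULL` a weak default is built
#'   from the data scale (use [build_prior_from_dgp()] for benchmark
#'   runs).
#' @param hyper an [hdp_config()].
#' @param state_dim latent dimension `d`; defaults to `ncol(psi)` (set 3
#'   with 2D measurements for the hidden-z model).
#' @param H observation selector; default `cbind(diag(d_obs), 0...)`
#'   selecting the first `d_obs` latent coordinates.
#' @param seed integer seed (overrides `hyper$seed`).
#' @param verbose progress-print interval in sweeps (0 = silent).
#' @return an object of class `hdpslds` with components `chain`
#'   (the raw [run_mcmc()] chain), `estimate` (the [point_estimate()]),
#'   `psi`, `dt`, and the configuration. Supports `print`, `summary`,
#'   `coef`, `plot`, `residuals`, `fitted`, `logLik`, `predict` and
#'   `simulate` methods.
#' @examples
#' \donttest{
#' cfg <- dgp_config(n_obs = 300, n_traj = 1, seed = 7)
#' tr <- simulate_trajectory(cfg)
#' prior <- build_prior_from_dgp(cfg, mode = "exact")
#' fit <- hdpslds(tr$psi, dt = cfg$dt, prior = prior,
#'                hyper = hdp_config(n_sweeps = 200), seed = 1)
#' print(fit)
#' average_hamming(tr$s, fitted(fit))
#' }
#' @export
hdpslds <- function(psi, dt, prior = NULL, hyper = hdp_config(),
                    state_dim = NULL, H = NULL, seed = NULL, verbose = 0) {
  psi <- as.matrix(psi)
  storage.mode(psi) <- "double"
  p <- ncol(psi)
  d <- if (is.null(state_dim)) p else as.integer(state_dim)
  if (d < p) stop("state dimension cannot be smaller than the observed dimension")
  if (is.null(H)) H <- cbind(diag(p), matrix(0, p, d - p))
  if (is.null(prior)) prior <- default_data_prior(psi, d, H)
  if (!is.null(seed)) hyper$seed <- as.integer(seed)
  obs <- observation_model(H, prior$S_R)
  chain <- run_mcmc(psi, dt, obs, prior, hyper, d = d, verbose = verbose)
  est <- point_estimate(chain)
  structure(list(chain = chain, estimate = est, psi = psi, dt = dt,
                 prior = prior, hyper = hyper, d = d, H = H,
                 call = match.call()),
            class = "hdpslds")
}

# Weak data-driven default prior: Sigma mean from the lag-1 increment
# covariance (deconvolved heuristically), R mean from a fraction of it.
default_data_prior <- function(psi, d, H) {
  dpsi <- diff(psi)
  S_inc <- crossprod(dpsi) / max(nrow(dpsi) - 1, 1)
  s <- mean(diag(S_inc))
  S_Sigma <- diag(s / 2, d)
  S_R <- diag(s / 4, ncol(psi))
  slds_prior(S_Sigma = S_Sigma, S_R = S_R)
}

#' @export
print.hdpslds <- function(x, ...) {
  cat("Sticky HDP-SLDS fit:", x$chain$T, "observations, d =", x$d,
      ", d_obs =", ncol(x$psi), "\n")
  occ <- table(x$estimate$labels)
  cat("  inferred states (point estimate):", length(occ), "\n")
  cat("  occupancy:", paste(names(occ), "=", as.integer(occ),
                            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.hdpslds <- function(object, ...) {
  ch <- object$chain
  keep <- seq.int(ch$cfg$burn_in + 1L, nrow(ch$z))
  hyp <- colMeans(ch$hyper[keep, , drop = FALSE])
  occ <- table(object$estimate$labels)
  co <- coef(object)
  out <- list(n_obs = ch$T, d = object$d, dt = object$dt,
              n_states = length(occ),
              occupancy = occ,
              active_modes = stats::quantile(ch$n_active[keep],
                                             c(.25, .5, .75)),
              hyper_means = hyp,
              loglik = mean(ch$loglik[keep]),
              coef = co)
  class(out) <- "summary.hdpslds"
  out
}

#' @export
print.summary.hdpslds <- function(x, ...) {
  cat("Sticky HDP-SLDS segmentation summary\n")
  cat("  observations:", x$n_obs, " dt:", format(x$dt, digits = 4),
      "s  state dim:", x$d, "\n")
  cat("  states in point estimate:", x$n_states, "\n")
  cat("  active modes per sweep (quartiles):",
      paste(x$active_modes, collapse = " / "), "\n")
  cat("  posterior hyperparameter means: gamma =",
      format(x$hyper_means["gamma"], digits = 3),
      ", alpha+kappa =", format(x$hyper_means["alpha_plus_kappa"], digits = 3),
      ", rho =", format(x$hyper_means["rho"], digits = 3), "\n")
  cat("  mean post-burn-in data log-likelihood:",
      format(x$loglik, digits = 6), "\n\n")
  cat("Per-state posterior means (occupied states):\n")
  for (k in seq_along(x$coef$states)) {
    s <- x$coef$states[[k]]
    cat(sprintf("  state %s (%d points): diag(Sigma) = %s\n",
                names(x$coef$states)[k], s$n_points,
                paste(format(diag(s$Sigma), digits = 3), collapse = ", ")))
  }
  invisible(x)
}

#' Posterior-mean parameters of the occupied states
#'
#' Averages the per-sweep parameter draws over the post-burn-in window,
#' conditionally on each sweep's label at the time points the point
#' estimate assigns to a state. Also reports the shared measurement
#' covariance `R` and, where the posterior-mean propagator admits a real
#' continuous embedding, the physical diffusion matrix and fixed point via
#' [ou_continuize()].
#'
#' @param object an [hdpslds()] fit.
#' @param ... unused.
#' @return list with `states` (per-label `mu`, `F`, `Sigma`, `n_points`,
#'   and `continuous` when available) and `R`.
#' @export
coef.hdpslds <- function(object, ...) {
  ch <- object$chain
  keep <- seq.int(ch$cfg$burn_in + 1L, nrow(ch$z))
  labs <- sort(unique(object$estimate$labels))
  states <- list()
  for (k in labs) {
    idx <- which(object$estimate$labels == k)
    # weight each sweep's mode-k draw by how much of the segment it owns
    wmu <- 0; wF <- 0; wS <- 0; wtot <- 0
    for (s in keep) {
      w <- sum(ch$z[s, idx] == k)
      if (w == 0) next
      wmu <- wmu + w * ch$theta_mu[s, , k]
      wF <- wF + w * ch$theta_F[s, , , k]
      wS <- wS + w * ch$theta_Sigma[s, , , k]
      wtot <- wtot + w
    }
    if (wtot == 0) next
    st <- list(mu = wmu / wtot, F = matrix(wF / wtot, object$d, object$d),
               Sigma = matrix(wS / wtot, object$d, object$d),
               n_points = length(idx))
    st$continuous <- tryCatch(
      ou_continuize(disc_params(st$mu, st$F,
                                (st$Sigma + t(st$Sigma)) / 2,
                                R = apply(ch$R[keep, , , drop = FALSE],
                                          c(2, 3), mean),
                                dt = object$dt)),
      error = function(e) NULL)
    states[[as.character(k)]] <- st
  }
  Rbar <- apply(ch$R[keep, , , drop = FALSE], c(2, 3), mean)
  list(states = states, R = Rbar)
}

#' @export
fitted.hdpslds <- function(object, ...) object$estimate$labels

#' @export
residuals.hdpslds <- function(object, ...) {
  object$psi - object$chain$r_mean %*% t(object$H)
}

#' @export
logLik.hdpslds <- function(object, ...) {
  ch <- object$chain
  keep <- seq.int(ch$cfg$burn_in + 1L, nrow(ch$z))
  ll <- mean(ch$loglik[keep])
  attr(ll, "df") <- NA_integer_
  class(ll) <- "logLik"
  ll
}

#' Per-time-point posterior state probabilities
#'
#' @param object an [hdpslds()] fit.
#' @param type `"labels"` for the point-estimate sequence or `"prob"` for
#'   the T x L marginal matrix.
#' @param ... unused.
#' @export
predict.hdpslds <- function(object, type = c("labels", "prob"), ...) {
  type <- match.arg(type)
  if (type == "labels") object$estimate$labels else object$estimate$prob
}

#' Simulate new measurements from the fitted segmentation
#'
#' Generates `nsim` synthetic measurement sequences by propagating the
#' posterior-mean per-state dynamics along the fitted label sequence and
#' adding measurement noise from the posterior-mean `R` — a parametric
#' bootstrap of the fitted model.
#'
#' @param object an [hdpslds()] fit.
#' @param nsim number of replicate series.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a T x d_obs matrix, or a list of them when `nsim > 1`.
#' @export
simulate.hdpslds <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  co <- coef(object)
  labs <- object$estimate$labels
  T <- length(labs); d <- object$d
  out <- vector("list", nsim)
  chR <- chol(co$R + 1e-15 * diag(nrow(co$R)))
  for (j in seq_len(nsim)) {
    r <- matrix(0, T, d)
    r[1, ] <- object$chain$r_mean[1, ]
    for (i in seq_len(T - 1)) {
      st <- co$states[[as.character(labs[i])]]
      if (is.null(st)) st <- co$states[[1]]
      Lc <- t(chol((st$Sigma + t(st$Sigma)) / 2 + 1e-15 * diag(d)))
      r[i + 1, ] <- st$mu + st$F %*% r[i, ] + Lc %*% stats::rnorm(d)
    }
    out[[j]] <- r %*% t(object$H) +
      matrix(stats::rnorm(T * nrow(co$R)), T) %*% chR
  }
  if (nsim == 1) out[[1]] else out
}

#' Plot a fitted segmentation
#'
#' Two stacked base-graphics panels: the measured coordinates against
#' time, colored by the inferred state, and the inferred label sequence
#' (with the true sequence overlaid when supplied).
#'
#' @param x an [hdpslds()] fit.
#' @param truth optional true label sequence to overlay.
#' @param ... passed to `matplot`.
#' @export
plot.hdpslds <- function(x, truth = NULL, ...) {
  labs <- x$estimate$labels
  T <- length(labs)
  tt <- (seq_len(T) - 1) * x$dt
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::matplot(tt, x$psi, type = "l", lty = 1, col = "grey60",
                    ylab = "position", xlab = "", ...)
  graphics::points(rep(tt, ncol(x$psi)), as.numeric(x$psi),
                   col = labs, pch = ".", cex = 2)
  graphics::plot(tt, labs, type = "s", col = 2, ylab = "state",
                 xlab = "time (s)", ylim = range(c(labs, truth)))
  if (!is.null(truth)) graphics::lines(tt, truth, type = "s", col = 1, lty = 2)
  invisible(x)
}
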