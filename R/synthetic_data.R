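#' Region rules of the position-driven switching simulator
#'
#' The benchmark data-generating process switches kinetic state according
#' to where the particle currently is:
#' \itemize{
#'   \item State 3 ("bound/confined"): `z > 0` and `y > C2` — diffusion drops
#'     to `D_alt` and confinement tightens to `B_alt`.
#'   \item State 2 (slow diffusion): `z < C1` and `y < C2` — only the
#'     diffusion coefficient drops to `D_alt`.
#'   \item State 4 (shifted well): `z < 0` and `y_alt < y < C2` — only the
#'     fixed point moves to `rbar_alt` (an abrupt change in `mu`).
#'   \item State 1: the reference/base state, anywhere else.
#' }
#' Regions can overlap (e.g. `z < C1` implies `z < 0` when `C1 < 0`); the
#' fixed precedence 3, 2, 4, 1 makes the rule single-valued.
#'
#' @param C1 z-threshold of State 2 (length units).
#' @param C2 y-threshold separating States 3 and 2/4.
#' @param y_alt lower y-threshold of State 4; must satisfy `y_alt < C2`.
#' @param rbar_alt fixed point of State 4, `(x_alt, y_alt, z_alt)`.
#' @return an object of class `region_rules`.
#' @export
region_rules <- function(C1 = -0.3, C2 = 0.3, y_alt = -0.3,
                         rbar_alt = c(0.3, 0, -0.3)) {
  stopifnot(is.finite(C1), is.finite(C2), is.finite(y_alt),
            all(is.finite(rbar_alt)), length(rbar_alt) == 3)
  if (y_alt >= C2) stop("State 4 band is empty: need y_alt < C2")
  structure(list(C1 = C1, C2 = C2, y_alt = y_alt,
                 rbar_alt = as.numeric(rbar_alt)),
            class = "region_rules")
}

#' Classify a position into a kinetic state
#'
#' Deterministic, total map from a 3D position to the state label in
#' `{1, 2, 3, 4}` under the precedence 3, 2, 4, 1 (see [region_rules()]).
#'
#' @param pos length-3 position vector, or an n x 3 matrix of positions.
#' @param rules a [region_rules()] object.
#' @return integer label(s) in 1..4.
#' @export
classify_region <- function(pos, rules) {
  stopifnot(inherits(rules, "region_rules"))
  pos <- if (is.matrix(pos)) pos else matrix(pos, nrow = 1)
  stopifnot(ncol(pos) == 3)
  y <- pos[, 2]; z <- pos[, 3]
  s <- rep.int(1L, nrow(pos))
  s4 <- z < 0 & y > rules$y_alt & y < rules$C2
  s[s4] <- 4L
  s2 <- z < rules$C1 & y < rules$C2
  s[s2] <- 2L
  s3 <- z > 0 & y > rules$C2
  s[s3] <- 3L
  s
}

#' Configuration of the trajectory data-generating process
#'
#' Bundles the base-state kinetics, the alternative-state modifications and
#' the sampling scheme of the four-state switching simulator. Defaults
#' emulate a confined membrane-protein tracking scenario at 22 frames/s:
#' isotropic `D = 0.01` um^2/s, x/y relaxation 1/s with a near-unit-root z
#' axis (practically pure diffusion over 1000 frames), localization noise
#' of 30 nm per axis, and switching thresholds 0.3 um from the origin.
#'
#' @param base a [cont_params()] object for State 1 (3D).
#' @param D_alt_factor multiplicative drop of the diffusion matrix in
#'   States 2 and 3 (default 1/10).
#' @param B_alt_factor multiplicative increase of the confinement matrix in
#'   State 3 (default 10).
#' @param regions a [region_rules()] object.
#' @param n_obs observations per trajectory (>= 2).
#' @param dt sampling interval in seconds.
#' @param n_traj number of trajectories in an ensemble.
#' @param seed integer seed controlling all ensemble randomness.
#' @param switching_mode `"region"` (benchmark default: labels are a
#'   deterministic function of position) or `"markov"` (labels follow a
#'   Markov chain; used for illustrating abrupt `mu` switches).
#' @param markov_states states participating in markov mode (default
#'   `c(1, 4)`: two states differing only in their fixed point).
#' @param markov_trans transition matrix over `markov_states` (default a
#'   sticky chain with 1% switch probability per frame).
#' @return an object of class `dgp_config`.
#' @export
dgp_config <- function(base = NULL,
                       D_alt_factor = 0.1,
                       B_alt_factor = 10,
                       regions = region_rules(),
                       n_obs = 1000, dt = 1 / 22,
                       n_traj = 500, seed = 1,
                       switching_mode = c("region", "markov"),
                       markov_states = c(1L, 4L),
                       markov_trans = NULL) {
  switching_mode <- match.arg(switching_mode)
  if (is.null(base)) {
    base <- cont_params(rbar = c(0, 0, 0),
                        A = diag(c(1, 1, 1e-6)),
                        D = diag(0.01, 3),
                        R = diag(0.03^2, 3))
  }
  stopifnot(inherits(base, "cont_params"), length(base$rbar) == 3,
            n_obs >= 2, n_traj >= 1, dt > 0,
            D_alt_factor > 0, D_alt_factor <= 1)
  if (is.null(markov_trans)) {
    k <- length(markov_states)
    markov_trans <- matrix(0.01 / (k - 1), k, k)
    diag(markov_trans) <- 0.99
  }
  cfg <- structure(list(base = base, D_alt_factor = D_alt_factor,
                        B_alt_factor = B_alt_factor, regions = regions,
                        n_obs = as.integer(n_obs), dt = dt,
                        n_traj = as.integer(n_traj), seed = as.integer(seed),
                        switching_mode = switching_mode,
                        markov_states = as.integer(markov_states),
                        markov_trans = markov_trans),
                   class = "dgp_config")
  # validate all four implied state parameter sets
  invisible(lapply(1:4, function(k) dgp_state_params(cfg, k)))
  cfg
}

#' Continuous parameters of one DGP state
#'
#' Builds the [cont_params()] of state `k` in 1..4 from a [dgp_config()].
#' States 2 and 3 scale the diffusion matrix by `D_alt_factor` (and, through
#' the Einstein relation `Phi = D/kBT`, slow the realized relaxation rate
#' accordingly); State 3 additionally scales `B` by `B_alt_factor`; State 4
#' moves the fixed point to `regions$rbar_alt`.
#'
#' @param cfg a [dgp_config()].
#' @param k state label in 1..4.
#' @return a [cont_params()] object.
#' @export
dgp_state_params <- function(cfg, k) {
  stopifnot(inherits(cfg, "dgp_config"), k %in% 1:4)
  b <- cfg$base
  rbar <- b$rbar; B <- b$B; D <- b$D
  if (k == 2L) D <- D * cfg$D_alt_factor
  if (k == 3L) { D <- D * cfg$D_alt_factor; B <- B * cfg$B_alt_factor }
  if (k == 4L) rbar <- cfg$regions$rbar_alt
  cont_params(rbar = rbar, B = B, D = D, R = b$R, kBT = b$kBT)
}

#' Simulate one noisily measured switching trajectory
#'
#' Positions evolve by the exact one-step OU transition of the state
#' governing the current step; the state of step `i -> i+1` is
#' `classify_region(r_i)` in region mode (left-continuous switching) or a
#' Markov draw in markov mode. Measurements are `psi_i = H r_i + eps_i`
#' with `eps ~ N(0, R)`. The initial position is drawn around the base
#' fixed point with per-axis variance `min(stationary variance, 2 D T)`,
#' capping the initialization of near-unit-root (pure diffusion) axes at
#' the diffusion length of the trajectory.
#'
#' @param cfg a [dgp_config()].
#' @param seed integer seed (defaults to `cfg$seed`).
#' @param H observation selector (d_obs x 3); default identity (full 3D
#'   observation). Changing `H` changes only `psi`, never `r` or `s`.
#' @return an object of class `sim_trajectory`: list with `t` (times),
#'   `r` (n x 3 true positions), `psi` (n x d_obs measurements), `s`
#'   (true labels), `dt`, `H`.
#' @export
simulate_trajectory <- function(cfg, seed = cfg$seed, H = diag(3)) {
  stopifnot(inherits(cfg, "dgp_config"))
  H <- as.matrix(H)
  stopifnot(ncol(H) == 3)
  n <- cfg$n_obs
  disc <- lapply(1:4, function(k) ou_discretize(dgp_state_params(cfg, k), cfg$dt))
  chL <- lapply(disc, function(d) chol_or_zero(d$Sigma))

  set.seed(seed)
  # initial condition: base-state mean, variance capped at trajectory
  # diffusion scale on near-unit-root axes
  b1 <- disc[[1L]]
  A1 <- cfg$base$A
  statv <- vapply(1:3, function(j) {
    a <- A1[j, j]
    sv <- if (a > 1e-9) cfg$base$D[j, j] / a else Inf
    min(sv, 2 * cfg$base$D[j, j] * n * cfg$dt)
  }, numeric(1))
  r <- matrix(NA_real_, n, 3)
  r[1, ] <- cfg$base$rbar + rnorm(3) * sqrt(statv)
  s <- integer(n)

  if (cfg$switching_mode == "region") {
    for (i in seq_len(n - 1)) {
      s[i] <- classify_region(r[i, ], cfg$regions)
      k <- s[i]
      r[i + 1, ] <- disc[[k]]$mu + disc[[k]]$F %*% r[i, ] + chL[[k]] %*% rnorm(3)
      if (!all(is.finite(r[i + 1, ])))
        stop("non-finite simulated position at step ", i + 1)
    }
    s[n] <- classify_region(r[n, ], cfg$regions)
  } else {
    ks <- cfg$markov_states
    P <- cfg$markov_trans
    idx <- sample.int(length(ks), 1)
    for (i in seq_len(n - 1)) {
      s[i] <- ks[idx]
      k <- s[i]
      r[i + 1, ] <- disc[[k]]$mu + disc[[k]]$F %*% r[i, ] + chL[[k]] %*% rnorm(3)
      if (!all(is.finite(r[i + 1, ])))
        stop("non-finite simulated position at step ", i + 1)
      idx <- sample.int(length(ks), 1, prob = P[idx, ])
    }
    s[n] <- ks[idx]
  }

  p <- nrow(H)
  Rm <- cfg$base$R
  Robs <- H %*% Rm %*% t(H)
  psi <- r %*% t(H) + matrix(rnorm(n * p), n, p) %*% t(chol_or_zero(Robs))
  structure(list(t = (seq_len(n) - 1) * cfg$dt, r = r, psi = psi,
                 s = s, dt = cfg$dt, H = H, seed = seed),
            class = "sim_trajectory")
}

#' Simulate a reproducible ensemble of trajectories
#'
#' Per-trajectory seeds are derived deterministically from `cfg$seed`, so
#' the same configuration always yields a bitwise-identical ensemble (the
#' benchmark contract: every scenario re-analyzes the identical set of
#' trajectories).
#'
#' @inheritParams simulate_trajectory
#' @param min_states minimum number of distinct realized states per
#'   trajectory (default 1 = no filtering). The benchmark ensembles use 2:
#'   every benchmark trajectory mixes two to four states, so draws that
#'   happen to stay inside one region are deterministically re-drawn with
#'   a shifted sub-seed.
#' @return list of [simulate_trajectory()] results, with attribute
#'   `realized_states` (per-trajectory count of distinct true states).
#' @export
simulate_ensemble <- function(cfg, H = diag(3), min_states = 1) {
  stopifnot(inherits(cfg, "dgp_config"), min_states >= 1, min_states <= 4)
  seeds <- cfg$seed + 1000L * seq_len(cfg$n_traj)
  out <- vector("list", cfg$n_traj)
  for (i in seq_len(cfg$n_traj)) {
    for (try in 0:50) {
      tr <- tryCatch(simulate_trajectory(cfg, seed = seeds[i] + 17L * try,
                                         H = H),
                     error = function(e)
                       stop("trajectory ", i, ": ", conditionMessage(e)))
      if (length(unique(tr$s)) >= min_states) break
    }
    if (length(unique(tr$s)) < min_states)
      stop("trajectory ", i, ": could not realize ", min_states,
           " states in 50 attempts; regions unreachable?")
    out[[i]] <- tr
  }
  attr(out, "realized_states") <-
    vapply(out, function(tr) length(unique(tr$s)), integer(1))
  attr(out, "seed") <- cfg$seed
  out
}

#' Serialize / restore a DGP configuration through a YAML config
#'
#' Round-trips every field of [dgp_config()] (nested keys; matrices as
#' row-major lists) so a benchmark run can be reproduced from a plain-text
#' file.
#'
#' @param cfg a [dgp_config()] object.
#' @param path file path.
#' @return `read_dgp_config()` returns a [dgp_config()].
#' @export
write_dgp_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "dgp_config"))
  obj <- list(
    base = list(rbar = cfg$base$rbar, D = mat_to_rows(cfg$base$D),
                B = mat_to_rows(cfg$base$B), R = mat_to_rows(cfg$base$R),
                kBT = cfg$base$kBT),
    D_alt_factor = cfg$D_alt_factor, B_alt_factor = cfg$B_alt_factor,
    regions = list(C1 = cfg$regions$C1, C2 = cfg$regions$C2,
                   y_alt = cfg$regions$y_alt,
                   rbar_alt = cfg$regions$rbar_alt),
    n_obs = cfg$n_obs, dt = cfg$dt, n_traj = cfg$n_traj, seed = cfg$seed,
    switching_mode = cfg$switching_mode,
    markov_states = cfg$markov_states,
    markov_trans = mat_to_rows(cfg$markov_trans))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_dgp_config
#' @export
read_dgp_config <- function(path) {
  o <- yaml::read_yaml(path)
  dgp_config(
    base = cont_params(rbar = as.numeric(o$base$rbar),
                       D = rows_to_mat(o$base$D), B = rows_to_mat(o$base$B),
                       R = rows_to_mat(o$base$R), kBT = o$base$kBT),
    D_alt_factor = o$D_alt_factor, B_alt_factor = o$B_alt_factor,
    regions = region_rules(C1 = o$regions$C1, C2 = o$regions$C2,
                           y_alt = o$regions$y_alt,
                           rbar_alt = as.numeric(o$regions$rbar_alt)),
    n_obs = o$n_obs, dt = o$dt, n_traj = o$n_traj, seed = o$seed,
    switching_mode = o$switching_mode,
    markov_states = as.integer(o$markov_states),
    markov_trans = rows_to_mat(o$markov_trans))
}

# lower-triangular factor L with L L' = S; exact zero matrix stays zero,
# semidefinite inputs get escalating relative jitter
chol_or_zero <- function(S) {
  scale <- max(diag(S), 0)
  if (scale == 0) return(matrix(0, nrow(S), ncol(S)))
  jit <- 0
  for (k in 1:6) {
    L <- tryCatch(t(chol(S + jit * diag(nrow(S)))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jit <- if (jit == 0) 1e-12 * scale else jit * 100
  }
  stop("covariance factorization failed (matrix not PSD)")
}

#' @export
print.sim_trajectory <- function(x, ...) {
  cat("Simulated SPT trajectory:", nrow(x$r), "observations, dt =",
      format(x$dt, digits = 4), "s\n")
  cat("  realized states:", paste(sort(unique(x$s)), collapse = ", "), "\n")
  cat("  observed dimensions:", ncol(x$psi), "\n")
  invisible(x)
}
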