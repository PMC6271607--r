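test_that("symmetric likelihood gives uniform mode draws", {
  set.seed(31)
  T <- 10; L <- 3
  r <- matrix(rnorm(T * 2, sd = 0.1), T, 2)
  th <- list(mu = c(0, 0), F = diag(0.9, 2), Sigma = diag(0.01, 2))
  theta <- list(th, th, th)
  piU <- matrix(1 / L, L, L)
  draws <- sample_mode_sequence(r, theta, piU, pi0 = rep(1 / L, L),
                                ndraws = 20000, seed = 32)
  freq <- tabulate(draws, L) / length(draws)
  chi2 <- sum((tabulate(draws, L) - length(draws) / L)^2 / (length(draws) / L))
  expect_gt(stats::pchisq(chi2, df = L - 1, lower.tail = FALSE), 1e-3)
  expect_lt(max(abs(freq - 1 / L)), 0.01)
})

test_that("mode-sequence draws match exhaustive enumeration on a tiny chain", {
  set.seed(33)
  T <- 5; L <- 2
  r <- matrix(rnorm(T * 1, sd = 0.3), T, 1)
  theta <- list(list(mu = 0.05, F = matrix(0.9), Sigma = matrix(0.02)),
                list(mu = -0.1, F = matrix(0.5), Sigma = matrix(0.08)))
  Pi <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE)
  pi0 <- c(0.6, 0.4)
  # independent oracle: enumerate all 2^5 label sequences
  seqs <- as.matrix(expand.grid(rep(list(1:2), T)))
  logp <- apply(seqs, 1, function(z) {
    lp <- log(pi0[z[1]])
    for (t in 1:(T - 1)) {
      lp <- lp + log(Pi[z[t], z[t + 1]]) +
        dnorm(r[t + 1, 1], theta[[z[t]]]$mu + theta[[z[t]]]$F[1, 1] * r[t, 1],
              sqrt(theta[[z[t]]]$Sigma[1, 1]), log = TRUE)
    }
    lp
  })
  p_exact <- exp(logp - max(logp)); p_exact <- p_exact / sum(p_exact)
  ndraw <- 2e5
  draws <- sample_mode_sequence(r, theta, Pi, pi0 = pi0, ndraws = ndraw,
                                seed = 34)
  key <- apply(draws, 2, paste, collapse = "")
  keys_all <- apply(t(seqs), 2, paste, collapse = "")
  freq <- as.numeric(table(factor(key, levels = keys_all))) / ndraw
  expect_lt(max(abs(freq - p_exact)), 0.01)
})

test_that("a mode matching the generating dynamics dominates occupancy", {
  set.seed(35)
  T <- 300
  Fm <- diag(0.9, 2); Sg_true <- diag(1e-4, 2)
  r <- matrix(0, T, 2)
  for (t in 2:T) r[t, ] <- Fm %*% r[t - 1, ] + rnorm(2, sd = 1e-2)
  theta <- list(list(mu = c(0, 0), F = Fm, Sigma = 1e4 * Sg_true),
                list(mu = c(0, 0), F = Fm, Sigma = Sg_true))
  piU <- matrix(0.5, 2, 2)
  z <- sample_mode_sequence(r, theta, piU, seed = 36)
  expect_gt(mean(z == 2L), 0.99)
})

test_that("sticky transition updates are conjugate with empty counts", {
  L <- 4
  gamma <- 1e8        # pins the shared weights at 1/L
  ak <- 20; rho <- 0.6
  alpha <- (1 - rho) * ak; kappa <- rho * ak
  set.seed(37)
  reps <- 4000
  acc <- matrix(0, L, L)
  for (i in seq_len(reps)) {
    out <- sample_transition_params(beta = rep(1 / L, L), gamma = gamma,
                                    alpha_plus_kappa = ak, rho = rho, L = L,
                                    counts = matrix(0, L, L))
    acc <- acc + out$pi
  }
  pim <- acc / reps
  target <- matrix(alpha / L, L, L) + kappa * diag(L)
  target <- target / (alpha + kappa)
  expect_lt(max(abs(pim - target)), 0.01)
})

test_that("a huge sticky mass forces near-certain self-transitions", {
  set.seed(38)
  out <- sample_transition_params(beta = rep(0.25, 4), gamma = 1,
                                  alpha_plus_kappa = 1e5, rho = 1 - 1e-6,
                                  L = 4, counts = matrix(0, 4, 4))
  expect_gt(min(diag(out$pi)), 0.99)
})

test_that("row draws with fixed counts match the Dirichlet posterior mean", {
  L <- 3
  counts <- matrix(c(40, 5, 5,
                     2, 60, 8,
                     1, 3, 30), 3, 3, byrow = TRUE)
  gamma <- 1e8  # beta pinned at 1/L so the row prior is deterministic
  ak <- 10; rho <- 0.5
  alpha <- (1 - rho) * ak; kappa <- rho * ak
  set.seed(39)
  reps <- 20000
  acc <- matrix(0, L, L)
  for (i in seq_len(reps)) {
    out <- sample_transition_params(beta = rep(1 / L, L), gamma = gamma,
                                    alpha_plus_kappa = ak, rho = rho, L = L,
                                    counts = counts)
    acc <- acc + out$pi
  }
  pim <- acc / reps
  target <- counts + alpha / L
  diag(target) <- diag(target) + kappa
  target <- target / rowSums(target)
  expect_lt(max(abs(pim - target)), 0.005)
})

test_that("unoccupied modes are refreshed from the base measure", {
  # df = d + 10 keeps the inverse-Wishart variance finite so the Monte
  # Carlo mean converges; its mean is S / (nu - d - 1)
  prior <- slds_prior(S_Sigma = diag(0.07, 2), S_R = diag(1e-3, 2),
                      nu_Sigma = 12)
  set.seed(40)
  r <- matrix(rnorm(20 * 2, sd = 0.1), 20, 2)
  z <- rep(1L, 20)   # mode 2 never used
  reps <- 1500
  S_acc <- matrix(0, 2, 2)
  for (i in seq_len(reps)) {
    mp <- sample_mode_params(r, z, prior, L = 2)
    S_acc <- S_acc + mp$theta[[2]]$Sigma
  }
  target <- prior$S_Sigma / (12 - 2 - 1)
  expect_lt(max(abs(S_acc / reps - target)) / max(target), 0.1)
})

test_that("a long single-mode path recovers its generating dynamics", {
  set.seed(41)
  T <- 3000
  Ftrue <- diag(c(0.95, 0.9)); mu_true <- c(0.01, -0.02)
  Sg_true <- diag(c(4e-4, 6e-4))
  r <- matrix(0, T, 2)
  for (t in 2:T)
    r[t, ] <- mu_true + Ftrue %*% r[t - 1, ] + rnorm(2, sd = sqrt(diag(Sg_true)))
  prior <- slds_prior(S_Sigma = diag(1e-3, 2), S_R = diag(1e-3, 2))
  reps <- 200
  Fd <- array(NA_real_, c(reps, 2, 2)); Sd <- array(NA_real_, c(reps, 2, 2))
  for (i in seq_len(reps)) {
    mp <- sample_mode_params(r, rep(1L, T), prior, L = 1)
    Fd[i, , ] <- mp$theta[[1]]$F
    Sd[i, , ] <- mp$theta[[1]]$Sigma
  }
  for (a in 1:2) for (b in 1:2) {
    postm <- mean(Fd[, a, b]); posts <- sd(Fd[, a, b])
    expect_lt(abs(postm - Ftrue[a, b]), 4 * posts + 4 * posts / sqrt(reps))
  }
  expect_lt(abs(mean(Sd[, 1, 1]) - Sg_true[1, 1]) / Sg_true[1, 1], 0.15)
})

test_that("the shared measurement covariance converges to the residual covariance", {
  set.seed(42)
  T <- 5000
  r <- matrix(rnorm(T * 2, sd = 0.2), T, 2)
  Rtrue <- diag(c(9e-4, 4e-4))
  psi <- r + matrix(rnorm(T * 2), T, 2) %*% chol(Rtrue)
  prior <- slds_prior(S_Sigma = diag(1e-3, 2), S_R = diag(1e-2, 2))
  reps <- 100
  Racc <- matrix(0, 2, 2)
  for (i in seq_len(reps)) {
    mp <- sample_mode_params(r, rep(1L, T), prior, L = 1, psi = psi,
                             H = diag(2))
    Racc <- Racc + mp$R
  }
  emp <- crossprod(psi - r) / T
  expect_lt(max(abs(Racc / reps - emp)) / max(emp), 0.05)
})

test_that("hyperparameter draws respect tight priors and Beta symmetry", {
  cfg_tight <- hdp_config(L = 4, a_gamma = 1e6, b_gamma = 1e6 / 5,
                          a_ak = 1e6, b_ak = 1e6 / 50,
                          c_rho = 25, d_rho = 1, n_sweeps = 10)
  set.seed(43)
  z <- rep(c(1L, 2L), each = 50)
  g <- numeric(300); ak <- numeric(300)
  for (i in 1:300) {
    h <- sample_hyperparameters(beta = rep(0.25, 4), z = z, cfg = cfg_tight,
                                gamma = 5, alpha_plus_kappa = 50, rho = 0.96)
    g[i] <- h$gamma; ak[i] <- h$alpha_plus_kappa
  }
  expect_lt(sd(g) / mean(g), 0.05)
  expect_lt(abs(mean(g) - 5) / 5, 0.05)
  expect_lt(sd(ak) / mean(ak), 0.05)
  # c = d: with no observed transitions the rho conditional is symmetric
  cfg_sym <- hdp_config(L = 4, c_rho = 3, d_rho = 3, n_sweeps = 10)
  set.seed(44)
  rhos <- replicate(2000, sample_hyperparameters(
    beta = rep(0.25, 4), cfg = cfg_sym, gamma = 1, alpha_plus_kappa = 1,
    rho = 0.5, counts = matrix(0L, 4, 4))$rho)
  expect_lt(abs(mean(rhos) - 0.5), 4 * sd(rhos) / sqrt(2000))
})

test_that("the concentration kernel targets the grid-evaluated density", {
  # fixed table statistics: K dishes out of m tables
  K <- 4; m <- 60; a <- 1; b <- 0.1
  kern <- stickyslds:::sample_dp_concentration
  set.seed(45)
  g <- 1
  n_iter <- 20000
  draws <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    g <- kern(g, a, b, m, K)
    draws[i] <- g
  }
  # independent oracle: 1D grid integration of the unnormalized density
  grid <- seq(0.005, 400, length.out = 60000)
  logw <- dgamma(grid, a, rate = b, log = TRUE) + K * log(grid) +
    lgamma(grid) - lgamma(grid + m)
  w <- exp(logw - max(logw)); w <- w / sum(w)
  mean_grid <- sum(grid * w)
  sd_grid <- sqrt(sum(grid^2 * w) - mean_grid^2)
  ess <- n_iter / 10  # conservative for autocorrelation
  expect_lt(abs(mean(draws) - mean_grid), 4 * sd_grid / sqrt(ess))
  expect_lt(abs(sd(draws) - sd_grid) / sd_grid, 0.2)
})

test_that("chains are exactly reproducible from the seed", {
  cfg <- fix_small_dgp(n_obs = 150, n_traj = 1, seed = 3)
  tr <- simulate_trajectory(cfg)
  prior <- build_prior_from_dgp(cfg, "exact")
  obs <- observation_model(diag(3), prior$S_R)
  hy <- hdp_config(n_sweeps = 60, seed = 9)
  ch1 <- run_mcmc(tr$psi, cfg$dt, obs, prior, hy, d = 3)
  ch2 <- run_mcmc(tr$psi, cfg$dt, obs, prior, hy, d = 3)
  expect_identical(ch1$z, ch2$z)
  expect_identical(ch1$loglik, ch2$loglik)
  expect_identical(ch1$hyper, ch2$hyper)
  # rho identity holds exactly at every sweep by construction of storage
  expect_true(all(ch1$hyper[, "rho"] > 0 & ch1$hyper[, "rho"] < 1))
  # joint log-density is finite throughout and does not diverge
  expect_true(all(is.finite(ch1$joint_logdensity)))
  rm1 <- cumsum(ch1$joint_logdensity) / seq_along(ch1$joint_logdensity)
  expect_lt(abs(rm1[60] - rm1[40]) / abs(rm1[60]), 0.1)
})

test_that("single-state data is identified as one dominant mode", {
  # localization noise 10 nm: well below the per-step displacement, so a
  # single mode should own essentially every time point of every sweep
  base <- cont_params(rbar = c(0, 0, 0), A = diag(c(1, 1, 1e-6)),
                      D = diag(0.01, 3), R = diag(0.01^2, 3))
  cfg <- dgp_config(base = base, n_obs = 400, n_traj = 1, seed = 8,
                    regions = region_rules(C1 = -1e6, C2 = 1e6, y_alt = 1e5,
                                           rbar_alt = c(0, 1e5 + 1, 0)))
  tr <- simulate_trajectory(cfg)
  expect_true(all(tr$s == 1L))
  prior <- build_prior_from_dgp(cfg, "exact")
  obs <- observation_model(diag(3), prior$S_R)
  ch <- run_mcmc(tr$psi, cfg$dt, obs, prior,
                 hdp_config(n_sweeps = 400, seed = 10), d = 3)
  keep <- 201:400
  frac_dom <- mean(vapply(keep, function(s) {
    occ <- tabulate(ch$z[s, ], 10)
    max(occ) / 400 > 0.99
  }, logical(1)))
  expect_gte(frac_dom, 0.95)
})

test_that("the weak-limit truncation level barely affects the segmentation", {
  cfg <- fix_djump_cfg(n_obs = 800, seed = 6)
  tr <- simulate_trajectory(cfg)
  psi2 <- tr$psi[, 1:2]
  prior <- build_prior_from_dgp(cfg, "exact", state_dim = 2)
  obs <- observation_model(diag(2), prior$S_R)
  hm <- sapply(c(2L, 10L), function(L) {
    ch <- run_mcmc(psi2, cfg$dt, obs, prior,
                   hdp_config(L = L, n_sweeps = 500, seed = 12), d = 2)
    keep <- seq(301, 500, by = 10)
    mean(vapply(keep, function(s) average_hamming(tr$s, ch$z[s, ])$hamming,
                numeric(1)))
  })
  expect_lt(abs(hm[1] - hm[2]), 0.03)
})

test_that("point estimates aggregate aligned sweeps correctly", {
  mk_chain <- function(zmat, L = 4) {
    structure(list(z = zmat,
                   cfg = hdp_config(L = L, n_sweeps = nrow(zmat),
                                    burn_in = 0, seed = 1)),
              class = "hdpslds_chain")
  }
  # constant chain -> the estimate is that sweep
  z <- rep(c(1L, 2L, 1L), c(3, 4, 3))
  ch <- mk_chain(rbind(z, z, z))
  pe <- point_estimate(ch, burn_in = 0)
  expect_equal(pe$labels, z)
  expect_equal(rowSums(pe$prob), rep(1, 10))
  # label-permuted copies align to zero disagreement
  zp <- ifelse(z == 1L, 3L, 4L)
  chp <- mk_chain(rbind(z, zp, z, zp))
  pep <- point_estimate(chp, burn_in = 0)
  expect_equal(average_hamming(z, pep$labels)$hamming, 0)
  expect_true(all(apply(pep$prob, 1, max) == 1))
  # known 60/40 marginal at one time point
  rows <- do.call(rbind, c(replicate(6, z, simplify = FALSE),
                           replicate(4, ifelse(seq_along(z) == 5, 1L, z),
                                     simplify = FALSE)))
  pem <- point_estimate(mk_chain(rows), burn_in = 0)
  expect_equal(pem$prob[5, 1], 0.4, tolerance = 1e-12)
  expect_equal(pem$prob[5, 2], 0.6, tolerance = 1e-12)
  # empty window errors
  expect_error(point_estimate(mk_chain(rbind(z, z)), burn_in = 2), "burn-in")
})

test_that("prior-only transition draws reproduce GEM/Dirichlet moments", {
  L <- 5; gamma <- 3; ak <- 10; rho <- 0.3
  set.seed(46)
  reps <- 3000
  beta_acc <- numeric(L)
  for (i in seq_len(reps)) {
    out <- sample_transition_params(beta = rep(1 / L, L), gamma = gamma,
                                    alpha_plus_kappa = ak, rho = rho, L = L,
                                    counts = matrix(0, L, L))
    beta_acc <- beta_acc + out$beta
  }
  # symmetric Dirichlet(gamma/L): per-component mean 1/L
  expect_lt(max(abs(beta_acc / reps - 1 / L)), 0.02)
})
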