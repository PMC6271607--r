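# shared fixtures for the test suite (all built in code, no files)

# small stable 3D continuous state, benchmark-like scales
fix_cont3 <- function() {
  cont_params(rbar = c(0.1, -0.2, 0.05),
              A = diag(c(1, 2, 0.5)),
              D = diag(c(0.01, 0.02, 0.015)),
              R = diag(9e-4, 3))
}

fix_disc2 <- function() {
  disc_params(mu = c(0.1, -0.05),
              F = matrix(c(0.9, 0.1, 0, 0.8), 2, 2),
              Sigma = matrix(c(0.02, 0.005, 0.005, 0.01), 2, 2),
              R = diag(0.003, 2), dt = 0.05)
}

# log density of N(m, S) at x, written independently of the package
log_dmvn <- function(x, m, S) {
  d <- length(x)
  ch <- chol(S)
  a <- backsolve(ch, x - m, transpose = TRUE)
  -0.5 * (d * log(2 * pi) + sum(a^2)) - sum(log(diag(ch)))
}

# dense joint-Gaussian oracle for a shared-parameter LDS: returns the
# log-likelihood of psi and the conditional (smoothed) state means
dense_lds_oracle <- function(psi, dp, H, m0, P0) {
  T <- nrow(psi); d <- length(dp$mu); p <- ncol(psi)
  means <- vector("list", T); means[[1]] <- m0
  for (t in 2:T) means[[t]] <- dp$mu + dp$F %*% means[[t - 1]]
  C <- array(0, c(T, d, T, d)); C[1, , 1, ] <- P0
  for (t in 2:T) {
    for (s in 1:(t - 1)) {
      C[t, , s, ] <- dp$F %*% C[t - 1, , s, ]
      C[s, , t, ] <- t(C[t, , s, ])
    }
    C[t, , t, ] <- dp$F %*% C[t - 1, , t - 1, ] %*% t(dp$F) + dp$Sigma
  }
  bigC <- matrix(0, T * d, T * d); bigm <- numeric(T * d)
  for (t in 1:T) {
    bigm[(t - 1) * d + 1:d] <- means[[t]]
    for (s in 1:T)
      bigC[(t - 1) * d + 1:d, (s - 1) * d + 1:d] <- C[t, , s, ]
  }
  bigH <- kronecker(diag(T), H)
  S <- bigH %*% bigC %*% t(bigH) + kronecker(diag(T), dp$R)
  x <- as.numeric(t(psi))
  mObs <- as.numeric(bigH %*% bigm)
  ll <- log_dmvn(x, mObs, S)
  condm <- bigm + bigC %*% t(bigH) %*% solve(S, x - mObs)
  condC <- bigC - bigC %*% t(bigH) %*% solve(S, bigH %*% bigC)
  list(loglik = ll,
       smoothed_means = matrix(condm, T, d, byrow = TRUE),
       smoothed_cov = condC)
}

# brute-force best label alignment over all full injective maps (oracle
# for align_labels on small label sets)
brute_best_match <- function(true_seq, est_seq) {
  tl <- sort(unique(true_seq)); el <- sort(unique(est_seq))
  small <- if (length(el) <= length(tl)) el else tl
  big <- if (length(el) <= length(tl)) tl else el
  est_is_small <- length(el) <= length(tl)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  best <- 0
  for (pp in perms(big)) {
    sel <- pp[seq_along(small)]
    matched <- 0
    for (i in seq_along(small)) {
      if (est_is_small)
        matched <- matched + sum(est_seq == small[i] & true_seq == sel[i])
      else
        matched <- matched + sum(true_seq == small[i] & est_seq == sel[i])
    }
    best <- max(best, matched)
  }
  best
}

# tiny DGP for fast end-to-end runs
fix_small_dgp <- function(n_obs = 200, n_traj = 1, seed = 1, ...) {
  dgp_config(n_obs = n_obs, n_traj = n_traj, seed = seed, ...)
}

# markov-switching two-state diffusivity-jump configuration (states 1/2
# differ only in D by the factor 10); localization noise 10 nm
fix_djump_cfg <- function(n_obs = 1000, seed = 1) {
  base <- cont_params(rbar = c(0, 0, 0), A = diag(c(1, 1, 1e-6)),
                      D = diag(0.01, 3), R = diag(0.01^2, 3))
  dgp_config(base = base, n_obs = n_obs, n_traj = 1, seed = seed,
             switching_mode = "markov", markov_states = c(1L, 2L))
}
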