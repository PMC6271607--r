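test_that("region classification follows the documented rules and precedence", {
  rules <- region_rules(C1 = -0.3, C2 = 0.3, y_alt = -0.3,
                        rbar_alt = c(0.3, 0, -0.3))
  # z < C1 and y < C2 (not state 3) -> 2
  expect_equal(classify_region(c(0, 0, -0.5), rules), 2L)
  # z > 0 and y > C2 -> 3
  expect_equal(classify_region(c(0, 0.5, 0.1), rules), 3L)
  # z < 0 and y_alt < y < C2 -> 4
  expect_equal(classify_region(c(0, 0, -0.1), rules), 4L)
  # fall-through: z > 0, y < y_alt -> base state
  expect_equal(classify_region(c(0, -0.5, 0.1), rules), 1L)
  # overlap of 2 and 4 (z < C1 < 0 and y in the state-4 band): 2 wins
  expect_equal(classify_region(c(0, 0, -0.9), rules), 2L)
  # vectorized form agrees with scalar calls
  pts <- rbind(c(0, 0, -0.5), c(0, 0.5, 0.1), c(0, 0, -0.1), c(0, -0.5, 0.1))
  expect_equal(classify_region(pts, rules),
               vapply(1:4, function(i) classify_region(pts[i, ], rules),
                      integer(1)))
})

test_that("noise-free particle at the fixed point never moves", {
  base <- cont_params(rbar = c(1, 2, 3), B = diag(1, 3),
                      D = diag(0, 3), R = diag(0, 3))
  # regions placed so the fixed point lies in the base region
  cfg <- dgp_config(base = base, n_obs = 50, n_traj = 1, seed = 1,
                    regions = region_rules(C1 = -100, C2 = 100, y_alt = 99,
                                           rbar_alt = c(0, 99.5, 0)))
  tr <- simulate_trajectory(cfg)
  expect_true(all(abs(tr$r - rep(c(1, 2, 3), each = 50)) < 1e-12))
  expect_true(all(tr$s == 3L | tr$s == 1L))  # depends on region of (1,2,3)
  expect_equal(tr$psi, tr$r %*% t(tr$H))
})

test_that("ensembles are bitwise reproducible and labels are recomputable", {
  cfg <- fix_small_dgp(n_obs = 300, n_traj = 3, seed = 42)
  e1 <- simulate_ensemble(cfg)
  e2 <- simulate_ensemble(cfg)
  expect_identical(e1, e2)
  for (tr in e1)
    expect_equal(classify_region(tr$r, cfg$regions), tr$s)
})

test_that("unreachable regions yield single-state trajectories", {
  cfg <- dgp_config(n_obs = 200, n_traj = 4, seed = 3,
                    regions = region_rules(C1 = -1e6, C2 = 1e6, y_alt = 1e5,
                                           rbar_alt = c(0, 1e5 + 1, 0)))
  ens <- simulate_ensemble(cfg)
  expect_true(all(attr(ens, "realized_states") == 1L))
  expect_true(all(vapply(ens, function(tr) all(tr$s == 1L), logical(1))))
})

test_that("benchmark ensembles regenerate single-state draws when asked", {
  cfg <- fix_small_dgp(n_obs = 500, n_traj = 8, seed = 1)
  ens <- simulate_ensemble(cfg, min_states = 2)
  expect_true(all(attr(ens, "realized_states") >= 2))
})

test_that("pure-diffusion mean-squared displacement grows as 2 D lag dt", {
  D0 <- 0.01; dt <- 1 / 22
  base <- cont_params(rbar = c(0, 0, 0), B = matrix(0, 3, 3),
                      D = diag(D0, 3), R = diag(0, 3))
  cfg <- dgp_config(base = base, n_obs = 80, n_traj = 300, seed = 5, dt = dt,
                    regions = region_rules(C1 = -1e6, C2 = 1e6, y_alt = 1e5,
                                           rbar_alt = c(0, 1e5 + 1, 0)))
  ens <- simulate_ensemble(cfg)
  for (lag in c(1, 5)) {
    disp2 <- unlist(lapply(ens, function(tr) {
      dx <- tr$r[-seq_len(lag), 1] - tr$r[seq_len(nrow(tr$r) - lag), 1]
      dx^2
    }))
    msd <- mean(disp2)
    se <- sd(disp2) / sqrt(length(disp2) / lag)  # conservative: overlapping lags
    expect_lt(abs(msd - 2 * D0 * lag * dt), 4 * se)
  }
})

test_that("confined single-state paths reach the Lyapunov stationary covariance", {
  base <- cont_params(rbar = c(0.2, 0, 0), A = diag(c(2, 2, 1)),
                      D = diag(0.01, 3), R = diag(0, 3))
  cfg <- dgp_config(base = base, n_obs = 2e4, n_traj = 1, seed = 9,
                    regions = region_rules(C1 = -1e6, C2 = 1e6, y_alt = 1e5,
                                           rbar_alt = c(0, 1e5 + 1, 0)))
  tr <- simulate_trajectory(cfg)
  sm <- stationary_moments(ou_discretize(base, cfg$dt))
  emp <- cov(tr$r)
  expect_lt(max(abs(emp - sm$cov)) / max(sm$cov), 0.1)
  expect_lt(max(abs(colMeans(tr$r) - sm$mean)), 4 * sqrt(max(sm$cov) / 500))
})

test_that("measurement residuals have mean zero and covariance R", {
  cfg <- fix_small_dgp(n_obs = 200, n_traj = 50, seed = 17)
  ens <- simulate_ensemble(cfg)
  resid <- do.call(rbind, lapply(ens, function(tr) tr$psi - tr$r))
  N <- nrow(resid)
  Rtrue <- cfg$base$R
  expect_lt(max(abs(colMeans(resid))), 4 * sqrt(max(diag(Rtrue)) / N))
  expect_lt(max(abs(cov(resid) - Rtrue)), 4 * max(diag(Rtrue)) / sqrt(N))
})

test_that("the observation selector affects psi only, never the path or labels", {
  cfg <- fix_small_dgp(n_obs = 150, n_traj = 1, seed = 23)
  tr3 <- simulate_trajectory(cfg, H = diag(3))
  tr2 <- simulate_trajectory(cfg, H = cbind(diag(2), 0))
  expect_identical(tr3$r, tr2$r)
  expect_identical(tr3$s, tr2$s)
  expect_equal(ncol(tr2$psi), 2)
})

test_that("markov switching mode produces a label chain independent of position", {
  cfg <- fix_djump_cfg(n_obs = 2000, seed = 2)
  tr <- simulate_trajectory(cfg)
  expect_true(all(tr$s %in% c(1L, 2L)))
  expect_gt(length(unique(tr$s)), 1)
  # sticky chain: far fewer switches than a fair coin would give
  expect_lt(sum(diff(tr$s) != 0), 100)
})

test_that("DGP configurations round-trip through YAML and reproduce ensembles", {
  cfg <- fix_small_dgp(n_obs = 120, n_traj = 2, seed = 13)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_dgp_config(cfg, f)
  back <- read_dgp_config(f)
  expect_equal(back$base$D, cfg$base$D, tolerance = 1e-12)
  expect_equal(back$regions$C1, cfg$regions$C1)
  # the YAML stores 15 significant digits, so the restored run matches to
  # numerical precision (labels exactly, positions to ~1e-12)
  e1 <- simulate_ensemble(back); e2 <- simulate_ensemble(cfg)
  for (i in seq_along(e1)) {
    expect_identical(e1[[i]]$s, e2[[i]]$s)
    expect_lt(max(abs(e1[[i]]$r - e2[[i]]$r)), 1e-9)
    expect_lt(max(abs(e1[[i]]$psi - e2[[i]]$psi)), 1e-9)
  }
})

test_that("trajectory CSV round-trips and rejects skipped frames", {
  cfg <- fix_small_dgp(n_obs = 40, n_traj = 1, seed = 4)
  tr <- simulate_trajectory(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- read_trajectory_csv(f)
  expect_equal(back$psi, tr$psi, ignore_attr = TRUE)
  expect_equal(back$r, tr$r, ignore_attr = TRUE)
  expect_equal(back$s, tr$s)
  expect_equal(back$dt, tr$dt, tolerance = 1e-9)
  # drop a frame -> explicit rejection naming the row
  df <- utils::read.csv(f)
  utils::write.csv(df[-10, ], f, row.names = FALSE)
  expect_error(read_trajectory_csv(f), "row")
  # 2-column file -> 2D trajectory without z
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(list(t = tr$t, psi = tr$psi[, 1:2]), f2)
  back2 <- read_trajectory_csv(f2)
  expect_equal(ncol(back2$psi), 2)
  expect_null(back2$r)
  # missing required column -> schema error
  df <- utils::read.csv(f2)
  utils::write.csv(df[, setdiff(names(df), "psi_y")], f2, row.names = FALSE)
  expect_error(read_trajectory_csv(f2), "psi_y")
})
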