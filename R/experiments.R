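#' Build the base measure from the data-generating process
#'
#' Benchmark prior calibration: the inverse-Wishart prior means of `Sigma`
#' and `R` are set to the discretized base-state values of the DGP
#' ("Baseline"); the misspecified variants divide the known DGP average of
#' the relevant component by 4 (`D_div4` scales the process-noise mean,
#' `R_div4` the measurement-noise mean) while leaving the other untouched.
#'
#' @param dgp a [dgp_config()].
#' @param mode one of `"exact"`, `"D_div4"`, `"R_div4"`.
#' @param state_dim 3 for the full model, 2 for the naive-2D model (uses
#'   the x/y sub-blocks).
#' @param obs_dim observed dimension (2 for the naive-2D and hidden-z
#'   observation models); defaults to `state_dim`.
#' @return an [slds_prior()].
#' @export
build_prior_from_dgp <- function(dgp, mode = c("exact", "D_div4", "R_div4"),
                                 state_dim = 3, obs_dim = state_dim) {
  mode <- match.arg(mode)
  stopifnot(inherits(dgp, "dgp_config"), state_dim %in% c(2, 3),
            obs_dim <= state_dim)
  disc <- ou_discretize(dgp$base, dgp$dt)
  idx <- seq_len(state_dim)
  S_Sigma <- disc$Sigma[idx, idx, drop = FALSE]
  S_R <- dgp$base$R[seq_len(obs_dim), seq_len(obs_dim), drop = FALSE]
  if (mode == "D_div4") S_Sigma <- S_Sigma / 4
  if (mode == "R_div4") S_R <- S_R / 4
  if (min(diag(S_R)) <= 0)
    stop("degenerate base measure: the DGP has zero measurement noise, ",
         "so an inverse-Wishart prior mean for R cannot be formed")
  slds_prior(S_Sigma = S_Sigma, S_R = S_R)
}

#' Scenario configuration for the benchmark grid
#'
#' A named analysis condition over a fixed simulated ensemble: which base
#' measure to use (matched or misspecified), which observation/state
#' dimensionality, and which concentration hyperpriors.
#'
#' @param name one of `"baseline"`, `"D_div4"`, `"R_div4"`,
#'   `"gamma_b_sweep"`, `"rho_c_sweep"`, `"naive_2d"`, `"hidden_z"`, or a
#'   free-form custom name.
#' @param dgp a [dgp_config()] describing the shared ensemble.
#' @param n_sweeps,burn_in,L sampler size parameters.
#' @param gamma_b,rho_c concentration knobs (see
#'   [concentration_scenario()]).
#' @param value sweep value for `gamma_b_sweep` / `rho_c_sweep` scenarios.
#' @param min_states benchmark ensembles contain trajectories mixing two
#'   to four states (default 2; see [simulate_ensemble()]).
#' @param seed sampler seed offset.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(name = "baseline", dgp = dgp_config(),
                            n_sweeps = 2000, burn_in = floor(n_sweeps / 2),
                            L = 10, gamma_b = 0.01, rho_c = 25,
                            value = NULL, min_states = 2, seed = 100) {
  prior_mode <- switch(name, D_div4 = "D_div4", R_div4 = "R_div4", "exact")
  state_dim <- switch(name, naive_2d = 2L, 3L)
  obs_dim <- switch(name, naive_2d = 2L, hidden_z = 2L, 3L)
  if (identical(name, "gamma_b_sweep")) {
    stopifnot(!is.null(value)); gamma_b <- value
  }
  if (identical(name, "rho_c_sweep")) {
    stopifnot(!is.null(value)); rho_c <- value
  }
  structure(list(name = name, dgp = dgp, n_sweeps = as.integer(n_sweeps),
                 burn_in = as.integer(burn_in), L = as.integer(L),
                 gamma_b = gamma_b, rho_c = rho_c, value = value,
                 prior_mode = prior_mode, state_dim = state_dim,
                 obs_dim = obs_dim, min_states = as.integer(min_states),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Run one benchmark scenario over an ensemble
#'
#' Simulates (or reuses) the ensemble defined by `sc$dgp`, fits the sticky
#' HDP-SLDS to every trajectory under the scenario's prior and observation
#' model, scores each segmentation against the known truth by
#' label-aligned Hamming distance, and returns per-trajectory results plus
#' the ensemble summary and conditional state-assignment matrix. All
#' scenarios built on the same `dgp` seed consume the identical
#' trajectories (the ensemble is regenerated deterministically and its
#' hash recorded).
#'
#' @param sc a [scenario_config()].
#' @param ensemble optional pre-simulated ensemble (from
#'   [simulate_ensemble()] with the same `dgp`) to guarantee sharing
#'   across scenarios without re-simulation.
#' @param verbose print one line per trajectory.
#' @return object of class `scenario_report`: list with `name`, `results`
#'   (per-trajectory [average_hamming()] objects), `summary`
#'   ([ensemble_summary()]), `conditional` (the assignment matrix),
#'   `failures`, `ensemble_hash`, and the configuration.
#' @export
run_scenario <- function(sc, ensemble = NULL, verbose = FALSE) {
  stopifnot(inherits(sc, "scenario_config"))
  if (is.null(ensemble))
    ensemble <- simulate_ensemble(sc$dgp, min_states = sc$min_states)
  ens_hash <- hash_object(lapply(ensemble, function(tr) tr$psi))
  prior <- build_prior_from_dgp(sc$dgp, mode = sc$prior_mode,
                                state_dim = sc$state_dim,
                                obs_dim = sc$obs_dim)
  results <- list(); truths <- list(); failures <- integer(0)
  for (i in seq_along(ensemble)) {
    tr <- ensemble[[i]]
    psi <- tr$psi[, seq_len(sc$obs_dim), drop = FALSE]
    hyper <- concentration_scenario(gamma_b = sc$gamma_b, rho_c = sc$rho_c,
                                    L = sc$L, n_sweeps = sc$n_sweeps,
                                    burn_in = sc$burn_in,
                                    seed = sc$seed + i)
    fit <- tryCatch(
      hdpslds(psi, dt = sc$dgp$dt, prior = prior, hyper = hyper,
              state_dim = sc$state_dim),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning("scenario ", sc$name, ": trajectory ", i, " failed (",
              conditionMessage(fit), "); excluded from the summary")
      failures <- c(failures, i)
      next
    }
    mr <- average_hamming(tr$s, fitted(fit))
    results[[length(results) + 1]] <- mr
    truths[[length(truths) + 1]] <- tr$s
    if (verbose)
      message(sprintf("  [%s] trajectory %d/%d: Hamming %.3f",
                      sc$name, i, length(ensemble), mr$hamming))
  }
  if (length(results) == 0) stop("all trajectories failed in scenario ", sc$name)
  summ <- if (length(results) >= 2) ensemble_summary(results) else
    list(mean = results[[1]]$hamming, se = NA_real_, sd = NA_real_, n = 1L,
         match_score = results[[1]]$match_score)
  cond <- conditional_assignment_matrix(results, truths)
  structure(list(name = sc$name, results = results, summary = summ,
                 conditional = cond, failures = failures,
                 ensemble_hash = ens_hash, config = sc,
                 version = as.character(utils::packageVersion("stickyslds"))),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("Scenario '%s': mean Hamming %.3f (se %.3f, sd %.3f) over %d trajectories\n",
              x$name, x$summary$mean, x$summary$se, x$summary$sd,
              x$summary$n))
  if (length(x$failures))
    cat("  failed trajectories:", paste(x$failures, collapse = ", "), "\n")
  invisible(x)
}

#' Comparison table across scenario reports
#'
#' @param reports list of [run_scenario()] reports (>= 1).
#' @return data frame with one row per scenario: `scenario`,
#'   `mean_hamming`, `se`, `sd`, `n`, `match_score`.
#' @export
summarize_tables <- function(reports) {
  if (length(reports) == 0) stop("no scenario reports supplied")
  rows <- lapply(reports, function(r) {
    stopifnot(inherits(r, "scenario_report"))
    data.frame(scenario = r$name, mean_hamming = r$summary$mean,
               se = r$summary$se, sd = r$summary$sd, n = r$summary$n,
               match_score = r$summary$match_score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
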