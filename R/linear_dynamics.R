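#' Continuous-time SDE parameters of one kinetic state
#'
#' A single hidden state is an overdamped-Langevin (multivariate
#' Ornstein-Uhlenbeck) diffusion
#' \deqn{dr_t = \Phi B (\bar r - r_t)\,dt + \sqrt{2 D}\,dB_t}
#' with fixed point `rbar`, confinement matrix `B` (the restoring force is
#' `B (rbar - r)`, i.e. force toward the fixed point), noise loading `C`
#' with diffusion matrix `D = C C'`, and mobility `Phi = D / kBT`. The
#' effective mean-reversion rate matrix is `A = Phi B` (units 1/time); its
#' eigenvalues set the corral radius / relaxation time of the state.
#' Measurements add Gaussian localization noise with covariance `R`.
#'
#' `kBT` is a pure scale (default 1 in simulation units, so `Phi = D`);
#' temperature never enters independently.
#'
#' @param rbar fixed-point position (length-d vector, e.g. micrometres).
#' @param B d x d confinement matrix. Alternatively supply `A`.
#' @param C d x d noise loading (length/sqrt(time)); `D = C C'`.
#'   Alternatively supply `D` and `C` is taken as its symmetric square root.
#' @param R observation-noise covariance (d_obs x d_obs, length^2).
#' @param kBT energy scale; default 1.
#' @param A optional mean-reversion rate matrix `Phi B`; if given, `B` is
#'   derived as `kBT * solve(D, A)`.
#' @param D optional diffusion matrix used instead of `C`.
#' @return an object of class `cont_params`.
#' @examples
#' p <- cont_params(rbar = c(0, 0), A = diag(2), D = 0.01 * diag(2),
#'                  R = 9e-4 * diag(2))
#' ou_discretize(p, dt = 0.05)
#' @export
cont_params <- function(rbar, B = NULL, C = NULL, R, kBT = 1,
                        A = NULL, D = NULL) {
  rbar <- as.numeric(rbar)
  d <- length(rbar)
  if (is.null(D)) {
    if (is.null(C)) stop("supply either C or D")
    C <- as_matrix(C, d, "C")
    D <- C %*% t(C)
  } else {
    D <- as_matrix(D, d, "D")
    check_psd(D, "D")
    C <- mat_sqrt(D)
  }
  if (is.null(B)) {
    if (is.null(A)) stop("supply either B or A")
    A <- as_matrix(A, d, "A")
    B <- kBT * solve(D, A)
  } else {
    B <- as_matrix(B, d, "B")
    A <- (D / kBT) %*% B
  }
  R <- as.matrix(R)
  check_psd(R, "R")
  ev <- eigen(A, only.values = TRUE)$values
  if (any(Re(ev) < -1e-12))
    stop("unstable state: Phi B has an eigenvalue with negative real part")
  structure(list(rbar = rbar, B = B, C = C, D = D, A = A, R = R, kBT = kBT),
            class = "cont_params")
}

#' Discrete-time state-space parameters of one kinetic state
#'
#' The discrete companion of [cont_params()]: positions evolve as
#' \deqn{r_{i+1} = \mu + F r_i + \eta_i, \quad \eta_i \sim N(0, \Sigma)}
#' \deqn{\psi_i = H r_i + \epsilon_i, \quad \epsilon_i \sim N(0, R)}
#' at a uniform sampling interval `dt`. When all eigenvalues of `F` lie
#' inside the unit circle the process is stationary with mean
#' `solve(I - F, mu)`. (Writing the stationary mean as `-solve(F) %*% mu`
#' corresponds to the alternative sign convention `r_{i+1} = mu - F r_i + ...`;
#' this package uses the `+F` convention throughout, under which the fixed
#' point is `(I - F)^{-1} mu`.)
#'
#' @param mu length-d drift vector (length units).
#' @param F d x d propagator (dimensionless).
#' @param Sigma d x d process-noise covariance (length^2).
#' @param R observation-noise covariance (length^2).
#' @param dt sampling interval (time units).
#' @return an object of class `disc_params`.
#' @export
disc_params <- function(mu, F, Sigma, R, dt) {
  mu <- as.numeric(mu)
  d <- length(mu)
  F <- as_matrix(F, d, "F")
  Sigma <- as_matrix(Sigma, d, "Sigma")
  check_psd(Sigma, "Sigma")
  R <- as.matrix(R)
  check_psd(R, "R")
  stopifnot(dt > 0)
  structure(list(mu = mu, F = F, Sigma = Sigma, R = R, dt = dt),
            class = "disc_params")
}

#' Exact discretization of an Ornstein-Uhlenbeck state
#'
#' Maps the continuous SDE parameterization to the discrete state-space
#' form at sampling interval `dt`, exactly: `F = expm(-A dt)`,
#' `mu = (I - F) rbar`, and `Sigma` is the finite-horizon Lyapunov integral
#' \deqn{\Sigma = \int_0^{dt} e^{-A s} (2D) e^{-A' s} ds}
#' computed by the van Loan block matrix-exponential construction (exact;
#' no quadrature tolerance). `R` and `dt` are carried through.
#'
#' @param cont a [cont_params()] object.
#' @param dt sampling interval, > 0.
#' @return a [disc_params()] object reproducing the SDE's one-step
#'   transition distribution.
#' @export
ou_discretize <- function(cont, dt) {
  stopifnot(inherits(cont, "cont_params"), dt > 0)
  d <- length(cont$rbar)
  A <- cont$A
  Q <- 2 * cont$D
  # van Loan blocks for drift -A: expm(dt * [[A, Q], [0, -A']]) =
  # [[E11, E12], [0, E22]] with F = E22', Sigma = F %*% E12
  M <- rbind(cbind(A, Q), cbind(matrix(0, d, d), -t(A))) * dt
  E <- expm_mat(M)
  if (!all(is.finite(E)))
    stop("non-finite matrix exponential while discretizing (matrix A = Phi B)")
  Fd <- t(E[(d + 1):(2 * d), (d + 1):(2 * d), drop = FALSE])
  Sg <- Fd %*% E[1:d, (d + 1):(2 * d), drop = FALSE]
  Sg <- (Sg + t(Sg)) / 2
  ev <- min(eigen(Sg, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-12 * max(1, sum(diag(Sg))))
    stop("discretized process covariance lost positive semidefiniteness (matrix Sigma)")
  mu <- as.numeric((diag(d) - Fd) %*% cont$rbar)
  disc_params(mu = mu, F = Fd, Sigma = Sg, R = cont$R, dt = dt)
}

#' Continuous embedding of a discrete state
#'
#' Inverse of [ou_discretize()]: recovers `(rbar, B, C/D)` from
#' `(mu, F, Sigma, dt)` via the real matrix logarithm `A = -logm(F)/dt`,
#' then inverts the Lyapunov integral for the diffusion matrix. Needed to
#' report physical diffusion coefficients and fixed points from fitted
#' discrete parameters.
#'
#' @param disc a [disc_params()] object; `F` must admit a real matrix
#'   logarithm (no eigenvalues on the closed negative real axis).
#' @param kBT energy scale passed to [cont_params()].
#' @return a [cont_params()] object; `ou_discretize(ou_continuize(x), x$dt)`
#'   recovers `x` up to numerical tolerance.
#' @export
ou_continuize <- function(disc, kBT = 1) {
  stopifnot(inherits(disc, "disc_params"))
  d <- length(disc$mu)
  A <- -.logm_arma(disc$F) / disc$dt
  # invert vec(Sigma) = K vec(2D), K = (M^-1)(expm(M dt) - I), M = (-A) (+) (-A)
  M <- kronecker(diag(d), -A) + kronecker(-A, diag(d))
  E <- expm_mat(M * disc$dt)
  nrmM <- norm(M, "F") * disc$dt
  if (nrmM < 1e-7) {
    # series limit: K ~ dt (I + M dt/2 + (M dt)^2/6)
    K <- disc$dt * (diag(d * d) + M * disc$dt / 2 + M %*% M * disc$dt^2 / 6)
  } else {
    K <- solve(M, E - diag(d * d))
  }
  Q <- matrix(solve(K, as.numeric(disc$Sigma)), d, d)
  D <- (Q + t(Q)) / 4  # Q = 2D, symmetrized
  # minimum-norm fixed point; unit-root axes (pure diffusion) have no
  # finite corral center, so their component is pinned at zero
  rbar <- as.numeric(pinv_solve(diag(d) - disc$F, disc$mu))
  cont_params(rbar = rbar, A = A, D = D, R = disc$R, kBT = kBT)
}

#' Stationary mean and covariance of a stable discrete state
#'
#' The stationary mean solves `m = mu + F m`, i.e. `m = (I - F)^{-1} mu`
#' (equal to the continuous fixed point `rbar`); the stationary covariance
#' solves the discrete Lyapunov equation `P = F P F' + Sigma`.
#'
#' @param disc a [disc_params()] object with all `|eig(F)| < 1`.
#' @return list with `mean` (length-d) and `cov` (d x d).
#' @export
stationary_moments <- function(disc) {
  stopifnot(inherits(disc, "disc_params"))
  d <- length(disc$mu)
  ev <- abs(eigen(disc$F, only.values = TRUE)$values)
  if (any(ev >= 1 - 1e-12))
    stop("F has a (near) unit-root eigenvalue: no stationary distribution; ",
         "treat this state as non-stationary (pure diffusion)")
  m <- as.numeric(solve(diag(d) - disc$F, disc$mu))
  P <- matrix(solve(diag(d * d) - kronecker(disc$F, disc$F),
                    as.numeric(disc$Sigma)), d, d)
  list(mean = m, cov = (P + t(P)) / 2)
}

#' @export
print.cont_params <- function(x, ...) {
  cat("Continuous OU state parameters (d =", length(x$rbar), ")\n")
  cat("  fixed point rbar:", format(x$rbar, digits = 4), "\n")
  cat("  relaxation rates eig(Phi B):",
      format(Re(eigen(x$A, only.values = TRUE)$values), digits = 4), "1/time\n")
  cat("  diffusion diag(D):", format(diag(x$D), digits = 4), "length^2/time\n")
  cat("  measurement noise diag(R):", format(diag(x$R), digits = 4), "\n")
  invisible(x)
}

#' @export
print.disc_params <- function(x, ...) {
  cat("Discrete SLDS state parameters (d =", length(x$mu),
      ", dt =", x$dt, ")\n")
  cat("  |eig(F)|:",
      format(abs(eigen(x$F, only.values = TRUE)$values), digits = 4), "\n")
  cat("  diag(Sigma):", format(diag(x$Sigma), digits = 4), "\n")
  invisible(x)
}

#' Serialize / restore state parameters through a YAML config
#'
#' Plain-text round trip for parameter sets (nested keys `rbar`, `B` or
#' `D`, `C`, `R`, `kBT`; matrices as row-major lists).
#'
#' @param x a [cont_params()] object.
#' @param path file path to write to / read from.
#' @return `read_cont_params()` returns a [cont_params()] object.
#' @export
write_cont_params <- function(x, path) {
  stopifnot(inherits(x, "cont_params"))
  obj <- list(rbar = as.numeric(x$rbar),
              D = mat_to_rows(x$D),
              B = mat_to_rows(x$B),
              R = mat_to_rows(x$R),
              kBT = x$kBT)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_cont_params
#' @export
read_cont_params <- function(path) {
  obj <- yaml::read_yaml(path)
  cont_params(rbar = as.numeric(obj$rbar),
              D = rows_to_mat(obj$D),
              B = rows_to_mat(obj$B),
              R = rows_to_mat(obj$R),
              kBT = if (is.null(obj$kBT)) 1 else obj$kBT)
}

# ---- internal helpers -------------------------------------------------------

as_matrix <- function(M, d, name) {
  M <- as.matrix(M)
  if (length(M) == 1 && d > 1) M <- diag(as.numeric(M), d)
  if (!all(dim(M) == c(d, d)))
    stop(sprintf("%s must be %d x %d", name, d, d))
  M
}

check_psd <- function(M, name, tol = 1e-10) {
  if (max(abs(M - t(M))) > tol * max(1, max(abs(M))))
    stop(sprintf("%s must be symmetric", name))
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev))))
    stop(sprintf("%s must be positive semidefinite", name))
  invisible(TRUE)
}

mat_sqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = length(e$values)) %*%
    t(e$vectors)
}

expm_mat <- function(M) as.matrix(Matrix::expm(Matrix::Matrix(M)))

pinv_solve <- function(A, b, tol = 1e-12) {
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d, 1e-300)
  if (!any(keep)) return(rep(0, ncol(A)))
  sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep])
}

mat_to_rows <- function(M) lapply(seq_len(nrow(M)), function(i) as.numeric(M[i, ]))
rows_to_mat <- function(rows) do.call(rbind, lapply(rows, as.numeric))
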