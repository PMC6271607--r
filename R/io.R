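#' Read a trajectory from CSV
#'
#' The on-disk dialect is comma-separated with a header row, '.' decimal,
#' UTF-8, coordinates in physical units (micrometres, never pixels) and
#' the time stamp stored explicitly. Required columns: `frame`, `t`, and
#' at least `psi_x`, `psi_y` (optionally `psi_z`); truth columns `x`, `y`,
#' `z`, `state` are attached when present. Uniform sampling is verified:
#' the maximum deviation of the time steps must be below `1e-6 * dt`.
#'
#' @param path CSV file path.
#' @return a `sim_trajectory`-like list with `t`, `psi`, `dt`, and (when
#'   present) `r` and `s`.
#' @examples
#' f <- system.file("extdata", "example_trajectory.csv",
#'                  package = "stickyslds")
#' tr <- read_trajectory_csv(f)
#' str(tr$psi)
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("frame", "t", "psi_x", "psi_y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trajectory CSV schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  dts <- diff(df$t)
  dt <- stats::median(dts)
  bad <- which(abs(dts - dt) > 1e-6 * dt)
  if (length(bad))
    stop("non-uniform time stamps (skipped frame?) at row(s) ",
         paste(utils::head(bad + 1, 5), collapse = ", "))
  psi_cols <- intersect(c("psi_x", "psi_y", "psi_z"), names(df))
  psi <- as.matrix(df[, psi_cols, drop = FALSE])
  out <- list(t = df$t, psi = psi, dt = dt)
  truth_cols <- intersect(c("x", "y", "z"), names(df))
  if (length(truth_cols) > 0) out$r <- as.matrix(df[, truth_cols, drop = FALSE])
  if ("state" %in% names(df)) out$s <- as.integer(df$state)
  class(out) <- "sim_trajectory"
  out
}

#' Write a trajectory to CSV
#'
#' @param tr a [simulate_trajectory()] result (or compatible list).
#' @param path output file path.
#' @param truth include the true positions and labels (default TRUE when
#'   available).
#' @return the path, invisibly.
#' @export
write_trajectory_csv <- function(tr, path, truth = !is.null(tr$r)) {
  psi <- as.matrix(tr$psi)
  df <- data.frame(frame = seq_along(tr$t) - 1L, t = tr$t)
  ax <- c("psi_x", "psi_y", "psi_z")[seq_len(ncol(psi))]
  df[ax] <- psi
  if (truth && !is.null(tr$r)) {
    df[c("x", "y", "z")[seq_len(ncol(tr$r))]] <- tr$r
    if (!is.null(tr$s)) df$state <- tr$s
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Captures everything needed to re-run a stage bit-identically: a config
#' snapshot, the seeds, the package version, a timestamp and hashes of the
#' input/output files.
#'
#' @param config list (or config object) snapshotted into the manifest.
#' @param seeds named list/vector of seeds used.
#' @param files character vector of file paths to hash (existing files).
#' @return an object of class `run_manifest`.
#' @export
run_manifest <- function(config = list(), seeds = list(), files = character(0)) {
  files <- files[file.exists(files)]
  hashes <- if (length(files)) tools::md5sum(files) else character(0)
  structure(list(config = config, seeds = seeds,
                 package_version = as.character(utils::packageVersion("stickyslds")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 file_hashes = as.list(hashes)),
            class = "run_manifest")
}

#' Write a scenario report, summary table and manifest to a directory
#'
#' Deterministic file naming; each file is written to a temporary name and
#' atomically renamed, so partial failures never leave half-written
#' tables. Writes `scores_<name>.csv` (tidy per-trajectory scores),
#' `summary_<name>.json`, and `manifest_<name>.json`.
#'
#' @param report a [run_scenario()] report.
#' @param out_dir output directory (created if missing; an unwritable
#'   location errors before anything is computed).
#' @param manifest optional [run_manifest()]; a minimal one is built when
#'   omitted.
#' @return named character vector of the files written.
#' @export
write_outputs <- function(report, out_dir, manifest = NULL) {
  stopifnot(inherits(report, "scenario_report"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) },
                 error = function(e) FALSE)
  if (!isTRUE(ok)) stop("output directory is not writable: ", out_dir)
  unlink(probe)

  scores <- data.frame(
    trajectory_id = seq_along(report$results),
    hamming = vapply(report$results, function(r) r$hamming, numeric(1)),
    match_score = vapply(report$results, function(r) r$match_score, numeric(1)))
  summary_obj <- c(report$summary,
                   list(scenario = report$name,
                        ensemble_hash = report$ensemble_hash,
                        n_failures = length(report$failures)))
  if (is.null(manifest))
    manifest <- run_manifest(config = unclass(report$config),
                             seeds = list(dgp = report$config$dgp$seed,
                                          sampler = report$config$seed))

  paths <- c(scores = file.path(out_dir, paste0("scores_", report$name, ".csv")),
             summary = file.path(out_dir, paste0("summary_", report$name, ".json")),
             manifest = file.path(out_dir, paste0("manifest_", report$name, ".json")))
  write_atomic(paths["scores"], function(p)
    utils::write.csv(scores, p, row.names = FALSE, quote = FALSE))
  write_atomic(paths["summary"], function(p)
    jsonlite::write_json(summary_obj, p, auto_unbox = TRUE, digits = NA))
  write_atomic(paths["manifest"], function(p)
    jsonlite::write_json(manifest_to_list(manifest), p, auto_unbox = TRUE,
                         digits = NA))
  paths
}

manifest_to_list <- function(m) {
  lapply(unclass(m), function(x) {
    if (is.list(x)) lapply(x, sanitize_json) else sanitize_json(x)
  })
}

sanitize_json <- function(x) {
  if (is.matrix(x)) return(apply(x, 1, as.numeric, simplify = FALSE))
  if (inherits(x, c("cont_params", "region_rules", "dgp_config")))
    return(lapply(unclass(x), sanitize_json))
  x
}

write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

# content hash used for the ensemble re-analysis contract
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Persist / restore a Gibbs chain
#'
#' Chains are runtime artifacts; they are stored as RDS.
#'
#' @param chain an `hdpslds_chain` (or any fitted object).
#' @param path file path.
#' @return `read_chain()` returns the restored object.
#' @export
write_chain <- function(chain, path) {
  saveRDS(chain, path)
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) readRDS(path)
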