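#' Optimal label alignment between two segmentations
#'
#' Inferred labels are arbitrary, so before counting mismatches each
#' estimated label is injectively mapped to a true label (or to a sink,
#' counted as mismatch) so as to minimize the total number of mismatched
#' time points. The assignment is exact (dynamic programming over label
#' subsets, equivalent to Hungarian assignment on the negated confusion
#' matrix), never greedy: greedy alignment can double-map estimated labels
#' and understate error. Surplus estimated labels count as errors wherever
#' they occur (no free merging), penalizing over-segmentation.
#'
#' @param true_seq integer vector of reference labels.
#' @param est_seq integer vector of estimated labels, same length.
#' @return named integer vector mapping each estimated label to a true
#'   label (`NA` for sink/unmatched), with attribute `matched` (the total
#'   number of agreeing time points under the map).
#' @export
align_labels <- function(true_seq, est_seq) {
  stopifnot(length(true_seq) == length(est_seq))
  tl <- sort(unique(true_seq))
  el <- sort(unique(est_seq))
  C <- matrix(0, length(el), length(tl), dimnames = list(el, tl))
  tab <- table(factor(est_seq, levels = el), factor(true_seq, levels = tl))
  C[] <- as.numeric(tab)
  sol <- max_weight_assignment(C)
  map <- rep(NA_integer_, length(el))
  names(map) <- el
  map[sol$rows] <- tl[sol$cols]
  attr(map, "matched") <- sol$weight
  map
}

# Exact maximum-weight partial assignment (rows may stay unmatched) by DP
# over column subsets; exponential only in min(nrow, ncol), which is the
# number of distinct labels (small).
max_weight_assignment <- function(C) {
  transposed <- FALSE
  if (ncol(C) > nrow(C)) { C <- t(C); transposed <- TRUE }
  nr <- nrow(C); nc <- ncol(C)
  if (nc > 20) stop("too many labels for exact assignment")
  nS <- bitwShiftL(1L, nc)
  Sall <- seq_len(nS) - 1L
  f <- rep(-Inf, nS); f[1] <- 0
  choice <- matrix(0L, nr, nS)  # 0 = row unmatched, c = matched column c
  for (i in seq_len(nr)) {
    g <- f                      # skip-row option (choice stays 0)
    ch <- integer(nS)
    for (cc in seq_len(nc)) {
      bit <- bitwShiftL(1L, cc - 1L)
      free <- bitwAnd(Sall, bit) == 0L
      S2 <- Sall[free] + bit
      cand <- f[free] + C[i, cc]
      upd <- cand > g[S2 + 1L]
      g[S2[upd] + 1L] <- cand[upd]
      ch[S2[upd] + 1L] <- cc
    }
    choice[i, ] <- ch
    f <- g
  }
  S <- which.max(f) - 1L
  weight <- f[S + 1L]
  rows <- integer(0); cols <- integer(0)
  for (i in rev(seq_len(nr))) {
    cc <- choice[i, S + 1L]
    if (cc > 0L) {
      rows <- c(i, rows); cols <- c(cc, cols)
      S <- bitwAnd(S, bitwNot(bitwShiftL(1L, cc - 1L)))
    }
  }
  if (transposed) list(rows = cols, cols = rows, weight = weight)
  else list(rows = rows, cols = cols, weight = weight)
}

#' Label-aligned average Hamming distance and Match Score
#'
#' After optimal alignment ([align_labels()]), the average Hamming distance
#' is the fraction of time points whose aligned estimated label differs
#' from the true label: 0 means the segmentation is perfect (up to
#' relabeling), 1 means not a single time point matches. The Match Score
#' is one minus the average Hamming distance.
#'
#' @inheritParams align_labels
#' @return object of class `match_result`: list with `hamming`,
#'   `match_score`, `permutation` (the label map), `confusion` (true x
#'   estimated raw count matrix) and `aligned` (the mapped estimated
#'   sequence, `NA` where unmatched).
#' @export
average_hamming <- function(true_seq, est_seq) {
  if (length(true_seq) != length(est_seq))
    stop("sequences must have equal length")
  T <- length(true_seq)
  map <- align_labels(true_seq, est_seq)
  aligned <- map[as.character(est_seq)]
  hamming <- 1 - attr(map, "matched") / T
  tl <- sort(unique(true_seq)); el <- sort(unique(est_seq))
  confusion <- table(true = factor(true_seq, levels = tl),
                     est = factor(est_seq, levels = el))
  structure(list(hamming = hamming, match_score = 1 - hamming,
                 permutation = map, confusion = unclass(confusion),
                 aligned = unname(aligned)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("Segmentation match: Hamming =", format(x$hamming, digits = 4),
      " Match Score =", format(x$match_score, digits = 4), "\n")
  invisible(x)
}

#' Conditional state-assignment matrix over an ensemble
#'
#' For each true state `k`, the empirical distribution of the aligned
#' estimated labels over all time points whose true state is `k`. Rows sum
#' to one; a true state absent from the ensemble yields a flagged all-`NA`
#' row (never silent NaN propagation). The column `"unmatched"` collects
#' estimated labels that the alignment mapped to the sink.
#'
#' @param results list of [average_hamming()] results.
#' @param true_seqs list of the matching true label sequences.
#' @param states which true states to report rows for (default 1..4).
#' @return matrix of conditional probabilities with attribute
#'   `undefined_states`.
#' @export
conditional_assignment_matrix <- function(results, true_seqs, states = 1:4) {
  stopifnot(length(results) == length(true_seqs), length(results) >= 1)
  all_true <- unlist(true_seqs)
  all_est <- unlist(lapply(results, function(r) r$aligned))
  cols <- sort(unique(all_true))
  out <- matrix(NA_real_, length(states), length(cols) + 1,
                dimnames = list(true = states,
                                est = c(cols, "unmatched")))
  undefined <- integer(0)
  for (i in seq_along(states)) {
    k <- states[i]
    sel <- all_true == k
    if (!any(sel)) { undefined <- c(undefined, k); next }
    a <- all_est[sel]
    cnt <- c(vapply(cols, function(cc) sum(a == cc, na.rm = TRUE), numeric(1)),
             sum(is.na(a)))
    out[i, ] <- cnt / sum(cnt)
  }
  attr(out, "undefined_states") <- undefined
  out
}

#' Ensemble summary of segmentation scores
#'
#' Mean per-trajectory Hamming distance with both the empirical standard
#' deviation and the standard error of the mean (`sd / sqrt(n)`); both are
#' reported because published tables are often ambiguous about which of
#' the two the parenthesized number is.
#'
#' @param results list of [average_hamming()] results (n >= 2).
#' @return list with `mean`, `se`, `sd`, `n`, `match_score`.
#' @export
ensemble_summary <- function(results) {
  if (length(results) < 2) stop("need at least two results")
  h <- vapply(results, function(r) r$hamming, numeric(1))
  list(mean = mean(h), se = stats::sd(h) / sqrt(length(h)),
       sd = stats::sd(h), n = length(h), match_score = 1 - mean(h))
}
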