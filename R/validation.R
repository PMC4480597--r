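#' Out-of-sample mean squared error
#'
#' Mean over nodes of the squared difference between predicted and reference
#' divergence dates, on the Myr scale.
#'
#' @param predicted,reference equal-length numeric vectors (Myr).
#' @return nonnegative scalar.
#' @export
mse_oos <- function(predicted, reference) {
  stopifnot(is.numeric(predicted), is.numeric(reference))
  if (length(predicted) != length(reference) || length(predicted) < 1)
    stop("'predicted' and 'reference' must be nonempty and of equal length",
         call. = FALSE)
  mean((predicted - reference)^2)
}

#' One leave-one-out cross-validation round
#'
#' For each node in turn, fits each requested model kind to the remaining
#' nodes under the time-prediction criterion ([fit_time_model()]), then
#' predicts the held-out node's age from its substitution count via
#' [invert_time()]. Every node serves exactly once as the test point; the
#' test node's `(t, s)` never enters its own fold's objective.
#'
#' @param points one resampled set: data.frame with `node_id`, `t_myr`, `s`.
#' @param kinds model kinds to validate (default all four).
#' @param n_starts optimisation starts per fold fit.
#' @param maxiter Levenberg-Marquardt iteration cap per fold fit.
#' @return data.frame with columns `node_id`, `kind`, `predicted_t_myr`,
#'   `reference_t_myr`; non-converged folds yield `NA` predictions.
#' @export
loocv_round <- function(points, kinds = c("VEX", "EX", "VPL", "PL"),
                        n_starts = 3, maxiter = 40) {
  stopifnot(is.data.frame(points))
  kinds <- match.arg(kinds, c("VEX", "EX", "VPL", "PL"), several.ok = TRUE)
  n <- nrow(points)
  pmax_free <- max(vapply(kinds, n_free_params, integer(1)))
  if (n - 1 < pmax_free + 1)
    stop(sprintf("LOOCV needs at least %d points for the requested kinds, got %d",
                 pmax_free + 2, n), call. = FALSE)
  out <- vector("list", n * length(kinds))
  idx <- 1L
  for (i in seq_len(n)) {
    train <- points[-i, , drop = FALSE]
    test <- points[i, , drop = FALSE]
    for (kd in kinds) {
      pred <- tryCatch({
        f <- fit_decay_model(train, kd, "LSE_t", n_starts = n_starts,
                             maxiter = maxiter)
        m <- f$params
        if (kd == "EX" && test$s >= m$alpha / m$beta) NA_real_
        else invert_time(m, test$s)
      }, error = function(e) NA_real_)
      out[[idx]] <- data.frame(node_id = test$node_id, kind = kd,
                               predicted_t_myr = pred,
                               reference_t_myr = test$t_myr,
                               stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  do.call(rbind, out)
}

#' Friedman test with mean ranks
#'
#' Ranks the model kinds within each round (rank 1 = smallest error, ties
#' averaged) and computes the tie-corrected Friedman chi-square statistic,
#' its p-value, and each kind's mean rank across rounds.
#'
#' @param score_matrix numeric matrix, rounds x kinds, of per-round scores
#'   (e.g. out-of-sample MSE); column names identify the kinds.
#' @return list with `mean_ranks` (named vector), `statistic`, `p_value`,
#'   `df`.
#' @export
friedman_mean_ranks <- function(score_matrix) {
  score_matrix <- as.matrix(score_matrix)
  nrounds <- nrow(score_matrix); k <- ncol(score_matrix)
  if (nrounds < 2 || k < 2)
    stop("need at least 2 rounds and 2 kinds", call. = FALSE)
  if (anyNA(score_matrix))
    stop("score matrix must be complete (drop incomplete rounds first)",
         call. = FALSE)
  ranks <- t(apply(score_matrix, 1, rank))
  mean_ranks <- colMeans(ranks)
  names(mean_ranks) <- colnames(score_matrix)
  rsum <- colSums(ranks)
  # tie correction: 1 - sum(ties^3 - ties) / (n k (k^2 - 1))
  tie_term <- sum(apply(score_matrix, 1, function(row) {
    tt <- table(row)
    sum(tt^3 - tt)
  }))
  denom_corr <- 1 - tie_term / (nrounds * k * (k^2 - 1))
  if (denom_corr <= 0) {
    statistic <- 0
    p <- 1
  } else {
    statistic <- (12 * sum((rsum - nrounds * (k + 1) / 2)^2) /
                    (nrounds * k * (k + 1))) / denom_corr
    p <- stats::pchisq(statistic, df = k - 1, lower.tail = FALSE)
  }
  list(mean_ranks = mean_ranks, statistic = statistic, p_value = p, df = k - 1)
}

#' Pairwise Wilcoxon signed-rank tests with Bonferroni correction
#'
#' Two-sided paired signed-rank test on per-round scores for every unordered
#' pair of kinds, with p-values multiplied by the number of pairs and capped
#' at 1. The exact null distribution is used for 25 or fewer rounds, the
#' normal approximation with continuity correction otherwise. A pair whose
#' per-round differences are all zero gets p = 1.
#'
#' @inheritParams friedman_mean_ranks
#' @return data.frame with columns `kind_a`, `kind_b`, `p_raw`,
#'   `p_adjusted`.
#' @export
pairwise_wilcoxon_bonferroni <- function(score_matrix) {
  score_matrix <- as.matrix(score_matrix)
  k <- ncol(score_matrix)
  if (k < 2) stop("need at least 2 kinds", call. = FALSE)
  kinds <- colnames(score_matrix)
  if (is.null(kinds)) kinds <- paste0("K", seq_len(k))
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  n <- nrow(score_matrix)
  exact <- n <= 25
  rows <- lapply(seq_len(n_pairs), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- score_matrix[, a] - score_matrix[, b]
    p <- if (all(d == 0)) 1 else {
      suppressWarnings(
        stats::wilcox.test(score_matrix[, a], score_matrix[, b],
                           paired = TRUE, exact = exact,
                           correct = TRUE)$p.value)
    }
    data.frame(kind_a = kinds[a], kind_b = kinds[b], p_raw = p,
               p_adjusted = min(p * n_pairs, 1), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full leave-one-out cross-validation over an ensemble
#'
#' Runs [loocv_round()] on every resampled set, scores each round and kind
#' by [mse_oos()], and compares the kinds with the Friedman test (rounds as
#' blocks, kinds as treatments) followed by pairwise Wilcoxon signed-rank
#' tests under the Bonferroni correction. Rounds with any missing prediction
#' for any kind are excluded from the rank tests and counted.
#'
#' @param rate_sets a `rate_sample_sets` from [assemble_rate_sets()] or a
#'   list of point data.frames; each set is one validation round.
#' @param kinds model kinds (default all four).
#' @param n_starts optimisation starts per fold fit.
#' @param maxiter Levenberg-Marquardt iteration cap per fold fit.
#' @return object of class `loocv_result`: `predictions` (long data.frame),
#'   `mse` (round x kind matrix), `mse_summary` (median and central 95%
#'   interval per kind), `mean_ranks`, `friedman_statistic`, `friedman_p`,
#'   `pairwise` (data.frame), `n_rounds_dropped`.
#' @export
run_loocv <- function(rate_sets, kinds = c("VEX", "EX", "VPL", "PL"),
                      n_starts = 3, maxiter = 40) {
  sets <- if (inherits(rate_sets, "rate_sample_sets")) rate_sets$sets else rate_sets
  if (!length(sets)) stop("empty set collection", call. = FALSE)
  kinds <- match.arg(kinds, c("VEX", "EX", "VPL", "PL"), several.ok = TRUE)
  preds <- vector("list", length(sets))
  mse <- matrix(NA_real_, length(sets), length(kinds),
                dimnames = list(NULL, kinds))
  for (r in seq_along(sets)) {
    pr <- loocv_round(sets[[r]], kinds = kinds, n_starts = n_starts,
                      maxiter = maxiter)
    pr$round_index <- r
    preds[[r]] <- pr
    for (kd in kinds) {
      sub <- pr[pr$kind == kd, ]
      if (!anyNA(sub$predicted_t_myr))
        mse[r, kd] <- mse_oos(sub$predicted_t_myr, sub$reference_t_myr)
    }
  }
  predictions <- do.call(rbind, preds)
  complete <- stats::complete.cases(mse)
  fr <- if (length(kinds) >= 2 && sum(complete) >= 2)
          friedman_mean_ranks(mse[complete, , drop = FALSE])
        else list(mean_ranks = setNames(rep(NA_real_, length(kinds)), kinds),
                  statistic = NA_real_, p_value = NA_real_)
  pw <- if (length(kinds) >= 2 && sum(complete) >= 6)
          pairwise_wilcoxon_bonferroni(mse[complete, , drop = FALSE])
        else NULL
  msum <- do.call(rbind, lapply(kinds, function(kd) {
    v <- mse[, kd]; v <- v[is.finite(v)]
    q <- stats::quantile(v, c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(kind = kd, median = q[1], lower95 = q[2], upper95 = q[3],
               n_rounds = length(v), stringsAsFactors = FALSE)
  }))
  structure(
    list(predictions = predictions, mse = mse, mse_summary = msum,
         mean_ranks = fr$mean_ranks, friedman_statistic = fr$statistic,
         friedman_p = fr$p_value, pairwise = pw,
         n_rounds_dropped = sum(!complete)),
    class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("LOOCV over %d rounds (%d dropped)\n", nrow(x$mse),
              x$n_rounds_dropped))
  cat("Median out-of-sample MSE (Myr scale):\n")
  print(x$mse_summary, row.names = FALSE)
  cat("Mean ranks (1 = best):\n")
  print(round(x$mean_ranks, 3))
  cat(sprintf("Friedman chi-square = %.3f, p = %.3g\n",
              x$friedman_statistic, x$friedman_p))
  invisible(x)
}
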