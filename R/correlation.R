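#' Log-log linear regression of average rate on timescale
#'
#' Ordinary least squares of `log10(rbar)` on `log10(t)`, the preliminary
#' description of rate decay: under a pure power law the relationship is
#' exactly affine with slope `-beta`.
#'
#' @param points data.frame with positive columns `t_myr` and `rbar` (one
#'   resampled set from [assemble_rate_sets()]), at least 3 rows.
#' @return list with `slope`, `intercept`, and `coefficient` (Pearson
#'   correlation of the log-transformed values).
#' @export
loglog_fit <- function(points) {
  stopifnot(is.data.frame(points))
  if (nrow(points) < 3)
    stop("log-log regression needs at least 3 points", call. = FALSE)
  t <- points$t_myr; r <- points$rbar
  if (any(!is.finite(t)) || any(!is.finite(r)) || any(t <= 0) || any(r <= 0))
    stop("all t and rbar values must be positive and finite", call. = FALSE)
  x <- log10(t); y <- log10(r)
  fit <- stats::lm.fit(cbind(1, x), y)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       coefficient = stats::cor(x, y))
}

#' Randomisation test for spurious rate-timescale correlation
#'
#' Because `rbar = s / t`, a negative correlation between `rbar` and `t` can
#' arise spuriously from the shared denominator even when `s` and `t` are
#' unrelated. This test re-pairs the observed `s` values with the `t` values
#' across nodes at random, recomputes the log-log correlation each time, and
#' compares the observed coefficient to the null distribution so built.
#' One-sided, lower tail (decay means more-negative coefficients), with the
#' add-one correction: `p = (1 + #[null <= observed]) / (1 + n_null)`.
#'
#' @param s per-node substitution values (one value per dated node).
#' @param t_myr per-node ages in Myr, same length and node order as `s`.
#' @param n_null number of null re-pairings (default 100).
#' @param seed optional integer seed.
#' @return list with `p_value`, `observed` (coefficient), `null`
#'   (numeric vector of length `n_null`), `n_null`.
#' @export
randomization_test <- function(s, t_myr, n_null = 100, seed = NULL) {
  stopifnot(is.numeric(s), is.numeric(t_myr))
  if (length(s) != length(t_myr))
    stop("'s' and 't_myr' must have matching length", call. = FALSE)
  if (length(s) < 3)
    stop("at least 3 nodes required", call. = FALSE)
  if (any(s <= 0) || any(t_myr <= 0))
    stop("all s and t values must be positive", call. = FALSE)
  if (!is.numeric(n_null) || n_null < 1)
    stop("'n_null' must be a positive count", call. = FALSE)
  n_null <- as.integer(n_null)
  if (!is.null(seed)) set.seed(seed)
  lt <- log10(t_myr)
  obs <- stats::cor(lt, log10(s / t_myr))
  null <- vapply(seq_len(n_null), function(i) {
    sp <- s[sample.int(length(s))]
    stats::cor(lt, log10(sp / t_myr))
  }, numeric(1))
  list(p_value = (1 + sum(null <= obs)) / (1 + n_null),
       observed = obs, null = null, n_null = n_null)
}

#' Ensemble correlation analysis over resampled sets
#'
#' Runs [loglog_fit()] and [randomization_test()] on each resampled
#' `(t, s, rbar)` set and summarises slopes, correlation coefficients and
#' randomisation p-values across the ensemble by median and central 95%
#' interval.
#'
#' @param rate_sets a `rate_sample_sets` object from [assemble_rate_sets()].
#' @param n_null null replicates per set (default 100).
#' @param seed optional integer seed.
#' @return list with `per_set` (data.frame: `set_index`, `slope`,
#'   `intercept`, `coefficient`, `p_value`) and `summary` (data.frame of
#'   median / 2.5% / 97.5% rows for each statistic).
#' @export
correlate_ensemble <- function(rate_sets, n_null = 100, seed = NULL) {
  stopifnot(inherits(rate_sets, "rate_sample_sets"))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_along(rate_sets$sets), function(i) {
    p <- rate_sets$sets[[i]]
    f <- loglog_fit(p)
    rt <- randomization_test(p$s, p$t_myr, n_null = n_null, seed = NULL)
    data.frame(set_index = i, slope = f$slope, intercept = f$intercept,
               coefficient = f$coefficient, p_value = rt$p_value)
  })
  per_set <- do.call(rbind, rows)
  qs <- function(v) stats::quantile(v, c(0.5, 0.025, 0.975), names = FALSE)
  summ <- data.frame(
    statistic = c("slope", "coefficient", "p_value"),
    median = c(qs(per_set$slope)[1], qs(per_set$coefficient)[1], qs(per_set$p_value)[1]),
    lower95 = c(qs(per_set$slope)[2], qs(per_set$coefficient)[2], qs(per_set$p_value)[2]),
    upper95 = c(qs(per_set$slope)[3], qs(per_set$coefficient)[3], qs(per_set$p_value)[3])
  )
  list(per_set = per_set, summary = summ)
}
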