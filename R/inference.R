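#' Calibration-node schemes
#'
#' The six three-node calibration schemes used to probe how the choice of
#' calibrating nodes propagates rate-decay bias into date inference. The
#' aggregated schemes use nodes of similar depth (shallow, intermediate,
#' deep); the dispersed schemes spread the three calibrators across depths.
#' Nodes "7" and "9" (whose host-derived reference dates conflict with their
#' model-recovered dates) never appear.
#'
#' @param name one of `"shallow"`, `"intermediate"`, `"deep"`,
#'   `"dispersed-I"`, `"dispersed-II"`, `"dispersed-III"`.
#' @return character vector of the 3 calibrating node ids.
#' @export
calibration_scheme <- function(name = c("shallow", "intermediate", "deep",
                                        "dispersed-I", "dispersed-II",
                                        "dispersed-III")) {
  name <- match.arg(name)
  switch(name,
    "shallow"       = c("1", "2", "3"),
    "intermediate"  = c("4", "5", "6"),
    "deep"          = c("8", "10", "11"),
    "dispersed-I"   = c("2", "5", "8"),
    "dispersed-II"  = c("1", "4", "10"),
    "dispersed-III" = c("3", "6", "11")
  )
}

#' Summarise the ensemble rate at a fixed timescale
#'
#' Evaluates each fitted model's average rate at timescale `t_years` and
#' summarises across the ensemble by median and central 95% interval.
#' The conventional short- and long-term reference timescales are 10 years
#' and 30 Myr (`3e7` years).
#'
#' @param fits list of `fit_result` objects (e.g. `fit_ensemble(...)$fits`).
#' @param t_years strictly positive timescale in years.
#' @return list with `median`, `lower95`, `upper95` (substitutions/site/year)
#'   and `n` (number of usable fits).
#' @export
rate_at_timescale <- function(fits, t_years) {
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("no fits supplied", call. = FALSE)
  if (!is.numeric(t_years) || length(t_years) != 1L || t_years <= 0)
    stop("'t_years' must be a single positive time", call. = FALSE)
  rates <- vapply(fits, function(f) {
    m <- convert_time_unit(f$params, "year")
    average_rate(m, t_years)
  }, numeric(1))
  q <- stats::quantile(rates, c(0.5, 0.025, 0.975), names = FALSE)
  list(median = q[1], lower95 = q[2], upper95 = q[3], n = length(rates))
}

#' Infer divergence dates from substitution draws
#'
#' Applies an ensemble of time-criterion fits to per-node substitution
#' draws: replicate `i` pairs the `i`-th fit with the `i`-th draw of each
#' node (co-sampling, preserving within-replicate coherence) and predicts
#' the node's age via [invert_time()]. EX-family replicates whose draw lies
#' beyond the saturation bound yield no prediction and are counted.
#'
#' @param fits list of `fit_result` objects fitted under `"LSE_t"`, one per
#'   replicate.
#' @param s_draws matrix (replicates x nodes, column names = node ids) or a
#'   named list of per-node draw vectors of length `length(fits)`.
#' @return data.frame of class `date_estimates`: `node_id`, `median_myr`,
#'   `lower95_myr`, `upper95_myr`, `n_replicates` (usable replicates).
#' @export
infer_dates <- function(fits, s_draws) {
  if (is.list(s_draws) && !is.matrix(s_draws))
    s_draws <- do.call(cbind, s_draws)
  s_draws <- as.matrix(s_draws)
  if (length(fits) != nrow(s_draws))
    stop("one fit per replicate row of 's_draws' required", call. = FALSE)
  bad_crit <- vapply(fits, function(f)
    !is.null(f) && !identical(f$criterion, "LSE_t"), logical(1))
  if (any(bad_crit))
    stop("date inference requires fits under the LSE_t criterion", call. = FALSE)
  ids <- colnames(s_draws)
  if (is.null(ids)) ids <- paste0("node", seq_len(ncol(s_draws)))
  rows <- lapply(seq_along(ids), function(j) {
    t_pred <- vapply(seq_along(fits), function(i) {
      f <- fits[[i]]
      if (is.null(f)) return(NA_real_)
      m <- f$params
      s <- s_draws[i, j]
      if (m$kind == "EX" && s >= m$alpha / m$beta) return(NA_real_)
      invert_time(m, s)
    }, numeric(1))
    t_ok <- t_pred[is.finite(t_pred)]
    if (!length(t_ok))
      return(data.frame(node_id = ids[j], median_myr = NA_real_,
                        lower95_myr = NA_real_, upper95_myr = NA_real_,
                        n_replicates = 0L, stringsAsFactors = FALSE))
    q <- stats::quantile(t_ok, c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(node_id = ids[j], median_myr = q[1], lower95_myr = q[2],
               upper95_myr = q[3], n_replicates = length(t_ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("date_estimates", class(out))
  out
}

#' Date inference under a three-node calibration scheme
#'
#' Per replicate set: fits the chosen model to the three calibrating nodes
#' only (time-prediction criterion), then predicts every other dated node's
#' age from its co-sampled substitution value. The non-calibrating nodes'
#' reference ages never enter the fit. Three-parameter kinds (VEX, VPL)
#' would interpolate three points exactly, leaving no error signal, and are
#' refused unless `allow_interpolating = TRUE`.
#'
#' @param dataset a [cospeciation_dataset()].
#' @param scheme a scheme name accepted by [calibration_scheme()], or a
#'   character vector of exactly 3 dated node ids.
#' @param n_sets number of resampled replicates.
#' @param seed optional integer seed.
#' @param kind model kind (default `"PL"`).
#' @param n_starts optimisation starts per replicate fit.
#' @param allow_interpolating permit 3-parameter kinds on 3 calibrators.
#' @return data.frame: `node_id`, `role` (`"calibrator"` or `"predicted"`),
#'   `median_myr`, `lower95_myr`, `upper95_myr`, `n_replicates`,
#'   `reference_t_myr` (the calibration median, for comparison).
#' @export
run_calibration_scheme <- function(dataset, scheme, n_sets = 1500, seed = NULL,
                                   kind = "PL", n_starts = 3,
                                   allow_interpolating = FALSE) {
  stopifnot(inherits(dataset, "cospeciation_dataset"))
  cal_ids <- if (length(scheme) == 1L) calibration_scheme(scheme)
             else as.character(scheme)
  if (length(cal_ids) != 3L)
    stop("a calibration scheme names exactly 3 nodes", call. = FALSE)
  kind <- match.arg(kind, c("VEX", "EX", "VPL", "PL"))
  if (n_free_params(kind) >= 3L && !allow_interpolating)
    stop(paste0(kind, " has 3 free parameters: fitting 3 calibrating points ",
                "interpolates exactly and carries no error signal ",
                "(set allow_interpolating = TRUE to override)"), call. = FALSE)
  nd <- dataset$nodes
  dated_ids <- nd$node_id[nd$dated]
  if (!all(cal_ids %in% dated_ids))
    stop("all calibrating nodes must be dated", call. = FALSE)
  rs <- assemble_rate_sets(dataset, n_sets, seed = seed)
  target_ids <- setdiff(dated_ids, cal_ids)
  fits <- vector("list", n_sets)
  s_mat <- matrix(NA_real_, n_sets, length(target_ids),
                  dimnames = list(NULL, target_ids))
  for (i in seq_len(n_sets)) {
    pts <- rs$sets[[i]]
    cal <- pts[pts$node_id %in% cal_ids, , drop = FALSE]
    fits[[i]] <- tryCatch(
      fit_time_model(cal, kind, n_starts = n_starts,
                     allow_saturated = allow_interpolating),
      error = function(e) NULL)
    s_mat[i, ] <- pts$s[match(target_ids, pts$node_id)]
  }
  n_dropped <- sum(vapply(fits, is.null, logical(1)))
  est <- infer_dates(fits, s_mat)
  est$role <- "predicted"
  cal_rows <- data.frame(node_id = cal_ids,
                         median_myr = nd$t_median_myr[match(cal_ids, nd$node_id)],
                         lower95_myr = nd$t_lower95_myr[match(cal_ids, nd$node_id)],
                         upper95_myr = nd$t_upper95_myr[match(cal_ids, nd$node_id)],
                         n_replicates = n_sets - n_dropped,
                         role = "calibrator", stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(est), cal_rows)
  out$reference_t_myr <- nd$t_median_myr[match(out$node_id, nd$node_id)]
  attr(out, "n_replicates_dropped") <- n_dropped
  attr(out, "kind") <- kind
  out
}

#' Infer dates for uncalibrated nodes from the full dated set
#'
#' The "missing dates" analysis: fits the model to every dated node (minus
#' any excluded ids) across the replicate ensemble under the time-prediction
#' criterion, then predicts the ages of the nodes that carry substitution
#' draws but no calibration (e.g. cospeciation mismatches), co-sampling
#' fits and substitution draws by replicate index.
#'
#' @param dataset a [cospeciation_dataset()] with at least one undated node.
#' @param exclude dated node ids to drop from fitting (default `c("7", "9")`,
#'   the nodes whose reference dates are unreliable).
#' @param n_sets number of replicates.
#' @param seed optional integer seed.
#' @param kind model kind (default `"PL"`).
#' @param n_starts optimisation starts per replicate fit.
#' @return a `date_estimates` data.frame for the undated nodes.
#' @export
infer_missing_dates <- function(dataset, exclude = c("7", "9"), n_sets = 1500,
                                seed = NULL, kind = "PL", n_starts = 3) {
  stopifnot(inherits(dataset, "cospeciation_dataset"))
  nd <- dataset$nodes
  if (!any(!nd$dated))
    stop("dataset has no undated nodes to infer", call. = FALSE)
  rs <- assemble_rate_sets(dataset, n_sets, seed = seed)
  fits <- lapply(rs$sets, function(pts) {
    train <- pts[!pts$node_id %in% exclude, , drop = FALSE]
    tryCatch(fit_time_model(train, kind, n_starts = n_starts),
             error = function(e) NULL)
  })
  infer_dates(fits, rs$undated_s)
}
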