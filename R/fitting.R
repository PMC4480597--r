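#' Adjusted R-squared
#'
#' The standard small-sample adjustment
#' `1 - (1 - r2) * (n - 1) / (n - p - 1)`, penalising model flexibility.
#'
#' @param r2 coefficient of determination.
#' @param n_points number of observations; must exceed `n_params + 1`.
#' @param n_params number of free model parameters.
#' @return adjusted R-squared (<= 1).
#' @export
adjusted_r_squared <- function(r2, n_points, n_params) {
  stopifnot(is.numeric(r2), is.numeric(n_points), is.numeric(n_params))
  if (n_points <= n_params + 1)
    stop("adjusted R-squared requires n_points > n_params + 1", call. = FALSE)
  1 - (1 - r2) * (n_points - 1) / (n_points - n_params - 1)
}

n_free_params <- function(kind) if (kind %in% c("VEX", "VPL")) 3L else 2L

# ---- parameter transforms -------------------------------------------------
# Positivity (and beta < 1 for power laws) is enforced by optimising on an
# unconstrained scale: log(alpha), log(beta) or scaled-logit(beta), log(k).
.beta_lo <- 1e-6
.beta_hi <- 1 - 1e-6
.k_floor <- 1e-30

theta_from_params <- function(kind, alpha, beta, k = .k_floor) {
  b <- if (kind %in% c("VPL", "PL")) {
    bb <- min(max(beta, .beta_lo * 1.0001), .beta_hi * 0.9999999)
    log((bb - .beta_lo) / (.beta_hi - bb))
  } else log(beta)
  th <- c(log(alpha), b)
  if (kind %in% c("VEX", "VPL")) th <- c(th, log(max(k, .k_floor)))
  th
}

params_from_theta <- function(kind, theta, time_unit = "Myr") {
  p <- theta_raw(kind, theta)
  rate_model(kind, alpha = p$a, beta = p$b, k = p$k, time_unit = time_unit)
}

# ---- starting values ------------------------------------------------------
# One data-driven start from a (log-)linear regression, the rest from a
# seeded Latin hypercube, log-uniform over [1e-12, 1e3] per parameter
# (beta of power laws uniform over its (0,1) box). The hypercube is drawn
# under a fixed private seed so fits are deterministic functions of the data.
fit_starts <- function(kind, t, s, criterion, n_starts) {
  p <- n_free_params(kind)
  starts <- list()
  lt <- log(t)
  rbar <- s / t
  k0 <- if (kind %in% c("VEX", "VPL")) max(min(rbar) / 2, .k_floor) else .k_floor
  if (kind %in% c("VPL", "PL")) {
    # log rbar = log(alpha/(1-beta)) - beta log t ;  log s = ... + (1-beta) log t
    co <- stats::lm.fit(cbind(1, lt),
                        if (criterion == "LSE_rbar") log(rbar) else log(s)
                        )$coefficients
    b0 <- if (criterion == "LSE_rbar") -co[2] else 1 - co[2]
    b0 <- min(max(b0, 0.05), 0.95)
    a0 <- exp(co[1]) * (1 - b0)
    if (!is.finite(a0) || a0 <= 0)
      a0 <- stats::median(rbar) * (1 - b0) * stats::median(t)^b0
    starts[[1]] <- theta_from_params(kind, a0, b0, k0)
  } else {
    # exponential: decay scale from the age span; amplitude from the data
    b0 <- 1 / stats::median(t)
    a0 <- if (criterion == "LSE_rbar") max(rbar)
          else 1.5 * b0 * max(s)  # keep saturation alpha/beta above max s
    starts[[1]] <- theta_from_params(kind, max(a0, 1e-12), b0, k0)
  }
  n_rand <- max(n_starts - 1L, 0L)
  if (n_rand > 0) {
    rs <- local_seed_eval(7036190L + n_rand + p, {
      lhs::randomLHS(n_rand, p)
    })
    for (i in seq_len(n_rand)) {
      u <- rs[i, ]
      a <- 10^(-12 + 15 * u[1])             # 1e-12 .. 1e3
      b <- if (kind %in% c("VPL", "PL")) 0.02 + 0.96 * u[2] else 10^(-12 + 15 * u[2])
      kk <- if (p == 3L) 10^(-12 + 15 * u[3]) else .k_floor
      starts[[length(starts) + 1L]] <- theta_from_params(kind, a, b, kk)
    }
  }
  starts
}

# evaluate `expr` under a private RNG seed, restoring the caller's stream
local_seed_eval <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# ---- residual functions ---------------------------------------------------
# raw (alpha, beta, k) from the unconstrained optimisation scale; the
# log-scale coordinates are clamped to +-55 (values within ~1e-24..7e23) so
# intermediate optimiser steps cannot overflow the model evaluations
theta_raw <- function(kind, theta) {
  theta <- pmin(pmax(theta, -55), 55)
  beta <- if (kind %in% c("VPL", "PL")) {
    .beta_lo + (.beta_hi - .beta_lo) / (1 + exp(-theta[2]))
  } else exp(theta[2])
  list(a = exp(theta[1]), b = beta,
       k = if (kind %in% c("VEX", "VPL")) exp(theta[3]) else 0)
}

resid_rbar <- function(theta, kind, t, rbar_myr) {
  p <- theta_raw(kind, theta)
  rbar_myr - cumsub_raw(kind, p$a, p$b, p$k, t) / t
}

# gradient of s(t) w.r.t. the natural parameters (a, b[, k]); n x p matrix
grad_s_raw <- function(kind, a, b, k, t) {
  if (kind %in% c("VEX", "EX")) {
    E <- exp(-t * b)
    om <- -expm1(-t * b)  # 1 - E without cancellation at small t*b
    g <- cbind(om / b,
               -a / b^2 * om + a / b * t * E)
  } else {
    tp <- t^(1 - b)
    g <- cbind(tp / (1 - b),
               a * tp / (1 - b) * (1 / (1 - b) - log(t)))
  }
  if (kind %in% c("VEX", "VPL")) g <- cbind(g, t)
  g
}

# d(natural)/d(transformed) chain factors for theta_raw's parameterisation
theta_chain <- function(kind, p) {
  db <- if (kind %in% c("VPL", "PL")) {
    (p$b - .beta_lo) * (.beta_hi - p$b) / (.beta_hi - .beta_lo)
  } else p$b
  if (kind %in% c("VEX", "VPL")) c(p$a, db, p$k) else c(p$a, db)
}

jac_rbar <- function(theta, kind, t, rbar_myr) {
  p <- theta_raw(kind, theta)
  J <- -grad_s_raw(kind, p$a, p$b, p$k, t) / t
  sweep(J, 2, theta_chain(kind, p), "*")
}

jac_time <- function(theta, kind, t, s) {
  p <- theta_raw(kind, theta)
  if (kind == "EX") {
    ok <- s < p$a / p$b
    J <- matrix(0, length(s), 2L)
    if (any(ok)) {
      Tok <- -log1p(-s[ok] * p$b / p$a) / p$b
      sp <- rate_raw(kind, p$a, p$b, p$k, Tok)
      J[ok, ] <- grad_s_raw(kind, p$a, p$b, p$k, Tok)[, 1:2, drop = FALSE] / sp
    }
    if (any(!ok)) {
      tm <- max(t)
      J[!ok, 1] <- -tm * s[!ok] * p$b / p$a^2
      J[!ok, 2] <- tm * s[!ok] / p$a
    }
    return(sweep(J, 2, theta_chain(kind, p), "*"))
  }
  Tt <- if (kind == "PL") ((1 - p$b) * s / p$a)^(1 / (1 - p$b))
        else invert_time_numeric(list(kind = kind, alpha = p$a, beta = p$b,
                                      k = p$k), s, t_start = t)
  sp <- rate_raw(kind, p$a, p$b, p$k, pmax(Tt, .Machine$double.xmin))
  J <- grad_s_raw(kind, p$a, p$b, p$k, pmax(Tt, .Machine$double.xmin)) / sp
  sweep(J, 2, theta_chain(kind, p), "*")
}

resid_time <- function(theta, kind, t, s) {
  p <- theta_raw(kind, theta)
  if (kind == "EX") {
    smax <- p$a / p$b
    ok <- s < smax
    res <- numeric(length(s))
    res[ok] <- t[ok] + log1p(-s[ok] * p$b / p$a) / p$b
    # finite, continuous penalty for unreachable s (keeps the optimiser moving)
    res[!ok] <- max(t) * (1 + (s[!ok] * p$b / p$a - 1))
    res
  } else if (kind == "PL") {
    t - ((1 - p$b) * s / p$a)^(1 / (1 - p$b))
  } else {
    m <- list(kind = kind, alpha = p$a, beta = p$b, k = p$k)
    t - invert_time_numeric(m, s, t_start = t)
  }
}

# ---- core fitter ----------------------------------------------------------
fit_decay_model <- function(points, kind, criterion, n_starts = 20,
                            allow_saturated = FALSE, maxiter = 150) {
  stopifnot(is.data.frame(points))
  kind <- match.arg(kind, c("VEX", "EX", "VPL", "PL"))
  criterion <- match.arg(criterion, c("LSE_rbar", "LSE_t"))
  t <- points$t_myr; s <- points$s
  if (any(!is.finite(t)) || any(!is.finite(s)) || any(t <= 0) || any(s <= 0))
    stop("all t and s values must be positive and finite", call. = FALSE)
  p <- n_free_params(kind)
  n <- length(t)
  min_n <- if (allow_saturated) p else p + 1L
  if (n < min_n)
    stop(sprintf("%s (%d free parameters) needs at least %d points, got %d",
                 kind, p, min_n, n), call. = FALSE)
  y <- if (criterion == "LSE_rbar") s / t else t  # per-Myr average rate, or time
  if (criterion == "LSE_rbar") {
    resid_fn <- function(th) resid_rbar(th, kind, t, y)
    jac_fn <- function(th) jac_rbar(th, kind, t, y)
  } else {
    resid_fn <- function(th) resid_time(th, kind, t, s)
    jac_fn <- function(th) jac_time(th, kind, t, s)
  }
  starts <- fit_starts(kind, t, s, criterion, n_starts)
  best <- NULL
  n_conv <- 0L
  for (th0 in starts) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = th0, fn = resid_fn, jac = jac_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = maxiter, ftol = 1e-11, ptol = 1e-11))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    conv <- fit$info %in% 1:4
    if (conv) n_conv <- n_conv + 1L
    if (is.null(best) || sse < best$sse)
      best <- list(theta = fit$par, sse = sse, converged = conv)
  }
  if (is.null(best))
    stop(sprintf("all %d starts failed for %s under %s", length(starts), kind,
                 criterion), call. = FALSE)
  params <- params_from_theta(kind, best$theta)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - best$sse / ss_tot else NA_real_
  adj <- if (n > p + 1 && is.finite(r2)) adjusted_r_squared(r2, n, p) else NA_real_
  structure(
    list(params = params, criterion = criterion, sse = best$sse,
         r2 = r2, adj_r2 = adj, n_points = n,
         n_starts_converged = n_conv, converged = best$converged),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit (%s, criterion %s): sse = %.6g, adj R2 = %s, %d points\n",
              x$params$kind, x$criterion, x$sse,
              ifelse(is.na(x$adj_r2), "NA", sprintf("%.4f", x$adj_r2)),
              x$n_points))
  print(x$params)
  invisible(x)
}

#' Fit a rate-decay model to average-rate data
#'
#' Nonlinear least squares of the model's average-rate curve against the
#' observed node-to-tip average rates: minimises
#' `sum((rbar_i - rbar_model(t_i))^2)` over the positivity-constrained
#' parameter box. Fitting is internally done with `t` in Myr and rates in
#' substitutions/site/Myr (better conditioning); the fitted `rate_model` is
#' returned on the Myr scale and can be converted with [convert_time_unit()].
#' Levenberg-Marquardt from a data-driven start plus seeded Latin-hypercube
#' multi-starts; the best optimum is returned.
#'
#' @param points data.frame with columns `t_myr`, `s` (one resampled set).
#' @param kind model kind: `"VEX"`, `"EX"`, `"VPL"`, `"PL"`.
#' @param n_starts total number of optimisation starts (default 20).
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return a `fit_result`: `params` ([rate_model()]), `criterion`, `sse`,
#'   `r2`, `adj_r2` (NA when residual degrees of freedom are < 1),
#'   `n_points`, `n_starts_converged`, `converged`.
#' @export
fit_average_rate_model <- function(points, kind, n_starts = 20, maxiter = 150) {
  fit_decay_model(points, kind, "LSE_rbar", n_starts = n_starts,
                  maxiter = maxiter)
}

#' Fit a rate-decay model as a divergence-date predictor
#'
#' Nonlinear least squares in the time domain: minimises
#' `sum((t_i - t_model(s_i))^2)` where `t_model` inverts the cumulative
#' substitution curve ([invert_time()]). This is the criterion under which
#' the models are cross-validated and used for date inference. For the EX
#' family, substitution values at or beyond the saturation bound
#' `alpha/beta` receive a finite, continuously increasing penalty residual
#' instead of failing, so the optimiser can leave infeasible regions.
#'
#' @inheritParams fit_average_rate_model
#' @param allow_saturated permit `n_points == n_params` (zero residual
#'   degrees of freedom); off by default.
#' @return a `fit_result` (see [fit_average_rate_model()]).
#' @export
fit_time_model <- function(points, kind, n_starts = 20,
                           allow_saturated = FALSE, maxiter = 150) {
  fit_decay_model(points, kind, "LSE_t", n_starts = n_starts,
                  allow_saturated = allow_saturated, maxiter = maxiter)
}

#' Fit one model kind across an ensemble of resampled sets
#'
#' Applies [fit_average_rate_model()] or [fit_time_model()] to every
#' resampled `(t, s)` set and summarises the fitted parameters and adjusted
#' R-squared by median and central 95% interval across the ensemble.
#'
#' @param rate_sets a `rate_sample_sets` from [assemble_rate_sets()], or a
#'   plain list of point data.frames.
#' @param kind model kind.
#' @param criterion `"LSE_rbar"` or `"LSE_t"`.
#' @param n_starts optimisation starts per set.
#' @return list with `fits` (list of `fit_result`; failed sets carry `NULL`
#'   and are counted in `n_failed`), `per_set` (data.frame of parameters and
#'   adj R2 per set) and `summary` (median / 2.5% / 97.5% per quantity).
#' @export
fit_ensemble <- function(rate_sets, kind, criterion = c("LSE_rbar", "LSE_t"),
                         n_starts = 20) {
  criterion <- match.arg(criterion)
  sets <- if (inherits(rate_sets, "rate_sample_sets")) rate_sets$sets else rate_sets
  if (!length(sets)) stop("empty set collection", call. = FALSE)
  fits <- lapply(sets, function(p) {
    tryCatch(fit_decay_model(p, kind, criterion, n_starts = n_starts),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  per_set <- do.call(rbind, lapply(which(ok), function(i) {
    f <- fits[[i]]
    data.frame(set_index = i, alpha = f$params$alpha, beta = f$params$beta,
               k = f$params$k, sse = f$sse, adj_r2 = f$adj_r2,
               converged = f$converged)
  }))
  qrow <- function(v, nm) {
    v <- v[is.finite(v)]
    if (!length(v)) return(NULL)
    q <- stats::quantile(v, c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(quantity = nm, median = q[1], lower95 = q[2], upper95 = q[3])
  }
  summ <- do.call(rbind, list(qrow(per_set$alpha, "alpha"),
                              qrow(per_set$beta, "beta"),
                              qrow(per_set$k, "k"),
                              qrow(per_set$adj_r2, "adj_r2")))
  list(fits = fits, per_set = per_set, summary = summ,
       n_failed = sum(!ok), kind = kind, criterion = criterion)
}
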