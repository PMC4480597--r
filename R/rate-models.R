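#' Empirical substitution-rate decay models
#'
#' Constructs a parameterised rate-decay model describing how the
#' instantaneous substitution rate \eqn{r(t)} decays with the timescale of
#' measurement \eqn{t}. Four empirical families are supported:
#'
#' \describe{
#'   \item{VEX}{vertically-translated exponential: \eqn{r = \alpha e^{-t\beta} + k}}
#'   \item{EX}{simple exponential: \eqn{r = \alpha e^{-t\beta}}}
#'   \item{VPL}{vertically-translated power law: \eqn{r = \alpha t^{-\beta} + k}}
#'   \item{PL}{simple power law: \eqn{r = \alpha t^{-\beta}}}
#' }
#'
#' `t` is measured in the present-to-past direction (`t = 0` is the present),
#' so under a strict clock with aligned tips it is interchangeable with node
#' height / divergence date. `k` is the stable long-term rate asymptote of
#' the vertically-translated families; `alpha` and `beta` are free shape
#' parameters. For the power-law families `beta` must lie in (0, 1), else the
#' cumulative-substitution integral through the origin diverges.
#'
#' @param kind one of `"VEX"`, `"EX"`, `"VPL"`, `"PL"`.
#' @param alpha positive rate-scale parameter (substitutions/site/unit-time;
#'   for power laws the unit is time^beta-adjusted).
#' @param beta positive decay parameter; in (0, 1) for `"VPL"`/`"PL"`.
#' @param k nonnegative long-term rate asymptote; only meaningful for
#'   `"VEX"`/`"VPL"` and forced to 0 for the simple families.
#' @param time_unit `"Myr"` or `"year"`; the unit `t` is expressed in.
#' @return an object of class `rate_model`.
#' @examples
#' m <- rate_model("PL", alpha = 2, beta = 0.5)
#' instantaneous_rate(m, 4) # 1
#' @seealso [instantaneous_rate()], [cumulative_substitutions()],
#'   [average_rate()], [invert_time()]
#' @export
rate_model <- function(kind = c("VEX", "EX", "VPL", "PL"),
                       alpha, beta, k = 0, time_unit = c("Myr", "year")) {
  kind <- match.arg(kind)
  time_unit <- match.arg(time_unit)
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(beta), length(beta) == 1L,
            is.numeric(k), length(k) == 1L)
  if (!is.finite(alpha) || !is.finite(beta) || !is.finite(k))
    stop("rate_model parameters must be finite", call. = FALSE)
  if (alpha <= 0) stop("'alpha' must be > 0", call. = FALSE)
  if (beta <= 0) stop("'beta' must be > 0", call. = FALSE)
  if (kind %in% c("VPL", "PL") && beta >= 1)
    stop("power-law models require beta < 1 (finite integral through the origin)",
         call. = FALSE)
  if (k < 0) stop("'k' must be >= 0", call. = FALSE)
  if (kind %in% c("EX", "PL")) k <- 0
  structure(
    list(kind = kind, alpha = alpha, beta = beta, k = k, time_unit = time_unit),
    class = "rate_model"
  )
}

#' @export
print.rate_model <- function(x, ...) {
  lab <- c(VEX = "vertically-translated exponential",
           EX = "simple exponential",
           VPL = "vertically-translated power-law",
           PL = "simple power-law")[[x$kind]]
  cat(sprintf("Rate-decay model: %s (%s)\n", x$kind, lab))
  cat(sprintf("  alpha = %.6g, beta = %.6g", x$alpha, x$beta))
  if (x$kind %in% c("VEX", "VPL")) cat(sprintf(", k = %.6g", x$k))
  cat(sprintf("  [t in %s]\n", x$time_unit))
  invisible(x)
}

#' Instantaneous substitution rate at a timescale
#'
#' Evaluates \eqn{r(t)} under the model's decay law. Power-law kinds are
#' singular at `t = 0` and reject it.
#'
#' @param model a [rate_model()].
#' @param t nonnegative time(s) in the model's `time_unit`; strictly positive
#'   for power-law kinds.
#' @return numeric vector of rates (substitutions/site/unit-time).
#' @export
instantaneous_rate <- function(model, t) {
  stopifnot(inherits(model, "rate_model"), is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and >= 0", call. = FALSE)
  if (model$kind %in% c("VPL", "PL") && any(t == 0))
    stop("power-law rate is singular at t = 0", call. = FALSE)
  switch(model$kind,
    VEX = model$alpha * exp(-t * model$beta) + model$k,
    EX  = model$alpha * exp(-t * model$beta),
    VPL = model$alpha * t^(-model$beta) + model$k,
    PL  = model$alpha * t^(-model$beta)
  )
}

#' Cumulative node-to-tip substitutions over a timescale
#'
#' Integrates the instantaneous rate from the present back to `t`, using the
#' closed forms of each family. All curves pass through the origin: zero
#' substitutions at zero elapsed time.
#'
#' @inheritParams instantaneous_rate
#' @param t nonnegative time(s).
#' @return expected substitutions per site accumulated over `[0, t]`.
#' @export
cumulative_substitutions <- function(model, t) {
  stopifnot(inherits(model, "rate_model"), is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and >= 0", call. = FALSE)
  a <- model$alpha; b <- model$beta; k <- model$k
  switch(model$kind,
    VEX = -a / b * expm1(-t * b) + t * k,
    EX  = -a / b * expm1(-t * b),
    VPL = a * t^(1 - b) / (1 - b) + t * k,
    PL  = a * t^(1 - b) / (1 - b)
  )
}

#' Node-to-tip average substitution rate
#'
#' The mean rate over `[0, t]`: [cumulative_substitutions()] divided by `t`.
#' This is the quantity (often written \eqn{\bar r}) whose decay with
#' measurement timescale constitutes the time-dependent rate phenomenon.
#'
#' @inheritParams instantaneous_rate
#' @param t strictly positive time(s).
#' @return numeric vector of average rates.
#' @export
average_rate <- function(model, t) {
  stopifnot(inherits(model, "rate_model"), is.numeric(t))
  if (any(!is.finite(t)) || any(t <= 0))
    stop("'t' must be finite and > 0", call. = FALSE)
  cumulative_substitutions(model, t) / t
}

#' Invert a rate-decay model: time from substitutions
#'
#' Solves \eqn{s(t) = s} for `t`, i.e. predicts the divergence date that a
#' given node-to-tip substitution count implies under the model. `s(t)` is
#' strictly increasing from 0, so the solution is unique. PL and EX invert in
#' closed form; VEX and VPL use a safeguarded Newton iteration inside a
#' geometrically expanded bracket. The EX family saturates at `alpha/beta`
#' substitutions: larger `s` is unreachable at any finite time.
#'
#' @inheritParams instantaneous_rate
#' @param s nonnegative substitutions/site (vectorised).
#' @return time(s) `t` in the model's `time_unit`, with
#'   `cumulative_substitutions(model, t) == s` to within
#'   `1e-10 + 1e-8 * t` absolute-plus-relative tolerance.
#' @export
invert_time <- function(model, s) {
  stopifnot(inherits(model, "rate_model"), is.numeric(s))
  if (any(!is.finite(s)) || any(s < 0))
    stop("'s' must be finite and >= 0", call. = FALSE)
  a <- model$alpha; b <- model$beta
  out <- switch(model$kind,
    PL = ((1 - b) * s / a)^(1 / (1 - b)),
    EX = {
      if (any(s >= a / b))
        stop(sprintf(
          "EX model saturates at s = alpha/beta = %.6g; s beyond it is unreachable",
          a / b), call. = FALSE)
      -log1p(-s * b / a) / b
    },
    VEX = ,
    VPL = invert_time_numeric(model, s)
  )
  out[s == 0] <- 0
  out
}

# Raw closed-form evaluators without S3/validation overhead, for hot loops
# (root-finding and least-squares objectives).
cumsub_raw <- function(kind, a, b, k, t) {
  switch(kind,
    VEX = -a / b * expm1(-t * b) + t * k,
    EX  = -a / b * expm1(-t * b),
    VPL = a * t^(1 - b) / (1 - b) + t * k,
    PL  = a * t^(1 - b) / (1 - b))
}

rate_raw <- function(kind, a, b, k, t) {
  switch(kind,
    VEX = a * exp(-t * b) + k,
    EX  = a * exp(-t * b),
    VPL = a * t^(-b) + k,
    PL  = a * t^(-b))
}

# Vectorised safeguarded Newton for the vertically-translated families.
# s(t) is smooth, strictly increasing, s'(t) = r(t) > 0, so Newton from a
# bracketed start converges; bisection fallback keeps iterates in bracket.
invert_time_numeric <- function(model, s, t_start = NULL) {
  n <- length(s)
  if (n == 0L) return(numeric(0))
  kind <- model$kind; a <- model$alpha; b <- model$beta; k <- model$k
  lo <- rep(0, n)
  hi <- if (is.null(t_start)) rep(1, n) else pmax(2 * t_start, 1)
  for (j in 1:256) {
    under <- cumsub_raw(kind, a, b, k, hi) < s
    under[is.na(under)] <- FALSE
    if (!any(under)) break
    lo[under] <- hi[under]
    hi[under] <- hi[under] * 4
  }
  t <- if (is.null(t_start)) (lo + hi) / 2 else pmin(pmax(t_start, lo), hi)
  t[t <= 0] <- hi[t <= 0] / 2
  act <- seq_len(n)
  for (iter in 1:100) {
    ta <- t[act]
    f <- cumsub_raw(kind, a, b, k, ta) - s[act]
    f[is.na(f)] <- Inf  # overflowed evaluation: treat as overshoot
    step <- f / rate_raw(kind, a, b, k, pmax(ta, .Machine$double.xmin))
    conv <- abs(step) <= 1e-10 + 1e-8 * ta
    neg <- f < 0
    lo[act[neg]] <- ta[neg]
    hi[act[!neg]] <- ta[!neg]
    t_new <- ta - step
    bad <- !is.finite(t_new) | t_new <= lo[act] | t_new >= hi[act]
    t_new[bad & !conv] <- (lo[act] + hi[act])[bad & !conv] / 2
    t_new[bad & conv] <- ta[bad & conv]
    t[act] <- t_new
    act <- act[!conv]
    if (!length(act)) break
  }
  t
}

#' Convert a fitted model between time units
#'
#' Rescales the parameters so that the model describes the identical decay
#' curve with `t` expressed in the new unit (exact factors of 1e6 between
#' years and Myr). Rates transform reciprocally with time, `beta` rescales
#' for the exponential families and is dimensionless for the power laws.
#'
#' @inheritParams instantaneous_rate
#' @param to target unit, `"Myr"` or `"year"`.
#' @return a [rate_model()] in the target unit.
#' @export
convert_time_unit <- function(model, to = c("Myr", "year")) {
  stopifnot(inherits(model, "rate_model"))
  to <- match.arg(to)
  if (model$time_unit == to) return(model)
  # f = (new units per old unit): year <- Myr is 1e6
  f <- if (model$time_unit == "Myr") 1e6 else 1e-6
  a <- model$alpha; b <- model$beta; k <- model$k
  if (model$kind %in% c("VEX", "EX")) {
    # r_new(t_new) = r_old(t_new / f) / f
    a2 <- a / f; b2 <- b / f; k2 <- k / f
  } else {
    # alpha t^-beta: alpha_new = alpha * f^(beta - 1)
    a2 <- a * f^(b - 1); b2 <- b; k2 <- k / f
  }
  rate_model(model$kind, alpha = a2, beta = b2, k = k2, time_unit = to)
}

#' Serialise / deserialise a rate model as JSON
#'
#' The JSON document holds `{kind, alpha, beta, k, time_unit}` with full
#' double precision (17 significant digits), so a round trip is value-exact.
#'
#' @param model a [rate_model()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return `model_to_json()`: the JSON string (invisibly, if written to file);
#'   `model_from_json()`: a [rate_model()].
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "rate_model"))
  js <- jsonlite::toJSON(
    list(kind = model$kind, alpha = model$alpha, beta = model$beta,
         k = model$k, time_unit = model$time_unit),
    auto_unbox = TRUE, digits = I(17)
  )
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname model_to_json
#' @param json a JSON string or path to a JSON file.
#' @export
model_from_json <- function(json) {
  x <- if (length(json) == 1L && file.exists(json)) {
    jsonlite::fromJSON(json)
  } else {
    jsonlite::fromJSON(paste(json, collapse = "\n"))
  }
  rate_model(x$kind, alpha = x$alpha, beta = x$beta, k = x$k,
             time_unit = x$time_unit)
}
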