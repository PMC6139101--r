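# Trait (control parameter) dynamics: exponentially weighted running-window
# filters of state deviations, normalized driver combiners, saturation with
# threshold gating, and mixing of an empirical alliance series into the
# alliance parameter a.

#' Filter configuration for the state-deviation filters
#'
#' The trait update reads the recent history of each state variable through
#' a running window of length `n` (days). Within the window, deviations from
#' the window mean are weighted by an exponential decay in sample age with
#' decay constant `lambda = ln(2)/tau` (`tau` = half-life in days), and the
#' weighted sum is rescaled by a mean-shift correction factor `d`.
#'
#' @param n window length in iterations (days); default 14.
#' @param tau half-life in days, scalar or named per-variable vector over
#'   `E, P, M, I, S`; default 7 for every variable.
#' @param d mean-shift correction factor, scalar or named per-variable
#'   vector; default 0.535 for every variable.
#' @param lambda decay constant(s); computed as `ln(2)/tau` when omitted.
#' @return an object of class `st_filter_config`.
#' @examples
#' filter_config()                 # the defaults: n = 14, tau = 7 d
#' filter_config(n = 7, tau = 3.5)
#' @export
filter_config <- function(n = 14, tau = 7, d = 0.535, lambda = NULL) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 2 ||
      n != round(n))
    stop("n must be a single integer >= 2", call. = FALSE)
  tau <- expand_per_variable(tau, "tau")
  d <- expand_per_variable(d, "d")
  if (any(tau <= 0)) stop("tau must be > 0", call. = FALSE)
  if (any(d <= 0)) stop("d must be > 0", call. = FALSE)
  if (is.null(lambda)) {
    lambda <- vapply(tau, decay_constant, numeric(1))
  } else {
    lambda <- expand_per_variable(lambda, "lambda")
    if (any(lambda <= 0)) stop("lambda must be > 0", call. = FALSE)
  }
  structure(list(n = as.integer(n), tau = tau, lambda = lambda, d = d),
            class = "st_filter_config")
}

expand_per_variable <- function(x, what) {
  vars <- state_names()
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(what, " must be finite numeric", call. = FALSE)
  if (length(x) == 1L) x <- rep(x, 5)
  if (is.null(names(x))) names(x) <- vars
  if (length(x) != 5L || !all(vars %in% names(x)))
    stop(what, " must be a scalar or named per-variable vector over ",
         paste(vars, collapse = ", "), call. = FALSE)
  x[vars]
}

expand_per_trait <- function(x, what) {
  vars <- trait_names()
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(what, " must be finite numeric", call. = FALSE)
  if (length(x) == 1L) x <- rep(x, 4)
  if (is.null(names(x))) names(x) <- vars
  if (length(x) != 4L || !all(vars %in% names(x)))
    stop(what, " must be a scalar or named per-trait vector over ",
         paste(vars, collapse = ", "), call. = FALSE)
  x[vars]
}

#' Trait update configuration
#'
#' Sensitivity weights, windowed parameter bounds and threshold gates for the
#' trait update rule. The gain factor of the saturation function is
#' `k = p_max - p_min`; with the default bounds `(0.1, 0.8)` (printed for the
#' competence parameter c, adopted for all four traits) `k = 0.7`.
#'
#' @param w sensitivity weight(s), scalar or named per-trait vector over
#'   `a, c, r, m`; default 0.004167.
#' @param p_min,p_max windowed range bounds, scalar or per-trait; defaults
#'   0.1 and 0.8.
#' @param gate_low,gate_high thresholds below/above which the boundary gates
#'   of the saturation function engage; defaults 0.2 and 0.8.
#' @param literal_low_gate logical; keep the printed `(p - 1)` factor of the
#'   low gate (a restoring force near the floor). Set `FALSE` to use
#'   `|p - 1|` instead for sensitivity analysis.
#' @return an object of class `st_trait_config`.
#' @export
trait_update_config <- function(w = 0.004167, p_min = 0.1, p_max = 0.8,
                                gate_low = 0.2, gate_high = 0.8,
                                literal_low_gate = TRUE) {
  w <- expand_per_trait(w, "w")
  p_min <- expand_per_trait(p_min, "p_min")
  p_max <- expand_per_trait(p_max, "p_max")
  if (any(w <= 0)) stop("weights w must be > 0", call. = FALSE)
  if (any(p_min < 0) || any(p_max > 1) || any(p_min >= p_max))
    stop("bounds must satisfy 0 <= p_min < p_max <= 1", call. = FALSE)
  if (!is.numeric(gate_low) || !is.numeric(gate_high) ||
      gate_low >= gate_high)
    stop("gate_low must be < gate_high", call. = FALSE)
  structure(list(w = w, p_min = p_min, p_max = p_max, k = p_max - p_min,
                 gate_low = gate_low, gate_high = gate_high,
                 literal_low_gate = isTRUE(literal_low_gate)),
            class = "st_trait_config")
}

#' Decay constant from a half-life
#'
#' `lambda = ln(2) / tau`. With the default half-life of 7 days this gives
#' `lambda = 0.099` (3 decimals).
#'
#' @param tau half-life in days, > 0.
#' @return the decay constant.
#' @examples
#' round(decay_constant(7), 3)  # 0.099
#' @export
decay_constant <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("tau must be a single positive number", call. = FALSE)
  log(2) / tau
}

#' Exponential age weights for a running window
#'
#' Weights for window positions `i = 1..n` (oldest to newest), decaying with
#' the age of the sample: the newest sample has weight exactly 1, the oldest
#' `exp(-lambda * (n - 1))`. Weights depend only on the position within the
#' window, never on absolute time, so the filter is time-translation
#' invariant.
#'
#' @param n window length, integer >= 2.
#' @param lambda decay constant, > 0.
#' @return numeric vector of length `n`, strictly increasing, last element 1.
#' @export
decay_weights <- function(n, lambda) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 2 ||
      n != round(n))
    stop("n must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0)
    stop("lambda must be a single positive number", call. = FALSE)
  exp(-lambda * (n - seq_len(n)))
}

#' Exponentially weighted deviation filter of one state variable
#'
#' `d * sum_i (x_i - mean(x)) * w_i` with the age weights of
#' [decay_weights()]. Because the window is mean-centered, the filter
#' responds to relative increases or decreases of the variable, never to its
#' absolute level: any constant window maps to exactly 0, and adding a
#' constant to every element leaves the value unchanged.
#'
#' @param x numeric vector: one variable's window values, oldest to newest.
#' @param d mean-shift correction factor.
#' @param lambda decay constant.
#' @param n expected window length; defaults to `length(x)` and is checked
#'   against it.
#' @return the filter value (scalar).
#' @examples
#' filter_value(rep(0.4, 14), d = 0.535, lambda = 0.099)  # exactly 0
#' @export
filter_value <- function(x, d, lambda, n = length(x)) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0 ||
      !is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0)
    stop("invalid filter parameters d/lambda", call. = FALSE)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("window values must be finite numeric", call. = FALSE)
  if (length(x) != n || n < 2)
    stop(errorCondition(
      paste0("window is incomplete: need ", n, " values, got ", length(x)),
      class = "st_short_window"))
  d * sum((x - mean(x)) * decay_weights(n, lambda))
}

#' Normalized driver of one trait parameter
#'
#' Combines the five state filters (and, for the competence and resource
#' parameters, the previous value of the respectively coupled trait) into the
#' normalized driver of the trait update:
#' \describe{
#'   \item{a}{`(f_S - f_E) / 2` — success up, negative emotions down.}
#'   \item{c}{`(f_I + f_S + r_prev) / 3` — insight, success, and behavioral
#'     resources.}
#'   \item{r}{`(f_S + c_prev) / 2` — success and cognitive competencies.}
#'   \item{m}{`(-f_E - f_P + f_M + f_S) / 4` — problem and distress reduction,
#'     motivation, success.}
#' }
#'
#' @param param one of `"a"`, `"c"`, `"r"`, `"m"`.
#' @param filters named numeric vector of filter values over `E, P, M, I, S`.
#' @param traits_prev previous trait vector (used for the cross-terms).
#' @return the driver (scalar).
#' @export
combine_drivers <- function(param, filters, traits_prev) {
  if (is.null(names(filters))) names(filters) <- state_names()
  f <- filters[state_names()]
  if (any(!is.finite(f))) stop("filters must be finite", call. = FALSE)
  tp <- as_traits(traits_prev)
  switch(param,
    a = (f[["S"]] - f[["E"]]) / 2,
    c = (f[["I"]] + f[["S"]] + tp[["r"]]) / 3,
    r = (f[["S"]] + tp[["c"]]) / 2,
    m = (-f[["E"]] - f[["P"]] + f[["M"]] + f[["S"]]) / 4,
    stop("unknown trait parameter '", param, "'; must be one of a, c, r, m",
         call. = FALSE)
  )
}

#' Saturating, gated trait increment
#'
#' Applies the saturation function and threshold gating to a raw
#' (pre-saturation) increment `delta = w * p_prev * driver`:
#' the effective increment is `s* = k * delta * (p_max - p_prev)` for
#' `delta > 0` and `s* = k * delta * (p_prev - p_min)` for `delta < 0`
#' (sign-gated branches), then the boundary gates engage:
#' multiplied by `(1 - p_prev)` if `p_prev > gate_high` and `delta > 0`,
#' by `(p_prev - 1)` if `p_prev < gate_low` and `delta < 0` (the printed
#' form, a restoring force near the floor; see `literal_low_gate` in
#' [trait_update_config()]), and passed through otherwise. `delta = 0`
#' returns 0.
#'
#' @param param one of `"a"`, `"c"`, `"r"`, `"m"` (selects per-trait bounds).
#' @param p_prev previous parameter value in \[0, 1\].
#' @param delta raw pre-saturation increment.
#' @param cfg an [trait_update_config()] object.
#' @return the effective (saturated, gated) increment.
#' @export
saturate <- function(param, p_prev, delta, cfg = trait_update_config()) {
  stopifnot(inherits(cfg, "st_trait_config"))
  if (!is.finite(p_prev) || p_prev < 0 || p_prev > 1)
    stop("p_prev must be in [0, 1]", call. = FALSE)
  if (!is.finite(delta)) stop("delta must be finite", call. = FALSE)
  if (delta == 0) return(0)
  pmin <- cfg$p_min[[param]]; pmax <- cfg$p_max[[param]]
  k <- cfg$k[[param]]
  sstar <- if (delta > 0) k * delta * (pmax - p_prev)
           else           k * delta * (p_prev - pmin)
  if (p_prev > cfg$gate_high && delta > 0) {
    (1 - p_prev) * sstar
  } else if (p_prev < cfg$gate_low && delta < 0) {
    low <- if (cfg$literal_low_gate) (p_prev - 1) else abs(p_prev - 1)
    low * sstar
  } else {
    sstar
  }
}

#' Mix the empirical alliance value into the alliance parameter
#'
#' The alliance parameter has two faces: a disposition (the trait proper) and
#' the realized quality of the therapeutic relationship, measured daily as
#' `b_t`. When an alliance value is available the two are combined by their
#' arithmetic mean; when not, `b_t` falls back to the previous parameter
#' value, leaving it unchanged.
#'
#' @param a_prev previous alliance parameter in \[0, 1\].
#' @param b_t measured alliance value in \[0, 1\], or `NULL`/`NA` if absent.
#' @return the mixed alliance value.
#' @examples
#' mix_alliance(0.2, 0.4)   # 0.3
#' mix_alliance(0.2, NULL)  # 0.2
#' @export
mix_alliance <- function(a_prev, b_t = NULL) {
  if (!is.finite(a_prev) || a_prev < 0 || a_prev > 1)
    stop("a_prev must be in [0, 1]", call. = FALSE)
  if (is.null(b_t) || (length(b_t) == 1L && is.na(b_t))) return(a_prev)
  if (!is.numeric(b_t) || length(b_t) != 1L || !is.finite(b_t) ||
      b_t < 0 || b_t > 1)
    stop("alliance value b_t must be in [0, 1]", call. = FALSE)
  (a_prev + b_t) / 2
}

#' Synchronous update of the four trait parameters
#'
#' One trait-update step from a full state window. For each parameter the
#' five state filters are computed, combined into the normalized driver, and
#' turned into a raw increment `delta = w * base * driver`; the applied
#' increment then passes through [saturate()]. All four parameters are
#' updated from the same previous trait vector (synchronous update), and the
#' results are clamped to \[0, 1\] as a hard safety net.
#'
#' For the alliance parameter, `base` is the mixed value
#' [mix_alliance()]`(a_prev, b_t)`, which replaces the previous alliance
#' value throughout its update (additive base, raw increment, and
#' saturation), so that with a measured alliance series the parameter is
#' pulled toward the experienced alliance quality.
#'
#' @param traits_prev previous trait vector.
#' @param window numeric matrix with `n` rows (oldest to newest) and columns
#'   `E, P, M, I, S`: the trailing state window.
#' @param fcfg a [filter_config()].
#' @param tcfg a [trait_update_config()].
#' @param b_t optional measured alliance value for this iteration.
#' @return the updated trait vector (named, in \[0, 1\]).
#' @export
update_traits <- function(traits_prev, window, fcfg = filter_config(),
                          tcfg = trait_update_config(), b_t = NULL) {
  stopifnot(inherits(fcfg, "st_filter_config"),
            inherits(tcfg, "st_trait_config"))
  tp <- as_traits(traits_prev)
  window <- as.matrix(window)
  if (is.null(colnames(window))) colnames(window) <- state_names()
  if (nrow(window) != fcfg$n)
    stop("state window is incomplete: need ", fcfg$n, " rows, got ",
         nrow(window), call. = FALSE)
  filters <- vapply(state_names(), function(v) {
    filter_value(window[, v], d = fcfg$d[[v]], lambda = fcfg$lambda[[v]],
                 n = fcfg$n)
  }, numeric(1))

  new <- tp
  for (p in trait_names()) {
    base <- if (p == "a") mix_alliance(tp[["a"]], b_t) else tp[[p]]
    driver <- combine_drivers(p, filters, tp)
    delta <- tcfg$w[[p]] * base * driver
    new[[p]] <- base + saturate(p, base, delta, tcfg)
  }
  pmin(pmax(new, 0), 1)
}
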