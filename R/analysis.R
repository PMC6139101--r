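# Reporting transforms used for figure-style output: z-transformation,
# gliding-window smoothing, and pre/post transition summaries.

#' z-transform a series
#'
#' Standardizes a series to mean 0 and sample standard deviation 1
#' (denominator n - 1), computed over the full series. A constant series has
#' no scale; it maps to all zeros with a warning.
#'
#' @param x numeric vector, length >= 2.
#' @return the standardized series.
#' @examples
#' z_transform(c(1, 2, 3))  # -1 0 1
#' @export
z_transform <- function(x) {
  if (!is.numeric(x) || length(x) < 2L)
    stop("need a numeric series of length >= 2", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) {
    warning("constant series: z-transform returned zeros", call. = FALSE)
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Gliding-window moving average
#'
#' Centered arithmetic mean over an overlapping gliding window (default
#' width 3, the smoothing used for figure display). Endpoints use the
#' truncated available window, so the output has the same length as the
#' input and a constant series is returned unchanged.
#'
#' @param x numeric vector.
#' @param width odd window width, `<= length(x)`; default 3.
#' @return the smoothed series.
#' @examples
#' moving_average(c(0, 3, 0))        # 1.5 1.0 1.5
#' @export
moving_average <- function(x, width = 3) {
  if (!is.numeric(x) || length(x) < 1L)
    stop("need a numeric series", call. = FALSE)
  if (!is.numeric(width) || length(width) != 1L || width != round(width) ||
      width < 1 || width %% 2 == 0)
    stop("width must be an odd integer", call. = FALSE)
  if (width > length(x))
    stop("width exceeds series length", call. = FALSE)
  h <- (width - 1) / 2
  nx <- length(x)
  vapply(seq_len(nx), function(i) {
    mean(x[max(1, i - h):min(nx, i + h)])
  }, numeric(1))
}

#' Pre/post transition summary of a trajectory
#'
#' Compares the state variables before and after a (suspected) order
#' transition: per-variable means and standard deviations over a pre- and a
#' post-interval, both on the raw internal scale and on whole-run z-views,
#' plus the post-minus-pre mean differences.
#'
#' @param traj an `st_trajectory` from [run_scenario()], or a data.frame /
#'   matrix with columns `E, P, M, I, S` indexed by iteration 0..T.
#' @param pre,post iteration intervals `c(first, last)` (inclusive, on the
#'   0-based iteration index); must be disjoint and within the trajectory.
#' @return a data.frame with one row per variable: raw and z pre/post means,
#'   SDs, and mean differences.
#' @examples
#' traj <- run_scenario(preset_scenario("fig3"))
#' transition_summary(traj, pre = c(0, 100), post = c(250, 400))
#' @export
transition_summary <- function(traj, pre, post) {
  states <- if (inherits(traj, "st_trajectory")) traj$states
            else as.matrix(as.data.frame(traj)[, state_names()])
  TT <- nrow(states) - 1L
  check_interval <- function(iv, what) {
    if (!is.numeric(iv) || length(iv) != 2L || iv[1] > iv[2] ||
        iv[1] < 0 || iv[2] > TT)
      stop(what, " interval must be c(first, last) within [0, ", TT, "]",
           call. = FALSE)
  }
  check_interval(pre, "pre")
  check_interval(post, "post")
  if (pre[2] >= post[1] && post[2] >= pre[1])
    stop("pre and post intervals must be disjoint", call. = FALSE)

  idx_pre <- (pre[1]:pre[2]) + 1L
  idx_post <- (post[1]:post[2]) + 1L
  rows <- lapply(state_names(), function(v) {
    x <- states[, v]
    z <- if (stats::sd(x) == 0) rep(0, length(x)) else z_transform(x)
    data.frame(
      variable = v,
      pre_mean = mean(x[idx_pre]), post_mean = mean(x[idx_post]),
      diff = mean(x[idx_post]) - mean(x[idx_pre]),
      pre_sd = stats::sd(x[idx_pre]), post_sd = stats::sd(x[idx_post]),
      pre_mean_z = mean(z[idx_pre]), post_mean_z = mean(z[idx_post]),
      diff_z = mean(z[idx_post]) - mean(z[idx_pre]),
      pre_sd_z = stats::sd(z[idx_pre]), post_sd_z = stats::sd(z[idx_post]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
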