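# S3 methods for scenario and trajectory objects.

#' @export
print.st_scenario <- function(x, ...) {
  cat("State-trait simulation scenario\n")
  cat("  iterations:", x$iterations, " seed:", x$seed, "\n")
  cat("  initial states (empirical scale):",
      paste(sprintf("%s=%g", state_names(), x$init_states), collapse = " "),
      "\n")
  cat("  initial traits:",
      paste(sprintf("%s=%g", trait_names(), x$init_traits), collapse = " "),
      "\n")
  cat("  noise levels (%):",
      paste(sprintf("%s=%g", state_names(), x$noise$levels),
            collapse = " "), "\n")
  cat("  interventions:", nrow(x$interventions), "event(s)\n")
  if (length(x$override) > 0)
    cat("  pinned traits:", paste(names(x$override), collapse = ", "), "\n")
  if (!is.null(x$alliance))
    cat("  alliance series: length", length(x$alliance), "\n")
  invisible(x)
}

#' Coerce a trajectory to a data.frame
#'
#' @param x an `st_trajectory`.
#' @param row.names,optional unused (S3 signature).
#' @param audit include audit columns (`noise_*`, `int_*`) with the applied
#'   increments.
#' @param ... unused.
#' @return data.frame with columns `t, E, P, M, I, S, a, c, r, m` (plus
#'   audit columns when requested), one row per iteration 0..T.
#' @export
as.data.frame.st_trajectory <- function(x, row.names = NULL,
                                        optional = FALSE, audit = FALSE,
                                        ...) {
  df <- data.frame(t = x$t, x$states, x$traits, check.names = FALSE)
  if (audit) {
    noise <- x$noise_inc; colnames(noise) <- paste0("noise_", state_names())
    int <- x$intervention_inc; colnames(int) <- paste0("int_", state_names())
    df <- cbind(df, as.data.frame(noise), as.data.frame(int))
  }
  rownames(df) <- NULL
  df
}

#' @export
print.st_trajectory <- function(x, ...) {
  TT <- x$scenario$iterations
  cat("State-trait trajectory:", TT, "iterations (+ initial condition)\n")
  cat("  final states:",
      paste(sprintf("%s=%.3f", state_names(), x$states[TT + 1L, ]),
            collapse = " "), "\n")
  cat("  final traits:",
      paste(sprintf("%s=%.3f", trait_names(), x$traits[TT + 1L, ]),
            collapse = " "), "\n")
  invisible(x)
}

#' Summarize a trajectory
#'
#' Per-variable and per-trait means, SDs and ranges over the whole run, plus
#' the net trait change from the initial condition.
#'
#' @param object an `st_trajectory`.
#' @param ... unused.
#' @return a list with data.frames `states` and `traits`, classed for
#'   printing.
#' @export
summary.st_trajectory <- function(object, ...) {
  st <- object$states; tr <- object$traits
  states <- data.frame(
    variable = state_names(),
    mean = colMeans(st), sd = apply(st, 2, stats::sd),
    min = apply(st, 2, min), max = apply(st, 2, max),
    row.names = NULL
  )
  traits <- data.frame(
    parameter = trait_names(),
    initial = tr[1, ], final = tr[nrow(tr), ],
    change = tr[nrow(tr), ] - tr[1, ],
    mean = colMeans(tr),
    row.names = NULL
  )
  structure(list(iterations = object$scenario$iterations,
                 states = states, traits = traits),
            class = "summary.st_trajectory")
}

#' @export
print.summary.st_trajectory <- function(x, ...) {
  cat("Trajectory over", x$iterations, "iterations\n\nStates:\n")
  print(x$states, digits = 4)
  cat("\nTraits:\n")
  print(x$traits, digits = 4)
  invisible(x)
}

#' Plot a trajectory
#'
#' Draws the z-transformed state variables over iterations with the trait
#' parameters overlaid on their natural \[0, 1\] scale (right axis), in the
#' style of the published simulation figures.
#'
#' @param x an `st_trajectory`.
#' @param z z-transform the states for display (default `TRUE`).
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.st_trajectory <- function(x, z = TRUE, ...) {
  st <- x$states
  if (z) st <- apply(st, 2, function(col)
    if (stats::sd(col) == 0) rep(0, length(col)) else z_transform(col))
  state_cols <- c(E = "firebrick", P = "black", M = "darkgreen",
                  I = "purple", S = "orange")
  trait_cols <- c(a = "red", c = "skyblue", r = "navy", m = "green3")
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::matplot(x$t, st, type = "l", lty = 1, col = state_cols,
                    xlab = "iteration (day)",
                    ylab = if (z) "state (z)" else "state", ...)
  graphics::par(new = TRUE)
  graphics::matplot(x$t, x$traits, type = "l", lty = 2, col = trait_cols,
                    ylim = c(0, 1), axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("trait", side = 4, line = 2.5)
  graphics::legend("topright",
                   legend = c(state_names(), trait_names()),
                   col = c(state_cols, trait_cols),
                   lty = c(rep(1, 5), rep(2, 4)), cex = 0.7, bty = "n")
  invisible(x)
}
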