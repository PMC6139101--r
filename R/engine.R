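# Scenario engine: scale mapping of empirical initial values, the
# per-iteration update cycle (state step -> interventions -> noise -> clamp
# -> trait update), trait-override schedules, and trajectory recording.

#' Map empirical initial values to the internal model scale
#'
#' Figure-caption initial values are given on the empirical 100-point scale
#' of the daily process questionnaire (E and S bipolar on \[-100, 100\];
#' P, M, I on \[0, 100\]). Division by 100 maps them to the internal scale.
#'
#' @param empirical named numeric vector over `E, P, M, I, S` on the
#'   empirical scale.
#' @return a state vector on the internal scale.
#' @examples
#' rescale_initial(c(E = 97.6, P = 61.5, M = 7.5, I = 100, S = -40.7))
#' @export
rescale_initial <- function(empirical) {
  x <- empirical
  if (is.null(names(x))) names(x) <- state_names()
  x <- x[state_names()]
  if (any(!is.finite(x)))
    stop("initial values must be finite", call. = FALSE)
  rng <- state_ranges()
  low <- rng$lower * 100; up <- rng$upper * 100
  bad <- x < low | x > up
  if (any(bad))
    stop("initial value out of empirical range for: ",
         paste(state_names()[bad], collapse = ", "), call. = FALSE)
  x / 100
}

#' Intervention schedules
#'
#' An intervention adds a signed number of points of the 100-point empirical
#' scale to one state variable over a range of iterations (inclusive).
#' Punctual interventions have `t_start == t_end`; overlapping events add.
#'
#' @param variable one of `E, P, M, I, S`.
#' @param t_start,t_end first and last iteration (inclusive), `t_start >= 1`.
#' @param magnitude signed percent of the empirical scale (e.g. `+38` adds
#'   0.38 on the internal scale at each active iteration).
#' @return `intervention()` returns a one-row data.frame;
#'   `intervention_schedule()` binds any number of such events (or none)
#'   into a schedule.
#' @examples
#' intervention_schedule(
#'   intervention("S", 17, 17, +38),
#'   intervention("S", 30, 30, +38)
#' )
#' @export
intervention <- function(variable, t_start, t_end, magnitude) {
  if (!variable %in% state_names())
    stop("unknown variable '", variable, "'", call. = FALSE)
  if (!is.finite(t_start) || !is.finite(t_end) || t_start > t_end ||
      t_start < 1)
    stop("need 1 <= t_start <= t_end", call. = FALSE)
  if (!is.finite(magnitude))
    stop("magnitude must be finite", call. = FALSE)
  data.frame(variable = variable, t_start = as.integer(t_start),
             t_end = as.integer(t_end), magnitude = magnitude,
             stringsAsFactors = FALSE)
}

#' @rdname intervention
#' @param ... intervention events (one-row data.frames from
#'   [intervention()]), or a single data.frame with the same columns.
#' @export
intervention_schedule <- function(...) {
  events <- list(...)
  if (length(events) == 1L && is.data.frame(events[[1]]) &&
      nrow(events[[1]]) != 1L) events <- list(events[[1]])
  out <- if (length(events) == 0L) {
    data.frame(variable = character(), t_start = integer(),
               t_end = integer(), magnitude = numeric(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, events)
  }
  stopifnot(identical(names(out),
                      c("variable", "t_start", "t_end", "magnitude")))
  class(out) <- c("st_interventions", "data.frame")
  out
}

#' Apply an intervention schedule at one iteration
#'
#' Adds `magnitude / 100` to each targeted variable for every event active at
#' iteration `t`; iterations with no active event return the state unchanged.
#'
#' @param state state vector on the internal scale.
#' @param schedule an [intervention_schedule()].
#' @param t iteration index (>= 1).
#' @return the shifted state vector (un-clamped).
#' @export
apply_interventions <- function(state, schedule, t) {
  as_state(state) + intervention_increment(schedule, t)
}

intervention_increment <- function(schedule, t) {
  inc <- c(E = 0, P = 0, M = 0, I = 0, S = 0)
  if (is.null(schedule) || nrow(schedule) == 0L) return(inc)
  active <- schedule$t_start <= t & t <= schedule$t_end
  if (any(active)) {
    for (i in which(active))
      inc[[schedule$variable[i]]] <-
        inc[[schedule$variable[i]]] + schedule$magnitude[i] / 100
  }
  inc
}

#' Dynamic-noise specification
#'
#' Per-variable noise levels as percent of the variable's range. At every
#' iteration an independent uniform draw on
#' `[-level/100 * R/2, +level/100 * R/2]` is added to each variable, where
#' `R` is the internal range width (2 for the bipolar `E` and `S`, 1 for
#' `P`, `M`, `I`). A level of 0 leaves the variable untouched, bit-exactly.
#'
#' @param levels percent level(s), scalar or named per-variable vector;
#'   default 0 (no noise).
#' @param distribution currently `"uniform"` only.
#' @return an object of class `st_noise_spec`.
#' @examples
#' noise_spec(30)                          # 30% on every variable
#' noise_spec(c(E = 10, P = 10, M = 5, I = 5, S = 5))
#' @export
noise_spec <- function(levels = 0, distribution = "uniform") {
  levels <- expand_per_variable(levels, "noise levels")
  if (any(levels < 0)) stop("noise levels must be >= 0", call. = FALSE)
  distribution <- match.arg(distribution, "uniform")
  structure(list(levels = levels, distribution = distribution),
            class = "st_noise_spec")
}

#' Apply dynamic noise to a state vector
#'
#' @param state state vector on the internal scale.
#' @param spec a [noise_spec()].
#' @param unit unit draws on \[-1, 1\], one per variable (supplied by the
#'   engine from its seeded per-variable streams; defaults to fresh
#'   `runif(5, -1, 1)` draws).
#' @return the perturbed state vector (un-clamped).
#' @export
apply_noise <- function(state, spec, unit = stats::runif(5, -1, 1)) {
  stopifnot(inherits(spec, "st_noise_spec"))
  as_state(state) + noise_increment(spec, unit)
}

noise_increment <- function(spec, unit) {
  rng <- state_ranges()
  half <- (rng$upper - rng$lower) / 2
  spec$levels / 100 * half * unit
}

#' Clamp a state vector to its internal ranges
#'
#' @param state state vector (finite).
#' @param lower,upper per-variable bounds; default the internal ranges of
#'   [state_ranges()].
#' @return the clipped state vector; idempotent.
#' @export
clamp_states <- function(state, lower = state_ranges()$lower,
                         upper = state_ranges()$upper) {
  pmin(pmax(as_state(state), lower[state_names()]), upper[state_names()])
}

#' Trait-override schedules
#'
#' A trait override pins one parameter to an exogenous piecewise-linear
#' schedule of values versus iteration, disabling its endogenous dynamics.
#' This is how parameter-ramp experiments (order transitions driven by a
#' slow, externally controlled parameter shift) are run.
#'
#' @param ... named arguments, one per pinned parameter (`a`, `c`, `r`,
#'   `m`); each either a single constant value or a data.frame with columns
#'   `t` and `value` defining the breakpoints (linear interpolation between
#'   breakpoints, constant extrapolation beyond them).
#' @return an object of class `st_trait_override` (possibly empty).
#' @examples
#' trait_override(
#'   c = data.frame(t = c(0, 100, 200), value = c(0.60, 0.60, 1.00)),
#'   a = 0.5, r = 0.5, m = 0.5
#' )
#' @export
trait_override <- function(...) {
  sched <- list(...)
  if (length(sched) > 0 &&
      (is.null(names(sched)) || !all(names(sched) %in% trait_names())))
    stop("override names must be trait parameters (a, c, r, m)",
         call. = FALSE)
  for (p in names(sched)) {
    s <- sched[[p]]
    if (is.numeric(s) && length(s) == 1L) {
      s <- data.frame(t = 0, value = s)
    }
    if (!is.data.frame(s) || !all(c("t", "value") %in% names(s)) ||
        nrow(s) < 1L)
      stop("override for '", p,
           "' must be a constant or a data.frame with columns t, value",
           call. = FALSE)
    if (is.unsorted(s$t, strictly = TRUE))
      stop("override breakpoints for '", p,
           "' must have strictly increasing t", call. = FALSE)
    if (any(s$value < 0 | s$value > 1))
      stop("override values for '", p, "' must be in [0, 1]", call. = FALSE)
    sched[[p]] <- s[, c("t", "value")]
  }
  structure(sched, class = "st_trait_override")
}

override_value <- function(override, param, t) {
  s <- override[[param]]
  if (nrow(s) == 1L) return(s$value[1])
  stats::approx(s$t, s$value, xout = t, rule = 2)$y
}

#' Define a simulation scenario
#'
#' A scenario is the complete, reproducible specification of one simulation
#' run: duration, initial states on the empirical 100-point scale, initial
#' traits, filter and trait-update configuration, intervention schedule,
#' noise specification, optional measured alliance series, optional trait
#' overrides, and the master RNG seed.
#'
#' @param iterations number of iterations `T >= 1` (days); the trajectory
#'   additionally records the initial condition at `t = 0`.
#' @param init_states named numeric vector over `E, P, M, I, S` on the
#'   empirical scale (`E`, `S` in \[-100, 100\]; `P`, `M`, `I` in
#'   \[0, 100\]).
#' @param init_traits named numeric vector over `a, c, r, m` in \[0, 1\].
#' @param filter a [filter_config()].
#' @param trait_cfg a [trait_update_config()].
#' @param interventions an [intervention_schedule()].
#' @param noise a [noise_spec()].
#' @param alliance optional numeric vector of measured alliance values `b_t`
#'   in \[0, 1\], of length >= `iterations`.
#' @param override an optional [trait_override()].
#' @param seed master RNG seed (integer).
#' @return an object of class `st_scenario`.
#' @export
scenario <- function(iterations, init_states, init_traits,
                     filter = filter_config(),
                     trait_cfg = trait_update_config(),
                     interventions = intervention_schedule(),
                     noise = noise_spec(0),
                     alliance = NULL,
                     override = trait_override(),
                     seed = 1L) {
  if (!is.numeric(iterations) || length(iterations) != 1L ||
      !is.finite(iterations) || iterations < 1 ||
      iterations != round(iterations))
    stop("iterations must be a single integer >= 1", call. = FALSE)
  init_internal <- rescale_initial(init_states)  # validates ranges
  init_traits <- as_traits(init_traits)
  stopifnot(inherits(filter, "st_filter_config"),
            inherits(trait_cfg, "st_trait_config"),
            inherits(interventions, "st_interventions"),
            inherits(noise, "st_noise_spec"),
            inherits(override, "st_trait_override"))
  if (!is.null(alliance)) {
    if (!is.numeric(alliance) || any(!is.finite(alliance)) ||
        any(alliance < 0 | alliance > 1))
      stop("alliance series must be numeric in [0, 1]", call. = FALSE)
    if (length(alliance) < iterations)
      stop("alliance series must cover all ", iterations, " iterations",
           call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != round(seed))
    stop("seed must be a single integer", call. = FALSE)
  structure(list(
    iterations = as.integer(iterations),
    init_states = init_internal * 100,  # stored on the empirical scale
    init_traits = init_traits,
    filter = filter, trait_cfg = trait_cfg,
    interventions = interventions, noise = noise,
    alliance = alliance, override = override,
    seed = as.integer(seed)
  ), class = "st_scenario")
}

# Seeded, per-variable unit-draw streams: one master seed spawns five
# independent substreams, so changing interventions (which consume no
# randomness) or another variable's level never shifts a variable's draws.
noise_unit_matrix <- function(seed, iterations) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 5L)
  u <- matrix(0, nrow = iterations, ncol = 5,
              dimnames = list(NULL, state_names()))
  for (j in 1:5) {
    set.seed(sub[j])
    u[, j] <- stats::runif(iterations, -1, 1)
  }
  u
}

#' Run a simulation scenario
#'
#' Iterates the full update cycle for `t = 1..T`: (1) one synchronous step
#' of the five state equations under the current traits; (2) intervention
#' shifts; (3) dynamic noise; (4) clamping to the internal ranges; (5) from
#' the first iteration with a full state window onward, the synchronous
#' trait update from the trailing window (traits are frozen during the
#' warm-up, and parameters pinned by an override follow their schedule
#' verbatim at every iteration). Identical scenarios (including the seed)
#' yield bit-identical trajectories.
#'
#' @param sc an [scenario()] (or a preset from [preset_scenario()]).
#' @return an object of class `st_trajectory`: a list with the iteration
#'   index `t` (0..T), `states` and `traits` matrices (T+1 rows), audit
#'   matrices `noise_inc` and `intervention_inc` of applied increments, and
#'   the scenario itself.
#' @examples
#' traj <- run_scenario(preset_scenario("fig6a"))
#' summary(traj)
#' @export
run_scenario <- function(sc) {
  stopifnot(inherits(sc, "st_scenario"))
  TT <- sc$iterations
  n <- sc$filter$n
  vars <- state_names(); prm <- trait_names()

  states <- matrix(NA_real_, nrow = TT + 1L, ncol = 5,
                   dimnames = list(NULL, vars))
  traits <- matrix(NA_real_, nrow = TT + 1L, ncol = 4,
                   dimnames = list(NULL, prm))
  noise_inc <- matrix(0, nrow = TT + 1L, ncol = 5,
                      dimnames = list(NULL, vars))
  int_inc <- matrix(0, nrow = TT + 1L, ncol = 5,
                    dimnames = list(NULL, vars))

  s <- rescale_initial(sc$init_states)
  tr <- sc$init_traits
  pinned <- names(sc$override)
  for (p in pinned) tr[[p]] <- override_value(sc$override, p, 0)
  states[1L, ] <- s
  traits[1L, ] <- tr

  unit <- noise_unit_matrix(sc$seed, TT)

  for (t in seq_len(TT)) {
    s_new <- tryCatch(step_states(s, tr), error = function(e)
      stop("iteration ", t, ": ", conditionMessage(e), call. = FALSE))
    di <- intervention_increment(sc$interventions, t)
    dn <- noise_increment(sc$noise, unit[t, ])
    s <- clamp_states(s_new + di + dn)
    states[t + 1L, ] <- s
    int_inc[t + 1L, ] <- di
    noise_inc[t + 1L, ] <- dn

    if (t >= n && length(pinned) < 4L) {
      win <- states[(t - n + 2L):(t + 1L), , drop = FALSE]
      b_t <- if (!is.null(sc$alliance)) sc$alliance[t] else NULL
      tr <- update_traits(tr, win, sc$filter, sc$trait_cfg, b_t)
    }
    for (p in pinned) tr[[p]] <- override_value(sc$override, p, t)
    traits[t + 1L, ] <- tr
  }

  structure(list(
    t = 0:TT, states = states, traits = traits,
    noise_inc = noise_inc, intervention_inc = int_inc,
    scenario = sc
  ), class = "st_trajectory")
}

#' Replay a trajectory from its audit record
#'
#' Re-applies the recorded intervention and noise increments to the pure
#' state map, starting from the initial condition, and checks that the raw
#' trajectory is reproduced exactly.
#'
#' @param traj an `st_trajectory`.
#' @return `TRUE` invisibly if the replayed states match bit-exactly;
#'   otherwise an error.
#' @export
replay_trajectory <- function(traj) {
  stopifnot(inherits(traj, "st_trajectory"))
  sc <- traj$scenario
  TT <- sc$iterations
  s <- rescale_initial(sc$init_states)
  for (t in seq_len(TT)) {
    tr <- traj$traits[t, ]
    s <- clamp_states(step_states(s, tr) + traj$intervention_inc[t + 1L, ] +
                        traj$noise_inc[t + 1L, ])
    if (!identical(unname(s), unname(traj$states[t + 1L, ])))
      stop("replay diverged at iteration ", t, call. = FALSE)
  }
  invisible(TRUE)
}
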