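# Serialization: scenario config files (YAML), trajectory CSVs with full
# precision, alliance series CSVs, and run manifests for bit-exact replay.

scenario_to_list <- function(sc) {
  stopifnot(inherits(sc, "st_scenario"))
  out <- list(
    iterations = sc$iterations,
    init_states = as.list(sc$init_states),
    init_traits = as.list(sc$init_traits),
    filter = list(n = sc$filter$n, tau = as.list(sc$filter$tau),
                  lambda = as.list(sc$filter$lambda),
                  d = as.list(sc$filter$d)),
    trait_cfg = list(w = as.list(sc$trait_cfg$w),
                     p_min = as.list(sc$trait_cfg$p_min),
                     p_max = as.list(sc$trait_cfg$p_max),
                     gate_low = sc$trait_cfg$gate_low,
                     gate_high = sc$trait_cfg$gate_high,
                     literal_low_gate = sc$trait_cfg$literal_low_gate),
    noise = list(levels = as.list(sc$noise$levels),
                 distribution = sc$noise$distribution),
    interventions = if (nrow(sc$interventions) == 0L) list() else
      lapply(seq_len(nrow(sc$interventions)), function(i)
        as.list(sc$interventions[i, ])),
    override = lapply(unclass(sc$override), function(s)
      list(t = s$t, value = s$value)),
    alliance = if (is.null(sc$alliance)) NULL else as.numeric(sc$alliance),
    seed = sc$seed
  )
  out
}

scenario_from_list <- function(x) {
  need <- c("iterations", "init_states", "init_traits", "seed")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("scenario config is missing required field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  fl <- x$filter
  filter <- if (is.null(fl)) filter_config() else
    filter_config(n = fl$n %||% 14, tau = unlist(fl$tau) %||% 7,
                  d = unlist(fl$d) %||% 0.535,
                  lambda = if (is.null(fl$lambda)) NULL else unlist(fl$lambda))
  tc <- x$trait_cfg
  trait_cfg <- if (is.null(tc)) trait_update_config() else
    trait_update_config(
      w = unlist(tc$w) %||% 0.004167,
      p_min = unlist(tc$p_min) %||% 0.1, p_max = unlist(tc$p_max) %||% 0.8,
      gate_low = tc$gate_low %||% 0.2, gate_high = tc$gate_high %||% 0.8,
      literal_low_gate = tc$literal_low_gate %||% TRUE)
  ns <- x$noise
  noise <- if (is.null(ns)) noise_spec(0) else
    noise_spec(unlist(ns$levels) %||% 0, ns$distribution %||% "uniform")
  iv <- x$interventions
  interventions <- if (is.null(iv) || length(iv) == 0L)
    intervention_schedule()
  else do.call(intervention_schedule, lapply(iv, function(e)
    intervention(e$variable, e$t_start, e$t_end, e$magnitude)))
  ov <- x$override
  override <- if (is.null(ov) || length(ov) == 0L) trait_override() else
    do.call(trait_override, lapply(ov, function(s)
      data.frame(t = unlist(s$t), value = unlist(s$value))))
  scenario(
    iterations = x$iterations,
    init_states = unlist(x$init_states),
    init_traits = unlist(x$init_traits),
    filter = filter, trait_cfg = trait_cfg,
    interventions = interventions, noise = noise,
    alliance = if (is.null(x$alliance)) NULL else unlist(x$alliance),
    override = override,
    seed = x$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write scenario configuration files
#'
#' Scenarios are serialized as a flat, hand-editable YAML file (keys and an
#' intervention event list). `read_scenario(write_scenario(sc))` returns an
#' equal scenario.
#'
#' @param path file path.
#' @param sc an [scenario()].
#' @return `read_scenario()` returns an `st_scenario`; `write_scenario()`
#'   the path, invisibly.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("malformed scenario config '", path, "': ", conditionMessage(e),
         call. = FALSE))
  scenario_from_list(x)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(sc, path) {
  yaml::write_yaml(scenario_to_list(sc), path, precision = 17)
  invisible(path)
}

#' Read and write trajectory CSVs
#'
#' The trajectory CSV has the header `t,E,P,M,I,S,a,c,r,m` and, when
#' `audit = TRUE`, additional per-variable audit columns with the applied
#' noise and intervention increments. Values are written in scientific
#' notation with 17 significant digits, so round-trips preserve doubles
#' exactly.
#'
#' @param traj an `st_trajectory`.
#' @param path file path.
#' @param audit include audit increment columns (default `TRUE`).
#' @return `write_trajectory()` returns the path invisibly;
#'   `read_trajectory()` a data.frame.
#' @export
write_trajectory <- function(traj, path, audit = TRUE) {
  df <- as.data.frame(traj, audit = audit)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "t"
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", state_names(), trait_names())
  if (!all(need %in% names(df)))
    stop("trajectory file lacks required columns ",
         paste(need, collapse = ","), call. = FALSE)
  num <- setdiff(names(df), "t")
  df[num] <- lapply(df[num], as.numeric)  # "1" parses as integer otherwise
  df
}

#' Read an alliance series from a single-column CSV
#'
#' Values may be on the \[0, 1\] scale or on the empirical 0--100 scale; the
#' scale is auto-detected (maximum > 1 means percent) and the decision is
#' reported in a message.
#'
#' @param path file path (one column, with or without a header).
#' @return numeric vector in \[0, 1\].
#' @export
read_alliance <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(first)))
  df <- utils::read.csv(path, header = has_header,
                        stringsAsFactors = FALSE)
  b <- as.numeric(df[[1]])
  if (any(!is.finite(b)))
    stop("alliance series contains non-numeric values", call. = FALSE)
  if (max(b) > 1) {
    message("alliance series read on the 0-100 scale; divided by 100")
    b <- b / 100
  }
  if (any(b < 0 | b > 1))
    stop("alliance values must lie in [0, 1] (or [0, 100])", call. = FALSE)
  b
}

declared_conventions <- function() {
  list(
    noise_model = "additive uniform on [-level/100 * range/2, +level/100 * range/2]",
    intervention_model = "additive shift of magnitude/100 internal units",
    decay_indexing = "sample age: weight exp(-lambda * (n - i)), newest = 1",
    delta_interpretation = "pre-saturation raw increment w * base * driver",
    alliance_substitution = "mixed value replaces a_{t-1} throughout the alliance update",
    warmup = "traits frozen until the state window is full",
    z_scores = "whole series, sample (n-1) SD",
    smoothing_edges = "truncated windows"
  )
}

#' Write a simulation run (trajectory + manifest) to a directory
#'
#' Writes `trajectory.csv` and a paired `manifest.json` holding the full
#' scenario, its hash, the seed, the package version and the declared
#' modelling conventions. [replay_manifest()] re-runs the manifest and
#' checks that the stored trajectory is reproduced bit-exactly.
#'
#' @param traj an `st_trajectory`.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_run <- function(traj, dir) {
  stopifnot(inherits(traj, "st_trajectory"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traj_path <- file.path(dir, "trajectory.csv")
  write_trajectory(traj, traj_path)
  sc_list <- scenario_to_list(traj$scenario)
  tmp <- tempfile()
  yaml::write_yaml(sc_list, tmp, precision = 17)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(
    package = "statetrait",
    version = as.character(utils::packageVersion("statetrait")),
    created = format(Sys.time(), tz = "UTC"),
    seed = traj$scenario$seed,
    scenario_hash = hash,
    conventions = declared_conventions(),
    scenario = sc_list
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_run
#' @param path path to a `manifest.json` written by [write_run()].
#' @param check compare against the stored `trajectory.csv` next to the
#'   manifest (default `TRUE`).
#' @export
replay_manifest <- function(path, check = TRUE) {
  m <- jsonlite::read_json(path)
  sc <- scenario_from_list(m$scenario)
  traj <- run_scenario(sc)
  if (check) {
    stored <- file.path(dirname(path), "trajectory.csv")
    if (file.exists(stored)) {
      old <- read_trajectory(stored)
      new <- as.data.frame(traj, audit = TRUE)
      if (!isTRUE(all.equal(old, new, tolerance = 0)))
        stop("replayed trajectory differs from the stored one",
             call. = FALSE)
    }
  }
  traj
}

#' Synthesize a therapeutic-alliance series
#'
#' Generates a synthetic stand-in for the daily alliance ratings `b_t`
#' (constant level, linear trend, or a logistic alliance-building curve),
#' with optional Gaussian measurement noise, clipped to \[0, 1\].
#'
#' @param iterations series length `T >= 1`.
#' @param shape one of `"constant"`, `"linear"`, `"logistic"`.
#' @param level base level for `"constant"` (default 0.5); `"linear"` rises
#'   from `from` to `to`; `"logistic"` rises from `from` to `to` with
#'   midpoint at `iterations/2`.
#' @param from,to start and end levels for the trend shapes.
#' @param noise_sd standard deviation of additive Gaussian noise (0 = none).
#' @param seed RNG seed.
#' @return numeric vector of length `iterations`, values in \[0, 1\].
#' @examples
#' synth_alliance(10, "constant", level = 0.5)
#' @export
synth_alliance <- function(iterations, shape = c("logistic", "constant",
                                                 "linear"),
                           level = 0.5, from = 0.2, to = 0.8,
                           noise_sd = 0, seed = 1L) {
  if (!is.numeric(iterations) || length(iterations) != 1L ||
      iterations < 1 || iterations != round(iterations))
    stop("iterations must be a single integer >= 1", call. = FALSE)
  shape <- match.arg(shape)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  tt <- seq_len(iterations)
  base <- switch(shape,
    constant = rep(level, iterations),
    linear = if (iterations == 1L) from else
      from + (to - from) * (tt - 1) / (iterations - 1),
    logistic = from + (to - from) /
      (1 + exp(-10 * (tt - iterations / 2) / iterations))
  )
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    base <- base + stats::rnorm(iterations, 0, noise_sd)
  }
  pmin(pmax(base, 0), 1)
}
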