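# Preset scenarios encoding the published simulation experiments: initial
# values, trait levels, noise levels and intervention windows as printed in
# the figure captions; durations and the ramp-experiment settings are
# documented package choices (see the methods vignette).

preset_names <- function() {
  c("fig3", "fig5", "fig6a", "fig6b", "fig7", "fig8", "fig9")
}

# the recurring empirical starting profile of the simulation experiments
.init_case <- c(E = 97.6, P = 61.5, M = 7.5, I = 100, S = -40.7)

#' Preset simulation scenarios
#'
#' Named, ready-to-run scenarios for the published simulation experiments:
#'
#' \describe{
#'   \item{fig3}{Order-transition ramp experiment: all four traits pinned
#'     (endogenous trait dynamics disabled); the competence parameter c held
#'     at 0.60 up to iteration 100, ramped linearly to 1.00 over iterations
#'     100--200, and held at 1.00 afterwards; 400 iterations.}
#'   \item{fig5}{Noise-driven order transition: 30% dynamic noise on all
#'     variables, traits starting at 0.30, a multiple intervention
#'     (+20 points on M, I, S and -20 on E, P) over iterations 50--60.}
#'   \item{fig6a}{Punctual interventions on S (+38 points) at iterations 17,
#'     30 and 50; 10% noise.}
#'   \item{fig6b}{Continuous intervention on S (+38 points) over iterations
#'     17--25; otherwise as fig6a.}
#'   \item{fig7}{Noise-only run (10% on E and P, 5% on M, I, S); different
#'     seeds give the two published realizations.}
#'   \item{fig8}{Sustained interventions with rebound: -10 on E and P and +5
#'     on M from iteration 20, +10 on I and S from iteration 25; all end at
#'     iteration 100 except E, which continues to 200; 2% noise; traits
#'     0.20.}
#'   \item{fig9}{Day-clinic case schedule: -10 on P, +10 on M and S over
#'     iterations 35--100; -10 on E and +10 on I over iterations 35--50;
#'     noise 2% on E, P and 5% on M, I, S; 108 iterations. A measured
#'     alliance series can be attached via the `alliance` field (see
#'     [synth_alliance()] for a synthetic stand-in).}
#' }
#'
#' @param name preset name, one of `fig3, fig5, fig6a, fig6b, fig7, fig8,
#'   fig9`.
#' @param seed master RNG seed for the run (default 1).
#' @return an [scenario()] object.
#' @examples
#' preset_scenario("fig6a")
#' @export
preset_scenario <- function(name, seed = 1L) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% preset_names())
    stop("unknown preset '", name, "'; available presets: ",
         paste(preset_names(), collapse = ", "), call. = FALSE)

  init6 <- c(E = 100, P = 79, M = 32.5, I = 50, S = 33.5)
  traits6 <- c(a = 0.10, c = 0.35, r = 0.35, m = 0.10)

  switch(name,
    fig3 = scenario(
      iterations = 400,
      init_states = .init_case,
      init_traits = c(a = 0.5, c = 0.6, r = 0.7, m = 0.35),
      noise = noise_spec(5),
      override = trait_override(
        c = data.frame(t = c(0, 100, 200), value = c(0.60, 0.60, 1.00)),
        a = 0.5, r = 0.7, m = 0.35
      ),
      seed = seed
    ),
    fig5 = scenario(
      iterations = 150,
      init_states = .init_case,
      init_traits = c(a = 0.30, c = 0.30, r = 0.30, m = 0.30),
      noise = noise_spec(30),
      interventions = intervention_schedule(
        intervention("M", 50, 60, +20),
        intervention("I", 50, 60, +20),
        intervention("S", 50, 60, +20),
        intervention("E", 50, 60, -20),
        intervention("P", 50, 60, -20)
      ),
      seed = seed
    ),
    fig6a = scenario(
      iterations = 100,
      init_states = init6,
      init_traits = traits6,
      noise = noise_spec(10),
      interventions = intervention_schedule(
        intervention("S", 17, 17, +38),
        intervention("S", 30, 30, +38),
        intervention("S", 50, 50, +38)
      ),
      seed = seed
    ),
    fig6b = scenario(
      iterations = 100,
      init_states = init6,
      init_traits = traits6,
      noise = noise_spec(10),
      interventions = intervention_schedule(
        intervention("S", 17, 25, +38)
      ),
      seed = seed
    ),
    fig7 = scenario(
      iterations = 150,
      init_states = .init_case,
      init_traits = c(a = 0.10, c = 0.75, r = 0.46, m = 0.53),
      noise = noise_spec(c(E = 10, P = 10, M = 5, I = 5, S = 5)),
      seed = seed
    ),
    fig8 = scenario(
      iterations = 300,
      init_states = .init_case,
      init_traits = c(a = 0.20, c = 0.20, r = 0.20, m = 0.20),
      noise = noise_spec(2),
      interventions = intervention_schedule(
        intervention("E", 20, 200, -10),
        intervention("P", 20, 100, -10),
        intervention("M", 20, 100, +5),
        intervention("I", 25, 100, +10),
        intervention("S", 25, 100, +10)
      ),
      seed = seed
    ),
    fig9 = scenario(
      iterations = 108,
      init_states = c(E = 100, P = 79, M = 32.5, I = 50, S = 1),
      init_traits = c(a = 0.10, c = 0.60, r = 0.35, m = 0.10),
      noise = noise_spec(c(E = 2, P = 2, M = 5, I = 5, S = 5)),
      interventions = intervention_schedule(
        intervention("P", 35, 100, -10),
        intervention("M", 35, 100, +10),
        intervention("S", 35, 100, +10),
        intervention("E", 35, 50, -10),
        intervention("I", 35, 50, +10)
      ),
      seed = seed
    )
  )
}
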