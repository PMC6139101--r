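# Core state equations: five coupled nonlinear difference equations for the
# order parameters E (emotions), P (problem intensity), M (motivation to
# change), I (insight) and S (therapeutic success), modulated by the four
# control parameters a, c, r, m.

#' Names and internal ranges of the state variables
#'
#' The five state variables live on an internal, dimensionless scale:
#' `E` (bipolar emotion intensity) and `S` (therapeutic success) on
#' \[-1, 1\], `P` (problem/symptom intensity), `M` (state motivation to
#' change) and `I` (insight) on \[0, 1\]. One iteration corresponds to one
#' day (one daily self-rating).
#'
#' @return `state_names()` returns the character vector `c("E","P","M","I","S")`;
#'   `state_ranges()` a list with numeric vectors `lower` and `upper` named
#'   by variable.
#' @export
state_names <- function() c("E", "P", "M", "I", "S")

#' @rdname state_names
#' @export
state_ranges <- function() {
  list(
    lower = c(E = -1, P = 0, M = 0, I = 0, S = -1),
    upper = c(E =  1, P = 1, M = 1, I = 1, S =  1)
  )
}

#' @rdname state_names
#' @export
trait_names <- function() c("a", "c", "r", "m")

#' Construct a state vector
#'
#' A state vector holds the five order-parameter values at one iteration on
#' the internal model scale (see [state_ranges()]). The constructor validates
#' finiteness and returns a named numeric vector in canonical order
#' `E, P, M, I, S`.
#'
#' @param E,P,M,I,S numeric scalars on the internal scale.
#' @return named numeric vector of length 5.
#' @examples
#' state_vector(E = 0.976, P = 0.615, M = 0.075, I = 1, S = -0.407)
#' @export
state_vector <- function(E, P, M, I, S) {
  x <- c(E = E, P = P, M = M, I = I, S = S)
  if (!is.numeric(x) || length(x) != 5L || !all(is.finite(x)))
    stop("state variables must be finite numeric scalars", call. = FALSE)
  x
}

#' Construct a trait vector
#'
#' The four control parameters: `a` (alliance/attachment disposition),
#' `c` (cognitive and emotion-regulation competencies), `r` (behavioral
#' resources) and `m` (trait motivation / self-efficacy), each confined to
#' \[0, 1\].
#'
#' @param a,c,r,m numeric scalars in \[0, 1\].
#' @return named numeric vector of length 4 in order `a, c, r, m`.
#' @examples
#' trait_vector(a = 0.1, c = 0.35, r = 0.35, m = 0.1)
#' @export
trait_vector <- function(a, c, r, m) {
  x <- c(a = a, c = c, r = r, m = m)
  if (!is.numeric(x) || length(x) != 4L || !all(is.finite(x)))
    stop("trait parameters must be finite numeric scalars", call. = FALSE)
  if (any(x < 0 | x > 1))
    stop("trait parameters must lie in [0, 1]", call. = FALSE)
  x
}

as_state <- function(x) {
  if (is.null(names(x))) names(x) <- state_names()
  x <- x[state_names()]
  if (any(!is.finite(x))) stop("non-finite state value", call. = FALSE)
  x
}

as_traits <- function(x) {
  if (is.null(names(x))) names(x) <- trait_names()
  x <- x[trait_names()]
  if (any(!is.finite(x)) || any(x < 0 | x > 1))
    stop("traits must be finite and in [0, 1]", call. = FALSE)
  x
}

#' Falling logistic building block
#'
#' Every sigmoid term of the state equations has the form `1/(1 + exp(u))`,
#' a strictly decreasing logistic in the exponent `u` with range (0, 1).
#'
#' @param u numeric (finite); vectorized.
#' @return `1/(1 + exp(u))`.
#' @examples
#' sig(0)   # 0.5
#' sig(-5)  # close to 1
#' @export
sig <- function(u) {
  if (!is.numeric(u) || any(!is.finite(u)))
    stop("sig(): exponent must be finite numeric", call. = FALSE)
  1 / (1 + exp(u))
}

#' Literal constants of the five state equations
#'
#' A flat audit table of every numeric literal appearing in the five coupled
#' equations, keyed by equation and term. The table is a record of the
#' implemented values (including the unrounded `1.261` scale factor of the
#' motivation equation); it is not meant to be edited.
#'
#' @return a data.frame with columns `equation`, `term`, `constant`, `value`.
#' @export
equation_constants <- function() {
  tab <- rbind(
    c("E", "E<-E", "sigmoid gain",        -10),
    c("E", "E<-E", "competence offset",    -1),    # coefficient of c
    c("E", "E<-I", "sigmoid gain",        -20),
    c("E", "E<-I", "sigmoid offset",        5),
    c("E", "E<-P", "numerator gain base",   2),
    c("E", "E<-P", "numerator gain slope",  3),
    c("E", "E<-P", "numerator offset",      0.5),
    c("E", "E<-P", "numerator trait scale", 0.5),
    c("E", "E<-P", "denominator gain",     25),
    c("E", "E<-P", "threshold base",        0.2),
    c("E", "E<-P", "threshold trait scale", 0.75),
    c("E", "E<-S", "scale",                 1.25),
    c("E", "E<-S", "sigmoid gain",          5),
    c("E", "E<-S", "sigmoid offset",       -0.5),
    c("E", "E<-S", "offset",               -0.5),
    c("E", "E<-S", "trait offset scale",   -0.5),  # coefficient of m
    c("I", "I<-E", "sigmoid gain",        -20),
    c("I", "I<-E", "sigmoid offset",        5),
    c("I", "I<-M", "sigmoid gain",        -20),
    c("I", "I<-M", "sigmoid offset",        5),
    c("I", "I<-S", "sigmoid gain",        -20),
    c("I", "I<-S", "sigmoid offset",        5),
    c("M", "M<-P", "scale",                 1.261),
    c("M", "M<-P", "threshold base",        0.05),
    c("M", "M<-P", "threshold trait scale", 0.85),
    c("M", "M<-P", "gain base",            10.1),
    c("M", "M<-P", "gain trait slope",     19.9),
    c("M", "M<-P", "gate threshold base",   0.43),
    c("M", "M<-P", "gate threshold slope",  0.03),
    c("M", "M<-P", "gate gain base",        7),
    c("M", "M<-P", "gate gain slope",      -3),
    c("M", "M<-S", "scale",                -1),
    c("M", "M<-S", "sigmoid gain",          5),
    c("M", "M<-rm", "mean weight",          0.5),
    c("P", "P<-E", "sigmoid gain",        -10),
    c("P", "P<-c", "coefficient",          -1),
    c("P", "P<-S", "scale",                 1.2),
    c("P", "P<-S", "sigmoid gain",          5),
    c("P", "P<-S", "sigmoid offset",       -0.5),
    c("P", "P<-const", "offset",           -0.2),
    c("P", "P<-r", "coefficient",          -0.8),
    c("S", "S<-E", "scale",                 1.3),
    c("S", "S<-E", "sigmoid gain",          5),
    c("S", "S<-E", "sigmoid offset",       -0.5),
    c("S", "S<-E", "offset",               -0.65),
    c("S", "S<-E", "trait offset scale",    0.35),
    c("S", "S<-I", "sigmoid gain",        -20),
    c("S", "S<-I", "sigmoid offset",        5),
    c("S", "S<-M+", "sigmoid gain",       -20),
    c("S", "S<-M+", "sigmoid offset",       5),
    c("S", "S<-M-", "sigmoid gain",        20),
    c("S", "S<-M-", "sigmoid offset",       5),
    c("S", "S<-P", "scale",                 1.25),
    c("S", "S<-P", "sigmoid gain",          5),
    c("S", "S<-P", "sigmoid offset",       -0.5),
    c("S", "S<-P", "offset",               -0.5),
    c("S", "S<-P", "trait offset scale",   -0.5),
    c("S", "S<-S", "sigmoid gain",        -10),
    c("S", "S<-mr", "mean weight",          0.5),
    c("S", "S<-mr", "offset",              -1)
  )
  data.frame(
    equation = tab[, 1], term = tab[, 2], constant = tab[, 3],
    value = as.numeric(tab[, 4]), stringsAsFactors = FALSE
  )
}

#' Evaluate the individual terms of one state equation
#'
#' Returns each additive term of the requested equation (the motivation
#' equation's leading product of two sigmoids is composed into a single
#' multiplicative term-group, `M<-P`), labelled by its source interaction.
#' The sum of the returned terms equals [eval_state()] on the same input.
#'
#' Grouping follows the printed form of each equation: constant and trait
#' offsets that belong to a sigmoid are folded into its term (e.g. the
#' success term of the emotion equation is
#' `1.25/(1 + exp(5S - 0.5)) - 0.5 - 0.5 m`), while the problem-intensity
#' equation is returned as its five printed atoms.
#'
#' @param equation one of `"E"`, `"P"`, `"M"`, `"I"`, `"S"`.
#' @param state named numeric state vector (see [state_vector()]).
#' @param traits named numeric trait vector (see [trait_vector()]).
#' @return named numeric vector of term values.
#' @examples
#' st <- state_vector(E = 0, P = 0, M = 0, I = 0, S = 0.1)
#' tr <- trait_vector(a = 0.5, c = 0.5, r = 0.5, m = 0)
#' eval_state_terms("E", st, tr)
#' @export
eval_state_terms <- function(equation, state, traits) {
  state <- as_state(state)
  traits <- as_traits(traits)
  .eval_terms(equation, state, traits)
}

# unvalidated term evaluation shared by the user-facing accessors and the
# engine hot path
.eval_terms <- function(equation, state, traits) {
  E <- state[["E"]]; P <- state[["P"]]; M <- state[["M"]]
  I <- state[["I"]]; S <- state[["S"]]
  a <- traits[["a"]]; cc <- traits[["c"]]; r <- traits[["r"]]; m <- traits[["m"]]

  terms <- switch(equation,
    E = {
      cm <- 1 - (cc + m) / 2                 # competence deficit, in [0, 1]
      c("E<-E" = sig(-10 * E) - cc,
        "E<-I" = sig(-20 * I * (1 - (cc + r) / 2) + 5),
        "E<-P" = (-sig((2 + 3 * cm) * P) + 0.5 + 0.5 * cm) /
                 (1 + exp(25 * cm * (P - 0.2 - 0.75 * cm))),
        "E<-S" = 1.25 * sig(5 * S - 0.5) - 0.5 - 0.5 * m)
    },
    I = {
      ac <- (a + cc) / 2
      c("I<-E" = sig(-20 * E * ac + 5),
        "I<-M" = sig(-20 * M * ac + 5),
        "I<-S" = sig(-20 * abs(S) * cc + 5))
    },
    M = {
      c("M<-P"  = 1.261 * sig((P - 0.05 - 0.85 * m) * (10.1 + 19.9 * m)) *
                  sig(-(P - 0.43 + 0.03 * m) * (7 - 3 * m)),
        "M<-S"  = -sig(5 * S),
        "M<-rm" = (r + m) / 2)
    },
    P = {
      c("P<-E"     = sig(-10 * E),
        "P<-c"     = -cc,
        "P<-S"     = 1.2 * sig(5 * S - 0.5),
        "P<-const" = -0.2,
        "P<-r"     = -0.8 * r)
    },
    S = {
      amr <- (a + m + r) / 3
      c("S<-E"  = 1.3 * sig(5 * E - 0.5) - 0.65 + 0.35 * (cc + m - 1),
        "S<-I"  = sig(-20 * I * amr + 5),
        "S<-M+" = sig(-20 * M * amr + 5),
        "S<-M-" = -sig(20 * M * (1 - amr) + 5),
        "S<-P"  = 1.25 * sig(5 * P - 0.5) - 0.5 - 0.5 * (1 - (cc + m) / 2),
        "S<-S"  = sig(-10 * S),
        "S<-mr" = (m + r) / 2 - 1)
    },
    stop("unknown equation '", equation, "'; must be one of E, P, M, I, S",
         call. = FALSE)
  )
  terms
}

#' Evaluate the right-hand side of one state equation
#'
#' @inheritParams eval_state_terms
#' @return the new value of the requested variable (un-clamped).
#' @seealso [eval_state_terms()] for the individual contributions,
#'   [step_states()] for the full synchronous map.
#' @export
eval_state <- function(equation, state, traits) {
  sum(eval_state_terms(equation, state, traits))
}

#' One synchronous step of the five coupled state equations
#'
#' All five equations read only the input state (the previous iteration);
#' no equation sees another variable's freshly computed value. The map is
#' pure and deterministic: no clamping, noise or intervention is applied
#' here (that is the engine's job, see [run_scenario()]).
#'
#' @inheritParams eval_state_terms
#' @return named numeric vector: the un-clamped state at the next iteration.
#' @examples
#' st <- state_vector(E = 0.3, P = 0.6, M = 0.2, I = 0.4, S = -0.2)
#' tr <- trait_vector(a = 0.4, c = 0.5, r = 0.4, m = 0.3)
#' step_states(st, tr)
#' @export
step_states <- function(state, traits) {
  state <- as_state(state)
  traits <- as_traits(traits)
  out <- c(E = sum(.eval_terms("E", state, traits)),
           P = sum(.eval_terms("P", state, traits)),
           M = sum(.eval_terms("M", state, traits)),
           I = sum(.eval_terms("I", state, traits)),
           S = sum(.eval_terms("S", state, traits)))
  bad <- !is.finite(out)
  if (any(bad))
    stop("non-finite value in equation(s): ",
         paste(state_names()[bad], collapse = ", "), call. = FALSE)
  out
}
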