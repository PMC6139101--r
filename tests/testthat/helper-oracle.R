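# Independent transcription oracles. These re-derive the model from the
# published closed forms, term by term, on purpose WITHOUT using any
# package building block (no sig(), no filter_value(), ...), so that they
# stay an independent route against which the implementation is checked.

oracle_E <- function(E, P, M, I, S, a, c, r, m) {
  1 / (1 + exp(-10 * E)) - c +
    1 / (1 + exp(-20 * I * (1 - (c + r) / 2) + 5)) +
    (-1 / (1 + exp((2 + 3 * (1 - (c + m) / 2)) * P)) +
       0.5 + 0.5 * (1 - (c + m) / 2)) /
      (1 + exp(25 * (1 - (c + m) / 2) *
                 (P - 0.2 - 0.75 * (1 - (c + m) / 2)))) +
    1.25 / (1 + exp(5 * S - 0.5)) - 0.5 - 0.5 * m
}

oracle_I <- function(E, P, M, I, S, a, c, r, m) {
  1 / (1 + exp(-20 * E * (a + c) / 2 + 5)) +
    1 / (1 + exp(-20 * M * (a + c) / 2 + 5)) +
    1 / (1 + exp(-20 * abs(S) * c + 5))
}

oracle_M <- function(E, P, M, I, S, a, c, r, m) {
  1.261 / (1 + exp((P - 0.05 - 0.85 * m) * (10.1 + 19.9 * m))) *
    1 / (1 + exp(-(P - 0.43 + 0.03 * m) * (7 - 3 * m))) -
    1 / (1 + exp(5 * S)) + (r + m) / 2
}

oracle_P <- function(E, P, M, I, S, a, c, r, m) {
  1 / (1 + exp(-10 * E)) - c + 1.2 / (1 + exp(5 * S - 0.5)) -
    0.2 - 0.8 * r
}

oracle_S <- function(E, P, M, I, S, a, c, r, m) {
  1.3 / (1 + exp(5 * E - 0.5)) - 0.65 + 0.35 * (c + m - 1) +
    1 / (1 + exp(-20 * I * (a + m + r) / 3 + 5)) +
    1 / (1 + exp(-20 * M * (a + m + r) / 3 + 5)) -
    1 / (1 + exp(20 * M * (1 - (a + m + r) / 3) + 5)) +
    1.25 / (1 + exp(5 * P - 0.5)) - 0.5 - 0.5 * (1 - (c + m) / 2) +
    1 / (1 + exp(-10 * S)) + (m + r) / 2 - 1
}

oracle_step <- function(state, traits) {
  args <- c(as.list(state[c("E", "P", "M", "I", "S")]),
            as.list(traits[c("a", "c", "r", "m")]))
  c(E = do.call(oracle_E, args), P = do.call(oracle_P, args),
    M = do.call(oracle_M, args), I = do.call(oracle_I, args),
    S = do.call(oracle_S, args))
}

# Filter: d * sum over i of (x_i - window mean) * exp(-lambda * age_i),
# age 0 for the newest sample (i = n) up to n-1 for the oldest (i = 1).
oracle_filter <- function(x, d, lam) {
  n <- length(x)
  acc <- 0
  for (i in seq_len(n)) acc <- acc + (x[i] - mean(x)) * exp(-lam * (n - i))
  d * acc
}

# Trait update, Eqs. (1)-(8): drivers, raw increment, sign-gated saturation,
# threshold gating, alliance mixing (mixed value substituted throughout).
oracle_update_traits <- function(traits, win, n, tau, d, w,
                                 pmin, pmax, glo, ghi, b = NULL) {
  lam <- log(2) / tau
  f <- sapply(c("E", "P", "M", "I", "S"),
              function(v) oracle_filter(win[, v], d, lam))
  drv <- c(
    a = (f[["S"]] - f[["E"]]) / 2,
    c = (f[["I"]] + f[["S"]] + traits[["r"]]) / 3,
    r = (f[["S"]] + traits[["c"]]) / 2,
    m = (-f[["E"]] - f[["P"]] + f[["M"]] + f[["S"]]) / 4
  )
  k <- pmax - pmin
  out <- traits
  for (p in c("a", "c", "r", "m")) {
    prev <- if (p == "a" && !is.null(b)) (traits[["a"]] + b) / 2
            else traits[[p]]
    delta <- w * prev * drv[[p]]
    sstar <- k * delta * ((1 + sign(delta)) / 2 * (pmax - prev) +
                          (1 - sign(delta)) / 2 * (prev - pmin))
    s <- if (prev > ghi && delta > 0) (1 - prev) * sstar
         else if (prev < glo && delta < 0) (prev - 1) * sstar
         else sstar
    out[[p]] <- min(max(prev + s, 0), 1)
  }
  out
}

# random valid inputs under a fixed seed
random_state <- function() {
  c(E = runif(1, -1, 1), P = runif(1), M = runif(1), I = runif(1),
    S = runif(1, -1, 1))
}
random_traits <- function() {
  c(a = runif(1), c = runif(1), r = runif(1), m = runif(1))
}
random_window <- function(n = 14) {
  w <- cbind(E = runif(n, -1, 1), P = runif(n), M = runif(n),
             I = runif(n), S = runif(n, -1, 1))
  w
}
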