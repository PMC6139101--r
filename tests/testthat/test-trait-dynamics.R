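test_that("decay_constant is ln2/tau, decreasing, and rejects bad input", {
  expect_equal(round(decay_constant(7), 3), 0.099)
  expect_equal(decay_constant(log(2)), 1.0)
  # frozen golden value from direct arithmetic log(2)/14
  expect_equal(decay_constant(14), 0.049510512897138946, tolerance = 1e-15)
  taus <- c(1, 2, 5, 7, 14, 30)
  expect_true(all(diff(vapply(taus, decay_constant, numeric(1))) < 0))
  expect_error(decay_constant(0), "positive")
  expect_error(decay_constant(-3), "positive")
})

test_that("decay weights decay with sample age, newest weight exactly 1", {
  w <- decay_weights(14, 0.099)
  expect_length(w, 14)
  expect_identical(w[14], 1)
  expect_true(all(diff(w) > 0))                 # strictly increasing
  expect_equal(w[1], exp(-0.099 * 13), tolerance = 1e-15)
  # direct arithmetic oracle for the whole sequence
  expect_equal(w, exp(-0.099 * (13:0)), tolerance = 1e-15)
  # no-decay limit
  expect_equal(decay_weights(5, 1e-12), rep(1, 5), tolerance = 1e-9)
  expect_error(decay_weights(1, 0.1), "integer")
  expect_error(decay_weights(14, 0), "positive")
})

test_that("filter of a constant window is exactly zero", {
  for (v in c(-1, 0, 0.3, 1, 42)) {
    expect_identical(filter_value(rep(v, 14), d = 0.535, lambda = 0.099), 0)
  }
})

test_that("filter matches the two-point closed form", {
  # window [x, x+h], n = 2: d * (h/2) * (1 - exp(-lambda))
  got <- filter_value(c(0.2, 1.2), d = 0.535, lambda = 0.099)
  expect_equal(got, 0.025213825603700776, tolerance = 1e-12)  # frozen
  expect_equal(got, 0.535 * 0.5 * (1 - exp(-0.099)), tolerance = 1e-12)
})

test_that("filter is shift-invariant and linear on random windows", {
  set.seed(201)
  for (i in 1:1000) {
    n <- sample(2:20, 1)
    x <- runif(n, -1, 1)
    d <- runif(1, 0.1, 1); lam <- runif(1, 0.01, 1)
    f <- filter_value(x, d, lam)
    shift <- runif(1, -5, 5)
    expect_equal(filter_value(x + shift, d, lam), f, tolerance = 1e-10)
    alpha <- runif(1, -3, 3)
    expect_equal(filter_value(alpha * x, d, lam), alpha * f,
                 tolerance = 1e-10)
  }
})

test_that("filter agrees with the direct-sum oracle", {
  set.seed(202)
  for (i in 1:50) {
    x <- runif(14, -1, 1)
    expect_equal(filter_value(x, 0.535, 0.099),
                 oracle_filter(x, 0.535, 0.099), tolerance = 1e-13)
  }
})

test_that("short or malformed windows raise distinct errors", {
  e <- tryCatch(filter_value(c(1, 2, 3), d = 0.535, lambda = 0.099, n = 14),
                error = identity)
  expect_s3_class(e, "st_short_window")
  e2 <- tryCatch(filter_value(runif(14), d = -1, lambda = 0.099),
                 error = identity)
  expect_false(inherits(e2, "st_short_window"))
})

test_that("drivers combine filters with the printed normalizations", {
  tp <- trait_vector(a = 0.2, c = 0.4, r = 0.3, m = 0.6)
  f0 <- c(E = 0, P = 0, M = 0, I = 0, S = 0)
  expect_equal(combine_drivers("a", f0, tp), 0)
  expect_equal(combine_drivers("m", f0, tp), 0)
  expect_equal(combine_drivers("c", f0, tp), 0.1)   # r_prev/3 = 0.3/3
  expect_equal(combine_drivers("r", f0, tp), 0.2)   # c_prev/2 = 0.4/2
  set.seed(203)
  for (i in 1:100) {
    f <- stats::setNames(runif(5, -1, 1), state_names())
    tp <- random_traits()
    expect_equal(combine_drivers("a", f, tp), (f[["S"]] - f[["E"]]) / 2)
    expect_equal(combine_drivers("c", f, tp),
                 (f[["I"]] + f[["S"]] + tp[["r"]]) / 3)
    expect_equal(combine_drivers("r", f, tp), (f[["S"]] + tp[["c"]]) / 2)
    expect_equal(combine_drivers("m", f, tp),
                 (-f[["E"]] - f[["P"]] + f[["M"]] + f[["S"]]) / 4)
  }
  expect_error(combine_drivers("z", f0, tp), "unknown trait")
})

test_that("saturation applies sign-gated branches, gain and boundary gates", {
  cfg <- trait_update_config()
  expect_identical(saturate("c", 0.5, 0), 0)
  # interior, positive increment: k * delta * (p_max - p)
  expect_equal(saturate("c", 0.5, 0.01, cfg), 0.7 * 0.01 * 0.3,
               tolerance = 1e-15)
  expect_equal(saturate("c", 0.5, 0.01, cfg), 0.0021, tolerance = 1e-12)
  # interior, negative increment: k * delta * (p - p_min)
  expect_equal(saturate("c", 0.5, -0.01, cfg), 0.7 * -0.01 * 0.4,
               tolerance = 1e-15)
  # above the high gate with positive delta: (1 - p) * s*, and since
  # p > p_max the distance (p_max - p) < 0 makes the result restoring
  sstar <- 0.7 * 0.01 * (0.8 - 0.9)
  expect_equal(saturate("c", 0.9, 0.01, cfg), (1 - 0.9) * sstar,
               tolerance = 1e-15)
  expect_lt(saturate("c", 0.9, 0.01, cfg), 0)
  # below the low gate with negative delta: printed (p - 1) factor flips
  # the sign of the decrease (restoring force near the floor)
  sstar_lo <- 0.7 * -0.01 * (0.15 - 0.1)
  expect_equal(saturate("c", 0.15, -0.01, cfg), (0.15 - 1) * sstar_lo,
               tolerance = 1e-15)
  expect_gt(saturate("c", 0.15, -0.01, cfg), 0)
  # the |p - 1| variant keeps the literal decrease direction
  cfg2 <- trait_update_config(literal_low_gate = FALSE)
  expect_lt(saturate("c", 0.15, -0.01, cfg2), 0)
  # in-gate increments keep the sign of delta
  set.seed(204)
  for (i in 1:200) {
    p <- runif(1, 0.2, 0.8)
    delta <- runif(1, -0.05, 0.05)
    expect_identical(sign(saturate("c", p, delta, cfg)), sign(delta))
  }
})

test_that("alliance mixing is the arithmetic mean with identity fallback", {
  expect_equal(mix_alliance(0.2, 0.4), 0.3)
  expect_identical(mix_alliance(0.7), 0.7)
  expect_identical(mix_alliance(0.7, NULL), 0.7)
  for (x in c(0, 0.31, 1)) expect_equal(mix_alliance(x, x), x)
  expect_error(mix_alliance(0.5, 1.4), "\\[0, 1\\]")
  expect_error(mix_alliance(1.4, 0.5), "\\[0, 1\\]")
})

test_that("a constant state window leaves a and m unchanged exactly", {
  win <- matrix(rep(c(0.3, 0.5, 0.2, 0.4, -0.1), each = 14), ncol = 5,
                dimnames = list(NULL, state_names()))
  tp <- trait_vector(a = 0.5, c = 0.5, r = 0.3, m = 0.5)
  out <- update_traits(tp, win)
  expect_identical(out[["a"]], 0.5)
  expect_identical(out[["m"]], 0.5)
  # c and r move only through their trait cross-terms
  expect_gt(out[["c"]], 0.5)
  expect_gt(out[["r"]], 0.3)
  # frozen cross-term increment for c: saturate(c, w_c * 0.5 * (0.3/3))
  cfg <- trait_update_config()
  delta_c <- 0.004167 * 0.5 * (0.3 / 3)
  expect_equal(out[["c"]], 0.5 + 0.7 * delta_c * (0.8 - 0.5),
               tolerance = 1e-15)
})

test_that("update_traits matches the transcription oracle of the update rule", {
  set.seed(205)
  for (i in 1:100) {
    tp <- random_traits()
    win <- random_window(14)
    b <- if (i %% 3 == 0) runif(1) else NULL
    got <- update_traits(tp, win, filter_config(), trait_update_config(),
                         b_t = b)
    want <- oracle_update_traits(tp, win, n = 14, tau = 7, d = 0.535,
                                 w = 0.004167, pmin = 0.1, pmax = 0.8,
                                 glo = 0.2, ghi = 0.8, b = b)
    expect_equal(unname(got), unname(want[trait_names()]),
                 tolerance = 1e-12)
  }
})

test_that("trait trajectories stay in [0,1] under long random driving", {
  set.seed(206)
  cfg <- trait_update_config()
  fcfg <- filter_config()
  for (rep in 1:200) {
    tp <- random_traits()
    # feed 1000 random raw increments through the saturating update
    for (t in 1:1000) {
      p <- sample(trait_names(), 1)
      driver <- runif(1, -2, 2)
      delta <- cfg$w[[p]] * tp[[p]] * driver
      tp[[p]] <- min(max(tp[[p]] + saturate(p, tp[[p]], delta, cfg), 0), 1)
    }
    expect_true(all(tp >= 0 & tp <= 1))
  }
})

test_that("update_traits rejects an incomplete window", {
  tp <- random_traits()
  expect_error(update_traits(tp, random_window(10)), "incomplete")
})

test_that("filter and trait configs validate their invariants", {
  fc <- filter_config()
  expect_identical(fc$n, 14L)
  expect_equal(unname(fc$lambda), rep(log(2) / 7, 5))
  expect_error(filter_config(n = 1), "integer")
  expect_error(filter_config(tau = -1), "> 0")
  tc <- trait_update_config()
  expect_equal(unname(tc$k), rep(0.7, 4))
  expect_error(trait_update_config(p_min = 0.9, p_max = 0.8), "p_min")
  expect_error(trait_update_config(gate_low = 0.9, gate_high = 0.8),
               "gate_low")
  # per-trait override keeps k consistent
  tc2 <- trait_update_config(p_min = c(a = 0, c = 0.1, r = 0.1, m = 0.2),
                             p_max = 0.9)
  expect_equal(tc2$k[["a"]], 0.9)
  expect_equal(tc2$k[["m"]], 0.7)
})
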