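test_that("empirical initial values map to the internal scale by /100", {
  got <- rescale_initial(c(E = 97.6, P = 61.5, M = 7.5, I = 100, S = -40.7))
  expect_equal(unname(got), c(0.976, 0.615, 0.075, 1.0, -0.407))
  expect_identical(unname(rescale_initial(c(E = 0, P = 0, M = 0, I = 0,
                                            S = 0))), rep(0, 5))
  expect_equal(rescale_initial(c(E = -100, P = 0, M = 0, I = 0, S = 0))[["E"]],
               -1.0)
  expect_error(rescale_initial(c(E = 120, P = 0, M = 0, I = 0, S = 0)), "E")
  expect_error(rescale_initial(c(E = 0, P = -5, M = 0, I = 0, S = 0)), "P")
})

test_that("interventions add percent/100 on the internal scale, only when active", {
  s <- state_vector(0, 0.5, 0.5, 0.5, 0)
  empty <- intervention_schedule()
  for (t in c(1, 17, 99)) expect_identical(apply_interventions(s, empty, t), s)
  sched <- intervention_schedule(intervention("S", 17, 17, +38))
  expect_equal(apply_interventions(s, sched, 17)[["S"]], 0.38)
  expect_identical(apply_interventions(s, sched, 18), s)
  expect_identical(apply_interventions(s, sched, 16), s)
  # overlapping events add
  twice <- intervention_schedule(intervention("E", 5, 10, -10),
                                 intervention("E", 8, 12, -10))
  expect_equal(apply_interventions(s, twice, 9)[["E"]], -0.20)
  expect_equal(apply_interventions(s, twice, 11)[["E"]], -0.10)
  expect_error(intervention("Q", 1, 2, 10), "unknown variable")
  expect_error(intervention("E", 5, 2, 10), "t_start")
})

test_that("noise respects levels, range scaling and the zero-level identity", {
  s <- state_vector(0.2, 0.5, 0.5, 0.5, -0.2)
  expect_identical(apply_noise(s, noise_spec(0), unit = rep(0.99, 5)), s)
  spec30 <- noise_spec(c(E = 30, P = 0, M = 0, I = 0, S = 0))
  set.seed(301)
  for (i in 1:500) {
    out <- apply_noise(s, spec30)
    expect_true(abs(out[["E"]] - s[["E"]]) <= 0.3)  # 30% of range 2 / 2
    expect_identical(out[["P"]], s[["P"]])          # untouched, bit-exact
  }
  # P has range width 1: level 30 bounds the shift by 0.15
  specP <- noise_spec(c(E = 0, P = 30, M = 0, I = 0, S = 0))
  set.seed(302)
  shifts <- replicate(2000, apply_noise(s, specP)[["P"]] - s[["P"]])
  expect_true(all(abs(shifts) <= 0.15))
  # Monte-Carlo mean-zero check: mean within 3 standard errors
  expect_lt(abs(mean(shifts)), 3 * sd(shifts) / sqrt(length(shifts)))
})

test_that("clamping clips to the internal ranges and is idempotent", {
  s <- c(E = 1.7, P = -0.3, M = 0.5, I = 1.2, S = -2)
  out <- clamp_states(s)
  expect_equal(unname(out), c(1, 0, 0.5, 1, -1))
  expect_identical(clamp_states(out), out)
  inr <- state_vector(0.3, 0.4, 0.5, 0.6, -0.7)
  expect_identical(clamp_states(inr), inr)
})

test_that("scenario construction validates its fields", {
  expect_error(scenario(0, c(E = 0, P = 0, M = 0, I = 0, S = 0),
                        c(a = 0.5, c = 0.5, r = 0.5, m = 0.5)),
               "iterations")
  expect_error(scenario(10, c(E = 150, P = 0, M = 0, I = 0, S = 0),
                        c(a = 0.5, c = 0.5, r = 0.5, m = 0.5)), "E")
  expect_error(scenario(10, c(E = 0, P = 0, M = 0, I = 0, S = 0),
                        c(a = 1.5, c = 0.5, r = 0.5, m = 0.5)), "\\[0, 1\\]")
  expect_error(scenario(10, c(E = 0, P = 0, M = 0, I = 0, S = 0),
                        c(a = 0.5, c = 0.5, r = 0.5, m = 0.5),
                        alliance = rep(0.5, 5)), "alliance")
  sc <- scenario(10, c(E = 0, P = 0, M = 0, I = 0, S = 0),
                 c(a = 0.5, c = 0.5, r = 0.5, m = 0.5))
  expect_s3_class(sc, "st_scenario")
})

test_that("runs are seed-deterministic and noise-free runs are seed-independent", {
  sc <- preset_scenario("fig6a", seed = 7)
  t1 <- run_scenario(sc)
  t2 <- run_scenario(sc)
  expect_identical(t1$states, t2$states)
  expect_identical(t1$traits, t2$traits)
  # a noise-free, intervention-free, pinned-traits run ignores the seed
  mk <- function(seed) scenario(
    60, c(E = 30, P = 50, M = 40, I = 20, S = 0),
    c(a = 0.4, c = 0.5, r = 0.4, m = 0.3), noise = noise_spec(0),
    override = trait_override(a = 0.4, c = 0.5, r = 0.4, m = 0.3),
    seed = seed)
  a <- run_scenario(mk(1)); b <- run_scenario(mk(999))
  expect_identical(a$states, b$states)
  # and equals pure iteration of the state map
  s <- rescale_initial(mk(1)$init_states)
  tr <- c(a = 0.4, c = 0.5, r = 0.4, m = 0.3)
  for (t in 1:60) {
    s <- clamp_states(step_states(s, tr))
    expect_identical(unname(a$states[t + 1, ]), unname(s))
  }
})

test_that("per-variable noise substreams are independent of other settings", {
  base <- preset_scenario("fig6a", seed = 11)
  no_int <- base; no_int$interventions <- intervention_schedule()
  t1 <- run_scenario(base); t2 <- run_scenario(no_int)
  expect_identical(t1$noise_inc, t2$noise_inc)
})

test_that("traits are frozen during warm-up and respect overrides", {
  sc <- preset_scenario("fig6a", seed = 3)
  traj <- run_scenario(sc)
  n <- sc$filter$n
  for (t in 1:(n - 1))
    expect_identical(traj$traits[t + 1, ], traj$traits[1, ])
  # fig3 pins every trait: c follows the printed ramp verbatim
  traj3 <- run_scenario(preset_scenario("fig3", seed = 1))
  expect_identical(unname(traj3$traits[, "c"]),
                   unname(stats::approx(c(0, 100, 200), c(0.6, 0.6, 1),
                                        xout = 0:400, rule = 2)$y))
  expect_identical(unique(traj3$traits[, "a"]), 0.5)
})

test_that("the audit record replays to the recorded trajectory bit-exactly", {
  for (name in c("fig5", "fig6b", "fig8")) {
    traj <- run_scenario(preset_scenario(name, seed = 5))
    expect_true(replay_trajectory(traj))
  }
})

test_that("trait trajectories stay in [0,1] across random scenarios", {
  set.seed(303)
  for (rep in 1:20) {
    sc <- scenario(
      iterations = 250,
      init_states = c(E = runif(1, -100, 100), P = runif(1, 0, 100),
                      M = runif(1, 0, 100), I = runif(1, 0, 100),
                      S = runif(1, -100, 100)),
      init_traits = c(a = runif(1), c = runif(1), r = runif(1),
                      m = runif(1)),
      noise = noise_spec(runif(1, 0, 40)),
      seed = sample.int(1e6, 1))
    traj <- run_scenario(sc)
    expect_true(all(traj$traits >= 0 & traj$traits <= 1))
    expect_true(all(is.finite(traj$states)))
    rng <- state_ranges()
    expect_true(all(t(traj$states) >= rng$lower - 1e-15 &
                    t(traj$states) <= rng$upper + 1e-15))
  }
})

test_that("a measured alliance series pulls the alliance parameter toward it", {
  b <- rep(0.9, 120)
  sc <- scenario(120, c(E = 97.6, P = 61.5, M = 7.5, I = 100, S = -40.7),
                 c(a = 0.1, c = 0.35, r = 0.35, m = 0.1),
                 noise = noise_spec(5), alliance = b, seed = 2)
  traj <- run_scenario(sc)
  # after warm-up, a is repeatedly averaged with b = 0.9 and converges up
  expect_gt(traj$traits[121, "a"], 0.8)
  sc0 <- sc; sc0$alliance <- NULL
  traj0 <- run_scenario(sc0)
  expect_lt(traj0$traits[121, "a"], traj$traits[121, "a"])
})
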