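square_wave <- function(period, duty_high, duration = 10, dt = 0.001) {
  t <- seq(0, duration, by = dt)
  x <- as.numeric((t %% period) < duty_high * period)
  list(t = t, x = x)
}

test_that("square-wave phase extraction is exact for arbitrary period and duty", {
  w <- square_wave(1.0, 0.4)
  ev <- detect_phase_events(w$t, w$x)
  cyc <- tabulate_cycles(ev)
  expect_true(all(abs(cyc$swing_s - 0.4) < 2.5e-3))
  expect_true(all(abs(cyc$stance_s - 0.6) < 2.5e-3))
  expect_true(all(abs(cyc$cycle_s - 1.0) < 2.5e-3))

  set.seed(7)
  for (i in 1:8) {
    period <- runif(1, 0.3, 2)
    duty <- runif(1, 0.1, 0.9)
    w <- square_wave(period, duty, duration = 8 * period, dt = period / 500)
    cyc <- tabulate_cycles(detect_phase_events(w$t, w$x))
    expect_gt(nrow(cyc), 2)
    expect_true(all(abs(cyc$cycle_s - period) < period / 150))
    expect_true(all(abs(cyc$swing_s - duty * period) < period / 150))
  }
})

test_that("non-rhythmic traces return an empty flagged event list", {
  t <- seq(0, 5, by = 0.01)
  ev <- detect_phase_events(t, rep(0.01, length(t)))
  expect_equal(nrow(ev), 0)
  expect_true(attr(ev, "non_rhythmic"))
  ev2 <- detect_phase_events(t, rep(0.9, length(t)))
  expect_equal(nrow(ev2), 0)
  expect_true(attr(ev2, "non_rhythmic"))
})

test_that("a symmetric sinusoid splits the cycle evenly as hysteresis vanishes", {
  t <- seq(0, 12, by = 0.0005)
  x <- 0.5 + 0.5 * sin(2 * pi * t / 2)
  cyc <- tabulate_cycles(detect_phase_events(t, x, theta_sw = 0.5, hysteresis = 1e-6))
  expect_true(all(abs(cyc$swing_s - 1) < 0.005))
  expect_true(all(abs(cyc$stance_s - 1) < 0.005))
})

test_that("cycle tabulation matches the event algebra exactly", {
  ev <- tibble::tibble(
    time = c(0, 0.6, 1.0, 1.6, 2.0),
    event = c("stance_onset", "swing_onset", "stance_onset", "swing_onset",
              "stance_onset"))
  cyc <- tabulate_cycles(ev)
  expect_equal(nrow(cyc), 2)
  expect_equal(cyc$cycle_s, c(1, 1))
  expect_equal(cyc$stance_s, c(0.6, 0.6))
  expect_equal(cyc$swing_s, c(0.4, 0.4))
  expect_equal(cyc$duty, c(0.6, 0.6))

  single <- tibble::tibble(time = 0, event = "stance_onset")
  empty <- tabulate_cycles(single)
  expect_equal(nrow(empty), 0)
  expect_match(attr(empty, "flag"), "fewer than 2")
})

test_that("stance plus swing equals cycle to machine precision, with jitter", {
  set.seed(11)
  times <- cumsum(runif(40, 0.2, 0.8))
  ev <- tibble::tibble(time = times,
                       event = rep(c("stance_onset", "swing_onset"), 20))
  cyc <- tabulate_cycles(ev)
  expect_identical(cyc$stance_s + cyc$swing_s, cyc$cycle_s)
  expect_equal(cyc$duty, cyc$stance_s / cyc$cycle_s)
  # duty below one half exactly when swing exceeds stance
  expect_identical(cyc$duty < 0.5, cyc$swing_s > cyc$stance_s)
  # independent recomputation of the per-cycle means
  st <- times[seq(1, 39, 2)]
  sw <- times[seq(2, 40, 2)]
  expect_equal(mean(cyc$cycle_s), mean(diff(st)))
  expect_equal(mean(cyc$stance_s), mean((sw - st)[-20]))
})

test_that("crossing speed interpolates the first stance-swing sign change", {
  b <- seq(0.5, 1.0, 0.1)
  sweep <- tibble::tibble(
    beta = rep(b, 2), side = rep(c("right", "left"), each = length(b)),
    stance_mean = rep(0.6 - 0.5 * b, 2),
    swing_mean = rep(0.2 + 0.1 * b, 2))
  expect_equal(find_crossing_speed(sweep, "right"), 2 / 3, tolerance = 1e-10)

  none <- sweep; none$swing_mean <- 0.01
  expect_true(is.na(find_crossing_speed(none, "right")))

  exact <- sweep
  exact$stance_mean <- 0.5 - (exact$beta - 0.7)
  exact$swing_mean <- 0.5 - (0.7 - exact$beta)
  expect_equal(find_crossing_speed(exact, "right"), 0.7)
})

test_that("rhythmicity needs at least two cycles and a steady period", {
  steady <- tibble::tibble(cycle_s = rep(1, 5))
  expect_true(is_rhythmic(steady))
  expect_false(is_rhythmic(steady[1, ]))
  jittery <- tibble::tibble(cycle_s = c(1, 2, 0.5, 1.6, 0.8))
  expect_false(is_rhythmic(jittery))
})
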