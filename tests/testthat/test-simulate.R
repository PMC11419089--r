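test_that("speed-to-drive map applies the affine law and condition zeroing", {
  expect_equal(drive_from_speed(0.4, "left", "intact")$alpha, 0.4)
  expect_equal(drive_from_speed(0.9, "right", "hemisected")$alpha, 0)
  expect_equal(drive_from_speed(0.9, "right", "hemisected")$gamma, 0)
  expect_equal(drive_from_speed(0.9, "left", "transected")$alpha, 0)
  alphas <- vapply(seq(0.4, 1.0, 0.1),
                   function(b) drive_from_speed(b, "left", "intact")$alpha, 0)
  expect_true(all(diff(alphas) > 0))
  expect_error(drive_from_speed(-0.1, "left", "intact"), "nonnegative")
  # custom map coefficients pass through
  m <- list(a0 = 0.2, a1 = 0.5, gamma = 1)
  expect_equal(drive_from_speed(0.6, "left", "intact", m)$alpha, 0.5)
})

test_that("integrator reproduces the closed-form linear relaxation", {
  net <- single_pop_network("InF-L") # relay: pure leak when unconnected
  p <- net$params$neuron
  V0 <- p$EL + 10
  sim <- simulate_gait(net, 0, 0, duration = 0.2, dt = 0.1, feedback = FALSE,
                       drives = list(alphaL = 0, alphaR = 0, gammaL = 0, gammaR = 0),
                       init = list(V0 = V0, h0 = 1), record_dt = 0.1,
                       record_v = TRUE)
  nr <- net$populations[1, ]
  expected <- p$EL + 10 * exp(-nr$gL * (sim$time * 1000) / nr$C)
  expect_equal(sim$V[, 1], expected, tolerance = 1e-6)
})

test_that("simulation is deterministic given identical inputs", {
  net <- build_network("intact")
  s1 <- simulate_gait(net, 0.6, 0.6, duration = 2)
  s2 <- simulate_gait(net, 0.6, 0.6, duration = 2)
  expect_identical(s1$out, s2$out)
  expect_identical(s1$final, s2$final)
})

test_that("halving the step changes the steady cycle duration by under 0.1%", {
  net <- build_network("intact")
  cyc <- function(dt) {
    sim <- simulate_gait(net, 0.6, 0.6, duration = 30, dt = dt)
    cs <- step_cycles(sim, transient = 10)
    mean(cs$cycle_s[cs$side == "left"])
  }
  expect_equal(cyc(0.05) / cyc(0.1) - 1, 0, tolerance = 1e-3)
})

test_that("belt protocols define the study speed grids", {
  tied <- belt_protocol("tied", 0.1)
  expect_equal(tied$betaL, tied$betaR)
  expect_equal(range(tied$beta), c(0.4, 1.0))
  lsrf <- belt_protocol("lsrf", 0.1)
  expect_true(all(lsrf$betaL == 0.4))
  expect_equal(lsrf$betaR, seq(0.5, 1.0, 0.1))
  lfrs <- belt_protocol("lfrs", 0.1)
  expect_true(all(lfrs$betaR == 0.4))
  expect_equal(lfrs$betaL, seq(0.5, 1.0, 0.1))
})

test_that("sweep summaries carry one labeled row per point and side", {
  sw <- cached_sweep("intact", "tied")
  expect_s3_class(sw, "gait_sweep")
  expect_equal(nrow(sw), 2 * 7)
  expect_identical(attr(sw, "condition"), "intact")
  expect_true(all(c("betaL", "betaR", "beta", "side", "rhythmic", "cycle_mean",
                    "stance_mean", "swing_mean", "duty_mean") %in% names(sw)))
  expect_true(all(sw$rhythmic))
})

test_that("intact tied-belt cycle duration decreases with treadmill speed", {
  sw <- cached_sweep("intact", "tied")
  left <- sw[sw$side == "left", ]
  left <- left[order(left$beta), ]
  expect_lt(left$cycle_mean[nrow(left)], left$cycle_mean[1])
  # decreasing overall trend: each point no higher than ~8% above its predecessor
  expect_true(all(diff(left$cycle_mean) < 0.08 * utils::head(left$cycle_mean, -1)))
})

test_that("intact network is left-right symmetric in steady state", {
  sw <- cached_sweep("intact", "tied")
  for (b in unique(sw$beta)) {
    l <- sw[sw$beta == b & sw$side == "left", ]
    r <- sw[sw$beta == b & sw$side == "right", ]
    expect_equal(l$cycle_mean, r$cycle_mean, tolerance = 0.01)
  }
})

test_that("coupled sides share a 1:1 period at rhythmic sweep points", {
  for (key in list(c("hemisected", "tied"), c("hemisected", "lsrf"),
                   c("hemisected", "lfrs"))) {
    sw <- cached_sweep(key[1], key[2])
    for (b in unique(sw$beta)) {
      pt <- sw[sw$beta == b, ]
      if (all(pt$rhythmic)) {
        expect_equal(pt$cycle_mean[1], pt$cycle_mean[2], tolerance = 0.02)
      }
    }
  }
})

test_that("doubling the transient discard leaves mean durations stable", {
  net <- build_network("intact")
  sim <- simulate_gait(net, 0.7, 0.7)
  a <- step_cycles(sim, transient = 10)
  b <- step_cycles(sim, transient = 20)
  ml <- function(d) mean(d$cycle_s[d$side == "left"])
  expect_equal(ml(a), ml(b), tolerance = 0.01)
})
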