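test_that("intact network is mirror-symmetric under left-right relabeling", {
  net <- build_network("intact")
  swap <- function(x) {
    x <- sub("-L$", "-@", x); x <- sub("-R$", "-L", x); sub("-@$", "-R", x)
  }
  swap_drive <- function(x) {
    x <- sub("alphaL", "alpha@", x); x <- sub("alphaR", "alphaL", x)
    x <- sub("alpha@", "alphaR", x)
    x <- sub("gammaL", "gamma@", x); x <- sub("gammaR", "gammaL", x)
    sub("gamma@", "gammaR", x)
  }
  cn <- net$connections
  mirrored <- cn
  mirrored$source <- swap_drive(swap(mirrored$source))
  mirrored$target <- swap(mirrored$target)
  orig <- cn[order(cn$source, cn$target), c("source", "target", "weight", "sign")]
  mirr <- mirrored[order(mirrored$source, mirrored$target),
                   c("source", "target", "weight", "sign")]
  expect_equal(as.data.frame(orig), as.data.frame(mirr), ignore_attr = TRUE)

  pops <- net$populations
  left <- pops[pops$side == "left", ]
  right <- pops[pops$side == "right", ]
  left$id <- sub("-L$", "", left$id); right$id <- sub("-R$", "", right$id)
  expect_equal(left[-2], right[-2], ignore_attr = TRUE)
})

test_that("hemisection zeroes only right-drive-sourced weights", {
  intact <- build_network("intact")
  hemi <- build_network("hemisected")
  from_right_drive <- intact$connections$source %in% c("drive-alphaR", "drive-gammaR")
  expect_true(all(hemi$connections$weight[from_right_drive] == 0))
  expect_identical(hemi$connections$weight[!from_right_drive],
                   intact$connections$weight[!from_right_drive])
  expect_identical(hemi$connections[c("source", "target", "sign", "crossed", "type")],
                   intact$connections[c("source", "target", "sign", "crossed", "type")])
  expect_identical(hemi$populations, intact$populations)
})

test_that("transection zeroes all four drive sources and keeps feedback", {
  tx <- build_network("transected")
  drives <- grepl("^drive-", tx$connections$source)
  expect_true(all(tx$connections$weight[drives] == 0))
  fb <- tx$connections$type == "feedback"
  expect_true(all(tx$connections$weight[fb] > 0))
})

test_that("unknown condition and crossed-flag consistency are enforced", {
  expect_error(build_network("lesioned"), "unknown condition")
  net <- build_network("intact")
  side_of <- function(x) ifelse(grepl("(-L$|L$)", x) & !grepl("R$", x), "L", "R")
  pop_rows <- net$connections[net$connections$type == "pop", ]
  expect_identical(pop_rows$crossed,
                   side_of(pop_rows$source) != side_of(pop_rows$target))
})

test_that("output function is a clamped linear ramp", {
  spec <- list(Vout_min = -50, Vout_max = 0)
  expect_equal(output_function(-50, spec), 0)
  expect_equal(output_function(0, spec), 1)
  expect_equal(output_function(-25, spec), 0.5)
  expect_equal(output_function(-80, spec), 0)
  expect_equal(output_function(30, spec), 1)
  v <- seq(-80, 20, by = 0.5)
  expect_true(all(diff(output_function(v, spec)) >= 0))
})

test_that("population right-hand side matches its closed-form pieces", {
  net <- build_network("intact")
  relay <- as.list(net$populations[net$populations$id == "InF-L", ])
  eq <- population_rhs(list(V = relay$EL, h = 1), relay, gE = 0, gI = 0)
  expect_equal(eq$dV, 0)
  expect_equal(eq$dh, 0)

  burster <- as.list(net$populations[net$populations$id == "RG-F-L", ])
  # h-nullcline midpoint: h_inf = 0.5 exactly at Vh_half
  r <- population_rhs(list(V = burster$Vh_half, h = 0.5), burster, 0, 0)
  expect_equal(r$dh, 0)
  # with h = 0 the NaP term vanishes: pure leak
  r0 <- population_rhs(list(V = -30, h = 0), burster, 0, 0)
  expect_equal(r0$dV, -burster$gL * (-30 - burster$EL) / burster$C)

  expect_error(population_rhs(list(V = -50, h = 1.4), burster, 0, 0), "outside")
  expect_error(population_rhs(list(V = -50, h = 0.5), burster, -1, 0), "nonnegative")
})

test_that("synaptic inputs accumulate linearly over sources", {
  net <- build_network("intact")
  ids <- net$populations$id
  zero_out <- setNames(rep(0, length(ids)), ids)
  zero_drv <- list(alphaL = 0, alphaR = 0, gammaL = 0, gammaR = 0)
  zero_fb <- list(sfE1_L = 0, sfE1_R = 0, sfE2_L = 0, sfE2_R = 0)
  g0 <- synaptic_inputs(net, zero_out, zero_drv, zero_fb)
  expect_true(all(g0$gE == 0) && all(g0$gI == 0))

  # single active source: contribution is weight times activation
  outs <- zero_out; outs["RG-F-L"] <- 0.3
  g1 <- synaptic_inputs(net, outs, zero_drv, zero_fb)
  w <- net$connections$weight[net$connections$source == "RG-F-L" &
                                net$connections$target == "InF-L"]
  expect_equal(g1$gE[g1$id == "InF-L"], w * 0.3)

  # hemisected: right drives contribute nothing, crossed alphaL persists
  hemi <- build_network("hemisected")
  drv <- list(alphaL = 0.6, alphaR = 0.6, gammaL = 1, gammaR = 1)
  gh <- synaptic_inputs(hemi, zero_out, drv, zero_fb)
  w_c <- default_params()$weights$alpha_F_contra
  w_i <- default_params()$weights$alpha_F_ipsi
  expect_equal(gh$gE[gh$id == "RG-F-R"], w_c * 0.6) # crossed left drive only
  expect_equal(gh$gE[gh$id == "RG-F-L"], (w_i + 0) * 0.6)
  expect_equal(gh$gE[gh$id == "RG-E-R"], 0)

  bad <- net
  bad$connections$target[1] <- "RG-X-L"
  expect_error(synaptic_inputs(bad, zero_out, zero_drv, zero_fb), "unknown population")
})

test_that("network configuration round-trips exactly through JSON", {
  net <- build_network("hemisected")
  path <- withr::local_tempfile(fileext = ".json")
  write_network_config(net, path)
  back <- read_network_config(path)
  expect_equal(back$populations, net$populations)
  expect_equal(back$connections, net$connections)
  expect_identical(back$condition, net$condition)
  expect_equal(back$params$weights, net$params$weights)
  expect_equal(back$params$neuron, net$params$neuron)
})
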