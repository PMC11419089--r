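test_that("identical states give a zero state effect with p = 1", {
  set.seed(1)
  half <- tidyr::expand_grid(cat = paste0("c", 1:4), state = "intact",
                             speed = seq(0.4, 1, 0.2))
  half$y <- rnorm(nrow(half))
  both <- dplyr::bind_rows(half, dplyr::mutate(half, state = "hemisected"))
  fit <- rm_anova(cells_to_dataset(both), "cycle", "left")
  tb <- tidy(fit)
  expect_equal(tb$statistic[tb$effect == "state"], 0)
  expect_equal(tb$p.value[tb$effect == "state"], 1)
})

test_that("a tiny two-by-two design matches a hand-worked decomposition", {
  # 2 cats x 2 states x 2 speeds, chosen so sums of squares are simple
  cells <- tidyr::expand_grid(cat = c("a", "b"), state = c("i", "h"),
                              speed = c(1, 2))
  cells$y <- c(10.2, 12.1, 13.4, 17.3, 11.1, 13.9, 15.2, 19.8)
  fit <- rm_anova(cells_to_dataset(cells), "cycle", "left")
  o <- aov_oracle(cells)
  tb <- tidy(fit)
  expect_equal(tb$statistic[tb$effect == "state"], unname(o["state"]), tolerance = 1e-10)
  expect_equal(tb$statistic[tb$effect == "speed"], unname(o["speed"]), tolerance = 1e-10)
  expect_equal(tb$statistic[tb$effect == "state:speed"],
               unname(o["interaction"]), tolerance = 1e-10)
  expect_equal(tb$df1, c(1, 1, 1))
  expect_equal(tb$df2, c(1, 1, 1))
})

test_that("F statistics agree with the aov oracle on random balanced designs", {
  set.seed(202)
  for (i in 1:25) {
    cells <- random_cells(n_cats = sample(3:6, 1), n_speeds = sample(3:7, 1))
    fit <- rm_anova(cells_to_dataset(cells), "cycle", "left")
    o <- aov_oracle(cells)
    tb <- tidy(fit)
    expect_equal(tb$statistic, unname(o[c("state", "speed", "interaction")]),
                 tolerance = 1e-8)
  }
})

test_that("cycles are averaged within cell before the subject-level analysis", {
  set.seed(3)
  cells <- random_cells(4, 3)
  # replicate rows with balanced noise that cancels in the cell means
  twice <- dplyr::bind_rows(dplyr::mutate(cells, y = y + 0.25),
                            dplyr::mutate(cells, y = y - 0.25))
  f1 <- rm_anova(cells_to_dataset(cells), "cycle", "left")
  f2 <- rm_anova(cells_to_dataset(twice), "cycle", "left")
  expect_equal(tidy(f1)$statistic, tidy(f2)$statistic)
})

test_that("unbalanced or degenerate designs are rejected with named cells", {
  set.seed(4)
  cells <- random_cells(4, 3)
  broken <- cells[-5, ]
  expect_error(rm_anova(cells_to_dataset(broken), "cycle", "left"),
               "missing cells")
  solo <- cells[cells$cat == "c1", ]
  expect_error(rm_anova(cells_to_dataset(solo), "cycle", "left"), "at least 2")
  expect_error(rm_anova(cells_to_dataset(cells), "cycle", "right"), "no rows")
})

test_that("permuting state labels within cats destroys the state effect", {
  cfg <- effect_config(n_cycles = 5, protocols = "tied")
  d <- generate_cat_dataset(cfg, seed = 5)
  d <- d[d$protocol == "tied", ]
  f_obs <- glance(rm_anova(d, "swing", "right"))$f_state
  set.seed(6)
  f_perm <- replicate(20, {
    dd <- d
    for (cat in unique(dd$cat)) {
      if (runif(1) < 0.5) {
        ix <- dd$cat == cat
        dd$state[ix] <- ifelse(dd$state[ix] == "intact", "hemisected", "intact")
      }
    }
    glance(rm_anova(dd, "swing", "right"))$f_state
  })
  expect_gt(f_obs, stats::quantile(f_perm, 0.95))
})

test_that("glance and tidy expose the fitted summaries", {
  d <- generate_cat_dataset(effect_config(n_cycles = 4), seed = 2)
  fit <- rm_anova(d[d$protocol == "tied", ], "stance", "left", gg = TRUE)
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_true(all(c("f_state", "p_state", "p_speed", "p_interaction",
                    "state_diff") %in% names(g)))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_output(print(fit), "repeated-measures ANOVA")
})
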