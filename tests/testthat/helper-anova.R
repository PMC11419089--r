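# independent oracle for the repeated-measures ANOVA: classical aov() with
# within-subject error strata
aov_oracle <- function(cells) {
  cells$cat <- factor(cells$cat)
  cells$state <- factor(cells$state)
  cells$speed <- factor(cells$speed)
  fit <- stats::aov(y ~ state * speed + Error(cat / (state * speed)), data = cells)
  s <- summary(fit)
  get_f <- function(stratum, term) {
    tb <- s[[stratum]][[1]]
    tb[trimws(rownames(tb)) == term, "F value"]
  }
  c(state = get_f("Error: cat:state", "state"),
    speed = get_f("Error: cat:speed", "speed"),
    interaction = get_f("Error: cat:state:speed", "state:speed"))
}

random_cells <- function(n_cats = 5, n_speeds = 4) {
  tidyr::expand_grid(cat = paste0("c", seq_len(n_cats)),
                     state = c("intact", "hemisected"),
                     speed = seq_len(n_speeds)) |>
    dplyr::mutate(y = rnorm(dplyr::n()))
}

cells_to_dataset <- function(cells, dv = "cycle", side = "left") {
  out <- cells
  out$side <- side
  out$cycle_s <- out$stance_s <- out$swing_s <- out$y
  out
}
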