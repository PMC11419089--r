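#' Configuration for the synthetic cat step-cycle generator
#'
#' Defines the repeated-measures design and effect structure of the
#' synthetic experiment: cats walk in two states (intact, hemisected) on a
#' tied-belt treadmill at 0.4 to 1.0 m/s and in two split-belt protocols
#' (slow belt fixed at 0.4 m/s, fast belt 0.5 to 1.0 m/s), with 0.1 m/s
#' increments. Baseline mean durations follow the hyperbolic forms
#' `T0(v) = c0 + c1/v` (cycle) and `S0(v) = d0 + d1/v` (stance), monotone
#' decreasing in belt speed `v`; swing is `T0 - S0`. Hemisection effects are
#' multiplicative shifts on the stance and swing means per protocol and
#' side; cycle is their sum, preserving the stance + swing = cycle identity
#' per row.
#'
#' The default effect table encodes the qualitative direction pattern of the
#' calibrated simulation: on the ipsilesional (right) side stance shortens
#' and swing lengthens (strongly when that limb is on the fast belt, mildly
#' when tied or on the slow belt) with little cycle change, while the
#' contralesional (left) side is unchanged except in the left-slow/right-fast
#' protocol, where left stance and hence cycle lengthen.
#'
#' @param n_cats_tied,n_cats_split Cats per protocol family (defaults 5 and
#'   6, the study's retained group sizes).
#' @param n_cycles Step cycles per cat x state x speed x side cell.
#' @param baseline Named numeric vector `c(c0, c1, d0, d1)` (seconds; the
#'   defaults give a cycle of about 0.9 s at 0.4 m/s and 0.55 s at 1.0 m/s
#'   with cat-like duty factors).
#' @param effects Tibble with columns `protocol`, `side`, `stance_mult`,
#'   `swing_mult` applied in the hemisected state.
#' @param sd_cat_stance,sd_cat_swing Between-cat intercept SDs (s).
#' @param sd_resid Cycle-to-cycle residual SD (s), applied to stance and
#'   swing independently.
#' @param min_duration Truncation floor for generated phase durations (s).
#' @param protocols Which protocols to generate.
#' @return A list of class `effect_config`.
#' @export
effect_config <- function(n_cats_tied = 5, n_cats_split = 6, n_cycles = 15,
                          baseline = c(c0 = 0.31667, c1 = 0.23333,
                                       d0 = 0.12, d1 = 0.2),
                          effects = default_effects(),
                          sd_cat_stance = 0.03, sd_cat_swing = 0.02,
                          sd_resid = 0.015, min_duration = 0.1,
                          protocols = c("tied", "lsrf", "lfrs")) {
  stopifnot(n_cats_tied >= 2, n_cats_split >= 2, n_cycles >= 1,
            sd_cat_stance >= 0, sd_cat_swing >= 0, sd_resid >= 0)
  cfg <- structure(list(n_cats_tied = n_cats_tied, n_cats_split = n_cats_split,
                        n_cycles = n_cycles, baseline = baseline,
                        effects = effects, sd_cat_stance = sd_cat_stance,
                        sd_cat_swing = sd_cat_swing, sd_resid = sd_resid,
                        min_duration = min_duration, protocols = protocols),
                   class = "effect_config")
  validate_effect_config(cfg)
  cfg
}

#' @rdname effect_config
#' @export
default_effects <- function() {
  tibble::tribble(
    ~protocol, ~side,   ~stance_mult, ~swing_mult,
    "tied",    "left",  1.00,         1.00,
    "tied",    "right", 0.85,         1.28,
    "lsrf",    "left",  1.10,         1.00,
    "lsrf",    "right", 0.88,         1.35,
    "lfrs",    "left",  1.00,         1.00,
    "lfrs",    "right", 0.93,         1.16
  )
}

#' @rdname effect_config
#' @export
null_effects <- function() {
  e <- default_effects()
  e$stance_mult <- 1
  e$swing_mult <- 1
  e
}

validate_effect_config <- function(cfg) {
  b <- cfg$baseline
  grid <- design_grid(cfg)
  key <- dplyr::distinct(grid, .data$protocol, .data$side, .data$speed)
  key <- dplyr::left_join(key, cfg$effects, by = c("protocol", "side"))
  if (anyNA(key$stance_mult)) {
    rlang::abort("effects table must cover every (protocol, side)")
  }
  S <- b[["d0"]] + b[["d1"]] / key$speed
  W <- (b[["c0"]] + b[["c1"]] / key$speed) - S
  if (any(W * key$swing_mult <= 0) || any(S * key$stance_mult <= 0)) {
    rlang::abort("effect configuration implies nonpositive phase duration at some grid point")
  }
  invisible(cfg)
}

# full design: one row per cat x state x protocol x speed x side
design_grid <- function(cfg) {
  speeds <- function(pr) if (pr == "tied") seq(0.4, 1.0, by = 0.1) else seq(0.5, 1.0, by = 0.1)
  purrr::map_dfr(cfg$protocols, function(pr) {
    n_cats <- if (pr == "tied") cfg$n_cats_tied else cfg$n_cats_split
    tidyr::expand_grid(protocol = pr,
                       cat = paste0(if (pr == "tied") "T" else "S", seq_len(n_cats)),
                       state = c("intact", "hemisected"),
                       speed = speeds(pr),
                       side = c("left", "right"))
  })
}

#' Generate a synthetic cat step-cycle dataset
#'
#' Draws a balanced repeated-measures dataset with the configured design:
#' per-cat stance and swing intercepts (drawn once per cat), mean phase
#' durations from the baseline curves at each limb's own belt speed (the
#' slow belt in split protocols is fixed at 0.4 m/s) times the state-effect
#' multipliers, and per-cycle normal residuals truncated below at
#' `min_duration`. Cycle duration is stance + swing exactly, per row.
#'
#' @param config An [effect_config()].
#' @param seed Integer seed; the dataset is deterministic given the seed.
#' @return A tibble (`CatDataset`) with columns `cat`, `state`, `protocol`,
#'   `speed` (the varying belt, m/s), `belt_speed` (this limb's own belt,
#'   m/s), `side`, `cycle`, `cycle_s`, `stance_s`, `swing_s`.
#' @examples
#' d <- generate_cat_dataset(effect_config(), seed = 1)
#' dplyr::count(d, protocol, state)
#' @export
generate_cat_dataset <- function(config = effect_config(), seed = NULL) {
  validate_effect_config(config)
  if (!is.null(seed)) set.seed(seed)
  b <- config$baseline
  grid <- design_grid(config)
  cats <- dplyr::distinct(grid, .data$protocol, .data$cat)
  cats$icpt_stance <- rnorm(nrow(cats), 0, config$sd_cat_stance)
  cats$icpt_swing <- rnorm(nrow(cats), 0, config$sd_cat_swing)
  grid <- dplyr::left_join(grid, cats, by = c("protocol", "cat"))
  grid <- dplyr::left_join(grid, config$effects, by = c("protocol", "side"))
  grid$belt_speed <- dplyr::case_when(
    grid$protocol == "tied" ~ grid$speed,
    grid$protocol == "lsrf" & grid$side == "left" ~ 0.4,
    grid$protocol == "lfrs" & grid$side == "right" ~ 0.4,
    TRUE ~ grid$speed
  )
  S0 <- b[["d0"]] + b[["d1"]] / grid$belt_speed
  W0 <- (b[["c0"]] + b[["c1"]] / grid$belt_speed) - S0
  hemi <- grid$state == "hemisected"
  mu_stance <- S0 * ifelse(hemi, grid$stance_mult, 1) + grid$icpt_stance
  mu_swing <- W0 * ifelse(hemi, grid$swing_mult, 1) + grid$icpt_swing

  rows <- tidyr::expand_grid(i = seq_len(nrow(grid)), cycle = seq_len(config$n_cycles))
  stance <- pmax(config$min_duration,
                 mu_stance[rows$i] + rnorm(nrow(rows), 0, config$sd_resid))
  swing <- pmax(config$min_duration,
                mu_swing[rows$i] + rnorm(nrow(rows), 0, config$sd_resid))
  out <- dplyr::bind_cols(grid[rows$i, c("cat", "state", "protocol", "speed",
                                         "belt_speed", "side")],
                          tibble::tibble(cycle = rows$cycle, stance_s = stance,
                                         swing_s = swing,
                                         cycle_s = stance + swing))
  dplyr::relocate(out, "cycle_s", .before = "stance_s")
}
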