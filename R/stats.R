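#' Two-factor repeated-measures ANOVA on step-cycle data
#'
#' Classical within-subject (state x speed) repeated-measures ANOVA for one
#' dependent variable and one hindlimb. Cycles are first averaged within
#' cat x state x speed (the cat is the repeated-measures unit); the total
#' sum of squares of the cell means is then partitioned into subject,
#' state, speed and state x speed components plus the matching
#' effect-by-subject interaction error terms, and each effect is tested as
#' `F = MS_effect / MS_(effect x subject)` with p-values from the F
#' distribution. Speed is treated as a categorical within-subject factor.
#' No sphericity correction is applied by default; Greenhouse-Geisser is
#' available behind a flag.
#'
#' @param data A step-cycle tibble with columns `cat`, `state`, `speed`,
#'   `side` and the duration columns `cycle_s`, `stance_s`, `swing_s`
#'   (e.g. from [generate_cat_dataset()], possibly filtered to one
#'   protocol).
#' @param dv Dependent variable: `"cycle"`, `"stance"` or `"swing"`.
#' @param side Which hindlimb: `"left"` or `"right"`.
#' @param gg Apply the Greenhouse-Geisser correction to the speed and
#'   state x speed tests.
#' @return An object of class `rm_anova` with the ANOVA `table` (effect,
#'   df1, df2, ss, ms, statistic, p.value), the design sizes, the cell
#'   means and the state marginal means.
#' @examples
#' d <- generate_cat_dataset(effect_config(), seed = 1)
#' fit <- rm_anova(dplyr::filter(d, protocol == "tied"), "swing", "right")
#' tidy(fit)
#' glance(fit)
#' @export
rm_anova <- function(data, dv = c("cycle", "stance", "swing"),
                     side = c("left", "right"), gg = FALSE) {
  dv <- match.arg(dv)
  side_sel <- match.arg(side)
  col <- paste0(dv, "_s")
  d <- data[data$side == side_sel, ]
  if (nrow(d) == 0) rlang::abort(sprintf("no rows for side '%s'", side_sel))
  cells <- dplyr::summarise(
    dplyr::group_by(d, cat = .data$cat, state = .data$state, speed = .data$speed),
    y = mean(.data[[col]]), .groups = "drop")

  cats <- sort(unique(cells$cat))
  states <- sort(unique(cells$state))
  speeds <- sort(unique(cells$speed))
  n <- length(cats); s <- length(states); p <- length(speeds)
  if (n < 2) rlang::abort("repeated-measures ANOVA needs at least 2 cats")
  full <- tidyr::expand_grid(cat = cats, state = states, speed = speeds)
  miss <- dplyr::anti_join(full, cells, by = c("cat", "state", "speed"))
  if (nrow(miss) > 0) {
    rlang::abort(paste0("unbalanced design; missing cells: ",
                        paste(utils::head(paste(miss$cat, miss$state, miss$speed,
                                                sep = "/"), 5), collapse = ", ")))
  }
  y <- array(0, dim = c(n, s, p))
  idx <- cbind(match(cells$cat, cats), match(cells$state, states),
               match(cells$speed, speeds))
  y[idx] <- cells$y

  m <- mean(y)
  m_i <- apply(y, 1, mean); m_j <- apply(y, 2, mean); m_k <- apply(y, 3, mean)
  m_ij <- apply(y, c(1, 2), mean); m_ik <- apply(y, c(1, 3), mean)
  m_jk <- apply(y, c(2, 3), mean)

  ss_state <- n * p * sum((m_j - m)^2)
  ss_speed <- n * s * sum((m_k - m)^2)
  ss_sxsp <- n * sum((m_jk - outer(m_j, rep(1, p)) - outer(rep(1, s), m_k) + m)^2)
  ss_subj <- s * p * sum((m_i - m)^2)
  ss_state_subj <- p * sum((m_ij - outer(m_i, rep(1, s)) - outer(rep(1, n), m_j) + m)^2)
  ss_speed_subj <- s * sum((m_ik - outer(m_i, rep(1, p)) - outer(rep(1, n), m_k) + m)^2)
  resid <- y
  for (i in seq_len(n)) for (j in seq_len(s)) for (k in seq_len(p)) {
    resid[i, j, k] <- y[i, j, k] - m_ij[i, j] - m_ik[i, k] - m_jk[j, k] +
      m_i[i] + m_j[j] + m_k[k] - m
  }
  ss_resid <- sum(resid^2)

  eff <- tibble::tibble(
    effect = c("state", "speed", "state:speed"),
    df1 = c(s - 1, p - 1, (s - 1) * (p - 1)),
    df2 = c((s - 1) * (n - 1), (p - 1) * (n - 1), (s - 1) * (p - 1) * (n - 1)),
    ss = c(ss_state, ss_speed, ss_sxsp),
    ss_err = c(ss_state_subj, ss_speed_subj, ss_resid)
  )
  eff$ms <- eff$ss / eff$df1
  eff$ms_err <- eff$ss_err / eff$df2
  eff$statistic <- ifelse(eff$ms_err > 0, eff$ms / eff$ms_err,
                          ifelse(eff$ss > 1e-24, Inf, 0))
  eps <- c(1, 1, 1)
  if (gg) {
    eps[2] <- gg_epsilon(m_ik)  # speed within subject
    # interaction: per-subject state-difference profiles across speeds
    dmat <- y[, 2, ] - y[, 1, ]
    eps[3] <- if (s == 2) gg_epsilon(dmat) else 1
  }
  eff$p.value <- pf(eff$statistic, eff$df1 * eps, eff$df2 * eps, lower.tail = FALSE)
  eff$p.value[eff$statistic == 0] <- 1

  state_means <- setNames(m_j, states)
  structure(list(table = eff[, c("effect", "df1", "df2", "ss", "ms",
                                 "statistic", "p.value")],
                 dv = dv, side = side_sel, n_cats = n, n_states = s,
                 n_speeds = p, gg = gg, cell_means = cells,
                 state_means = state_means),
            class = "rm_anova")
}

# Greenhouse-Geisser epsilon from a subjects x levels matrix
gg_epsilon <- function(mat) {
  S <- stats::cov(mat)
  k <- ncol(S)
  db <- mean(diag(S)) - mean(S)
  eps <- (k * db)^2 /
    ((k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * mean(S)^2))
  min(1, max(1 / (k - 1), eps))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Two-factor (state x speed) repeated-measures ANOVA: %s duration, %s hindlimb\n",
              x$dv, x$side))
  cat(sprintf("  %d cats x %d states x %d speeds%s\n", x$n_cats, x$n_states,
              x$n_speeds, if (x$gg) " (Greenhouse-Geisser)" else ""))
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
tidy.rm_anova <- function(x, ...) {
  x$table
}

#' @export
glance.rm_anova <- function(x, ...) {
  tb <- x$table
  tibble::tibble(dv = x$dv, side = x$side, n_cats = x$n_cats,
                 n_speeds = x$n_speeds,
                 f_state = tb$statistic[tb$effect == "state"],
                 p_state = tb$p.value[tb$effect == "state"],
                 f_speed = tb$statistic[tb$effect == "speed"],
                 p_speed = tb$p.value[tb$effect == "speed"],
                 f_interaction = tb$statistic[tb$effect == "state:speed"],
                 p_interaction = tb$p.value[tb$effect == "state:speed"],
                 state_diff = unname(x$state_means["hemisected"] -
                                       x$state_means["intact"]))
}

#' Simulation-vs-experiment qualitative agreement report
#'
#' For each (protocol, side, variable) cell, computes the sign of the
#' simulated hemisection effect -- the mean relative difference of the
#' hemisected and intact sweep curves over their common speed grid, zeroed
#' inside a dead-band -- and the sign of the data-estimated state effect --
#' the relative state marginal-mean difference from the repeated-measures
#' ANOVA, zeroed when the state effect is not significant at `alpha` or the
#' relative difference lies inside the same dead-band -- and flags whether
#' they match. Applying the dead-band to both signs keeps sub-resolution
#' differences from being over-interpreted on either route.
#'
#' @param sim_sweeps A tibble binding [run_sweep()] results for the intact
#'   and hemisected conditions (rows carrying `condition`, `protocol`,
#'   `beta`, `side` and the duration means; use [bind_sweeps()]).
#' @param dataset A [generate_cat_dataset()] tibble.
#' @param dead_band Relative dead-band below which an effect counts as 0.
#' @param alpha Significance level for the data-side state effect.
#' @return A tibble of class `agreement_report` with columns `protocol`,
#'   `side`, `variable`, `sim_effect`, `sim_sign`, `data_effect`,
#'   `p_state`, `data_sign`, `match` (signs coded -1, 0, +1).
#' @export
compare_sim_experiment <- function(sim_sweeps, dataset, dead_band = 0.02,
                                   alpha = 0.05) {
  stopifnot(all(c("condition", "protocol", "beta", "side") %in% names(sim_sweeps)))
  cells <- tidyr::expand_grid(
    protocol = intersect(unique(sim_sweeps$protocol), unique(dataset$protocol)),
    side = c("left", "right"),
    variable = c("cycle", "stance", "swing"))
  if (nrow(cells) == 0) rlang::abort("no common protocols between simulation and data")
  out <- purrr::pmap_dfr(cells, function(protocol, side, variable) {
    col <- paste0(variable, "_mean")
    si <- sim_sweeps[sim_sweeps$protocol == protocol & sim_sweeps$side == side, ]
    a <- si[si$condition == "intact", c("beta", col)]
    b <- si[si$condition == "hemisected", c("beta", col)]
    common <- intersect(round(a$beta, 6), round(b$beta, 6))
    if (length(common) == 0) {
      rlang::abort(sprintf("disjoint speed grids for protocol '%s'", protocol))
    }
    a <- a[round(a$beta, 6) %in% common, ]
    b <- b[round(b$beta, 6) %in% common, ]
    sim_eff <- mean(b[[col]] - a[[col]]) / mean(a[[col]])
    sim_sign <- sign_db(sim_eff, dead_band)

    fit <- rm_anova(dataset[dataset$protocol == protocol, ], variable, side)
    p_state <- fit$table$p.value[fit$table$effect == "state"]
    data_eff <- unname(fit$state_means["hemisected"] - fit$state_means["intact"]) /
      unname(fit$state_means["intact"])
    data_sign <- if (is.finite(p_state) && p_state >= alpha) 0L else sign_db(data_eff, dead_band)

    tibble::tibble(protocol = protocol, side = side, variable = variable,
                   sim_effect = sim_eff, sim_sign = sim_sign,
                   data_effect = data_eff, p_state = p_state,
                   data_sign = data_sign, match = sim_sign == data_sign)
  })
  structure(out, class = c("agreement_report", class(out)))
}

sign_db <- function(x, dead_band) {
  if (abs(x) < dead_band) 0L else as.integer(sign(x))
}

#' Bind sweep summaries with condition/protocol labels
#'
#' @param ... `gait_sweep` tibbles from [run_sweep()].
#' @return One tibble with `condition` and `protocol` columns.
#' @export
bind_sweeps <- function(...) {
  purrr::map_dfr(list(...), function(sw) {
    dplyr::mutate(tibble::as_tibble(sw),
                  condition = attr(sw, "condition"),
                  protocol = attr(sw, "protocol"), .before = 1)
  })
}
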