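#' Detect phase events on a flexor output trace
#'
#' Swing onsets are upward crossings of `theta_sw + hysteresis`; stance
#' onsets are downward crossings of `theta_sw - hysteresis` (flexion = swing
#' by the model's phase convention). Crossing times are linearly
#' interpolated between samples and events alternate strictly by
#' construction of the hysteresis state machine.
#'
#' @param time Sample times (s), strictly increasing.
#' @param x Flexor output trace in \[0, 1\].
#' @param theta_sw Threshold.
#' @param hysteresis Hysteresis half-band.
#' @return A tibble with columns `time` (s) and `event`
#'   (`"swing_onset"` / `"stance_onset"`), with attribute
#'   `non_rhythmic = TRUE` when fewer than 3 crossings are found.
#' @examples
#' t <- seq(0, 10, by = 0.001)
#' x <- as.numeric((t %% 1) < 0.4)
#' detect_phase_events(t, x)
#' @export
detect_phase_events <- function(time, x, theta_sw = 0.1, hysteresis = 0.05) {
  stopifnot(length(time) == length(x), all(is.finite(x)))
  up <- theta_sw + hysteresis
  dn <- theta_sw - hysteresis
  n <- length(x)
  # initial hysteresis state: first sample outside the band, else first exit
  state <- NA_character_
  i0 <- 1L
  for (i in seq_len(n)) {
    if (x[i] > up) { state <- "high"; i0 <- i; break }
    if (x[i] < dn) { state <- "low"; i0 <- i; break }
  }
  times <- numeric(0)
  events <- character(0)
  if (!is.na(state) && i0 < n) {
    for (i in seq(i0 + 1L, n)) {
      if (state == "low" && x[i] > up) {
        frac <- (up - x[i - 1L]) / (x[i] - x[i - 1L])
        times <- c(times, time[i - 1L] + frac * (time[i] - time[i - 1L]))
        events <- c(events, "swing_onset")
        state <- "high"
      } else if (state == "high" && x[i] < dn) {
        frac <- (dn - x[i - 1L]) / (x[i] - x[i - 1L])
        times <- c(times, time[i - 1L] + frac * (time[i] - time[i - 1L]))
        events <- c(events, "stance_onset")
        state <- "low"
      }
    }
  }
  out <- tibble::tibble(time = times, event = events)
  attr(out, "non_rhythmic") <- length(times) < 3
  out
}

#' Tabulate step cycles from phase events
#'
#' A cycle runs from one stance onset to the next; stance is the interval to
#' the intervening swing onset; swing is cycle minus stance (exact by
#' construction). Partial cycles at either end are discarded.
#'
#' @param events A tibble from [detect_phase_events()].
#' @return A tibble (`StepCycleTable` rows) with columns `cycle`, `cycle_s`,
#'   `stance_s`, `swing_s`, `duty`; empty (with attribute `flag`) when fewer
#'   than two complete cycles exist.
#' @export
tabulate_cycles <- function(events) {
  empty <- tibble::tibble(cycle = integer(0), cycle_s = numeric(0),
                          stance_s = numeric(0), swing_s = numeric(0),
                          duty = numeric(0))
  st <- which(events$event == "stance_onset")
  if (length(st) < 2) {
    attr(empty, "flag") <- "fewer than 2 complete cycles"
    return(empty)
  }
  rows <- purrr::map_dfr(seq_len(length(st) - 1L), function(k) {
    t0 <- events$time[st[k]]
    t1 <- events$time[st[k + 1L]]
    sw <- events$time[events$event == "swing_onset" & events$time > t0 & events$time < t1]
    if (length(sw) != 1) return(NULL)
    cyc <- t1 - t0
    stance <- sw - t0
    tibble::tibble(cycle = k, cycle_s = cyc, stance_s = stance,
                   swing_s = cyc - stance, duty = stance / cyc)
  })
  if (nrow(rows) < 1) {
    attr(empty, "flag") <- "fewer than 2 complete cycles"
    return(empty)
  }
  rows
}

#' Step-cycle table of a simulation
#'
#' Applies [detect_phase_events()] and [tabulate_cycles()] to both sides'
#' flexor half-center output traces, after discarding the initial transient.
#'
#' @param sim A [simulate_gait()] result.
#' @param transient Transient to discard (s); defaults to the value stored
#'   in the simulation.
#' @return A tibble with a `side` column bound to the per-cycle rows.
#' @export
step_cycles <- function(sim, transient = NULL) {
  transient <- transient %||% sim$transient
  keep <- sim$time >= transient
  th <- sim$params$threshold
  purrr::map_dfr(c(left = "RG-F-L", right = "RG-F-R"), function(id) {
    ev <- detect_phase_events(sim$time[keep], sim$out[keep, id],
                              th$theta_sw, th$hysteresis)
    tabulate_cycles(ev)
  }, .id = "side")
}

#' Rhythmicity test
#'
#' A cycle set is rhythmic when it has at least 3 threshold crossings (i.e.
#' at least 2 complete cycles) and the relative SD of the cycle period is
#' below `tol`.
#'
#' @param cycles A per-side cycle table ([tabulate_cycles()] rows).
#' @param tol Relative period-SD tolerance.
#' @return Logical.
#' @export
is_rhythmic <- function(cycles, tol = 0.05) {
  if (nrow(cycles) < 2) return(FALSE)
  stats::sd(cycles$cycle_s) / mean(cycles$cycle_s) < tol
}

#' Stance/swing crossing speed
#'
#' Finds the belt-speed parameter at which stance and swing durations first
#' become equal along a sweep, by linear interpolation of the first sign
#' change of (stance - swing); a crossing exactly on a grid point is
#' returned as that point.
#'
#' @param sweep A [run_sweep()] summary (or any tibble with `beta`,
#'   `side`, `stance_mean`, `swing_mean`).
#' @param side `"left"` or `"right"`.
#' @return The interpolated crossing `beta`, or `NA` if no sign change.
#' @export
find_crossing_speed <- function(sweep, side = c("right", "left")) {
  side <- match.arg(side)
  s <- sweep[sweep$side == side, ]
  s <- s[order(s$beta), ]
  if (nrow(s) < 2) rlang::abort("sweep must have at least 2 points")
  d <- s$stance_mean - s$swing_mean
  if (!all(is.finite(d))) rlang::abort("non-finite durations in sweep")
  z <- which(d == 0)
  sgn_change <- which(d[-length(d)] * d[-1] < 0)
  if (length(z) > 0 && (length(sgn_change) == 0 || z[1] <= sgn_change[1])) {
    return(s$beta[z[1]])
  }
  if (length(sgn_change) == 0) return(NA_real_)
  i <- sgn_change[1]
  s$beta[i] + (0 - d[i]) * (s$beta[i + 1] - s$beta[i]) / (d[i + 1] - d[i])
}

#' Classify the operating regime of one rhythm generator
#'
#' Isolates a single side's rhythm generator (flexor and extensor
#' half-centers with their InF/InE mutual-inhibition relays; all commissural
#' pathways removed), drives it with `alpha` (flexor) and the default
#' `gamma` (extensor), disables sensory feedback, and applies the decision
#' procedure: non-oscillatory output means the *state-machine* regime (an
#' external signal such as sensory feedback is needed to trigger the
#' extension-to-flexion switch); if oscillatory, the extensor-to-flexor
#' inhibition (`InE -> RG-F`) is silenced and the RG re-simulated -- if the
#' flexor half-center still bursts on its own the regime is *flexor-driven*
#' (intrinsic NaP bursting paces the rhythm), otherwise *classical
#' half-center* (mutual inhibition is essential).
#'
#' @param alpha Flexor-side supraspinal drive.
#' @param params Model parameters.
#' @param feedback Must be `FALSE` (the classification is defined for the
#'   isolated RG without feedback); present for interface symmetry.
#' @param duration Simulated time per probe (s).
#' @return One of `"state-machine"`, `"flexor-driven"`, `"half-center"`.
#' @examples
#' \donttest{
#' classify_regime(0)    # "state-machine"
#' classify_regime(0.5)  # "flexor-driven"
#' }
#' @export
classify_regime <- function(alpha, params = default_params(), feedback = FALSE,
                            duration = 30) {
  if (feedback) rlang::abort("regime classification is defined with feedback disabled")
  probe <- function(p) {
    net <- build_network("intact", p)
    keep_pops <- c("RG-F-L", "RG-E-L", "InF-L", "InE-L")
    net$populations <- net$populations[net$populations$id %in% keep_pops, ]
    net$connections <- net$connections[
      net$connections$source %in% c(keep_pops, "drive-alphaL", "drive-gammaL") &
        net$connections$target %in% keep_pops, ]
    # drive applies ipsilaterally only in the isolated RG
    sim <- simulate_gait(net, 0, 0, duration = duration, feedback = FALSE,
                         drives = list(alphaL = alpha, alphaR = 0,
                                       gammaL = params$drive$gamma, gammaR = 0),
                         init = list(V0 = rep(params$neuron$EL, 4),
                                     h0 = rep(0.9, 4)))
    keep <- sim$time >= min(10, duration / 3)
    ev <- detect_phase_events(sim$time[keep], sim$out[keep, "RG-F-L"],
                              params$threshold$theta_sw, params$threshold$hysteresis)
    is_rhythmic(tabulate_cycles(ev))
  }
  if (!probe(params)) return("state-machine")
  p2 <- params
  p2$weights$InE_F <- 0
  if (probe(p2)) "flexor-driven" else "half-center"
}

#' Minimum drive for intrinsic network rhythmicity
#'
#' Bisects for the smallest bilateral supraspinal drive `alpha` at which the
#' intact network, with all sensory feedback disconnected, sustains rhythmic
#' alternating flexor-extensor activity (rhythmicity per [is_rhythmic()] on
#' both sides).
#'
#' @param params Model parameters.
#' @param resolution Bisection resolution on `alpha`.
#' @param lower,upper Initial bracket.
#' @param duration Simulated time per probe (s).
#' @return The minimum rhythmic `alpha` (to `resolution`), or `NA` if no
#'   rhythmic drive exists in `[lower, upper]`.
#' @details The network is rhythmic over a bounded window of drives (too
#'   little drive leaves the flexor half-centers below their activation
#'   barrier; too much locks them in sustained activity), so the search
#'   first scans a coarse grid for any rhythmic drive and then bisects the
#'   lower edge of the window.
#' @export
min_rhythmic_drive <- function(params = default_params(), resolution = 0.01,
                               lower = 0, upper = 1, duration = NULL) {
  net <- build_network("intact", params)
  rhythmic_at <- function(alpha) {
    sim <- simulate_gait(net, 0, 0, duration = duration, feedback = FALSE,
                         drives = list(alphaL = alpha, alphaR = alpha,
                                       gammaL = params$drive$gamma,
                                       gammaR = params$drive$gamma))
    cyc <- step_cycles(sim)
    all(purrr::map_lgl(c("left", "right"),
                       ~ is_rhythmic(cyc[cyc$side == .x, ])))
  }
  if (rhythmic_at(lower)) return(lower)
  grid <- seq(lower, upper, by = max(resolution, (upper - lower) / 20))
  hit <- NA_real_
  for (a in grid[-1]) {
    if (rhythmic_at(a)) { hit <- a; break }
    lower <- a
  }
  if (is.na(hit)) return(NA_real_)
  upper <- hit
  while (upper - lower > resolution) {
    mid <- (lower + upper) / 2
    if (rhythmic_at(mid)) upper <- mid else lower <- mid
  }
  upper
}
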