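#' Supraspinal drive from belt speed
#'
#' The voluntary flexor drive follows the ipsilateral belt speed through the
#' affine map `alpha = max(0, a0 + a1 * beta)`; the extensor drive `gamma` is
#' held constant. The lesion condition is then applied: a right hemisection
#' zeroes both right-side drives, a transection zeroes all four.
#'
#' @param beta Belt-speed parameter (>= 0).
#' @param side `"left"` or `"right"`.
#' @param condition `"intact"`, `"hemisected"` or `"transected"`.
#' @param map Drive map, `default_params()$drive`.
#' @return Named list with `alpha` and `gamma` for that side.
#' @examples
#' drive_from_speed(0.4, "left", "intact")$alpha
#' drive_from_speed(0.9, "right", "hemisected")$alpha  # 0
#' @export
drive_from_speed <- function(beta, side = c("left", "right"),
                             condition = c("intact", "hemisected", "transected"),
                             map = default_params()$drive) {
  side <- match.arg(side)
  condition <- match.arg(condition)
  if (beta < 0) rlang::abort("belt-speed parameter beta must be nonnegative")
  alpha <- max(0, map$a0 + map$a1 * beta)
  gamma <- map$gamma
  if ((condition == "hemisected" && side == "right") || condition == "transected") {
    alpha <- 0
    gamma <- 0
  }
  list(alpha = alpha, gamma = gamma)
}

# Compile a cpg_network + protocol point into the argument lists the C++
# integrator takes. Returns the list of arguments for cpg_integrate_cpp.
compile_for_engine <- function(network, betaL, betaR, drives, feedback_on) {
  pops <- network$populations
  ids <- pops$id
  idx <- stats::setNames(seq_along(ids) - 1L, ids) # 0-based
  pop_list <- c(list(n = nrow(pops)),
                as.list(pops[, c("C", "gNaP", "gL", "ENa", "EL", "EsynE", "EsynI",
                                 "Vm_half", "km", "Vh_half", "kh", "tau0", "Vtau",
                                 "ktau", "Vout_min", "Vout_max")]),
                list(burster = as.integer(pops$kind == "burster")))

  cn <- network$connections
  sgn <- ifelse(cn$sign == "excitatory", 1L, -1L)
  is_pop <- cn$type == "pop"
  conns <- list(src = unname(idx[cn$source[is_pop]]),
                tgt = unname(idx[cn$target[is_pop]]),
                w = cn$weight[is_pop], sign = sgn[is_pop])

  gE0 <- gI0 <- numeric(nrow(pops))
  is_drv <- cn$type == "drive"
  drv_val <- c(`drive-alphaL` = drives$alphaL, `drive-alphaR` = drives$alphaR,
               `drive-gammaL` = drives$gammaL, `drive-gammaR` = drives$gammaR)
  for (k in which(is_drv)) {
    v <- drv_val[[cn$source[k]]] * cn$weight[k]
    j <- idx[[cn$target[k]]] + 1L
    if (sgn[k] > 0) gE0[j] <- gE0[j] + v else gI0[j] <- gI0[j] + v
  }

  is_fb <- cn$type == "feedback" & feedback_on
  chan_of <- c(`SF-E1-L` = 0L, `SF-E1-R` = 1L, `SF-E2-L` = 2L, `SF-E2-R` = 3L)
  fb <- list(chan = unname(chan_of[cn$source[is_fb]]),
             tgt = unname(idx[cn$target[is_fb]]),
             w = cn$weight[is_fb], sign = sgn[is_fb])
  if (sum(is_fb) == 0) fb <- list(chan = integer(0), tgt = integer(0),
                                  w = numeric(0), sign = integer(0))

  p <- network$params
  pop_idx0 <- function(id) if (id %in% ids) unname(idx[[id]]) else -1L
  limbs <- list(theta_sw = p$threshold$theta_sw, hysteresis = p$threshold$hysteresis,
                kE1 = p$gains$kE1, kE2 = p$gains$kE2,
                psiL = presynaptic_gain(drives$alphaL, p$gains$kPSI),
                psiR = presynaptic_gain(drives$alphaR, p$gains$kPSI),
                betaL = betaL, betaR = betaR,
                iRGF_L = pop_idx0("RG-F-L"), iRGF_R = pop_idx0("RG-F-R"),
                iRGE_L = pop_idx0("RG-E-L"), iRGE_R = pop_idx0("RG-E-R"),
                phaseL0 = 0L, phaseR0 = 1L, sL0 = 0, sR0 = 0)
  list(pops = pop_list, conns = conns, gE0 = gE0, gI0 = gI0, fb = fb, limbs = limbs)
}

#' Integrate the closed-loop model at one protocol point
#'
#' Fixed-step 4th-order Runge-Kutta integration of all population states
#' together with the two limb state machines and their sensory feedback.
#' Deterministic given the initial state. The default initial condition is
#' antisymmetric (left limb in stance, right flexor half-center active) to
#' select the alternating gait branch.
#'
#' @param network A [build_network()] result.
#' @param betaL,betaR Left/right belt-speed parameters.
#' @param duration Simulated time (s); defaults to `params$sim$duration`.
#' @param dt Integration step (ms, <= 1); defaults to `params$sim$dt`.
#' @param feedback Logical; `FALSE` disconnects SF-E1 and SF-E2 everywhere.
#' @param drives Optional named list `alphaL, alphaR, gammaL, gammaR`
#'   overriding the speed-to-drive map (the lesion condition still applies
#'   its zeroing on top).
#' @param record_dt Trace sampling interval (ms).
#' @param init Optional list with `V0`, `h0`, `phaseL0`, `phaseR0`, `sL0`,
#'   `sR0` to continue from a previous state.
#' @param record_v Also record membrane voltages.
#' @return An object of class `gait_sim`: list with `time` (s), `out`
#'   (matrix, one column per population), `phase`, `s`, `feedback` traces,
#'   the applied `drives`, metadata and final state.
#' @examples
#' \donttest{
#' net <- build_network("intact")
#' sim <- simulate_gait(net, 0.5, 0.5, duration = 20)
#' step_cycles(sim)
#' }
#' @export
simulate_gait <- function(network, betaL, betaR, duration = NULL, dt = NULL,
                          feedback = TRUE, drives = NULL, record_dt = 1,
                          init = NULL, record_v = FALSE) {
  p <- network$params
  duration <- duration %||% p$sim$duration
  dt <- dt %||% p$sim$dt
  if (dt > 1) rlang::abort("dt must be <= 1 ms")
  if (is.null(drives)) {
    dl <- drive_from_speed(betaL, "left", network$condition, p$drive)
    dr <- drive_from_speed(betaR, "right", network$condition, p$drive)
    drives <- list(alphaL = dl$alpha, alphaR = dr$alpha,
                   gammaL = dl$gamma, gammaR = dr$gamma)
  } else {
    if (network$condition == "hemisected") drives$alphaR <- drives$gammaR <- 0
    if (network$condition == "transected") {
      drives <- list(alphaL = 0, alphaR = 0, gammaL = 0, gammaR = 0)
    }
  }

  args <- compile_for_engine(network, betaL, betaR, drives, feedback)
  n <- args$pops$n
  ids <- network$populations$id
  if (is.null(init)) {
    V0 <- rep(network$params$neuron$EL, n)
    h0 <- rep(0.9, n)
    # antisymmetric seed: right flexor and left extensor active
    act <- ids %in% c("RG-F-R", "RG-E-L")
    V0[act] <- -30
    h0[ids == "RG-F-R"] <- 0.6
    init <- list(V0 = V0, h0 = h0, phaseL0 = 0L, phaseR0 = 1L, sL0 = 0, sR0 = 0)
  }
  args$limbs$phaseL0 <- init$phaseL0 %||% 0L
  args$limbs$phaseR0 <- init$phaseR0 %||% 1L
  args$limbs$sL0 <- init$sL0 %||% 0
  args$limbs$sR0 <- init$sR0 %||% 0

  nsteps <- round(duration * 1000 / dt)
  every <- max(1L, as.integer(round(record_dt / dt)))
  control <- list(dt = dt, nsteps = nsteps, record_every = every,
                  record_v = record_v, V0 = init$V0, h0 = init$h0)
  res <- cpg_integrate_cpp(args$pops, args$conns, args$gE0, args$gI0,
                           args$fb, args$limbs, control)
  colnames(res$out) <- ids
  if (record_v) colnames(res$V) <- ids
  colnames(res$phase) <- c("left", "right")
  colnames(res$s) <- c("left", "right")
  colnames(res$feedback) <- c("sfE1_L", "sfE1_R", "sfE2_L", "sfE2_R")
  structure(list(time = res$time / 1000, out = res$out, V = res$V,
                 phase = res$phase, s = res$s, feedback = res$feedback,
                 drives = drives, betaL = betaL, betaR = betaR,
                 condition = network$condition, dt = dt, duration = duration,
                 transient = p$sim$transient, params = p,
                 final = list(V0 = res$V_final, h0 = res$h_final)),
            class = "gait_sim")
}

#' @export
print.gait_sim <- function(x, ...) {
  cat(sprintf("<gait_sim> %s, betaL = %.2f, betaR = %.2f, %g s at dt = %g ms\n",
              x$condition, x$betaL, x$betaR, x$duration, x$dt))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Belt protocol sweep grid
#'
#' @param protocol `"tied"` (both belts 0.4 to 1.0), `"lsrf"` (left fixed at
#'   0.4, right 0.5 to 1.0) or `"lfrs"` (right fixed at 0.4, left 0.5 to
#'   1.0).
#' @param beta_step Grid step (0.05 for smooth simulation curves, 0.1 to
#'   mirror the experimental speed grid).
#' @return Tibble with `betaL`, `betaR` and `beta` (the varying belt).
#' @export
belt_protocol <- function(protocol = c("tied", "lsrf", "lfrs"), beta_step = 0.05) {
  protocol <- match.arg(protocol)
  grid <- function(from) seq(from, 1.0, by = beta_step)
  switch(protocol,
    tied = tibble::tibble(betaL = grid(0.4), betaR = grid(0.4), beta = grid(0.4)),
    lsrf = tibble::tibble(betaL = 0.4, betaR = grid(0.5), beta = grid(0.5)),
    lfrs = tibble::tibble(betaL = grid(0.5), betaR = 0.4, beta = grid(0.5))
  )
}

#' Run a belt-speed sweep
#'
#' Simulates every point of a tied-belt or split-belt protocol, extracts
#' per-side step cycles and returns one summary row per (protocol point,
#' side): mean and SD of cycle, stance and swing durations (s), mean duty
#' factor, number of retained cycles and a rhythmicity flag. Points that are
#' not rhythmic are flagged (`rhythmic = FALSE`), never dropped.
#'
#' @param condition `"intact"`, `"hemisected"` or `"transected"`.
#' @param protocol `"tied"`, `"lsrf"` or `"lfrs"`.
#' @param beta_step Sweep grid step.
#' @param params Model parameters.
#' @param feedback Logical; disconnect sensory feedback if `FALSE`.
#' @param duration,dt Override the integrator settings.
#' @return A tibble of class `gait_sweep` with attributes `condition` and
#'   `protocol`.
#' @examples
#' \donttest{
#' sw <- run_sweep("hemisected", "lsrf", beta_step = 0.1)
#' find_crossing_speed(sw, "right")
#' }
#' @export
run_sweep <- function(condition = c("intact", "hemisected", "transected"),
                      protocol = c("tied", "lsrf", "lfrs"), beta_step = 0.05,
                      params = default_params(), feedback = TRUE,
                      duration = NULL, dt = NULL) {
  condition <- match.arg(condition)
  protocol <- match.arg(protocol)
  net <- build_network(condition, params)
  pts <- belt_protocol(protocol, beta_step)
  res <- purrr::pmap_dfr(pts, function(betaL, betaR, beta) {
    sim <- simulate_gait(net, betaL, betaR, duration = duration, dt = dt,
                         feedback = feedback)
    cyc <- step_cycles(sim)
    purrr::map_dfr(c("left", "right"), function(sd) {
      cs <- cyc[cyc$side == sd, ]
      rhy <- is_rhythmic(cs)
      tibble::tibble(
        betaL = betaL, betaR = betaR, beta = beta, side = sd,
        n_cycles = nrow(cs), rhythmic = rhy,
        cycle_mean = mean(cs$cycle_s), cycle_sd = sd_or_na(cs$cycle_s),
        stance_mean = mean(cs$stance_s), stance_sd = sd_or_na(cs$stance_s),
        swing_mean = mean(cs$swing_s), swing_sd = sd_or_na(cs$swing_s),
        duty_mean = mean(cs$duty)
      )
    })
  })
  structure(res, class = c("gait_sweep", class(res)),
            condition = condition, protocol = protocol)
}

sd_or_na <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
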