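#' Limb state constructor
#'
#' A limb is a two-phase state machine (stance / swing) with a
#' stance-progress coordinate `s` that integrates belt displacement: during
#' stance `ds/dt = beta` (with time in seconds, so `s` is in dimensionless
#' belt-displacement units numerically equal to metres at the matched belt
#' speeds), `s` is frozen during swing and resets to 0 at each stance onset.
#'
#' @param side `"left"` or `"right"`.
#' @param phase `"stance"` or `"swing"`.
#' @param s Stance progress (>= 0).
#' @param t_phase_onset Time of the last phase switch (ms).
#' @return A list of class `limb_state`.
#' @export
limb_state <- function(side = "left", phase = "stance", s = 0, t_phase_onset = 0) {
  stopifnot(side %in% c("left", "right"), phase %in% c("stance", "swing"), s >= 0)
  structure(list(side = side, phase = phase, s = s, t_phase_onset = t_phase_onset),
            class = "limb_state")
}

#' Advance a limb state by one time step
#'
#' Applies the phase rule (swing while the ipsilateral flexor half-center
#' output exceeds the threshold, with hysteresis) and the stance-progress
#' integration/freeze/reset rules.
#'
#' @param limb A [limb_state()].
#' @param beta Belt-speed parameter (>= 0).
#' @param flexor_out Ipsilateral `RG-F` output in \[0, 1\].
#' @param dt Time step (ms, > 0).
#' @param theta_sw Phase threshold on the flexor output.
#' @param hysteresis Hysteresis half-band: swing starts above
#'   `theta_sw + hysteresis`, stance starts below `theta_sw - hysteresis`.
#' @param t Current time (ms), used to stamp phase onsets.
#' @return The updated `limb_state`.
#' @export
update_limb <- function(limb, beta, flexor_out, dt,
                        theta_sw = 0.1, hysteresis = 0.05, t = NA_real_) {
  stopifnot(dt > 0, beta >= 0)
  if (limb$phase == "stance") {
    limb$s <- limb$s + beta * dt / 1000
    if (flexor_out > theta_sw + hysteresis) {
      limb$phase <- "swing"
      limb$t_phase_onset <- t
    }
  } else if (flexor_out < theta_sw - hysteresis) {
    limb$phase <- "stance"
    limb$s <- 0
    limb$t_phase_onset <- t
  }
  limb
}

#' Raw sensory feedback signals for one limb
#'
#' During stance, `sfE1 = kE1 * s` (a ramp whose slope is the belt speed,
#' modeling hip-flexor stretch afferents whose firing grows as the hip
#' extends under belt displacement) and `sfE2 = kE2 * extensor_out`
#' (extensor-force / group Ib load feedback, proxied by the ipsilateral
#' `RG-E` output). During swing both signals are 0. Presynaptic scaling is
#' applied separately by [presynaptic_gain()].
#'
#' @param limb A [limb_state()].
#' @param beta Belt-speed parameter (unused directly; enters through `s`).
#' @param extensor_out Ipsilateral `RG-E` output in \[0, 1\].
#' @param gains List with `kE1`, `kE2`.
#' @return Named numeric vector `c(sfE1, sfE2)`.
#' @export
compute_feedback <- function(limb, beta, extensor_out, gains = default_params()$gains) {
  if (limb$phase == "swing") {
    return(c(sfE1 = 0, sfE2 = 0))
  }
  c(sfE1 = gains$kE1 * limb$s, sfE2 = gains$kE2 * extensor_out)
}

#' Presynaptic inhibition of sensory feedback
#'
#' The ipsilateral supraspinal drive `alpha` attenuates all ipsilateral
#' sensory feedback multiplicatively: the multiplier is
#' `max(0, 1 - kPSI * alpha)`, applied to both SF-E1 and SF-E2 of that side
#' (including SF-E1's crossed inhibitory branch, which is scaled by its
#' source side's drive). With `alpha = 0` (hemisected side) feedback runs at
#' full gain; at `alpha >= 1/kPSI` feedback is fully suppressed.
#'
#' @param alpha Ipsilateral supraspinal drive (>= 0).
#' @param kPSI Presynaptic-inhibition coefficient (>= 0).
#' @return Multiplier in \[0, 1\], monotone nonincreasing in `alpha`.
#' @examples
#' presynaptic_gain(0, 2)    # hemisected side: full-gain feedback
#' presynaptic_gain(0.5, 2)  # high drive: feedback suppressed
#' @export
presynaptic_gain <- function(alpha, kPSI = default_params()$gains$kPSI) {
  stopifnot(all(alpha >= 0), all(kPSI >= 0))
  pmax(0, 1 - kPSI * alpha)
}
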