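#' Default model parameters
#'
#' Returns the full parameter set of the bilateral rhythm-generator model:
#' single-population membrane constants, synaptic connection weights, sensory
#' feedback gains, the phase-detection threshold, the speed-to-drive mapping
#' and the integrator settings. All voltages are in mV, conductances in nS,
#' capacitances in pF and times in ms; population outputs and drives are
#' dimensionless.
#'
#' The membrane constants follow the standard persistent-sodium conditional
#' burster formulation: half-centers (`RG-F`, `RG-E`) carry a slowly
#' inactivating NaP current that produces the silence / bursting / tonic
#' regime sequence as excitatory drive grows; all interneurons are first-order
#' relays (`gNaP = 0`). Connection weights and feedback gains are the model's
#' calibration parameters: they were tuned once so that the intact network
#' starts bursting at a bilateral drive just below 0.35 and the closed-loop
#' sweeps reproduce the qualitative tied-belt and split-belt patterns.
#'
#' @param ... Named overrides, e.g. `default_params(kPSI = 1.5)` or
#'   `default_params(weights = list(V0D_F = 2))`. Scalar elements replace the
#'   default; list elements are merged field by field.
#' @return A nested list with elements `neuron` (membrane constants),
#'   `neuron_F` (optional overrides of those constants for the flexor
#'   half-centers only, which carry a stronger, more slowly inactivating NaP
#'   current than the extensor ones), `neuron_relay` (overrides for the
#'   relay interneurons, whose narrower output range gives them steep,
#'   switch-like recruitment),
#'   `weights` (synaptic weights), `gains` (feedback gains `kE1`, `kE2` and
#'   presynaptic-inhibition coefficient `kPSI`), `threshold` (`theta_sw`,
#'   `hysteresis` used both for the limb state machine and phase extraction),
#'   `drive` (speed-to-drive map `a0`, `a1` and the constant extensor drive
#'   `gamma`), and `sim` (duration, time step and transient discard, all in
#'   the units above with duration/transient in seconds).
#' @examples
#' p <- default_params()
#' p$neuron$gNaP
#' p2 <- default_params(gains = list(kPSI = 0))  # disable presynaptic inhibition
#' @export
default_params <- function(...) {
  p <- list(
    neuron = list(
      C = 20, gL = 4.5, EL = -64, ENa = 50, EsynE = -10, EsynI = -75,
      gNaP = 4.5, Vm_half = -40, km = -6, Vh_half = -45, kh = 4,
      tau0 = 500, Vtau = -50, ktau = 16, Vout_min = -45, Vout_max = -25
    ),
    # flexor half-centers: stronger, sharper NaP with slow inactivation at
    # plateau voltages and fast recovery at rest, giving a sustained flexion
    # plateau whose termination the network (extensor escape, crossed
    # inhibition) controls
    neuron_F = list(gNaP = 6, Vm_half = -40, km = -4, Vh_half = -42, kh = 4,
                    tau0 = 800, Vtau = -32, ktau = 8),
    # relays recruit steeply (narrow output range), giving the mutual- and
    # crossed-inhibition pathways switch-like, winner-take-all behavior
    neuron_relay = list(Vout_min = -50, Vout_max = -30),
    weights = list(
      F_InF = 12,  InF_E = 6,   E_InE = 3,   InE_F = 5,
      F_V0D = 12,  V0D_F = 1.2,
      F_V2a = 8,   V2a_V0V = 8, V0V_Ini = 8, Ini_F = 0.4,
      F_V3F = 8,   V3F_F = 0.2,
      E_V3E = 8,   V3E_E = 2.0,
      alpha_F_ipsi = 8.0, alpha_F_contra = 0.15, alpha_V2a = 2.0, alpha_InE = 8.0,
      gamma_E = 4.0,
      E1_F = 7.0, E1_Fc = 1.0, E2_E = 4.0
    ),
    gains = list(kE1 = 1.0, kE2 = 1.0, kPSI = 1.5),
    threshold = list(theta_sw = 0.1, hysteresis = 0.05),
    drive = list(a0 = 0.12, a1 = 0.7, gamma = 1),
    sim = list(duration = 50, dt = 0.1, transient = 10)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(p)) {
      rlang::abort(sprintf("unknown parameter group '%s'", nm))
    }
    if (is.list(dots[[nm]])) {
      legal <- if (nm %in% c("neuron_F", "neuron_relay")) names(p$neuron) else names(p[[nm]])
      bad <- setdiff(names(dots[[nm]]), legal)
      if (length(bad) > 0) {
        rlang::abort(sprintf("unknown parameter(s) in '%s': %s",
                             nm, paste(bad, collapse = ", ")))
      }
      if (nm %in% c("neuron_F", "neuron_relay")) p[[nm]] <- dots[[nm]]
      else p[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      p[[nm]] <- dots[[nm]]
    }
  }
  p
}
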