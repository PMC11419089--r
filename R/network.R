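#' Build the bilateral locomotor network
#'
#' Constructs the two-sided rhythm-generating circuit: on each side a flexor
#' (`RG-F`) and extensor (`RG-E`) conditional-burster half-center coupled by
#' inhibitory relays `InF`/`InE`, plus the commissural pathways that
#' coordinate the two sides (direct crossed inhibition via `V0D`, the
#' `V2a -> V0V -> Ini` crossed inhibitory route, and crossed excitation via
#' `V3-F` between flexor and `V3-E` between extensor half-centers).
#' Supraspinal drives `alpha` excite the flexor half-centers ipsi- and
#' contralaterally and the ipsilateral `V2a` population; `gamma` drives excite
#' the ipsilateral extensor half-center. Stance-phase sensory feedback enters
#' as `SF-E1` (hip-flexor stretch, excites the ipsilateral `RG-F`, inhibits
#' the contralateral one) and `SF-E2` (extensor load, excites the ipsilateral
#' `RG-E`).
#'
#' The `condition` argument applies the lesion transformations: a right
#' hemisection zeroes the weights of every connection sourced at the right
#' supraspinal drives (`drive-alphaR`, `drive-gammaR`) and nothing else; a
#' transection zeroes all four drive sources. Zeroing the right `alpha` drive
#' also removes presynaptic inhibition of right-limb feedback (see
#' [presynaptic_gain()]), so the hemisected right side runs on full-gain
#' sensory feedback.
#'
#' @param condition One of `"intact"`, `"hemisected"`, `"transected"`.
#' @param params Model parameters from [default_params()].
#' @return An object of class `cpg_network`: a list with `populations` (a
#'   tibble of per-population membrane constants), `connections` (a tibble
#'   with columns `source`, `target`, `weight`, `sign`, `crossed`, `type`),
#'   `condition` and `params`.
#' @examples
#' net <- build_network("hemisected")
#' dplyr::filter(net$connections, weight == 0)
#' @export
build_network <- function(condition = c("intact", "hemisected", "transected"),
                          params = default_params()) {
  condition <- tryCatch(match.arg(condition),
                        error = function(e) rlang::abort(
                          sprintf("unknown condition '%s': must be intact, hemisected or transected",
                                  condition[1])))
  nr <- params$neuron
  pop_ids <- c("RG-F", "RG-E", "InF", "InE", "V0D", "V2a", "V0V", "Ini", "V3-E", "V3-F")
  kinds <- c("burster", "burster", rep("relay", 8))
  pops <- purrr::map_dfr(c("L", "R"), function(sd) {
    tibble::tibble(
      id = paste0(pop_ids, "-", sd),
      side = ifelse(sd == "L", "left", "right"),
      kind = kinds,
      C = nr$C, gNaP = ifelse(kinds == "burster", nr$gNaP, 0), gL = nr$gL,
      ENa = nr$ENa, EL = nr$EL, EsynE = nr$EsynE, EsynI = nr$EsynI,
      Vm_half = nr$Vm_half, km = nr$km, Vh_half = nr$Vh_half, kh = nr$kh,
      tau0 = nr$tau0, Vtau = nr$Vtau, ktau = nr$ktau,
      Vout_min = nr$Vout_min, Vout_max = nr$Vout_max
    )
  })
  # flexor half-centers and relays may carry their own membrane constants
  nf <- params$neuron_F
  if (length(nf) > 0) {
    isF <- grepl("^RG-F", pops$id)
    for (fld in names(nf)) pops[[fld]][isF] <- nf[[fld]]
  }
  nrel <- params$neuron_relay
  if (length(nrel) > 0) {
    isR <- pops$kind == "relay"
    for (fld in names(nrel)) pops[[fld]][isR] <- nrel[[fld]]
  }

  w <- params$weights
  conn_side <- function(s) {
    o <- if (s == "L") "R" else "L" # contralateral tag
    P <- function(id) paste0(id, "-", s)
    Q <- function(id) paste0(id, "-", o)
    tibble::tribble(
      ~source,          ~target,      ~weight,           ~sign,        ~crossed, ~type,
      P("RG-F"),        P("InF"),     w$F_InF,           "excitatory", FALSE,    "pop",
      P("InF"),         P("RG-E"),    w$InF_E,           "inhibitory", FALSE,    "pop",
      P("RG-E"),        P("InE"),     w$E_InE,           "excitatory", FALSE,    "pop",
      P("InE"),         P("RG-F"),    w$InE_F,           "inhibitory", FALSE,    "pop",
      P("RG-F"),        P("V0D"),     w$F_V0D,           "excitatory", FALSE,    "pop",
      P("V0D"),         Q("RG-F"),    w$V0D_F,           "inhibitory", TRUE,     "pop",
      P("RG-F"),        P("V2a"),     w$F_V2a,           "excitatory", FALSE,    "pop",
      P("V2a"),         P("V0V"),     w$V2a_V0V,         "excitatory", FALSE,    "pop",
      P("V0V"),         Q("Ini"),     w$V0V_Ini,         "excitatory", TRUE,     "pop",
      P("Ini"),         P("RG-F"),    w$Ini_F,           "inhibitory", FALSE,    "pop",
      P("RG-F"),        P("V3-F"),    w$F_V3F,           "excitatory", FALSE,    "pop",
      P("V3-F"),        Q("RG-F"),    w$V3F_F,           "excitatory", TRUE,     "pop",
      P("RG-E"),        P("V3-E"),    w$E_V3E,           "excitatory", FALSE,    "pop",
      P("V3-E"),        Q("RG-E"),    w$V3E_E,           "excitatory", TRUE,     "pop",
      paste0("drive-alpha", s), P("RG-F"), w$alpha_F_ipsi,   "excitatory", FALSE, "drive",
      paste0("drive-alpha", s), Q("RG-F"), w$alpha_F_contra, "excitatory", TRUE,  "drive",
      paste0("drive-alpha", s), P("V2a"),  w$alpha_V2a,      "excitatory", FALSE, "drive",
      paste0("drive-alpha", s), P("InE"),  w$alpha_InE,      "excitatory", FALSE, "drive",
      paste0("drive-gamma", s), P("RG-E"), w$gamma_E,        "excitatory", FALSE, "drive",
      paste0("SF-E1-", s), P("RG-F"),  w$E1_F,            "excitatory", FALSE,    "feedback",
      paste0("SF-E1-", s), Q("RG-F"),  w$E1_Fc,           "inhibitory", TRUE,     "feedback",
      paste0("SF-E2-", s), P("RG-E"),  w$E2_E,            "excitatory", FALSE,    "feedback"
    )
  }
  conns <- dplyr::bind_rows(conn_side("L"), conn_side("R"))

  zero_src <- switch(condition,
    intact = character(0),
    hemisected = c("drive-alphaR", "drive-gammaR"),
    transected = c("drive-alphaL", "drive-alphaR", "drive-gammaL", "drive-gammaR")
  )
  conns$weight[conns$source %in% zero_src] <- 0

  structure(list(populations = pops, connections = conns,
                 condition = condition, params = params),
            class = "cpg_network")
}

#' @export
print.cpg_network <- function(x, ...) {
  cat("<cpg_network> condition:", x$condition, "\n")
  cat("  populations:", nrow(x$populations),
      sprintf("(%d bursters, %d relays)", sum(x$populations$kind == "burster"),
              sum(x$populations$kind == "relay")), "\n")
  cat("  connections:", nrow(x$connections),
      sprintf("(%d crossed, %d zero-weighted)", sum(x$connections$crossed),
              sum(x$connections$weight == 0)), "\n")
  invisible(x)
}

#' Normalized population output
#'
#' Piecewise-linear map from membrane voltage to a normalized activity in
#' \[0, 1\]: 0 at or below `Vout_min`, 1 at or above `Vout_max`, linear in
#' between.
#'
#' @param V Membrane voltage (mV), vectorized.
#' @param spec A list or one-row data frame with `Vout_min`, `Vout_max`.
#' @return Dimensionless output in \[0, 1\].
#' @examples
#' output_function(-25, list(Vout_min = -50, Vout_max = 0))
#' @export
output_function <- function(V, spec) {
  pmin(1, pmax(0, (V - spec$Vout_min) / (spec$Vout_max - spec$Vout_min)))
}

#' Population right-hand side
#'
#' Time derivatives of one population's state under the activity-based
#' formulation. For conditional bursters:
#' \deqn{C \dot V = -g_{NaP} m_\infty(V) h (V-E_{Na}) - g_L (V-E_L)
#'       - g_E (V-E_{synE}) - g_I (V-E_{synI})}
#' with \eqn{m_\infty(V) = 1/(1+\exp((V-V_{m1/2})/k_m))} (activation,
#' \eqn{k_m < 0}), and slow inactivation
#' \eqn{\dot h = (h_\infty(V) - h)/\tau_h(V)},
#' \eqn{h_\infty(V) = 1/(1+\exp((V-V_{h1/2})/k_h))},
#' \eqn{\tau_h(V) = \tau_0 / \cosh((V-V_\tau)/k_\tau)}.
#' Relays have `gNaP = 0` and `dh/dt = 0`.
#'
#' @param state List with `V` (mV) and `h` (in \[0, 1\]).
#' @param spec Population constants (a row of `build_network()$populations`
#'   or a list with the same fields, including `kind`).
#' @param gE,gI Nonnegative excitatory / inhibitory input conductances (nS).
#' @return List with `dV` (mV/ms) and `dh` (1/ms).
#' @export
population_rhs <- function(state, spec, gE, gI) {
  if (state$h < 0 || state$h > 1) {
    rlang::abort(sprintf("inactivation h = %g outside [0, 1]: corrupted state", state$h))
  }
  if (gE < 0 || gI < 0) rlang::abort("input conductances must be nonnegative")
  V <- state$V
  is_burster <- if (!is.null(spec$kind)) spec$kind == "burster" else spec$gNaP > 0
  INaP <- 0
  if (is_burster) {
    minf <- 1 / (1 + exp((V - spec$Vm_half) / spec$km))
    INaP <- spec$gNaP * minf * state$h * (V - spec$ENa)
  }
  dV <- (-INaP - spec$gL * (V - spec$EL) - gE * (V - spec$EsynE) -
           gI * (V - spec$EsynI)) / spec$C
  dh <- 0
  if (is_burster) {
    hinf <- 1 / (1 + exp((V - spec$Vh_half) / spec$kh))
    tauh <- spec$tau0 / cosh((V - spec$Vtau) / spec$ktau)
    dh <- (hinf - state$h) / tauh
  }
  list(dV = dV, dh = dh)
}

#' Per-population synaptic input conductances
#'
#' Accumulates excitatory and inhibitory conductances for every population
#' from (a) population-to-population connections weighted by the source's
#' current output, (b) supraspinal drive connections weighted by the scalar
#' drive values, and (c) sensory feedback connections weighted by the current
#' (already presynaptically scaled) feedback signal values.
#'
#' @param network A `cpg_network`.
#' @param outputs Named numeric vector of population outputs (complete over
#'   `network$populations$id`).
#' @param drives Named list/vector with `alphaL`, `alphaR`, `gammaL`,
#'   `gammaR`.
#' @param feedback Named list/vector with `sfE1_L`, `sfE1_R`, `sfE2_L`,
#'   `sfE2_R` (values after presynaptic scaling).
#' @return A tibble with columns `id`, `gE`, `gI`.
#' @export
synaptic_inputs <- function(network, outputs, drives, feedback) {
  ids <- network$populations$id
  missing_ids <- setdiff(ids, names(outputs))
  if (length(missing_ids) > 0) {
    rlang::abort(paste("outputs missing for:", paste(missing_ids, collapse = ", ")))
  }
  src_value <- c(
    outputs,
    `drive-alphaL` = unname(drives[["alphaL"]]), `drive-alphaR` = unname(drives[["alphaR"]]),
    `drive-gammaL` = unname(drives[["gammaL"]]), `drive-gammaR` = unname(drives[["gammaR"]]),
    `SF-E1-L` = unname(feedback[["sfE1_L"]]), `SF-E1-R` = unname(feedback[["sfE1_R"]]),
    `SF-E2-L` = unname(feedback[["sfE2_L"]]), `SF-E2-R` = unname(feedback[["sfE2_R"]])
  )
  cn <- network$connections
  unknown <- setdiff(unique(c(cn$source[cn$type == "pop"], cn$target)), ids)
  if (length(unknown) > 0) {
    rlang::abort(paste("connection references unknown population:",
                       paste(unknown, collapse = ", ")))
  }
  contrib <- cn$weight * src_value[cn$source]
  gE <- tapply(ifelse(cn$sign == "excitatory", contrib, 0), factor(cn$target, levels = ids), sum)
  gI <- tapply(ifelse(cn$sign == "inhibitory", contrib, 0), factor(cn$target, levels = ids), sum)
  tibble::tibble(id = ids, gE = as.numeric(gE), gI = as.numeric(gI))
}

#' Write / read a network configuration as JSON
#'
#' Serializes the full network (populations, connections, condition and the
#' parameter list) to a structured JSON file and reads it back exactly.
#'
#' @param network A `cpg_network`.
#' @param path File path.
#' @return `write_network_config()` returns `path` invisibly;
#'   `read_network_config()` returns a `cpg_network`.
#' @export
write_network_config <- function(network, path) {
  jsonlite::write_json(
    list(condition = network$condition,
         populations = network$populations,
         connections = network$connections,
         params = network$params),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(populations = tibble::as_tibble(x$populations),
                 connections = tibble::as_tibble(x$connections),
                 condition = x$condition,
                 params = x$params),
            class = "cpg_network")
}
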