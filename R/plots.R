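#' Plot a speed sweep
#'
#' Cycle, stance and swing duration curves against the varying belt-speed
#' parameter, faceted by hindlimb side.
#'
#' @param object A [run_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_sweep <- function(object, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(object),
                           c("cycle_mean", "stance_mean", "swing_mean"),
                           names_to = "variable", values_to = "duration")
  d$variable <- sub("_mean", "", d$variable)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta, y = .data$duration,
                                  colour = .data$variable)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~side) +
    ggplot2::labs(x = "belt-speed parameter (varying belt)",
                  y = "duration (s)", colour = NULL,
                  title = sprintf("%s sweep, %s model",
                                  attr(object, "protocol"), attr(object, "condition"))) +
    ggplot2::theme_minimal()
}

#' Plot simulated population activity
#'
#' Output traces of the four half-centers (left/right flexor and extensor),
#' with the per-limb stance phases shaded.
#'
#' @param object A [simulate_gait()] result.
#' @param from,to Time window (s).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_sim <- function(object, from = NULL, to = NULL, ...) {
  from <- from %||% object$transient
  to <- to %||% min(object$duration, from + 10)
  keep <- object$time >= from & object$time <= to
  ids <- c("RG-F-L", "RG-E-L", "RG-F-R", "RG-E-R")
  ids <- intersect(ids, colnames(object$out))
  d <- purrr::map_dfr(ids, function(id) {
    tibble::tibble(time = object$time[keep], population = id,
                   out = object$out[keep, id])
  })
  d$population <- factor(d$population, levels = ids)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$out)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~population, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "normalized output") +
    ggplot2::theme_minimal()
}

#' Plot an agreement report
#'
#' Tile map of simulated vs data effect signs per (protocol, side,
#' variable), marking mismatches.
#'
#' @param object A [compare_sim_experiment()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_report <- function(object, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(object),
                           c("sim_sign", "data_sign"),
                           names_to = "source", values_to = "sign")
  d$source <- sub("_sign", "", d$source)
  d$label <- c(`-1` = "-", `0` = "0", `1` = "+")[as.character(d$sign)]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$source,
                                  y = interaction(.data$side, .data$variable),
                                  fill = factor(.data$sign))) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label)) +
    ggplot2::facet_wrap(~protocol) +
    ggplot2::scale_fill_manual(values = c(`-1` = "#67a9cf", `0` = "grey85",
                                          `1` = "#ef8a62"), guide = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
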