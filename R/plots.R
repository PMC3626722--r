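# ggplot2 displays of simulated and measured labeling dynamics and NET
# concentration ranges.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot simulated mass-isotopomer dynamics
#'
#' One panel per fragment, one curve per mass isotopomer, log-scaled time
#' axis (sampling is exponentially spaced).
#'
#' @param object A `mid_timeseries`.
#' @param measured Optional measured `mid_timeseries` drawn as points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mid_timeseries <- function(object, measured = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$time_h, y = .data$fraction,
                                    colour = factor(.data$mass))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$fragment_id)) +
    ggplot2::labs(x = "time (h)", y = "mass-isotopomer fraction",
                  colour = "m+") +
    ggplot2::theme_bw()
  if (!is.null(measured)) {
    p <- p + ggplot2::geom_point(data = measured, size = 0.8)
  }
  p
}

#' Plot fitted against measured labeling dynamics
#'
#' @param fit A `flux_fit` (its stored residual table supplies the data).
#' @param system,feed The labeling system and feed used in the fit.
#' @return A ggplot object.
#' @export
plot_fit_dynamics <- function(fit, system, feed) {
  sim <- simulate_inst(system, fit$fluxes, fit$pools, feed,
                       sort(unique(fit$residuals$time_h)))
  autoplot(sim, measured = fit$residuals)
}

#' Plot NET concentration ranges
#'
#' Input (a-priori / measured) ranges as wide bars, NET-tightened ranges
#' overlaid, log-scaled concentration axis.
#'
#' @param object A `net_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.net_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(y = .data$metabolite)) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$lower,
                                         xmax = .data$upper),
                            linewidth = 3, colour = "grey80") +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$lower_net,
                                         xmax = .data$upper_net),
                            linewidth = 1.2, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (mM)", y = NULL) +
    ggplot2::theme_bw()
}
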