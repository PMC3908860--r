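#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an inverse-square-root law fit
#'
#' @param x an `isr_fit` from [fit_bd_law()] or [fit_ibi_law()].
#' @param ... unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.isr_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' One-row summary of an inverse-square-root law fit
#'
#' @inheritParams tidy.isr_fit
#' @return A tibble: `form`, `residual_norm`, `n`.
#' @export
glance.isr_fit <- function(x, ...) {
  tibble::tibble(form = x$form, residual_norm = x$residual_norm, n = x$n)
}

#' Plot a law fit in log-log coordinates
#'
#' Duration (minus the fitted baseline) against the parameter offset
#' from the bifurcation, with the fitted curve; an inverse-square-root
#' law appears as a line of slope -1/2.
#'
#' @param object an `isr_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.isr_fit <- function(object, ...) {
  cf <- object$coefficients
  bif <- if (object$form == "BD_law") cf[["c"]] else cf[["theta_bif"]]
  off <- if (object$form == "BD_law") bif - abs(object$data$theta)
         else bif - object$data$theta
  df <- tibble::tibble(offset = off,
                       excess = object$data$duration - cf[["b"]])
  line <- tibble::tibble(offset = exp(seq(log(min(off)), log(max(off)),
                                          length.out = 100)))
  line$excess <- cf[["a"]] / sqrt(line$offset)
  ggplot2::ggplot(df, ggplot2::aes(.data$offset, .data$excess)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, colour = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "parameter offset from bifurcation (V)",
                  y = "duration - baseline (s)",
                  title = paste("inverse-square-root law:", object$form))
}

#' Plot a voltage trace
#'
#' @param object a trace tibble from [integrate_neuron()] or
#'   [integrate_chain()] (faceted by segment when present).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.bw_trace <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$V)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "membrane voltage (V)")
  if ("segment" %in% names(object))
    p <- p + ggplot2::facet_grid(rows = ggplot2::vars(.data$segment))
  p
}

#' Plot a regime map
#'
#' Tile plot of the regime labels over the (theta_K2, theta_h) plane,
#' with duty cycle as tile transparency inside the bursting region.
#'
#' @param grid a [map_regimes()] tibble.
#' @return A ggplot object.
#' @export
plot_regime_map <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(.data$theta_K2, .data$theta_h,
                                     fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "theta_K2 (V)", y = "theta_h (V)", fill = "regime")
}

#' Plot the phase portrait of a metachronal wave
#'
#' Stacked voltage traces of all segments against time.
#'
#' @param experiment a [run_metachronal_experiment()] result.
#' @param offset vertical offset between consecutive segments, V.
#' @return A ggplot object.
#' @export
plot_wave <- function(experiment, offset = 0.08) {
  tr <- experiment$trace
  segs <- sort(unique(tr$segment))
  tr$V_offset <- tr$V + offset * match(tr$segment, segs)
  ggplot2::ggplot(tr, ggplot2::aes(.data$time, .data$V_offset,
                                   group = .data$segment)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::labs(x = "time (s)", y = "V by segment (offset)")
}
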