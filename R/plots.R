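#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic figures: length distributions
#' over time for a simulation, the rescaled steady profile, the log-log
#' moment trajectory with its fitted asymptotic line for a fit, and the
#' estimated kernel.
#'
#' @param object A `frag_sim`, `frag_profile`, `frag_fit` or `frag_kappa`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-purefrag
NULL

#' @rdname autoplot-purefrag
#' @export
autoplot.frag_sim <- function(object, ...) {
  sim_densities(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$x, .data$f,
                                 colour = factor(.data$time),
                                 group = .data$time)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "length x", y = "f(t, x)", colour = "time") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-purefrag
#' @export
autoplot.frag_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$g)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "rescaled length", y = "steady profile g") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-purefrag
#' @export
autoplot.frag_fit <- function(object, ...) {
  m <- object$gamma_fit$moments
  line <- tibble::tibble(
    time = m$time,
    moment = object$C * pmin(object$t_e^(-1 / object$gamma),
                             m$time^(-1 / object$gamma))
  )
  ggplot2::ggplot(m, ggplot2::aes(.data$time, .data$moment)) +
    ggplot2::geom_point(colour = "red", shape = 4, size = 2) +
    ggplot2::geom_line(data = line, colour = "darkgreen") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time", y = "mean length M1",
                  title = sprintf("gamma_e = %.3g, T_e = %.3g",
                                  object$gamma, object$t_e)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-purefrag
#' @export
autoplot.frag_kappa <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$z, .data$kappa)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "daughter ratio z", y = "estimated kappa(z)") +
    ggplot2::theme_minimal()
}
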