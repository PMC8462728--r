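#' Division-rate parameters of the fragmentation model
#'
#' The division (breakage) rate of a filament of length `x` is the power law
#' `B(x) = alpha * x^gamma`. `gamma` controls how much more fragile long
#' filaments are than short ones; `alpha` sets the overall time scale (time
#' is unitless, seconds divided by a 1 s reference).
#'
#' `gamma > 0` is the regime in which the rescaled length distribution
#' converges to a universal self-similar profile; `gamma = 0` is accepted so
#' that the solver can be validated against the closed-form Dirac-kernel
#' solution, but the self-similar machinery (moment-slope fits, Mellin
#' inversion) requires `gamma > 0`.
#'
#' @param gamma Non-negative exponent of the power-law division rate.
#' @param alpha Positive rate scale (per unit time).
#' @return An object of class `frag_params`.
#' @examples
#' frag_params(gamma = 1.3, alpha = 1)
#' @export
frag_params <- function(gamma, alpha = 1) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma < 0)
    stop_frag("`gamma` must be a single finite number >= 0")
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop_frag("`alpha` must be a single finite number > 0")
  structure(list(gamma = gamma, alpha = alpha), class = "frag_params")
}

#' @export
print.frag_params <- function(x, ...) {
  cat(sprintf("<frag_params> B(x) = %g * x^%g\n", x$alpha, x$gamma))
  invisible(x)
}

as_frag_params <- function(x) {
  if (inherits(x, "frag_params")) return(x)
  if (is.list(x) && all(c("gamma", "alpha") %in% names(x)))
    return(frag_params(x$gamma, x$alpha))
  stop_frag("cannot interpret `params`; use frag_params()")
}
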