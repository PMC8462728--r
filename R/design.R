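#' Recommend a measurement horizon for a fragmentation experiment
#'
#' Practical experimental-design helper: given the initial length
#' distribution that can be prepared and a first guess of the division-rate
#' parameters, it simulates the experiment, estimates the equilibrium time
#' `T_e` (the onset of the asymptotic straight line of `log M_1` vs
#' `log t`, taken from the [estimate_gamma()] fit), and recommends
#' measuring until `5 * T_e`. Late, well-spaced time points inform
#' `gamma` and `alpha`; if the kernel shape is the target, dense early time
#' points (before `T_e`) from a near-monodisperse start carry the most
#' information.
#'
#' @param params Guessed [frag_params()].
#' @param kernel Guessed [make_kernel()].
#' @param ic_name Planned initial condition (see [initial_condition()]).
#' @param probe_times The measurement schedule you plan to use (the fit is
#'   designed for sparse, late-ish experimental schedules, not dense early
#'   grids). Default `c(5, 10, 20, 30, 40)`.
#' @return A list with `T_e`, `recommended_horizon` (`5 * T_e`),
#'   `gamma_fit`, and an `advice` character vector.
#' @export
design_experiment <- function(params, kernel, ic_name,
                              probe_times = c(5, 10, 20, 30, 40)) {
  dens <- simulate_experiment(params, kernel, ic_name, times = probe_times,
                              N = 0)
  fit <- estimate_gamma(moment_series(dens, q = 1))
  te <- fit$t_e
  list(
    T_e = te,
    recommended_horizon = 5 * te,
    gamma_fit = fit,
    advice = c(
      sprintf("Estimated equilibrium time T_e = %.3g; measure until ~ %.3g (5 T_e).", te, 5 * te),
      "For gamma and alpha: several well-spaced time points after T_e, any initial distribution.",
      "For the kernel kappa: dense time points before T_e from a near-monodisperse (peaked) start."
    )
  )
}
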