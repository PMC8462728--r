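#' Closed-form reference solutions of the pure fragmentation equation
#'
#' A small registry of exact solutions used as ground truth when validating
#' the numerical solver. Each case fixes `(gamma, alpha, kernel)` and an
#' initial condition and evaluates `u(t, x)` from a printed formula:
#'
#' * `uniform_g1_general_f0`: `gamma = 1`, `alpha = 1`, uniform kernel, any
#'   initial profile `f0`:
#'   `u = e^{-tx} (f0(x) + Int_x^Inf f0(y) (2t + t^2 (y - x)) dy)`.
#' * `uniform_g2_general_f0`: `gamma = 2`, `alpha = 1`, uniform kernel:
#'   `u = e^{-t x^2} (f0(x) + Int_x^Inf 2 t y f0(y) dy)`.
#' * `uniform_anyg_exp_init`: any `gamma > 0`, `alpha = 1`, uniform kernel,
#'   `f0 = e^{-s x^gamma}`: `u = e^{-(t+s) x^gamma} (1 + t/s)^{2/gamma}`.
#' * `uniform_g2_exp_init`: `gamma = 2`, `alpha = 1`, uniform kernel,
#'   `f0 = e^{-x}`: `u = e^{-t x^2 - x} (1 + 2t (1 + x))`.
#' * `parabolic_g3`: `gamma = 3`, `alpha = 1/6`, kernel `12 z (1 - z)`:
#'   `u = f0 e^{-t x^3 / 6} + 2 t Int_x^Inf e^{-t y^3/6} y^{-2} Int_y^Inf l f0(l) dl dy`.
#' * `dirac_g0`: `gamma = 0`, `alpha = 1`, Dirac-half kernel:
#'   `u = e^{-t} sum_k (4t)^k / k! f0(2^k x)` (series truncated when a term
#'   falls below 1e-14 of the running sum).
#'
#' The general-`gamma` uniform-kernel solution for arbitrary initial data
#' involves Kummer's confluent hypergeometric function and is registered as
#' skipped (`oracle_cases()` lists it with `implemented = FALSE`).
#'
#' @param case_id One of the case names above.
#' @param t Time (scalar, `t >= 0`).
#' @param x Length vector (`x > 0`).
#' @param f0 Initial profile for the general-`f0` cases (vectorized
#'   function); default `exp(-x)`.
#' @param gamma,s Parameters for `uniform_anyg_exp_init`.
#' @return `oracle_solution()`: vector of `u(t, x)` values.
#' @examples
#' oracle_solution("uniform_anyg_exp_init", t = 1, x = 0.5, gamma = 1, s = 1)
#' @export
oracle_solution <- function(case_id, t, x, f0 = function(y) exp(-y),
                            gamma = 1, s = 1) {
  if (t < 0) stop_frag("t must be >= 0")
  if (any(x <= 0)) stop_frag("x must be > 0")
  switch(
    case_id,
    uniform_g1_general_f0 = {
      tail <- vapply(x, function(xi)
        stats::integrate(function(y) f0(y) * (2 * t + t^2 * (y - xi)),
                         xi, Inf, rel.tol = 1e-10)$value, numeric(1))
      exp(-t * x) * (f0(x) + tail)
    },
    uniform_g2_general_f0 = {
      tail <- vapply(x, function(xi)
        stats::integrate(function(y) 2 * t * y * f0(y),
                         xi, Inf, rel.tol = 1e-10)$value, numeric(1))
      exp(-t * x^2) * (f0(x) + tail)
    },
    uniform_anyg_exp_init = {
      if (gamma <= 0 || s <= 0) stop_frag("needs gamma > 0 and s > 0")
      exp(-(t + s) * x^gamma) * (1 + t / s)^(2 / gamma)
    },
    uniform_g2_exp_init = exp(-t * x^2 - x) * (1 + 2 * t * (1 + x)),
    parabolic_g3 = {
      FF <- function(y) vapply(y, function(yi)
        stats::integrate(function(l) l * f0(l), yi, Inf, rel.tol = 1e-10)$value,
        numeric(1))
      tail <- vapply(x, function(xi)
        stats::integrate(function(y) exp(-t * y^3 / 6) * FF(y) / y^2,
                         xi, Inf, rel.tol = 1e-10)$value, numeric(1))
      f0(x) * exp(-t * x^3 / 6) + 2 * t * tail
    },
    dirac_g0 = {
      total <- f0(x)
      coef <- 1
      k <- 0
      # terms (4t)^k/k! grow until k ~ 4t, then decay factorially
      while (t > 0) {
        k <- k + 1
        coef <- coef * 4 * t / k
        term <- coef * f0(2^k * x)
        total <- total + term
        if ((k >= 4 * t && max(abs(term)) < 1e-14 * max(abs(total))) || k > 10000)
          break
      }
      exp(-t) * total
    },
    stop_frag(sprintf("unknown oracle case '%s'", case_id))
  )
}

#' @rdname oracle_solution
#' @return `oracle_cases()`: a tibble describing the registry (id, gamma,
#'   alpha, kernel kind, whether implemented, and whether the case passes
#'   the conservation/PDE gate that qualifies it as solver ground truth).
#'   The `parabolic_g3` evaluator reproduces its printed formula but that
#'   formula is not mass-conserving (the printed coefficients appear
#'   garbled), so it is registered with `passes_gate = FALSE` and excluded
#'   from solver validation; the Kummer-function row is registered as not
#'   implemented (no confluent hypergeometric function in the supported
#'   numerical stack, and the printed argument list is ambiguous).
#' @export
oracle_cases <- function() {
  tibble::tibble(
    case_id = c("uniform_g1_general_f0", "uniform_g2_general_f0",
                "uniform_anyg_exp_init", "uniform_g2_exp_init",
                "parabolic_g3", "dirac_g0", "uniform_anyg_kummer"),
    gamma = c(1, 2, NA, 2, 3, 0, NA),
    alpha = c(1, 1, 1, 1, 1 / 6, 1, 1),
    kernel = c("uniform", "uniform", "uniform", "uniform",
               "parabolic", "dirac_half", "uniform"),
    implemented = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    passes_gate = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, NA)
  )
}

#' Mean length of an oracle solution
#'
#' Returns the first moment `M1(t)` of the normalized length distribution
#' `f(t, .) = u(t, .) / Int u`, computed in closed form where available
#' (`uniform_anyg_exp_init`: `M1 = (t + s)^{-1/gamma} Gamma(2/gamma) / Gamma(1/gamma)`)
#' and by adaptive quadrature otherwise.
#'
#' @inheritParams oracle_solution
#' @return Scalar mean length at time `t`.
#' @export
oracle_mean_length <- function(case_id, t, f0 = function(y) exp(-y),
                               gamma = 1, s = 1) {
  if (case_id == "uniform_anyg_exp_init")
    return((t + s)^(-1 / gamma) * gamma(2 / gamma) / gamma(1 / gamma))
  up <- 80
  num <- stats::integrate(function(x) x * oracle_solution(case_id, t, x, f0, gamma, s),
                          1e-10, up, rel.tol = 1e-9)$value
  den <- stats::integrate(function(x) oracle_solution(case_id, t, x, f0, gamma, s),
                          1e-10, up, rel.tol = 1e-9)$value
  num / den
}

# Numeric residual of the fragmentation PDE for an oracle case, used as the
# acceptance gate for typographically ambiguous printed formulas: central
# finite difference in t against the right-hand side computed by quadrature.
oracle_pde_residual <- function(case_id, t, x, f0 = function(y) exp(-y),
                                gamma_rate, alpha, kernel, dt = 1e-4) {
  u_now <- function(xx) oracle_solution(case_id, t, xx, f0)
  dudt <- (oracle_solution(case_id, t + dt, x, f0) -
             oracle_solution(case_id, t - dt, x, f0)) / (2 * dt)
  gain <- vapply(x, function(xi)
    stats::integrate(function(y) kernel$density(xi / y) * y^(gamma_rate - 1) * u_now(y),
                     xi, 80, rel.tol = 1e-8)$value, numeric(1))
  rhs <- -alpha * x^gamma_rate * u_now(x) + alpha * gain
  dudt - rhs
}
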