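#' Normalize a gridded length density to unit integral
#'
#' The observable in imaging experiments is the normalized length
#' distribution `f = u / Int u dx`. Input is a tibble with a length column
#' `x` and a density column `u` (or `f`); if a `time` column is present each
#' time point is normalized separately.
#'
#' @param data A data frame with columns `x` and `u` (or `f`), optionally
#'   `time`.
#' @return A tibble with columns (`time`,) `x`, `f`, unit trapezoid integral
#'   per time point.
#' @export
normalize_density <- function(data) {
  v <- density_cols(data)
  grouped <- "time" %in% names(data)
  out <- data |>
    tibble::as_tibble() |>
    dplyr::rename(.val = dplyr::all_of(v))
  if (any(out$.val < 0)) stop_frag("density values must be nonnegative")
  if (grouped) out <- dplyr::group_by(out, .data$time)
  out <- out |>
    dplyr::mutate(.mass = trapz(.data$x, .data$.val)) |>
    dplyr::mutate(f = .data$.val / .data$.mass) |>
    dplyr::ungroup()
  if (any(!is.finite(out$f))) stop_frag("zero-mass density cannot be normalized")
  cols <- c(if (grouped) "time", "x", "f")
  dplyr::select(out, dplyr::all_of(cols))
}

#' Moments of length distributions or length samples
#'
#' Computes `M_q(t) = Int x^q f(t, x) dx` for gridded distributions
#' (trapezoid quadrature, after normalization) or `mean(length^q)` for raw
#' length samples. For large times `log M_q(t)` approaches a straight line
#' of slope `-q / gamma` in `log t` — the basis of the `gamma` estimator.
#'
#' @param data Either densities (columns `time`, `x`, `f`/`u`) or samples
#'   (columns `time`, `length`).
#' @param q Moment orders (vector, `q >= 0`).
#' @return A tibble with columns `time`, `q`, `moment`.
#' @examples
#' d <- tibble::tibble(time = 1, x = seq(0.01, 30, by = 0.01),
#'                     f = exp(-seq(0.01, 30, by = 0.01)))
#' moment_series(d, q = 1:2) # ~ 1 and 2
#' @export
moment_series <- function(data, q = 1) {
  if (any(q < 0)) stop_frag("q must be >= 0")
  if ("length" %in% names(data)) {
    if (nrow(data) == 0L) stop_frag("empty sample")
    per_q <- function(qq)
      data |>
        dplyr::group_by(.data$time) |>
        dplyr::summarise(moment = mean(.data$length^qq), .groups = "drop") |>
        dplyr::mutate(q = qq)
  } else {
    dens <- normalize_density(if ("time" %in% names(data)) data else
      dplyr::mutate(tibble::as_tibble(data), time = 0))
    per_q <- function(qq)
      dens |>
        dplyr::group_by(.data$time) |>
        dplyr::summarise(moment = trapz(.data$x, .data$x^qq * .data$f),
                         .groups = "drop") |>
        dplyr::mutate(q = qq)
  }
  purrr::map_dfr(q, per_q) |>
    dplyr::select("time", "q", "moment") |>
    dplyr::arrange(.data$q, .data$time)
}

#' Self-similar rescaling of a late-time distribution
#'
#' For `gamma > 0` the rescaled distribution
#' `g_hat(x) = t^{-1/gamma} f(t, t^{-1/gamma} x)` converges to the unit-mass
#' steady profile as `t` grows. The rescaling is a coordinate change on the
#' stored grid (no interpolation is needed: the grid is mapped to
#' `x * t^{1/gamma}`), followed by renormalization to unit integral.
#'
#' @param data Densities (tibble with `time`, `x`, `f`/`u`) or a `frag_sim`.
#' @param gamma Rescaling exponent (`> 0`), typically the estimated gamma.
#' @param time Which time point to rescale; default the last one.
#' @return A `frag_profile`: tibble with columns `x`, `g` and attributes
#'   `t_f` (source time) and `gamma`.
#' @export
rescaled_profile <- function(data, gamma, time = NULL) {
  if (gamma <= 0) stop_frag("gamma must be > 0")
  if (inherits(data, "frag_sim")) data <- sim_densities(data)
  data <- normalize_density(data)
  tf <- time %||% max(data$time)
  if (tf <= 0) stop_frag("rescaling needs a time > 0")
  sel <- data[abs(data$time - tf) < 1e-9 * max(tf, 1), ]
  if (nrow(sel) == 0L) stop_frag("requested time not present in the data")
  x_new <- sel$x * tf^(1 / gamma)
  g <- sel$f * tf^(-1 / gamma)
  g <- g / trapz(x_new, g)
  new_profile(x_new, g, t_f = tf, gamma = gamma)
}

new_profile <- function(x, g, t_f = NA_real_, gamma = NA_real_) {
  out <- tibble::tibble(x = x, g = g)
  class(out) <- c("frag_profile", class(out))
  attr(out, "t_f") <- t_f
  attr(out, "gamma") <- gamma
  out
}

as_profile <- function(data) {
  if (inherits(data, "frag_profile")) return(data)
  v <- density_cols(data)
  g <- data[[v]]
  new_profile(data$x, g / trapz(data$x, g))
}

#' Numeric Mellin transform of a profile
#'
#' Evaluates `G_hat(s) = Int x^{s-1} g_hat(x) dx` by trapezoid quadrature in
#' `w = log x` (integrand `e^{s w} g(e^w)`), for real or complex `s`. For a
#' unit-mass profile `G_hat(1) = 1`. A warning is raised when the integrand
#' has not decayed at the grid ends (estimated tail contribution above 1% of
#' the result).
#'
#' @param profile A `frag_profile` (or tibble with `x` and `g`).
#' @param s Real or complex vector, `Re(s) >= 1` recommended.
#' @return Numeric or complex vector `G_hat(s)`.
#' @examples
#' xg <- exp(seq(log(1e-4), log(50), length.out = 800))
#' pr <- tibble::tibble(x = xg, g = exp(-xg))
#' mellin_numeric(pr, 2) # Gamma(2) = 1
#' @export
mellin_numeric <- function(profile, s) {
  profile <- as_profile(profile)
  w <- log(profile$x)
  g <- profile$g
  one <- function(si) {
    integrand <- exp(si * w) * g
    val <- trapz(w, integrand)
    edge <- (abs(integrand[1]) + abs(integrand[length(w)])) * mean(diff(w)) * 10
    if (is.finite(abs(val)) && abs(val) > 0 && edge > 0.01 * abs(val))
      warning("mellin_numeric: integrand has not decayed at the grid ends; value may be inaccurate",
              call. = FALSE)
    val
  }
  out <- vapply(s, one, if (is.complex(s)) complex(1) else numeric(1))
  out
}

#' Steady-profile Mellin values from the moment recursion
#'
#' The Mellin transform of the steady profile satisfies the non-local
#' functional equation `(2 - s) G(s) = alpha gamma (K(s) - 1) G(s + gamma)`,
#' which, anchored at the normalization `G_hat(1) = 1`, predicts the chain
#' `G_hat(1 + k gamma)` independently of any simulation:
#' `G_hat(s + gamma) = (2 - s) G_hat(s) / (alpha gamma (K(s) - 1))`.
#' The chain must avoid the resonance at `s = 2` where both `(2 - s)` and
#' `K(s) - 1` vanish.
#'
#' @param params [frag_params()] with `gamma > 0`.
#' @param kernel [make_kernel()].
#' @param start_s Chain anchor (default 1, where `G_hat = 1`).
#' @param n_steps Number of recursion steps.
#' @param G_start Value of `G_hat(start_s)` (default 1).
#' @param tol Resonance guard on `|s - 2|` and `|K(s) - 1|`.
#' @return A tibble with columns `s` and `G` (`G_hat(s)`), starting at the
#'   anchor.
#' @examples
#' steady_moments_recursion(frag_params(1, 1), make_kernel("uniform"), n_steps = 1)
#' @export
steady_moments_recursion <- function(params, kernel, start_s = 1, n_steps = 3,
                                     G_start = 1, tol = 1e-8) {
  params <- as_frag_params(params)
  if (params$gamma <= 0) stop_frag("the recursion needs gamma > 0")
  kernel <- as_frag_kernel(kernel)
  s <- start_s
  G <- G_start
  ss <- s
  GG <- G
  for (k in seq_len(n_steps)) {
    Ks <- kernel_mellin(kernel, s)
    if (abs(s - 2) < tol || abs(Ks - 1) < tol)
      stop_frag(sprintf("recursion chain hits the resonance near s = 2 (s = %g); choose another start_s", s))
    G <- (2 - s) * G / (params$alpha * params$gamma * (Ks - 1))
    s <- s + params$gamma
    ss <- c(ss, s)
    GG <- c(GG, G)
  }
  tibble::tibble(s = ss, G = GG)
}

#' Classify a steady profile by its behaviour at the origin
#'
#' Class A kernels (no endpoint breakage) produce steady profiles that
#' vanish at `x = 0` and have a single interior peak; class B kernels
#' (endpoint breakage) produce profiles that are positive at `x = 0` and
#' decreasing nearby. The test compares the profile value near the origin
#' with `theta * max(g)` and counts peaks on a lightly smoothed profile.
#'
#' @param profile A `frag_profile` (or tibble with `x`, `g`), resolved near
#'   `x = 0`.
#' @param theta Relative origin threshold, default 0.05.
#' @return `"A"`, `"B"` or `"undetermined"`.
#' @export
classify_profile <- function(profile, theta = 0.05) {
  profile <- as_profile(profile)
  g <- profile$g
  n <- length(g)
  if (n < 10L) return("undetermined")
  # 5-point moving average to suppress grid noise
  sm <- stats::filter(g, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- g[is.na(sm)]
  sm <- as.numeric(sm)
  mx <- max(sm)
  # origin value: average over the lowest 2% of the grid
  near0 <- sm[seq_len(max(3L, ceiling(0.02 * n)))]
  g0 <- mean(near0)
  peak_i <- which.max(sm)
  d <- diff(sm)
  sign_changes <- sum(diff(sign(d[abs(d) > 1e-10 * mx])) != 0)
  unimodal <- sign_changes <= 1
  if (g0 < theta * mx && unimodal && peak_i > 0.02 * n) return("A")
  early <- d[seq_len(max(3L, ceiling(0.05 * n)))]
  if (g0 >= theta * mx && mean(early <= 1e-6 * mx) > 0.7) return("B")
  "undetermined"
}
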