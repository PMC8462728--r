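#' Fragmentation kernels
#'
#' The fragmentation kernel `kappa(z)` is the distribution of the relative
#' daughter length `z = x/y` produced when a parent of length `y` divides.
#' Binary fission imposes `integral(kappa) = 2` (two daughters per event) and
#' mass conservation imposes `integral(z * kappa) = 1`. All built-in kernels
#' are symmetric about `z = 1/2` (daughters come in complementary pairs), so
#' the second condition follows automatically from the first.
#'
#' Built-in kinds:
#' * `uniform`: `kappa(z) = 2`, breakage equally likely anywhere.
#' * `gaussian`: truncated Gaussian bump; parameters `center` (default 1/2)
#'   and `sd` (default 0.1). Central breakage, class A.
#' * `two_peaked_gaussian`: symmetric sum of Gaussians at `1/2 +- offset`
#'   (default offset 0.25) with common `sd` (default 0.05).
#' * `parabolic`: `kappa(z) = 12 z (1 - z)`.
#' * `dirac_half`: an atom of weight 2 at `z = 1/2` (exact halving); stored
#'   as an atom, not a narrow density.
#' * `custom`: a tabulated density, `params = list(z = ..., kappa = ...)`,
#'   linearly interpolated and renormalized on construction.
#'
#' Densities are renormalized at construction so that the integral over
#' (0, 1) equals 2 to quadrature accuracy.
#'
#' @param kind One of `"uniform"`, `"gaussian"`, `"two_peaked_gaussian"`,
#'   `"parabolic"`, `"dirac_half"`, `"custom"`.
#' @param params Named list of kind-specific parameters (see Details).
#' @return An object of class `frag_kernel` with fields `kind`, `params`,
#'   `density` (a vectorized function of `z`), `atom` (for `dirac_half`),
#'   and `kernel_class` (`"A"`, `"B"` or `"mixed"`).
#' @examples
#' make_kernel("uniform")
#' make_kernel("gaussian", list(center = 0.5, sd = 0.1))
#' @export
make_kernel <- function(kind = c("uniform", "gaussian", "two_peaked_gaussian",
                                 "parabolic", "dirac_half", "custom"),
                        params = list()) {
  kind <- match.arg(kind)
  atom <- NULL
  raw <- NULL

  if (kind == "uniform") {
    raw <- function(z) rep_len(2, length(z))
  } else if (kind == "gaussian") {
    center <- params$center %||% 0.5
    sd <- params$sd %||% 0.1
    if (!is.finite(sd) || sd <= 0) stop_frag("gaussian kernel needs sd > 0")
    if (!is.finite(center) || center <= 0 || center >= 1)
      stop_frag("gaussian kernel needs center in (0, 1)")
    params <- list(center = center, sd = sd)
    raw <- function(z) stats::dnorm(z, center, sd)
  } else if (kind == "two_peaked_gaussian") {
    offset <- params$offset %||% 0.25
    sd <- params$sd %||% 0.05
    if (!is.finite(sd) || sd <= 0) stop_frag("two-peaked kernel needs sd > 0")
    if (!is.finite(offset) || offset <= 0 || offset >= 0.5)
      stop_frag("two-peaked kernel needs offset in (0, 1/2)")
    params <- list(offset = offset, sd = sd)
    raw <- function(z) stats::dnorm(z, 0.5 - offset, sd) + stats::dnorm(z, 0.5 + offset, sd)
  } else if (kind == "parabolic") {
    raw <- function(z) 12 * z * (1 - z)
  } else if (kind == "dirac_half") {
    atom <- list(z = 0.5, weight = 2)
  } else { # custom
    zt <- params$z
    kt <- params$kappa
    if (is.null(zt) || is.null(kt) || length(zt) != length(kt) || length(zt) < 3L)
      stop_frag("custom kernel needs params$z and params$kappa of equal length >= 3")
    if (any(!is.finite(zt)) || any(!is.finite(kt)) || any(kt < 0) ||
        any(zt < 0) || any(zt > 1))
      stop_frag("custom kernel table must be finite, nonnegative, with z in [0, 1]")
    o <- order(zt)
    zt <- zt[o]; kt <- kt[o]
    raw <- function(z) {
      out <- stats::approx(zt, kt, xout = z, rule = 2)$y
      out[z < min(zt) | z > max(zt)] <- 0
      pmax(out, 0)
    }
  }

  if (is.null(atom)) {
    if (kind == "custom") {
      # the density is piecewise linear: trapezoid on the knots is exact
      total <- trapz(zt, kt)
    } else {
      total <- stats::integrate(raw, 0, 1, rel.tol = 1e-12, abs.tol = 0,
                                subdivisions = 400L)$value
    }
    if (total <= 0) stop_frag("kernel density integrates to zero")
    cnorm <- 2 / total
    density <- function(z) {
      out <- numeric(length(z))
      inside <- z > 0 & z < 1
      out[inside] <- cnorm * raw(z[inside])
      out
    }
    zfine <- seq(1e-9, 1 - 1e-9, length.out = 20001L)
    zmass <- trapz(zfine, zfine * density(zfine))
    if (abs(zmass - 1) > 1e-3)
      stop_frag(sprintf(paste0("kernel first moment is %.4f, not 1: mass would not be ",
                               "conserved (kernels must be symmetric or rebalanced)"), zmass))
  } else {
    density <- function(z) numeric(length(z))
  }

  k <- structure(
    list(kind = kind, params = params, density = density, atom = atom),
    class = "frag_kernel"
  )
  k$kernel_class <- classify_kernel(k)
  k
}

#' @export
print.frag_kernel <- function(x, ...) {
  ps <- if (length(x$params)) paste(names(x$params), unlist(x$params),
                                    sep = " = ", collapse = ", ") else ""
  cat(sprintf("<frag_kernel> %s(%s), class %s\n", x$kind, ps, x$kernel_class))
  invisible(x)
}

as_frag_kernel <- function(x) {
  if (inherits(x, "frag_kernel")) return(x)
  if (is.character(x) && length(x) == 1L) return(make_kernel(x))
  if (is.list(x) && !is.null(x$kind)) return(make_kernel(x$kind, x$params %||% list()))
  stop_frag("cannot interpret `kernel`; use make_kernel()")
}

#' Mellin transform of a fragmentation kernel
#'
#' Evaluates `K(s) = integral over (0,1) of z^(s-1) kappa(z) dz`. Exact
#' closed forms are used for the uniform (`2/s`), Dirac-half (`2^(2-s)`) and
#' parabolic (`12 / ((s+1)(s+2))`) kernels; other kernels use adaptive
#' quadrature (real and imaginary parts separately for complex `s`).
#'
#' For any binary kernel `K(1) = 2` (two daughters) and `K(2) = 1`
#' (mass conservation).
#'
#' @param kernel A [make_kernel()] object.
#' @param s Numeric or complex vector with `Re(s) > 0`. All built-in
#'   kernels are bounded measures on (0, 1), so the integral converges for
#'   `Re(s) > 0`; convergence for unbounded custom tails is the caller's
#'   responsibility.
#' @return Numeric (for real `s`) or complex vector of `K(s)` values.
#' @examples
#' u <- make_kernel("uniform")
#' kernel_mellin(u, 1) # 2: binary fission
#' kernel_mellin(u, 2) # 1: mass conservation
#' @export
kernel_mellin <- function(kernel, s) {
  kernel <- as_frag_kernel(kernel)
  if (any(Re(s) <= 0)) stop_frag("kernel_mellin requires Re(s) > 0")
  out <- switch(
    kernel$kind,
    uniform = 2 / s,
    dirac_half = 2^(2 - s),
    parabolic = 12 / ((s + 1) * (s + 2)),
    custom = {
      # piecewise-linear table: fixed fine trapezoid (adaptive quadrature
      # stalls on the kinks)
      zf <- seq(1e-9, 1 - 1e-9, length.out = 20001L)
      kf <- kernel$density(zf)
      vapply(s, function(si) trapz(zf, kf * zf^(si - 1)),
             if (is.complex(s)) complex(1) else numeric(1))
    },
    {
      one <- function(si) {
        re <- stats::integrate(function(z) kernel$density(z) * Re(z^(si - 1)),
                               0, 1, rel.tol = 1e-10, subdivisions = 400L)$value
        if (is.complex(si)) {
          im <- stats::integrate(function(z) kernel$density(z) * Im(z^(si - 1)),
                                 0, 1, rel.tol = 1e-10, abs.tol = 1e-12,
                                 subdivisions = 400L)$value
          complex(real = re, imaginary = im)
        } else re
      }
      vapply(s, one, if (is.complex(s)) complex(1) else numeric(1))
    }
  )
  if (!is.complex(s)) out <- Re(out)
  out
}

#' Classify a kernel by its endpoint behaviour
#'
#' Smooth kernels fall in two qualitative classes: class A kernels vanish at
#' both endpoints (`kappa(0) = kappa(1) = 0`, interior breakage, e.g. a
#' Gaussian bump), class B kernels are positive at both endpoints (end
#' breakage, e.g. the uniform kernel). The class is read off the density
#' near `z = 0` and `z = 1` against a small threshold (`tol_zero` relative
#' to the kernel maximum); kernels with one large and one small endpoint
#' are reported as `"mixed"`. The Dirac-half atom has no endpoint mass and
#' is class A.
#'
#' @param kernel A [make_kernel()] object.
#' @param tol_zero Relative threshold below which an endpoint value counts
#'   as zero. Default 1e-3.
#' @return `"A"`, `"B"` or `"mixed"`.
#' @export
classify_kernel <- function(kernel, tol_zero = 1e-3) {
  if (!is.null(kernel$atom)) return("A")
  eps <- 1e-6
  zg <- seq(eps, 1 - eps, length.out = 2001L)
  mx <- max(kernel$density(zg))
  k0 <- kernel$density(eps) / mx
  k1 <- kernel$density(1 - eps) / mx
  if (k0 < tol_zero && k1 < tol_zero) "A"
  else if (k0 >= tol_zero && k1 >= tol_zero) "B"
  else "mixed"
}
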