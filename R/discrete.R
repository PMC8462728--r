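#' Solve the discrete (monomer-resolved) fragmentation model
#'
#' Companion model that tracks the number `u_l(t)` of filaments made of `l`
#' monomers of length `r`. Each filament of `l` monomers breaks at rate
#' `alpha (l r)^gamma`; a breaking filament of `j` monomers produces
#' daughters of `l < j` monomers with weights proportional to
#' `kappa(l / j)`, rebalanced per donor so that the total monomer count
#' `sum(l * u_l)` is conserved exactly. The Dirac-half kernel sends even
#' donors to `j/2` and splits odd donors between `(j-1)/2` and `(j+1)/2`.
#'
#' Integration is explicit Euler with a step satisfying
#' `alpha (N r)^gamma delta_t <= 0.1` (the model plays the role of a
#' validation companion to [solve_continuous()], not a production solver).
#'
#' @param params [frag_params()].
#' @param kernel [make_kernel()].
#' @param r Monomer length (length units).
#' @param u0_counts Numeric vector of length `N + 1`: initial counts for
#'   `l = 0, ..., N`.
#' @param N Largest filament size in monomers (`N >= 2`).
#' @param output_times Increasing times (0 allowed) for snapshots.
#' @param delta_t Time step; default `0.1 / (alpha (N r)^gamma)`.
#' @return A `frag_discrete` object; `tidy()` it into a tibble with columns
#'   `time`, `l`, `x = l * r`, `count`.
#' @export
solve_discrete <- function(params, kernel, r, u0_counts, N, output_times,
                           delta_t = NULL) {
  params <- as_frag_params(params)
  kernel <- as_frag_kernel(kernel)
  N <- as.integer(N)
  if (N < 2L) stop_frag("N must be >= 2")
  if (length(u0_counts) != N + 1L) stop_frag("u0_counts must have length N + 1")
  if (any(u0_counts < 0)) stop_frag("u0_counts must be nonnegative")
  if (any(output_times < 0) || is.unsorted(output_times, strictly = TRUE))
    stop_frag("output_times must be strictly increasing and >= 0")

  rate <- params$alpha * ((0:N) * r)^params$gamma # rate[l+1] = B(l r)
  rate[1] <- 0 # monomer-free "size zero" bin never breaks
  rate[2] <- 0 # single monomers cannot divide
  delta_t <- delta_t %||% (0.1 / max(rate))

  # G[l+1, j+1] = fraction weights c_{lj}: donor j sends c_{lj} daughters of
  # size l, with sum_l l * c_{lj} = j (exact monomer conservation) and
  # sum_l c_{lj} = 2 for symmetric kernels.
  G <- matrix(0, N + 1L, N + 1L)
  for (j in 2:N) {
    l <- seq_len(j - 1L)
    if (!is.null(kernel$atom)) {
      wts <- numeric(j - 1L)
      if (j %% 2L == 0L) wts[j %/% 2L] <- 2 else wts[c((j - 1L) %/% 2L, (j + 1L) %/% 2L)] <- 1
    } else {
      wts <- kernel$density(l / j)
    }
    s <- sum(l * wts)
    if (s > 0) G[l + 1L, j + 1L] <- wts * (j / s)
  }

  u <- as.numeric(u0_counts)
  targets <- output_times[output_times > 0]
  snaps <- matrix(NA_real_, N + 1L, length(targets))
  t <- 0
  for (k in seq_along(targets)) {
    while (t < targets[k] - 1e-12) {
      h <- min(delta_t, targets[k] - t)
      loss <- rate * u
      u <- u + h * (as.vector(G %*% loss) - loss)
      u[u < 0] <- 0
      t <- t + h
    }
    t <- targets[k]
    snaps[, k] <- u
  }
  if (0 %in% output_times) {
    snaps <- cbind(as.numeric(u0_counts), snaps)
    targets <- c(0, targets)
  }

  structure(list(counts = snaps, times = targets, r = r, N = N,
                 params = params, kernel = kernel),
            class = "frag_discrete")
}

#' @export
print.frag_discrete <- function(x, ...) {
  cat(sprintf("<frag_discrete> N = %d monomer cap, r = %g, %d snapshots\n",
              x$N, x$r, length(x$times)))
  invisible(x)
}

#' @rdname solve_discrete
#' @param x A `frag_discrete` object.
#' @param ... Unused.
#' @export
tidy.frag_discrete <- function(x, ...) {
  obj <- x
  tibble::tibble(
    time = rep(obj$times, each = obj$N + 1L),
    l = rep(0:obj$N, times = length(obj$times)),
    x = rep((0:obj$N) * obj$r, times = length(obj$times)),
    count = as.vector(obj$counts)
  )
}

#' Total monomer count of a discrete simulation over time
#'
#' @param sim A `frag_discrete`.
#' @return A tibble with columns `time` and `monomers` (`sum l * u_l`).
#' @export
discrete_monomers <- function(sim) {
  tibble::tibble(time = sim$times,
                 monomers = as.vector(crossprod(sim$counts, 0:sim$N))[seq_along(sim$times)])
}
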