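# Shared fixtures: small grids and profiles used across test files.

# exponential profile tabulated on a log grid (unit mass)
exp_profile <- function(n = 800, xmax = 50) {
  xg <- exp(seq(log(1e-4), log(xmax), length.out = n))
  tibble::tibble(x = xg, g = exp(-xg))
}

# compact grid for quick solver runs
quick_grid <- function(size = 300, xmin = 1e-3, xmax = 100, ...) {
  log_grid(xmin, xmax, size, ...)
}

# x-weighted relative L1 distance between a simulation snapshot and an
# oracle evaluated on the same grid
oracle_l1 <- function(sim, tt, oracle_u) {
  td <- tidy(sim)
  sel <- td[abs(td$time - tt) < 1e-9, ]
  uo <- oracle_u(sel$x)
  sum(abs(sel$u - uo) * sel$x) / sum(uo * sel$x)
}

all_builtin_kernels <- function() {
  list(
    uniform = make_kernel("uniform"),
    gaussian = make_kernel("gaussian"),
    two_peaked = make_kernel("two_peaked_gaussian"),
    parabolic = make_kernel("parabolic"),
    dirac_half = make_kernel("dirac_half")
  )
}
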