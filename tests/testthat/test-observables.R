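test_that("normalize_density rescales to unit integral and is scale invariant", {
  xg <- seq(0.01, 30, by = 0.01)
  d1 <- normalize_density(tibble::tibble(x = xg, u = exp(-xg)))
  d5 <- normalize_density(tibble::tibble(x = xg, u = 5 * exp(-xg)))
  expect_equal(d1$f, d5$f, tolerance = 1e-12)
  expect_equal(purefrag:::trapz(d1$x, d1$f), 1, tolerance = 1e-10)
  expect_error(normalize_density(tibble::tibble(x = xg, u = 0 * xg)), "zero-mass")
  # per-time normalization and a solver-backed check
  sim <- solve_continuous(frag_params(1, 1), make_kernel("uniform"),
                          function(x) exp(-x), output_times = c(1, 2),
                          grid = quick_grid())
  dens <- sim_densities(sim)
  ints <- tapply(seq_len(nrow(dens)), dens$time, function(i)
    purefrag:::trapz(dens$x[i], dens$f[i]))
  expect_equal(as.numeric(ints), c(1, 1), tolerance = 1e-10)
})

test_that("moments match Gamma-function integrals and sample means", {
  xg <- seq(0, 40, by = 0.002)
  dens <- tibble::tibble(time = 1, x = xg, f = exp(-xg))
  m <- moment_series(dens, q = c(0, 1, 2))
  expect_equal(m$moment[m$q == 0], 1, tolerance = 1e-6)
  expect_equal(m$moment[m$q == 1], 1, tolerance = 1e-5)
  expect_equal(m$moment[m$q == 2], 2, tolerance = 1e-4)
  samp <- tibble::tibble(time = rep(c(1, 2), each = 3),
                         length = c(1, 2, 3, 2, 2, 5))
  ms <- moment_series(samp, q = 1)
  expect_equal(ms$moment, c(2, 3))
  expect_error(moment_series(samp[0, ], 1), "empty")
})

test_that("rescaling is the identity at t = 1 and reaches the steady profile", {
  xg <- exp(seq(log(1e-4), log(80), length.out = 900))
  f1 <- tibble::tibble(time = 1, x = xg, f = exp(-xg))
  pr <- rescaled_profile(f1, gamma = 1)
  expect_equal(pr$g, exp(-pr$x), tolerance = 1e-3) # unit-mass renormalization on the finite grid

  # oracle gamma = 1 at t = 100: f ~ (1+t) e^{-(1+t)x}; rescaled -> e^{-x(1+t)/t}
  t <- 100
  f100 <- tibble::tibble(time = t, x = xg,
                         f = (1 + t) * exp(-(1 + t) * xg))
  pr100 <- rescaled_profile(f100, gamma = 1)
  sel <- pr100$x < 20
  expect_lt(max(abs(pr100$g[sel] - exp(-pr100$x[sel]))), 0.02)
})

test_that("two late times give the same rescaled profile", {
  sim <- solve_continuous(frag_params(1, 1), make_kernel("uniform"),
                          function(x) exp(-x), output_times = c(40, 80),
                          grid = log_grid(1e-4, 1e3, 600))
  pa <- rescaled_profile(sim, gamma = 1, time = 40)
  pb <- rescaled_profile(sim, gamma = 1, time = 80)
  gb <- stats::approx(pb$x, pb$g, xout = pa$x, rule = 2)$y
  l1 <- purefrag:::trapz(pa$x, abs(pa$g - gb))
  expect_lt(l1, 0.02)
})

test_that("numeric Mellin transform matches Gamma values, real and complex", {
  pr <- exp_profile()
  expect_equal(Re(mellin_numeric(pr, 2)), 1, tolerance = 2e-4)   # Gamma(2)
  expect_equal(Re(mellin_numeric(pr, 1)), 1, tolerance = 2e-4)   # normalization
  expect_equal(Re(mellin_numeric(pr, 3.5)), gamma(3.5), tolerance = 2e-4)
  skip_if_not_installed("pracma")
  z <- mellin_numeric(pr, 2 + 3i)
  expect_lt(Mod(z - pracma::gammaz(2 + 3i)), 1e-4)
})

test_that("steady-moment recursion anchors at G(1) = 1 and matches closed cases", {
  rec <- steady_moments_recursion(frag_params(1, 1), make_kernel("uniform"),
                                  n_steps = 1)
  expect_equal(rec$G, c(1, 1)) # G(2) = (2-1)*1/(1*1*(K(1)-1)) = 1, mean of e^-x
  rec2 <- steady_moments_recursion(frag_params(1.5, 1), make_kernel("uniform"),
                                   n_steps = 2)
  expect_equal(rec2$s, c(1, 2.5, 4))
  expect_equal(rec2$G[2], (2 - 1) / (1.5 * (2 - 1)), tolerance = 1e-12)
  # chain through s = 2 hits the resonance
  expect_error(steady_moments_recursion(frag_params(1, 1), make_kernel("uniform"),
                                        start_s = 2, n_steps = 1),
               "resonance")
})

test_that("profile classification separates endpoint and interior breakage", {
  xg <- exp(seq(log(1e-4), log(50), length.out = 700))
  expect_identical(classify_profile(tibble::tibble(x = xg, g = exp(-xg))), "B")
  expect_identical(classify_profile(tibble::tibble(x = xg, g = xg * exp(-xg))), "A")
})

test_that("small-z kernel exponent transfers to the profile near the origin", {
  # kappa ~ C z^eps near 0 implies g ~ C x^eps: eps = 0 (uniform) vs eps = 1
  # (parabolic); compare log-log slopes of the steady profile near x = 0
  g <- log_grid(1e-4, 1e3, 600)
  slopes <- vapply(c("uniform", "parabolic"), function(kk) {
    sim <- solve_continuous(frag_params(1, 1), make_kernel(kk),
                            function(x) exp(-x), output_times = 60, grid = g)
    pr <- rescaled_profile(sim, gamma = 1)
    sel <- pr$x > 1e-3 & pr$x < 1e-2
    unname(stats::lm(log(pr$g[sel]) ~ log(pr$x[sel]))$coefficients[2])
  }, numeric(1))
  expect_lt(abs(slopes[["uniform"]]), 0.2)
  expect_lt(abs(slopes[["parabolic"]] - 1), 0.2)
})
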