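test_that("gamma fit recovers exact piecewise power-law data", {
  tt <- c(1, 2, 4, 8, 16)
  fit <- estimate_gamma(tibble::tibble(time = tt, moment = 7 * tt^(-1 / 2)))
  expect_equal(fit$gamma, 2, tolerance = 1e-4)
  expect_equal(fit$C, 7, tolerance = 1e-4)
  expect_lt(fit$E, 1e-10)
  expect_true(fit$t_e >= min(tt) && fit$t_e <= max(tt))
  # data with a genuine plateau: recover the joint (gamma, C, t_e)
  te <- 6
  tt2 <- c(2, 4, 8, 16, 32, 64)
  m2 <- 3 * pmin(te^(-1 / 1.5), tt2^(-1 / 1.5))
  fit2 <- estimate_gamma(tibble::tibble(time = tt2, moment = m2))
  expect_equal(fit2$gamma, 1.5, tolerance = 1e-3)
  expect_equal(fit2$t_e, te, tolerance = 0.05)
})

test_that("gamma fit on closed-form gamma = 1 moments overestimates slightly", {
  tt <- c(5, 10, 20, 40, 80)
  fit <- estimate_gamma(tibble::tibble(time = tt, moment = 1 / (1 + tt)))
  expect_gte(fit$gamma, 1)
  expect_lt(fit$gamma, 1.1)
})

test_that("gamma fit needs at least 3 positive times and finite moments", {
  expect_error(estimate_gamma(tibble::tibble(time = c(1, 2), moment = c(1, 0.5))),
               "3 time points")
  expect_error(estimate_gamma(tibble::tibble(time = 1:4, moment = c(1, NA, 2, 1))),
               "finite")
})

test_that("the error E decreases as the horizon grows (more late-time data)", {
  horizons <- c(20, 40, 80, 160)
  errs <- vapply(horizons, function(h) {
    tt <- exp(seq(log(5), log(h), length.out = 6))
    fit <- estimate_gamma(tibble::tibble(time = tt, moment = 1 / (1 + tt)))
    abs(fit$gamma - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("alpha estimate inverts the Mellin identity on exact profiles", {
  pr <- exp_profile()
  expect_equal(estimate_alpha(pr, gamma = 1), 1, tolerance = 1e-3)
  # alpha-scaled profile: g(x) = 2 e^{-2x} has G(2) = 1/2, alpha = 2
  xg <- pr$x
  expect_equal(estimate_alpha(tibble::tibble(x = xg, g = 2 * exp(-2 * xg)),
                              gamma = 1), 2, tolerance = 1e-3)
  expect_error(estimate_alpha(pr, gamma = -1), "gamma")
})

test_that("kappa inversion recovers K(s) = 2/s and a flat kernel from e^-x", {
  pr <- exp_profile(n = 900, xmax = 60)
  kap <- estimate_kappa(pr, gamma = 1, alpha = 1)
  # the contour values reproduce the analytic K(s) = 2/s where usable
  K <- attr(kap, "mellin_K")
  s <- 2.5 + 1i * K$tau
  sel <- K$used & abs(K$tau) < 8
  expect_lt(max(Mod(K$K[sel] - 2 / s[sel])), 1e-6)
  # flat kernel on the interior, unit-normalized tails behave
  zin <- kap$z >= 0.1 & kap$z <= 0.9
  expect_lt(max(abs(kap$kappa[zin] - 2)) / 2, 0.10)
  expect_equal(purefrag:::trapz(kap$z, kap$kappa), 2, tolerance = 1e-9)
  expect_true(all(kap$kappa >= 0))
  # symmetrization is recorded and the estimate is symmetric
  expect_true(attr(kap, "settings")$symmetrized)
  expect_equal(kap$kappa, rev(kap$kappa), tolerance = 1e-12)
  expect_error(estimate_kappa(pr, gamma = 1, alpha = 1, s0 = 1.5), "exceed 2")
})

test_that("kappa class call matches the generating kernel class", {
  g <- log_grid(1e-4, 1e3, 600)
  classes <- vapply(c("gaussian", "uniform"), function(kk) {
    sim <- solve_continuous(frag_params(1, 1), make_kernel(kk),
                            function(x) exp(-x), output_times = 60, grid = g)
    pr <- rescaled_profile(sim, gamma = 1)
    kap <- estimate_kappa(pr, gamma = 1, alpha = 1)
    classify_kappa(kap)
  }, character(1))
  expect_identical(classes[["gaussian"]], "A")
  expect_false(classes[["uniform"]] == "A")
})

test_that("the full pipeline runs end to end on noiseless densities", {
  ds <- simulate_experiment(frag_params(2, 1), make_kernel("uniform"),
                            "exponential", times = c(4, 8, 16, 32), N = 0)
  fit <- analyze_experiment(ds, estimate_kernel = FALSE)
  expect_lt(abs(fit$gamma - 2) / 2, 0.05)
  expect_lt(abs(fit$alpha - 1), 0.10)
  expect_s3_class(glance(fit), "tbl_df")
  expect_identical(tidy(fit)$term, c("gamma", "alpha", "t_e", "C"))
  # single-time input fails in the gamma stage with a stage label
  expect_error(analyze_experiment(ds[ds$time == 4, ]), "\\[densities\\]")
})

test_that("overestimation property holds on noiseless simulated data", {
  for (gam in c(1, 1.5)) {
    ds <- simulate_experiment(frag_params(gam, 1), make_kernel("uniform"),
                              "exponential", times = c(5, 10, 20, 40), N = 0)
    fit <- analyze_experiment(ds, estimate_kernel = FALSE)
    expect_gte(fit$gamma, gam * 0.999)
  }
})
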