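test_that("built-in kernels carry total mass 2 and first moment 1", {
  for (nm in names(all_builtin_kernels())) {
    k <- all_builtin_kernels()[[nm]]
    if (!is.null(k$atom)) {
      expect_equal(k$atom$weight, 2, info = nm)
      expect_equal(k$atom$weight * k$atom$z, 1, info = nm)
      next
    }
    total <- stats::integrate(k$density, 0, 1, rel.tol = 1e-11)$value
    zmass <- stats::integrate(function(z) z * k$density(z), 0, 1, rel.tol = 1e-11)$value
    expect_lt(abs(total - 2), 1e-8, label = paste(nm, "integral"))
    expect_lt(abs(zmass - 1), 1e-8, label = paste(nm, "first moment"))
  }
})

test_that("uniform kernel is the constant 2 and parabolic is 12 z (1 - z)", {
  z <- seq(0.05, 0.95, by = 0.05)
  expect_equal(make_kernel("uniform")$density(z), rep(2, length(z)), tolerance = 1e-10)
  # oracle: c z(1-z) with c/6 = 2 (symbolic integral of z(1-z) is 1/6)
  expect_equal(make_kernel("parabolic")$density(z), 12 * z * (1 - z), tolerance = 1e-9)
})

test_that("invalid kernel parameters are rejected", {
  expect_error(make_kernel("gaussian", list(center = 0.5, sd = -1)), "sd > 0")
  expect_error(make_kernel("gaussian", list(center = 1.5, sd = 0.1)), "center")
  expect_error(make_kernel("two_peaked_gaussian", list(offset = 0.7, sd = 0.05)), "offset")
  expect_error(make_kernel("custom", list(z = c(0, 1), kappa = c(1, 1))), "length >= 3")
  # an asymmetric table breaks mass conservation and must be refused
  expect_error(make_kernel("custom", list(z = c(0, 0.2, 0.4, 1), kappa = c(4, 3, 0.5, 0))),
               "first moment")
})

test_that("custom tabulated kernels are renormalized on load", {
  z <- seq(0, 1, length.out = 101)
  k <- make_kernel("custom", list(z = z, kappa = 7 * z * (1 - z))) # wrong scale on purpose
  zf <- seq(1e-9, 1 - 1e-9, length.out = 40001)
  total <- purefrag:::trapz(zf, k$density(zf))
  expect_lt(abs(total - 2), 1e-7)
})

test_that("Mellin transform matches closed forms and binary-fission identities", {
  ks <- all_builtin_kernels()
  # K(1) = 2 for any binary kernel; K(2) = 1 by mass conservation
  for (nm in names(ks)) {
    expect_equal(kernel_mellin(ks[[nm]], 1), 2, tolerance = 1e-9, info = nm)
    expect_equal(kernel_mellin(ks[[nm]], 2), 1, tolerance = 1e-9, info = nm)
  }
  # closed forms: uniform 2/s (e.g. s = 3 -> 2/3 = symbolic int of 2 z^2),
  # dirac 2^(2-s), parabolic 12/((s+1)(s+2))
  svals <- c(1, 1.5, 2, 3, 4.7)
  expect_equal(kernel_mellin(ks$uniform, svals), 2 / svals, tolerance = 1e-10)
  expect_equal(kernel_mellin(ks$dirac_half, svals), 2^(2 - svals), tolerance = 1e-10)
  expect_equal(kernel_mellin(ks$parabolic, svals),
               12 / ((svals + 1) * (svals + 2)), tolerance = 1e-10)
  # quadrature route agrees with closed forms: force quadrature via a custom
  # tabulation of the parabolic kernel
  z <- seq(0, 1, length.out = 2001)
  kq <- make_kernel("custom", list(z = z, kappa = 12 * z * (1 - z)))
  for (s in svals)
    expect_lt(abs(kernel_mellin(kq, s) - 12 / ((s + 1) * (s + 2))), 1e-6)
})

test_that("Mellin transform at real s >= 1 is real, positive, decreasing", {
  svals <- seq(1, 6, by = 0.5)
  for (nm in c("uniform", "gaussian", "two_peaked", "parabolic")) {
    v <- kernel_mellin(all_builtin_kernels()[[nm]], svals)
    expect_true(all(v > 0), info = nm)
    expect_true(all(diff(v) < 0), info = nm)
  }
})

test_that("complex Mellin values are conjugate-symmetric", {
  k <- make_kernel("gaussian")
  v1 <- kernel_mellin(k, 2 + 3i)
  v2 <- kernel_mellin(k, 2 - 3i)
  expect_equal(v1, Conj(v2), tolerance = 1e-9)
  expect_error(kernel_mellin(k, -1 + 0i), "Re\\(s\\) > 0")
})

test_that("kernel classification follows endpoint behaviour", {
  expect_identical(make_kernel("gaussian", list(center = 0.5, sd = 0.1))$kernel_class, "A")
  expect_identical(make_kernel("uniform")$kernel_class, "B")
  expect_identical(make_kernel("parabolic")$kernel_class, "A")
  expect_identical(make_kernel("dirac_half")$kernel_class, "A")
  # near-boundary two-peaked kernel must NOT be called class A
  kb <- make_kernel("two_peaked_gaussian", list(offset = 0.45, sd = 0.02))
  expect_true(kb$kernel_class %in% c("B", "mixed"))
})
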