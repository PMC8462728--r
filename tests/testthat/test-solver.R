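test_that("log grid has the pivot at x = 1 and the index arithmetic", {
  g <- log_grid(1e-4, 1e3, 600)
  expect_equal(g$w[g$p], 0)
  expect_equal(g$x[g$p], 1)
  expect_equal(diff(g$w), rep(g$delta_w, g$size - 1))
  # w_i + w_j = w_{i+j-p}
  i <- 300L; j <- 400L
  expect_equal(g$w[i] + g$w[j], g$w[i + j - g$p])
  gs <- log_grid(1e-3, 100, 300, snap_log2 = TRUE)
  expect_equal(log(2) / gs$delta_w, round(log(2) / gs$delta_w))
})

test_that("t = 0 snapshot reproduces the initial condition on the grid", {
  g <- quick_grid()
  sim <- solve_continuous(frag_params(1, 1), make_kernel("uniform"),
                          function(x) exp(-x), output_times = c(0, 0.2), grid = g)
  td <- tidy(sim)
  expect_equal(td$u[td$time == 0], exp(-g$x), tolerance = 1e-12)
})

test_that("mass is conserved to machine precision and n stays nonnegative for any dt", {
  g <- quick_grid()
  for (dt in list("auto", 0.05, 2)) { # dt = 2 is far beyond any CFL-like scale
    sim <- solve_continuous(frag_params(1.5, 1), make_kernel("gaussian"),
                            function(x) exp(-x), output_times = c(1, 4), grid = g,
                            delta_t = dt)
    m <- sim_mass(sim)
    expect_lt(max(abs(m$mass - sim$rho)) / sim$rho, 1e-12)
    expect_true(all(sim$n >= 0))
  }
})

test_that("total particle number is non-decreasing in time", {
  g <- quick_grid()
  sim <- solve_continuous(frag_params(1, 1), make_kernel("two_peaked_gaussian"),
                          function(x) exp(-x), output_times = c(0, 0.5, 1, 2, 5),
                          grid = g)
  expect_true(all(diff(sim_number(sim)$number) > 0))
})

test_that("solver matches the gamma = 1 uniform-kernel closed form", {
  g <- quick_grid(400)
  sim <- solve_continuous(frag_params(1, 1), make_kernel("uniform"),
                          function(x) exp(-x), output_times = c(0.5, 1, 5), grid = g)
  for (tt in c(0.5, 1, 5)) {
    err <- oracle_l1(sim, tt, function(x)
      oracle_solution("uniform_anyg_exp_init", tt, x, gamma = 1, s = 1))
    expect_lt(err, 0.02)
  }
})

test_that("setup errors fire for bad grids and initial data", {
  g <- quick_grid(100, xmin = 0.5, xmax = 2) # far too narrow for exp(-x)
  expect_error(solve_continuous(frag_params(1, 1), make_kernel("uniform"),
                                function(x) exp(-x), output_times = 1, grid = g),
               "grid edges")
  expect_error(solve_continuous(frag_params(1, 1), make_kernel("uniform"),
                                function(x) exp(-x), output_times = c(2, 1),
                                grid = quick_grid()),
               "increasing")
})

test_that("explicit scheme refuses steps above the positivity bound and matches implicit", {
  g <- quick_grid(250, xmin = 1e-3, xmax = 50)
  p <- frag_params(1, 1)
  k <- make_kernel("uniform")
  bound <- 1 / (p$alpha * exp(p$gamma * max(g$w)))
  expect_error(solve_continuous_explicit(p, k, function(x) exp(-x), 1,
                                         grid = g, delta_t = 2 * bound),
               "CFL")
  se <- solve_continuous_explicit(p, k, function(x) exp(-x), 1, grid = g,
                                  delta_t = 0.9 * bound)
  si <- solve_continuous(p, k, function(x) exp(-x), 1, grid = g,
                         delta_t = 0.9 * bound)
  expect_true(all(tidy(se)$u >= 0))
  de <- tidy(se)$u; di <- tidy(si)$u; xx <- tidy(si)$x
  expect_lt(sum(abs(de - di) * xx) / sum(di * xx), 0.05) # both O(dt) around the same limit
})

test_that("dirac kernel needs a log2-snapped grid and shifts mass by exact octaves", {
  kd <- make_kernel("dirac_half")
  expect_error(solve_continuous(frag_params(0, 1), kd, function(x) exp(-x),
                                output_times = 1, grid = log_grid(1e-3, 100, 301)),
               "snap")
  g <- log_grid(1e-4, 100, 400, snap_log2 = TRUE)
  sim <- solve_continuous(frag_params(0, 1), kd, function(x) exp(-x),
                          output_times = c(0.5, 1, 2), grid = g)
  # closed-form series: total particle number grows as e^t
  nn <- sim_number(sim)
  expect_equal(nn$number, exp(nn$time) * nn$number[1] / exp(nn$time[1]),
               tolerance = 0.02)
})

test_that("alpha acts as a pure time rescaling of the solution", {
  g <- quick_grid(250, xmin = 1e-3, xmax = 50)
  k <- make_kernel("uniform")
  s1 <- solve_continuous(frag_params(1, 1), k, function(x) exp(-x), c(2, 4), grid = g)
  s2 <- solve_continuous(frag_params(1, 2), k, function(x) exp(-x), c(1, 2), grid = g)
  for (i in 1:2) {
    expect_lt(sum(abs(s2$n[, i] - s1$n[, i])) / sum(s1$n[, i]), 0.01)
  }
})
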