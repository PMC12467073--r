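test_that("closed-form elastic and viscous works match the reference energies", {
  expect_equal(elastic_work(k = 1000, D = 0.10), 5.0)
  expect_equal(elastic_work(k = 0.010, D = 1.00e-7), 5.00e-17)
  expect_identical(elastic_work(k = 123, D = 0), 0)
  expect_error(elastic_work(k = -1, D = 0.1), "non-negative")

  expect_equal(viscous_work_ramp(eta = 50, D = 0.10, T = 1.0), 0.50)
  expect_equal(viscous_work_ramp(eta = 50, D = 0.10, T = 0.01), 50.0)
  expect_equal(viscous_work_ramp(eta = 1.0e-6, D = 1.00e-7, T = 1.00e-4),
               1.00e-16)
  expect_error(viscous_work_ramp(eta = 50, D = 0.1, T = 0), "positive")
})

test_that("viscous work scales exactly as 1/T; elastic work is rate-invariant", {
  set.seed(7)
  for (i in 1:15) {
    eta <- runif(1, 1e-7, 100); D <- runif(1, 1e-8, 0.2)
    T <- runif(1, 1e-5, 10); c <- runif(1, 0.1, 1000)
    expect_equal(viscous_work_ramp(eta, D, T / c),
                 c * viscous_work_ramp(eta, D, T), tolerance = 1e-14)
  }
  # elastic storage has no T anywhere in it: identical across durations
  k <- 1000; D <- 0.10
  expect_equal(elastic_work(k, D), 5.0, tolerance = 1e-12)
  b_slow <- ramp_budget(kv_params(1000, 50), D = 0.10, T = 1.0)
  b_fast <- ramp_budget(kv_params(1000, 50), D = 0.10, T = 0.01)
  expect_identical(b_slow$w_el, b_fast$w_el)
})

test_that("numerical partition agrees with the closed forms at the default grid", {
  p <- kv_params(k = 1000, eta = 50)
  tr <- partition_trace(linear_ramp(D = 0.10, T = 1.0), p)
  b <- trace_budget(tr)
  expect_identical(b$method, "numerical")
  expect_rel(b$w_el, 5.0, 1e-6)
  expect_rel(b$w_visc, 0.50, 1e-6)
  expect_rel(b$w_total, 5.50, 1e-6)
  # cumulative columns: start at zero, non-decreasing total work
  expect_identical(tr$w_total[1], 0)
  expect_true(all(diff(tr$w_total) >= 0))
  # conservation along the whole trace, not just at the end
  expect_lt(max(abs(tr$w_total - (tr$w_el + tr$w_visc + tr$w_adh))),
            1e-6 * b$w_total + 1e-15)
})

test_that("adhesive work integrates to its closed form", {
  # pure adhesion: no spring, no dashpot
  p0 <- kv_params(k = 0, eta = 0)
  con <- adhesion("constant", f0 = 1e-9)
  b <- trace_budget(partition_trace(linear_ramp(D = 1e-7, T = 0.1), p0, con))
  expect_rel(b$w_adh, 1e-9 * 1e-7, 1e-4)  # f0 * D
  expect_rel(b$w_total, 1e-16, 1e-4)

  ex <- adhesion("exponential", f0 = 1e-9, lam = 5e-8)
  bex <- trace_budget(partition_trace(linear_ramp(D = 2e-7, T = 0.1), p0, ex))
  closed <- 1e-9 * 5e-8 * (1 - exp(-2e-7 / 5e-8))
  expect_rel(bex$w_adh, closed, 1e-6)
})

test_that("trapezoidal error decays as O(n^-2) on a non-affine integrand", {
  # exponential adhesion makes the work integrand curved, so the
  # quadrature error is visible and should shrink ~4x per grid doubling
  p0 <- kv_params(k = 0, eta = 0)
  ex <- adhesion("exponential", f0 = 1e-9, lam = 5e-8)
  closed <- 1e-9 * 5e-8 * (1 - exp(-2e-7 / 5e-8))
  err <- sapply(c(11, 21, 41, 81), function(n) {
    b <- trace_budget(partition_trace(linear_ramp(2e-7, 0.1, n = n), p0, ex))
    abs(b$w_adh - closed)
  })
  ratios <- err[-length(err)] / err[-1]
  expect_true(all(ratios > 3.5 & ratios < 4.5))
})

test_that("zero-displacement trace yields an all-zero budget", {
  b <- trace_budget(partition_trace(linear_ramp(0, 1, n = 11),
                                    kv_params(1000, 50)))
  expect_identical(c(b$w_el, b$w_visc, b$w_adh, b$w_total), rep(0, 4))
})

test_that("Hill work per contraction falls with velocity between exact endpoints", {
  p <- hill_params(fmax = 100, a = 10, b = 0.5)
  expect_equal(hill_work(p, D = 0.05, v = 0.10), 4.0833, tolerance = 1e-4)
  expect_equal(hill_work(p, D = 0.05, v = 0.50), 2.25)
  expect_equal(hill_work(p, D = 0.05, v = hill_vmax(p)), 0)
  expect_equal(hill_work(p, D = 0.05, v = 0), 100 * 0.05)
  v <- seq(0, hill_vmax(p), length.out = 200)
  expect_true(all(diff(hill_work(p, D = 0.05, v = v)) < 0))
  expect_error(hill_work(p, D = -0.05, v = 0.1), "non-negative")
})

test_that("crossover time equals 2 eta / k and balances the two budgets", {
  # oracle: solve eta*D^2/T = k*D^2/2 for T numerically at a fixed D
  cross_oracle <- function(k, eta, D = 0.03) {
    uniroot(function(T) viscous_work_ramp(eta, D, T) - elastic_work(k, D),
            interval = c(1e-12, 1e6), tol = 1e-15)$root
  }
  expect_equal(crossover_time(kv_params(1000, 50)), 0.1)
  expect_equal(crossover_time(kv_params(1000, 50)), cross_oracle(1000, 50),
               tolerance = 1e-9)
  expect_equal(crossover_time(kv_params(0.01, 1e-6)), 2.0e-4)
  expect_equal(crossover_time(kv_params(0.01, 1e-6)),
               cross_oracle(0.01, 1e-6, D = 1e-7), tolerance = 1e-6)
  expect_error(crossover_time(kv_params(0, 50)), "k = 0")
  # at T = T*, the budget splits exactly in half, for any D
  p <- kv_params(k = 40, eta = 3)
  Tstar <- crossover_time(p)
  for (D in c(1e-7, 0.01, 0.5)) {
    b <- ramp_budget(p, D = D, T = Tstar)
    expect_equal(b$w_visc, b$w_el, tolerance = 1e-12)
  }
})
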