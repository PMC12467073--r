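test_that("membrane stiffness and damping scale linearly with particle diameter", {
  p50 <- scale_np_params(50)
  expect_equal(c(p50$k, p50$eta), c(0.01, 5.00e-7))
  p200 <- scale_np_params(200)
  expect_equal(c(p200$k, p200$eta), c(0.04, 2.00e-6))
  p100 <- scale_np_params(100)
  expect_equal(c(p100$k, p100$eta), c(0.02, 1.00e-6))
  expect_error(scale_np_params(0), "positive")
  expect_error(scale_np_params(-50), "positive")
})

test_that("the nanoparticle grid reproduces the reference analytic energies", {
  grid <- np_scenarios()
  expect_equal(nrow(grid), 4L)
  # depth equals diameter, in metres
  expect_equal(grid$depth_m, from_nm(grid$diameter_nm))
  ref <- tibble::tribble(
    ~diameter_nm, ~T_s,  ~w_el,    ~w_visc,
    50,           0.1,   1.25e-17, 1.25e-20,
    50,           1e-4,  1.25e-17, 1.25e-17,
    200,          0.1,   8.00e-16, 8.00e-19,
    200,          1e-4,  8.00e-16, 8.00e-16)
  m <- dplyr::inner_join(grid, ref, by = c("diameter_nm", "T_s"),
                         suffix = c("", "_ref"))
  expect_equal(nrow(m), 4L)
  expect_rel(m$w_el, m$w_el_ref, 1e-9)
  expect_rel(m$w_visc, m$w_visc_ref, 1e-9)
  # analytic vs numerical agreement per cell
  expect_rel(grid$w_el_num, grid$w_el, 1e-6)
  expect_rel(grid$w_visc_num, grid$w_visc, 1e-6)
})

test_that("grid-level rate and crossover identities hold", {
  grid <- np_scenarios()
  for (d in unique(grid$diameter_nm)) {
    sub <- grid[grid$diameter_nm == d, ]
    slow <- sub[sub$T_s == max(sub$T_s), ]
    fast <- sub[sub$T_s == min(sub$T_s), ]
    # fast/slow dissipation ratio is exactly T_slow / T_fast = 10^3
    expect_equal(fast$w_visc / slow$w_visc, max(sub$T_s) / min(sub$T_s))
    expect_equal(fast$w_visc / slow$w_visc, 1e3)
    # the fast duration happens to sit at the crossover 2*eta/k, so
    # dissipation equals storage there
    expect_equal(crossover_time(kv_params(fast$k, fast$eta)), fast$T_s)
    expect_equal(fast$w_visc, fast$w_el)
  }
  expect_error(np_scenarios(diameters_nm = numeric(0)), "non-empty")
  one <- np_scenarios(diameters_nm = 50, times_s = 0.1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$w_visc, 1.25e-20)
})

test_that("the tissue/muscle benchmark rows are computed, not constants", {
  rows <- reference_rows()
  expect_equal(nrow(rows), 5L)
  expect_equal(rows$w_el[1:3], c(5, 5, 5))
  expect_equal(rows$w_visc[1:3], c(0, 0.50, 50.0))
  expect_equal(rows$w_total[1:3], c(5.0, 5.50, 55.0))
  expect_equal(rows$w_total[4], 4.0833, tolerance = 1e-4)
  expect_equal(rows$w_total[5], 2.25)
  # the Hill model exposes no internal elastic/viscous split
  expect_true(all(is.na(rows$w_el[4:5])) && all(is.na(rows$w_visc[4:5])))
})

test_that("the 100 nm worked example keeps its own coefficients", {
  we <- worked_example_np()
  expect_equal(nrow(we), 2L)
  expect_equal(unique(we$k), 0.010)     # not the 0.02 the scaling rule gives
  expect_equal(unique(we$eta), 1.0e-6)
  expect_rel(we$w_el, c(5.00e-17, 5.00e-17), 1e-9)
  slow <- we[we$T_s == 0.1, ]; fast <- we[we$T_s == 1e-4, ]
  expect_rel(slow$w_visc, 1.00e-19, 1e-9)
  expect_rel(fast$w_visc, 1.00e-16, 1e-9)
  expect_equal(fast$w_visc / slow$w_visc, 1e3)
  # slow entry is elastic-dominated, fast entry viscous-dominated
  expect_lt(slow$w_visc, slow$w_el)
  expect_gt(fast$w_visc, fast$w_el)
})

test_that("trace ordering matches the qualitative force/work picture", {
  # four nanoparticle traces: the large-fast case accumulates the most work
  grid <- np_scenarios(n = 501)
  traces <- purrr::pmap(grid[c("depth_m", "k", "eta", "T_s")],
    function(depth_m, k, eta, T_s) {
      sample_trace(linear_ramp(depth_m, T_s, n = 501), kv_params(k, eta))
    })
  finals <- purrr::map_dbl(traces, ~ dplyr::last(.x$w_total))
  peak_f <- purrr::map_dbl(traces, ~ max(.x$F))
  largest <- which(grid$diameter_nm == 200 & grid$T_s == 1e-4)
  expect_equal(which.max(finals), largest)
  expect_equal(which.max(peak_f), largest)
})
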