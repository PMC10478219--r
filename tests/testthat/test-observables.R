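series_of <- function(m, n_occ = 100) {
  tibble::tibble(sweep = seq_along(m), n_occupied = n_occ,
                 m_per_occupied = m)
}

test_that("magnetization statistics average |m| and m^2 after burn-in", {
  st <- magnetization_stats(series_of(rep(1, 50)), burn_in = 10)
  expect_equal(st$mean_abs_m, 1)
  expect_equal(st$mean_m2, 1)
  expect_equal(st$n_samples, 40L)
  st <- magnetization_stats(series_of(rep(c(1, -1), 25)))
  expect_equal(st$mean_abs_m, 1)   # |m| ignores the sign
  expect_equal(st$mean_m2, 1)
  set.seed(1)
  st <- magnetization_stats(series_of(runif(1e4, -1, 1)))
  expect_equal(st$mean_m2, 1 / 3, tolerance = 0.03)
  expect_error(magnetization_stats(series_of(rep(1, 5)), burn_in = 5),
               class = "cpim_analysis_error")
})

test_that("susceptibility measures |m| fluctuations per occupied site", {
  expect_equal(susceptibility(series_of(rep(0.7, 30)), T = 2), 0)
  expect_equal(susceptibility(series_of(rep(c(1, -1), 20)), T = 2), 0)
  set.seed(2)
  chi <- susceptibility(series_of(runif(2e4, -1, 1), n_occ = 100), T = 2)
  expect_equal(chi, 100 * (1 / 3 - 1 / 4) / 2, tolerance = 0.2 / 4.17)
  expect_error(susceptibility(series_of(rep(1, 10)), T = 0),
               class = "cpim_config_error")
})

test_that("Jensen's inequality holds for every scan row", {
  set.seed(3)
  for (k in 1:20) {
    st <- magnetization_stats(series_of(runif(200, -1, 1)))
    expect_gte(st$mean_m2, st$mean_abs_m^2 - 1e-12)
  }
})

synthetic_scan <- function(L, T_grid, T_c = 2.3, exponent = 7 / 4) {
  # Lorentzian susceptibility peak of height L^exponent at T_c
  chi <- L^exponent / (1 + ((T_grid - T_c) / 0.15)^2)
  tibble::tibble(T = T_grid, L = L, replicate = 1L,
                 mean_abs_m = 0.9 - 0.2 * (T_grid - min(T_grid)),
                 mean_m2 = 0.85, chi = chi,
                 mean_n_occ = L^2, n_samples = 100L)
}

test_that("finite-size scaling recovers an injected chi_max exponent", {
  T_grid <- seq(2.0, 2.6, 0.05)
  scans <- dplyr::bind_rows(lapply(c(16, 32, 64, 128), synthetic_scan,
                                   T_grid = T_grid))
  fss <- finite_size_scaling(scans)
  expect_equal(fss$slope_chi, 1.75, tolerance = 0.05 / 1.75)
  # peak location is L-independent, so the extrapolation returns it
  expect_equal(fss$T_c_extrapolated, 2.3, tolerance = 0.01)
  td <- tidy(fss)
  expect_named(td, c("term", "estimate"))
  expect_equal(glance(fss)$n_sizes, 4L)
})

test_that("finite-size scaling needs at least three sizes", {
  T_grid <- seq(2.0, 2.6, 0.1)
  scans <- dplyr::bind_rows(lapply(c(16, 32), synthetic_scan,
                                   T_grid = T_grid))
  expect_error(finite_size_scaling(scans), class = "cpim_analysis_error")
})

test_that("quadratic peak interpolation is exact on a parabola", {
  x <- c(2.0, 2.1, 2.2)
  y <- 5 - 30 * (x - 2.13)^2
  pk <- cpim:::quad_peak(x, y)
  expect_equal(pk$x, 2.13)
  expect_equal(pk$y, 5)
})
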