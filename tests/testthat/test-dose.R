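test_that("promoter activation probability matches closed forms", {
  expect_equal(p_on(0, 0, 1e-9, 1e-6), 0.5)
  expect_equal(p_on(0, 0, 1e-3, 1e-12, n = 3), 0.5)
  expect_equal(p_on(0, -2, 1e-9, 1e-6, n = 1), 1 / (1 + exp(2)),
               tolerance = 1e-12)
  # saturating limit: ratio -> Kd_on/Kd_off
  lim <- 1 / (1 + (1e-9 / 1e-6) * exp(2))
  expect_equal(p_on(10, -2, 1e-9, 1e-6, n = 1), lim, tolerance = 1e-3)
  expect_error(p_on(-1, 0, 1e-9, 1e-6), class = "cpim_domain_error")
  expect_error(p_on(1, 0, -1, 1e-6), class = "cpim_config_error")
})

test_that("p_on is monotone with the direction set by the Kd ordering", {
  L <- 10^seq(-12, -4, length.out = 100)
  up <- p_on(L, -1, 1e-9, 1e-6, n = 2)
  down <- p_on(L, 1, 1e-6, 1e-9, n = 2)
  flat <- p_on(L, 0.5, 1e-8, 1e-8, n = 1)
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(down) < 0))
  expect_equal(var(flat), 0)
  expect_true(all(up > 0 & up < 1 & down > 0 & down < 1))
})

test_that("noiseless dose-response curves return the generating values", {
  L <- 10^seq(-11, -5, length.out = 12)
  truth <- list(n_beta_dE = -2, Kd_on = 1e-9, Kd_off = 1e-6)
  curve <- tibble::tibble(L_molar = L,
                          rate_norm = p_on(L, truth$n_beta_dE,
                                           truth$Kd_on, truth$Kd_off))
  fit <- fit_dose_response(curve, n = 1)
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_equal(unname(est["n_beta_dE"]), -2, tolerance = 0.01)
  expect_equal(unname(10^est["log10_Kd_on"]), 1e-9, tolerance = 0.01)
  expect_equal(unname(10^est["log10_Kd_off"]), 1e-6, tolerance = 0.01)
  expect_false(fit$decreasing)
})

test_that("parameters are recovered from noisy replicated titrations", {
  L <- 10^seq(-11, -5, length.out = 12)
  truth <- p_on(L, -2, 1e-9, 1e-6)
  set.seed(30)
  err <- replicate(50, {
    curve <- tibble::tibble(L_molar = L,
                            rate_norm = pmax(truth + rnorm(12, 0, 0.03), 0))
    fit <- fit_dose_response(curve, n = 1)
    est <- setNames(fit$params$estimate, fit$params$term)
    c(abs(est["n_beta_dE"] + 2) / 2,
      abs(est["log10_Kd_on"] + 9) / 9,
      abs(est["log10_Kd_off"] + 6) / 6)
  })
  expect_true(all(apply(err, 1, median) < 0.15))
})

test_that("a repressed channel fits with a positive energy gap", {
  L <- 10^seq(-11, -5, length.out = 12)
  set.seed(31)
  curve <- tibble::tibble(
    L_molar = L,
    rate_norm = pmax(1 - p_on(L, -2, 1e-9, 1e-6) + rnorm(12, 0, 0.01), 0))
  fit <- fit_dose_response(curve, n = 1)
  expect_true(fit$decreasing)
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_gt(est["n_beta_dE"], 0)
})

test_that("the synthetic generator produces complementary channels", {
  cv <- simulate_dose_response(noise_sd = 0, seed = 2)
  wide <- tidyr::pivot_wider(cv[, c("L_molar", "rate_norm", "channel")],
                             names_from = "channel",
                             values_from = "rate_norm")
  # before per-channel normalization the channels sum to 1; both
  # channels reach 1 at their own maximum, so the normalized curves
  # cross where p_on = 1 - p_on
  raw_rfp <- wide$RFP * max(p_on(wide$L_molar, log(0.1), 1e-9, 1e-7))
  raw_gfp <- wide$GFP * max(1 - p_on(wide$L_molar, log(0.1), 1e-9, 1e-7))
  expect_equal(raw_rfp + raw_gfp, rep(1, nrow(wide)), tolerance = 1e-10)
  # crossover of the two channels sits near 1e-8 M (interpolated)
  dd <- wide$RFP - wide$GFP
  k <- which(diff(sign(dd)) != 0)[1]
  lx <- log10(wide$L_molar)
  cross <- lx[k] - dd[k] * (lx[k + 1] - lx[k]) / (dd[k + 1] - dd[k])
  expect_equal(cross, -8, tolerance = 0.15 / 8)
  expect_identical(simulate_dose_response(seed = 5),
                   simulate_dose_response(seed = 5))
})

test_that("dose-response fitting enforces its preconditions", {
  few <- tibble::tibble(L_molar = 10^seq(-9, -8, length.out = 4),
                        rate_norm = c(0.1, 0.2, 0.3, 0.4))
  expect_error(fit_dose_response(few), class = "cpim_usage_error")
})

test_that("fit objects expose tidy and glance summaries", {
  cv <- simulate_dose_response(noise_sd = 0.02, seed = 3)
  fit <- fit_dose_response(cv[cv$channel == "RFP", ], n = 1)
  expect_true(all(c("term", "estimate", "std.error") %in% names(tidy(fit))))
  expect_equal(nrow(glance(fit)), 1)
})
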