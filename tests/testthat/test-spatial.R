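test_that("the FFT sACF equals direct pair counting on masked grids", {
  set.seed(10)
  for (k in 1:3) {
    g <- matrix(sample(c(-1, 1), 81, TRUE), 9, 9)
    mask <- matrix(runif(81) > 0.3, 9, 9)
    a <- radial_acf(g, mask = mask, max_r = 13)
    b <- brute_radial_acf(g, mask)
    m <- merge(as.data.frame(a), b, by = "r")
    expect_equal(m$C.x, m$C.y, tolerance = 1e-12)
  }
})

test_that("an iid field is uncorrelated beyond r = 0", {
  g <- make_fixture("iid_random", 128, seed = 4)
  acf <- radial_acf(g, max_r = 30)
  expect_equal(acf$C[acf$r == 0], 1, tolerance = 1e-12)
  far <- acf[acf$r > 0, ]
  expect_true(all(abs(far$C) < 3 / sqrt(far$n_pairs)))
})

test_that("a checkerboard is perfectly anticorrelated at axis distance 1", {
  cb <- make_fixture("checkerboard", 32)
  acf <- radial_acf(cb, bin_width = 0.5)
  expect_equal(acf$C[acf$r == 0], 1, tolerance = 1e-12)
  expect_equal(acf$C[acf$r == 1], -1, tolerance = 1e-10)
  # ... and perfectly correlated along the diagonal
  expect_equal(acf$C[abs(acf$r - sqrt(2)) < 0.2], 1, tolerance = 1e-10)
})

test_that("stripes put the first sACF zero crossing near their width", {
  w <- 8
  g <- make_fixture("stripes", 64, width = w)
  acf <- radial_acf(g, max_r = 30)
  cross <- acf$r[which(acf$C <= 0)[1]]
  expect_gte(cross, w * 0.6)
  expect_lte(cross, w * 1.4)
})

test_that("masked embedding reproduces the unembedded sACF exactly", {
  g <- make_fixture("disk_mosaic", 48, scale = 8, seed = 2)
  acf1 <- radial_acf(g, max_r = 20)
  big <- matrix(0L, 80, 80)
  big[11:58, 13:60] <- unclass(g)
  acf2 <- radial_acf(big, max_r = 20)
  expect_equal(acf1$C, acf2$C, tolerance = 1e-10)
  expect_equal(acf1$n_pairs, acf2$n_pairs)
})

test_that("the sACF is invariant under 90-degree rotation of the grid", {
  g <- make_fixture("disk_mosaic", 40, scale = 6, seed = 3)
  a1 <- radial_acf(g, max_r = 15)
  rot <- unclass(g)[nrow(g):1, ]
  a2 <- radial_acf(t(rot), max_r = 15)
  expect_equal(a1$C, a2$C, tolerance = 1e-10)
})

test_that("a constant field has no defined autocorrelation", {
  expect_error(radial_acf(matrix(1L, 10, 10)),
               class = "cpim_analysis_error")
})

test_that("exponential decay fits recover known parameters", {
  r <- 0:60
  acf <- tibble::tibble(r = r, C = exp(-r / 15), n_pairs = 1000)
  fit <- fit_acf_exponential(acf)
  expect_equal(fit$b, 15, tolerance = 1e-6)
  acf2 <- tibble::tibble(r = r, C = 0.8 * exp(-r / 2) + 0.1, n_pairs = 1000)
  fit2 <- fit_acf_exponential(acf2)
  expect_equal(fit2$y0, 0.8, tolerance = 1e-6)
  expect_equal(fit2$b, 2, tolerance = 1e-6)
  expect_equal(fit2$C0, 0.1, tolerance = 1e-6)
  expect_named(tidy(fit2), c("term", "estimate", "std.error"))
})

test_that("the length constant survives measurement noise", {
  set.seed(5)
  r <- 0:60
  bs <- replicate(20, {
    acf <- tibble::tibble(r = r, C = exp(-r / 15) + rnorm(61, 0, 0.02),
                          n_pairs = 1000)
    fit_acf_exponential(acf)$b
  })
  expect_equal(mean(bs), 15, tolerance = 0.05)
})

test_that("power-law ACF fits recover eta, including the degenerate case", {
  r <- 1:64
  acf <- tibble::tibble(r = r, C = 1 * exp(-r / 1e6) / r^0.25,
                        n_pairs = 1000)
  fit <- fit_acf_powerlaw(acf, fit_range = c(1, 32))
  expect_equal(fit$eta, 0.25, tolerance = 1e-4)
  # pure exponential: eta pinned near zero
  acf2 <- tibble::tibble(r = r, C = exp(-r / 10), n_pairs = 1000)
  fit2 <- fit_acf_powerlaw(acf2, fit_range = c(1, 32))
  expect_lt(fit2$eta, 0.02)
  expect_error(fit_acf_powerlaw(acf[1:3, ], fit_range = c(1, 3)),
               class = "cpim_fit_error")
  expect_error(fit_acf_powerlaw(acf, fit_range = c(0, 32)),
               class = "cpim_fit_error")
})

test_that("cluster labelling matches hand-enumerated cases", {
  u <- matrix(1L, 10, 10)
  cl <- label_clusters(u, states = 1L)
  expect_equal(cl$sizes$size, 100)
  cb <- make_fixture("checkerboard", 8)
  expect_equal(nrow(label_clusters(cb, 4)$sizes), 64)
  expect_true(all(label_clusters(cb, 4)$sizes$size == 1))
  # two 3x3 blocks touching at a corner
  g <- matrix(-1L, 6, 6)
  g[1:3, 1:3] <- 1L; g[4:6, 4:6] <- 1L
  s4 <- label_clusters(g, 4, states = 1L)$sizes$size
  s8 <- label_clusters(g, 8, states = 1L)$sizes$size
  expect_equal(sort(s4), c(9, 9))
  expect_equal(s8, 18)
})

test_that("cluster sizes over both states conserve the site count", {
  g <- make_fixture("disk_mosaic", 64, scale = 6, seed = 7)
  cl <- label_clusters(g, 4)
  expect_equal(sum(cl$sizes$size), sum(unclass(g) != 0L))
})

test_that("labelling agrees with EBImage's connected components", {
  skip_if_not_installed("EBImage")
  set.seed(8)
  m <- matrix(rbinom(400, 1, 0.45), 20, 20)
  ours <- label_clusters(m, 4, states = 1L)$sizes$size
  ref <- EBImage::bwlabel(m)  # 4-connectivity labelling
  expect_equal(sort(ours), sort(as.vector(table(ref[ref > 0]))))
})

test_that("the empirical size distribution is a normalized histogram", {
  pdf <- cluster_size_distribution(c(1, 1, 2))
  expect_equal(pdf$p[pdf$size == 1], 2 / 3)
  expect_equal(pdf$p[pdf$size == 2], 1 / 3)
  set.seed(9)
  s <- rzeta(5e4, 2)
  pdf <- cluster_size_distribution(s)
  expect_equal(sum(pdf$p), 1)
  expect_equal(pdf$p[pdf$size == 1], 1 / (pi^2 / 6), tolerance = 0.02)
  lb <- cluster_size_distribution(s, log_bin = TRUE)
  expect_true(all(lb$density > 0))
  expect_equal(sum(lb$count), length(s))
})
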