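test_that("nearest-neighbour rescaling keeps patterns binary", {
  a <- make_fixture("checkerboard", 4)
  bin <- (unclass(a) == 1L) * 1L
  expect_identical(rescale_binary(bin, c(4, 4)), bin)
  up <- rescale_binary(matrix(c(1, 0, 0, 1), 2, 2), 4)
  expect_equal(up, matrix(c(1, 0, 0, 1), 2, 2)[rep(1:2, each = 2),
                                               rep(1:2, each = 2)])
  cb <- (unclass(make_fixture("checkerboard", 64)) == 1L) * 1L
  down <- rescale_binary(cb, 63)
  expect_true(all(down %in% c(0, 1)))
  expect_equal(dim(down), c(63, 63))
  expect_error(rescale_binary(cb, 1), class = "cpim_usage_error")
})

test_that("rotation is exact at multiples of 90 degrees", {
  set.seed(20)
  a <- matrix(rbinom(64^2, 1, 0.5), 64, 64)
  expect_identical(rotate_binary(a, 0), a)
  expect_identical(rotate_binary(a, 360), a)
  r90 <- rotate_binary(a, 90)
  expect_true(all(r90 %in% c(0, 1)))
  expect_identical(rotate_binary(r90, -90), a)
})

test_that("Hamming distance is the fraction of differing pixels", {
  set.seed(21)
  a <- matrix(rbinom(1e4, 1, 0.5), 100, 100)
  expect_equal(hamming_distance(a, a), 0)
  expect_equal(hamming_distance(a, 1 - a), 1)
  expect_equal(hamming_distance(a, 1 - a), hamming_distance(1 - a, a))
  b <- matrix(rbinom(1e6, 1, 0.5), 1000, 1000)
  c2 <- matrix(rbinom(1e6, 1, 0.5), 1000, 1000)
  expect_equal(hamming_distance(b, c2), 0.5, tolerance = 0.002 / 0.5)
  expect_error(hamming_distance(a, b), class = "cpim_usage_error")
  expect_error(hamming_distance(a * 2, a), class = "cpim_usage_error")
})

test_that("rotation search finds the inverse angle and bounds the distance", {
  g <- make_fixture("disk_mosaic", 128, scale = 20, seed = 22)
  a <- (unclass(g) == 1L) * 1L
  b <- rotate_binary(a, 45)
  res <- min_hamming_over_rotations(a, b)
  expect_equal(res$angle, 315)
  expect_lt(res$distance, 0.05)
  expect_lte(res$distance, hamming_distance(a, b))
  expect_equal(nrow(res$by_angle), 24)
  expect_equal(min_hamming_over_rotations(a, a)$distance, 0)
  expect_equal(min_hamming_over_rotations(a, a)$angle, 0)
})

test_that("simulated patterns best match a near-critical reference", {
  # grow ferromagnetic colonies across the coupling range and compare
  # each to a reference colony at the critical coupling: the mean
  # rotation-minimised Hamming distance is smallest near T_c
  colony <- function(T, seed, L = 64) {
    p <- cpim_params(L = L, T = T, J = 1, b = 0.03, d = 1e-5,
                     sweeps = 30000, seed = seed, record_every = 0)
    binarize_lattice(run_simulation(p)$lattice, 1L)
  }
  ref <- colony(2.27, 999)
  Ts <- seq(1.97, 2.57, 0.1)
  mean_dist <- vapply(Ts, function(T) {
    mean(vapply(1:10, function(s)
      min_hamming_over_rotations(ref, colony(T, 1000 + 37 * s))$distance,
      numeric(1)))
  }, numeric(1))
  expect_lt(abs(Ts[which.min(mean_dist)] - 2.27), 0.15)
})
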