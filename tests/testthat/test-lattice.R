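test_that("CPIM initialisation seeds a single founder cell at the centre", {
  lat <- init_lattice(cpim_params(L = 5, T = 2, sweeps = 0, seed = 1))
  expect_equal(sum(lat == 2L), 1L)
  expect_equal(sum(lat == 0L), 24L)
  expect_equal(lat[3, 3], 2L)
})

test_that("pure-Ising initialisation is a seeded iid +-1 field", {
  p <- cpim_params(L = 4, T = 2, sweeps = 0, seed = 7, mode = "pure_ising")
  set.seed(7); a <- init_lattice(p)
  set.seed(7); b <- init_lattice(p)
  expect_true(all(a %in% c(-1L, 1L)))
  expect_identical(unclass(a), unclass(b))
  expect_equal(attr(a, "boundary"), "periodic")
  p100 <- cpim_params(L = 100, T = 2, sweeps = 0, seed = 3,
                      mode = "pure_ising")
  set.seed(3)
  expect_lt(abs(mean(init_lattice(p100))), 3 / sqrt(100 * 100))
})

test_that("invalid configurations are rejected", {
  expect_error(cpim_params(L = 1, T = 2), class = "cpim_config_error")
  expect_error(cpim_params(L = 8, T = -1), class = "cpim_config_error")
  expect_error(cpim_params(L = 8, T = 2, J = 2), class = "cpim_config_error")
  expect_error(cpim_params(L = 8, T = 2, b = 1.5), class = "cpim_config_error")
})

test_that("hamiltonian counts each differentiated pair once", {
  expect_equal(hamiltonian(matrix(1L, 3, 3), J = 1), -12)
  cb <- matrix(ifelse((row(diag(3)) + col(diag(3))) %% 2 == 0, 1L, -1L), 3, 3)
  expect_equal(hamiltonian(cb, J = -1), -12)
  # vacant and undifferentiated sites carry no spin
  g <- matrix(0L, 4, 4); g[2, 2] <- 1L; g[1, 1] <- 2L
  expect_equal(hamiltonian(g, J = 1), 0)
  g[2, 3] <- -1L
  expect_equal(hamiltonian(g, J = 1), 1)
})

test_that("delta_energy matches the hamiltonian difference exactly", {
  set.seed(42)
  for (k in 1:200) {
    L <- sample(3:7, 1)
    g <- matrix(sample(c(0L, 2L, 1L, -1L), L * L, replace = TRUE,
                       prob = c(.15, .15, .35, .35)), L, L)
    diffed <- which(g == 1L | g == -1L, arr.ind = TRUE)
    if (nrow(diffed) == 0) next
    site <- diffed[sample(nrow(diffed), 1), ]
    nb <- if (k %% 2 == 0) "moore" else "von_neumann"
    bd <- if (k %% 3 == 0) "periodic" else "open"
    J <- sample(c(-1L, 1L), 1)
    dH <- delta_energy(g, site, J, neighborhood = nb, boundary = bd)
    g2 <- g; g2[site[1], site[2]] <- -g2[site[1], site[2]]
    expect_equal(dH, hamiltonian(g2, J, nb, bd) - hamiltonian(g, J, nb, bd))
  }
})

test_that("delta_energy handles mixed neighbourhoods per the spin-0 rule", {
  g <- matrix(0L, 3, 3)
  g[2, 2] <- 1L; g[1, 2] <- 1L; g[3, 2] <- 1L; g[2, 1] <- 1L; g[2, 3] <- 1L
  expect_equal(delta_energy(g, c(2, 2), J = 1), 8)
  g[2, 3] <- 2L  # undifferentiated neighbour excluded
  expect_equal(delta_energy(g, c(2, 2), J = 1), 6)
  g[2, 3] <- -1L; g[2, 1] <- -1L  # symmetric neighbourhood
  expect_equal(delta_energy(g, c(2, 2), J = 1), 0)
  expect_error(delta_energy(g, c(1, 1), J = 1), class = "cpim_domain_error")
})

test_that("ground states: uniform for J=+1, checkerboard for J=-1 (L=3)", {
  grids <- enumerate_spin_grids(3)
  H_fm <- vapply(grids, hamiltonian, numeric(1), J = 1)
  H_afm <- vapply(grids, hamiltonian, numeric(1), J = -1)
  fm_min <- which(H_fm == min(H_fm))
  # exactly the two uniform configurations
  expect_length(fm_min, 2)
  expect_true(all(vapply(grids[fm_min], function(g)
    length(unique(as.vector(g))) == 1, logical(1))))
  afm_min <- which(H_afm == min(H_afm))
  expect_length(afm_min, 2)
  expect_true(all(vapply(grids[afm_min], function(g)
    all(g == g[1, 1] * (-1)^((row(g) + col(g)) %% 2 == 1)) ||
      all(g == -g[1, 1] * (-1)^((row(g) + col(g)) %% 2 == 1)),
    logical(1))))
  # and the checkerboards really alternate
  expect_true(all(vapply(grids[afm_min], function(g)
    all(g * (-1)^(row(g) + col(g)) == g[1, 1] * (-1)^2), logical(1))))
})

test_that("lattice files reject illegal codes", {
  expect_error(cpim:::new_lattice(matrix(c(0L, 7L, 1L, -1L), 2, 2)),
               class = "cpim_parse_error")
})
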