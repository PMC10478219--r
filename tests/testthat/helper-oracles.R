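# Independent oracles used across the suite.  These deliberately avoid
# the package's own fast paths: direct pair counting for the sACF,
# exhaustive enumeration for small-lattice energetics.

# O(n^2) masked radial autocorrelation by explicit pair counting.
brute_radial_acf <- function(field, mask, bin_width = 1) {
  idx <- which(mask, arr.ind = TRUE)
  f <- field[mask] - mean(field[mask])
  va <- mean(f^2)
  num <- list(); cnt <- list()
  n <- nrow(idx)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    r <- sqrt(sum((idx[a, ] - idx[b, ])^2))
    k <- as.character(floor(r / bin_width + 0.5))
    num[[k]] <- (if (is.null(num[[k]])) 0 else num[[k]]) + f[a] * f[b]
    cnt[[k]] <- (if (is.null(cnt[[k]])) 0 else cnt[[k]]) + 1
  }
  bins <- as.numeric(names(num))
  ord <- order(bins)
  data.frame(r = bins[ord] * bin_width,
             C = (unlist(num) / unlist(cnt))[ord] / va)
}

# Exact Boltzmann distribution over the 16 configurations of a fully
# differentiated 2x2 periodic lattice.  Bonds are enumerated as
# right+down per site (each unordered pair twice at L = 2), matching
# the simulator's energy convention.
boltzmann_2x2 <- function(T, J) {
  H <- vapply(0:15, function(code) {
    g <- matrix(ifelse(bitwAnd(code, 2^(0:3)) > 0, 1, -1), 2, 2)
    -J * sum(g * (g[, c(2, 1)] + g[c(2, 1), ]))
  }, numeric(1))
  w <- exp(-H / T)
  w / sum(w)
}

# All 2^(L^2) fully differentiated configurations of an L x L lattice.
enumerate_spin_grids <- function(L) {
  n <- L * L
  lapply(0:(2^n - 1), function(code)
    matrix(ifelse(bitwAnd(code, 2^(0:(n - 1))) > 0, 1L, -1L), L, L))
}

# Ensemble average of per-snapshot ACFs on a shared r grid.
ensemble_acf <- function(acfs) {
  r <- acfs[[1]]$r
  C <- rowMeans(vapply(acfs, function(a) a$C[match(r, a$r)],
                       numeric(length(r))))
  out <- tibble::tibble(r = r, C = C, n_pairs = acfs[[1]]$n_pairs)
  class(out) <- c("cpim_acf", class(out))
  out
}

# Onsager's spontaneous magnetization of the square-lattice Ising
# ferromagnet below criticality.
onsager_magnetization <- function(T) (1 - sinh(2 / T)^(-4))^(1 / 8)
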