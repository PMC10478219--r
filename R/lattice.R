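#' Lattice state constructors and energetics
#'
#' A lattice state is an integer matrix with site codes `0` (vacant),
#' `2` (undifferentiated), and `+1` / `-1` (the two differentiated
#' cell states), carrying `boundary`, `mode` and `sweep` attributes.
#'
#' @name lattice
NULL

new_lattice <- function(grid, boundary = "open", mode = "cpim", sweep = 0L) {
  stopifnot(is.matrix(grid))
  storage.mode(grid) <- "integer"
  bad <- !(grid %in% c(0L, 2L, 1L, -1L))
  if (any(bad))
    abort(sprintf("illegal site code(s): %s",
                  paste(unique(grid[bad]), collapse = ", ")),
          class = "cpim_parse_error")
  structure(grid, boundary = boundary, mode = mode, sweep = as.integer(sweep),
            class = c("cpim_lattice", "matrix", "array"))
}

#' Initialise a lattice for a simulation
#'
#' In CPIM mode the lattice starts all-vacant with a single
#' undifferentiated founder cell at the centre; in pure-Ising mode
#' every site is an independent `+1`/`-1` spin with probability 1/2
#' and the boundary is periodic.
#'
#' @param params A [cpim_params()] object.
#' @return A `cpim_lattice` matrix.
#' @examples
#' lat <- init_lattice(cpim_params(L = 5, T = 2, sweeps = 0, seed = 1))
#' table(lat)
#' @export
init_lattice <- function(params) {
  stopifnot(inherits(params, "cpim_params"))
  L <- params$L
  if (params$mode == "cpim") {
    grid <- matrix(0L, L, L)
    ctr <- floor(L / 2) + 1L
    grid[ctr, ctr] <- 2L
    new_lattice(grid, boundary = params$boundary, mode = "cpim")
  } else {
    grid <- matrix(sample(c(-1L, 1L), L * L, replace = TRUE), L, L)
    new_lattice(grid, boundary = "periodic", mode = "pure_ising")
  }
}

lattice_attrs <- function(x) {
  list(boundary = attr(x, "boundary") %||% "open",
       mode = attr(x, "mode") %||% "cpim",
       sweep = attr(x, "sweep") %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

neighbour_offsets <- function(neighborhood = "von_neumann") {
  if (neighborhood == "moore")
    cbind(di = c(-1, 1, 0, 0, -1, -1, 1, 1), dj = c(0, 0, -1, 1, -1, 1, -1, 1))
  else
    cbind(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
}

neighbour_sites <- function(L, i, j, neighborhood, boundary) {
  off <- neighbour_offsets(neighborhood)
  ii <- i + off[, 1]; jj <- j + off[, 2]
  if (boundary == "periodic") {
    ii <- (ii - 1) %% L + 1; jj <- (jj - 1) %% L + 1
  } else {
    keep <- ii >= 1 & ii <= L & jj >= 1 & jj <= L
    ii <- ii[keep]; jj <- jj[keep]
  }
  cbind(ii, jj)
}

#' Interaction energy of a lattice configuration
#'
#' Computes `H = -J * sum over neighbouring pairs of sigma_i sigma_j`,
#' each unordered pair counted once, where only differentiated
#' (`+1`/`-1`) sites carry a spin; vacant and undifferentiated
#' neighbours contribute zero.
#'
#' @param lattice A `cpim_lattice` or plain integer matrix of site codes.
#' @param J Coupling sign, `+1` or `-1`.
#' @param neighborhood `"von_neumann"` or `"moore"`.
#' @param boundary `"open"` or `"periodic"`; defaults to the lattice
#'   attribute.
#' @return The dimensionless energy (a single number).
#' @examples
#' m <- matrix(1L, 3, 3)
#' hamiltonian(m, J = 1)  # 12 aligned pairs -> -12
#' @export
hamiltonian <- function(lattice, J, neighborhood = "von_neumann",
                        boundary = NULL) {
  boundary <- boundary %||% (attr(lattice, "boundary") %||% "open")
  g <- lattice
  storage.mode(g) <- "integer"
  total_energy_cpp(g, as.integer(J), neighborhood == "moore",
                   boundary == "periodic")
}

#' Energy change of flipping one differentiated site
#'
#' Returns `dH = 2 * J * sigma_site * sum(sigma_neighbours)` where the
#' sum runs over differentiated neighbours only.  Equals
#' `hamiltonian(after flip) - hamiltonian(before)`.
#'
#' @inheritParams hamiltonian
#' @param site Integer vector `c(i, j)` (row, column, 1-based).
#' @return The energy change.
#' @export
delta_energy <- function(lattice, site, J, neighborhood = "von_neumann",
                         boundary = NULL) {
  boundary <- boundary %||% (attr(lattice, "boundary") %||% "open")
  s <- lattice[site[1], site[2]]
  if (!s %in% c(-1L, 1L))
    abort("site is not differentiated; only +1/-1 sites can flip.",
          class = "cpim_domain_error")
  nb <- neighbour_sites(nrow(lattice), site[1], site[2], neighborhood,
                        boundary)
  sig <- lattice[nb]
  2 * J * s * sum(sig[sig %in% c(-1L, 1L)])
}

#' Single Metropolis flip attempt
#'
#' Flips the spin at `site` with probability `min(1, exp(-dH/T))`
#' (Boltzmann constant set to 1).  Draws one uniform variate from R's
#' RNG stream when `dH > 0`.
#'
#' @inheritParams delta_energy
#' @param T Coupling control parameter, `> 0`.
#' @return A list with the (possibly updated) `lattice` and logical
#'   `accepted`.
#' @export
metropolis_flip <- function(lattice, site, T, J,
                            neighborhood = "von_neumann", boundary = NULL) {
  if (T <= 0)
    abort("`T` must be positive.", class = "cpim_config_error")
  dH <- delta_energy(lattice, site, J, neighborhood, boundary)
  accepted <- dH <= 0 || runif(1) < exp(-dH / T)
  if (accepted) lattice[site[1], site[2]] <- -lattice[site[1], site[2]]
  list(lattice = lattice, accepted = accepted)
}

#' One contact-process/Ising update at a single site
#'
#' Applies the CPIM reaction scheme at one site: a vacant site is
#' colonized (becomes undifferentiated) with probability
#' `1 - (1 - b)^k` where `k` counts occupied neighbours; an
#' undifferentiated cell dies with probability `d`, otherwise
#' differentiates with probability `g` into `+1` or `-1` with equal
#' probability; a differentiated cell dies with probability `d`,
#' otherwise makes a Metropolis flip attempt.  Death is evaluated
#' before the flip.
#'
#' @inheritParams delta_energy
#' @param params A [cpim_params()] object.
#' @return A list with the updated `lattice` and an `event` string in
#'   `c("none", "colonization", "differentiation", "death",
#'   "flip_accepted", "flip_rejected")`.
#' @export
cp_event <- function(lattice, site, params) {
  s <- lattice[site[1], site[2]]
  L <- nrow(lattice)
  event <- "none"
  if (s == 0L) {
    nb <- neighbour_sites(L, site[1], site[2], params$neighborhood,
                          params$boundary)
    k <- sum(lattice[nb] != 0L)
    if (k > 0 && runif(1) < 1 - (1 - params$b)^k) {
      lattice[site[1], site[2]] <- 2L
      event <- "colonization"
    }
  } else if (s == 2L) {
    if (params$d > 0 && runif(1) < params$d) {
      lattice[site[1], site[2]] <- 0L
      event <- "death"
    } else if (runif(1) < params$g) {
      lattice[site[1], site[2]] <- if (runif(1) < 0.5) 1L else -1L
      event <- "differentiation"
    }
  } else {
    if (params$d > 0 && runif(1) < params$d) {
      lattice[site[1], site[2]] <- 0L
      event <- "death"
    } else {
      res <- metropolis_flip(lattice, site, params$T, params$J,
                             params$neighborhood, params$boundary)
      lattice <- res$lattice
      event <- if (res$accepted) "flip_accepted" else "flip_rejected"
    }
  }
  list(lattice = lattice, event = event)
}

#' One full sweep of asynchronous updates
#'
#' Performs `L^2` single-site update attempts at uniformly random
#' sites (random sequential updating) via the compiled kernel and
#' increments the sweep counter.
#'
#' @param lattice A `cpim_lattice`.
#' @param params A [cpim_params()] object.
#' @return A list with the updated `lattice` and a one-row tibble
#'   `counts` of event tallies.
#' @export
sweep_lattice <- function(lattice, params) {
  at <- lattice_attrs(lattice)
  g <- matrix(as.integer(lattice), nrow(lattice), ncol(lattice))
  res <- run_lattice_cpp(g, params$T, params$J, params$b, params$d,
                         params$g, params$neighborhood == "moore",
                         at$boundary == "periodic", 1L,
                         params$mode == "pure_ising", FALSE, 1L, 0L, FALSE)
  obs <- observables_tibble(res$observables)
  out <- new_lattice(res$grid, boundary = at$boundary, mode = at$mode,
                     sweep = at$sweep + 1L)
  counts <- obs[, c("colonizations", "deaths", "differentiations",
                    "flip_attempts", "flips_accepted")]
  list(lattice = out, counts = counts)
}

#' @export
print.cpim_lattice <- function(x, ...) {
  at <- lattice_attrs(x)
  tb <- table(factor(x, levels = c(0, 2, 1, -1),
                     labels = c("vacant", "undiff", "+1", "-1")))
  cat(sprintf("<cpim_lattice> %dx%d %s boundary=%s sweep=%d\n",
              nrow(x), ncol(x), at$mode, at$boundary, at$sweep))
  print(tb)
  invisible(x)
}
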