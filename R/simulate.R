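observables_tibble <- function(m) {
  colnames(m) <- c("sweep", "n_occupied", "n_plus", "n_minus", "M",
                   "m_per_occupied", "energy", "colonizations", "deaths",
                   "differentiations", "flip_attempts", "flips_accepted")
  as_tibble(m)
}

#' Run a CPIM (or pure-Ising) simulation
#'
#' Initialises the lattice from `params`, then performs sweeps of
#' `L^2` asynchronous single-site updates until the sweep budget is
#' exhausted or — in CPIM mode with `stop_at_edge = TRUE` — the colony
#' touches the lattice edge.  Per-sweep observables (occupancy, net
#' magnetization `M`, magnetization per occupied site `m`, energy, and
#' event tallies) are recorded every `record_every` sweeps and full
#' grid snapshots every `snapshot_every` sweeps.  The run is a pure
#' function of `(params, seed)`.
#'
#' @param params A [cpim_params()] object.
#' @param init Optional starting `cpim_lattice`; defaults to
#'   [init_lattice()].
#' @return An object of class `cpim_sim`: a list with elements
#'   `lattice` (final state), `observables` (tibble, one row per
#'   recorded sweep), `snapshots` (list of `cpim_lattice`),
#'   `snapshot_sweeps`, `stopped_at_edge`, `sweeps_done` and `params`.
#' @examples
#' sim <- run_simulation(cpim_params(L = 32, T = 2.27, sweeps = 100,
#'                                   seed = 1, record_every = 10))
#' tail(sim$observables)
#' @export
run_simulation <- function(params, init = NULL) {
  stopifnot(inherits(params, "cpim_params"))
  set.seed(params$seed)
  lattice <- init %||% init_lattice(params)
  at <- lattice_attrs(lattice)
  g <- matrix(as.integer(lattice), nrow(lattice), ncol(lattice))
  res <- run_lattice_cpp(
    g, params$T, params$J, params$b, params$d, params$g,
    params$neighborhood == "moore", at$boundary == "periodic",
    params$sweeps, params$mode == "pure_ising",
    params$mode == "cpim" && params$stop_at_edge,
    params$record_every, params$snapshot_every, FALSE)
  snaps <- lapply(res$snapshots, new_lattice, boundary = at$boundary,
                  mode = at$mode)
  structure(
    list(lattice = new_lattice(res$grid, boundary = at$boundary,
                               mode = at$mode, sweep = res$sweeps_done),
         observables = observables_tibble(res$observables),
         snapshots = snaps,
         snapshot_sweeps = as.integer(res$snapshot_sweeps),
         stopped_at_edge = res$stopped_at_edge,
         sweeps_done = res$sweeps_done,
         params = params),
    class = "cpim_sim")
}

#' @export
print.cpim_sim <- function(x, ...) {
  cat(sprintf(
    "<cpim_sim> %s L=%d T=%.4g J=%+d: %d sweeps%s, %d observable rows, %d snapshots\n",
    x$params$mode, x$params$L, x$params$T, x$params$J, x$sweeps_done,
    if (isTRUE(x$stopped_at_edge)) " (stopped at edge)" else "",
    nrow(x$observables), length(x$snapshots)))
  invisible(x)
}

#' Run the pure two-dimensional Ising reference model
#'
#' Full-occupancy Metropolis dynamics on a periodic lattice with the
#' same flip rule as the CPIM.  A convenience wrapper around
#' [run_simulation()] that also reports the equilibrium mean absolute
#' magnetization per site after a burn-in.
#'
#' @param params A [cpim_params()] with `mode = "pure_ising"`.
#' @param burn_in Sweeps discarded before averaging; defaults to 20%
#'   of the budget.
#' @return A `cpim_sim` with an extra element `mean_abs_m`.
#' @examples
#' p <- cpim_params(L = 16, T = 2, sweeps = 400, seed = 1,
#'                  mode = "pure_ising")
#' run_pure_ising(p)$mean_abs_m
#' @export
run_pure_ising <- function(params, burn_in = NULL) {
  if (params$mode != "pure_ising")
    abort("`params$mode` must be \"pure_ising\".",
          class = "cpim_config_error")
  sim <- run_simulation(params)
  burn_in <- burn_in %||% floor(0.2 * params$sweeps)
  st <- magnetization_stats(sim$observables, burn_in = burn_in)
  sim$mean_abs_m <- st$mean_abs_m
  sim
}

#' Equilibrium configuration sampling on a tiny lattice
#'
#' Runs flip-only Metropolis dynamics on a fully differentiated
#' periodic lattice (`L <= 4`) and returns the visited configuration
#' per sweep, encoded as an integer bitmask over sites (bit set where
#' the spin is `+1`, column-major order).  Used to compare the
#' empirical configuration distribution against exact Boltzmann
#' weights.
#'
#' @param L Lattice side (at most 4 so configurations fit one integer).
#' @param T,J Coupling parameters.
#' @param sweeps Number of sweeps to sample.
#' @param seed RNG seed.
#' @return Integer vector of configuration codes, one per sweep.
#' @export
sample_configurations <- function(L, T, J, sweeps, seed = 1L) {
  if (L > 4) abort("L must be <= 4 for configuration recording.",
                   class = "cpim_config_error")
  set.seed(seed)
  g <- matrix(sample(c(-1L, 1L), L * L, replace = TRUE), L, L)
  res <- run_lattice_cpp(g, T, as.integer(J), 0, 0, 0, FALSE, TRUE,
                         as.integer(sweeps), TRUE, FALSE, 0L, 0L, TRUE)
  as.integer(res$configs)
}
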