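#' Simulation parameters for the contact-process Ising model
#'
#' Bundles every control of a CPIM (or pure-Ising reference) run.  The
#' control parameter `T` plays the role of temperature in units of
#' `|J|/k_B` (with `k_B = 1`): small `T` means strong coupling between
#' neighbouring cell states, large `T` weak coupling.  `J = +1` gives a
#' ferromagnetic circuit (neighbours favour the same state), `J = -1`
#' an anti-ferromagnetic one.  Demographic rates are per-site
#' probabilities per update attempt: `b` is the per-occupied-neighbour
#' colonization probability of a vacant site, `d` the death
#' probability of any occupied site, and `g` the probability that an
#' undifferentiated cell commits to one of the two differentiated
#' states (chosen with equal probability).
#'
#' The defaults `b = 0.03` and `d = 1e-5` correspond to a
#' high-reproductive-number contact process in which nearly all sites
#' behind the colony front are occupied.  `g` has no canonical value;
#' the default 0.1 keeps the undifferentiated rim thin relative to the
#' colony radius.
#'
#' @param L Lattice side, in sites (`L >= 2`).
#' @param T Coupling control parameter, dimensionless, `> 0`.
#' @param J Coupling sign, `+1` (ferromagnetic) or `-1`
#'   (anti-ferromagnetic).
#' @param b Colonization probability per occupied neighbour per
#'   attempt, in `[0, 1]`.
#' @param d Death probability per attempt, in `[0, 1]`.
#' @param g Differentiation probability per attempt for
#'   undifferentiated cells, in `[0, 1]`.
#' @param neighborhood `"von_neumann"` (4 neighbours) or `"moore"`
#'   (8 neighbours, the next-nearest-neighbour variant).
#' @param sweeps Sweep budget; one sweep is `L^2` random single-site
#'   update attempts.
#' @param seed Integer RNG seed; every run is a pure function of
#'   `(params, seed)`.
#' @param mode `"cpim"` for the growing-colony model, `"pure_ising"`
#'   for the fully occupied periodic-boundary Ising reference.
#' @param boundary `"open"` or `"periodic"`; defaults to open for
#'   CPIM colonies and periodic for pure Ising.
#' @param stop_at_edge In CPIM mode, stop the run at the end of the
#'   first sweep in which the colony touches the lattice edge.
#' @param record_every Record observables every this many sweeps
#'   (0 = never).
#' @param snapshot_every Store a full grid snapshot every this many
#'   sweeps (0 = never).
#'
#' @return An object of class `cpim_params` (a validated list).
#' @examples
#' p <- cpim_params(L = 64, T = 2.27, J = 1, sweeps = 500, seed = 1)
#' p$b
#' @export
cpim_params <- function(L, T, J = 1L, b = 0.03, d = 1e-5, g = 0.1,
                        neighborhood = c("von_neumann", "moore"),
                        sweeps = 1000L, seed = 1L,
                        mode = c("cpim", "pure_ising"),
                        boundary = NULL, stop_at_edge = (mode == "cpim"),
                        record_every = 1L, snapshot_every = 0L) {
  mode <- match.arg(mode)
  neighborhood <- match.arg(neighborhood)
  stop_at_edge <- isTRUE(stop_at_edge[1])
  if (is.null(boundary)) boundary <- if (mode == "cpim") "open" else "periodic"
  boundary <- match.arg(boundary, c("open", "periodic"))
  if (!is.numeric(L) || length(L) != 1 || L < 2 || L != round(L))
    abort("`L` must be a single integer >= 2.", class = "cpim_config_error")
  if (!is.numeric(T) || length(T) != 1 || T <= 0)
    abort("`T` must be a single positive number.", class = "cpim_config_error")
  if (!J %in% c(-1L, 1L))
    abort("`J` must be +1 or -1.", class = "cpim_config_error")
  for (nm in c("b", "d", "g")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      abort(sprintf("`%s` must be a probability in [0, 1].", nm),
            class = "cpim_config_error")
  }
  if (sweeps < 0 || sweeps != round(sweeps))
    abort("`sweeps` must be a non-negative integer.",
          class = "cpim_config_error")
  if (mode == "pure_ising" && boundary != "periodic")
    abort("pure_ising mode requires a periodic boundary.",
          class = "cpim_config_error")
  structure(
    list(L = as.integer(L), T = as.numeric(T), J = as.integer(J),
         b = b, d = d, g = g, neighborhood = neighborhood,
         sweeps = as.integer(sweeps), seed = as.integer(seed),
         mode = mode, boundary = boundary, stop_at_edge = stop_at_edge,
         record_every = as.integer(record_every),
         snapshot_every = as.integer(snapshot_every)),
    class = "cpim_params")
}

#' @export
print.cpim_params <- function(x, ...) {
  cat(sprintf(
    "<cpim_params> mode=%s L=%d T=%.4g J=%+d b=%g d=%g g=%g %s/%s sweeps=%d seed=%d\n",
    x$mode, x$L, x$T, x$J, x$b, x$d, x$g, x$neighborhood, x$boundary,
    x$sweeps, x$seed))
  invisible(x)
}
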