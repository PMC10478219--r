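#' Time-averaged magnetization statistics
#'
#' Averages `|m|` and `m^2` over the post-burn-in rows of an
#' observable series, where `m` is the net magnetization per occupied
#' site.
#'
#' @param series Observables tibble from [run_simulation()] (needs a
#'   `m_per_occupied` column, or a numeric vector of `m` values).
#' @param burn_in Number of leading sweeps to discard (compared
#'   against the `sweep` column when present, otherwise row index).
#' @return A one-row tibble with `mean_abs_m`, `mean_m2` and
#'   `n_samples`.
#' @export
magnetization_stats <- function(series, burn_in = 0) {
  if (is.numeric(series)) series <- tibble(m_per_occupied = series,
                                           sweep = seq_along(series))
  keep <- series$sweep > burn_in
  m <- series$m_per_occupied[keep]
  m <- m[is.finite(m)]
  if (length(m) == 0)
    abort("no samples left after burn-in.", class = "cpim_analysis_error")
  tibble(mean_abs_m = mean(abs(m)), mean_m2 = mean(m^2),
         n_samples = length(m))
}

#' Magnetic susceptibility per occupied site
#'
#' `chi = <n_occ> * (<m^2> - <|m|>^2) / T`, the standard finite-lattice
#' estimator built on `|m|` (on long runs `<m>` averages to zero by
#' sign symmetry, so the absolute value is used).
#'
#' @inheritParams magnetization_stats
#' @param T Coupling control parameter used in the run.
#' @return A single non-negative number.
#' @export
susceptibility <- function(series, T, burn_in = 0) {
  if (T <= 0) abort("`T` must be positive.", class = "cpim_config_error")
  st <- magnetization_stats(series, burn_in)
  keep <- series$sweep > burn_in & is.finite(series$m_per_occupied)
  n_occ <- mean(series$n_occupied[keep])
  v <- st$mean_m2 - st$mean_abs_m^2
  if (v < 0) {
    if (v < -1e-12)
      warn("negative magnetization variance clamped to 0.")
    v <- 0
  }
  n_occ * v / T
}

cpim_burn_in_sweep <- function(series, params, min_occupancy = 0.5,
                               burn_in_frac = 0.2) {
  frac_bi <- floor(burn_in_frac * max(series$sweep))
  if (params$mode == "pure_ising") return(frac_bi)
  thr <- min_occupancy * params$L^2
  idx <- which(series$n_occupied >= thr)
  if (length(idx) == 0) return(max(series$sweep))  # never equilibrated
  # wait for the colony to fill AND for the spin transient to relax
  max(series$sweep[idx[1]], frac_bi)
}

#' Scan the coupling parameter and measure magnetization observables
#'
#' Runs independent, seeded simulations for every combination of a
#' `T` grid and replicate index, and records `<|m|>`, `<m^2>`, the
#' susceptibility per occupied site and the mean occupancy for each.
#' CPIM scans run without the edge-stop and start measuring only once
#' the colony occupies at least `min_occupancy` of the lattice, so the
#' estimates are not dominated by the small early colony; pure-Ising
#' scans discard the first `burn_in_frac` of sweeps.
#'
#' @param params Base [cpim_params()]; its `T` is overridden by the
#'   grid and its seed offsets the per-run seeds.
#' @param T_grid Strictly increasing vector of control-parameter
#'   values.
#' @param replicates Independent runs per grid point.
#' @param min_occupancy CPIM measurement threshold (fraction of
#'   lattice sites).
#' @param burn_in_frac Pure-Ising burn-in fraction.
#' @return A tibble of class `cpim_tscan` with columns `T`, `L`,
#'   `replicate`, `mean_abs_m`, `mean_m2`, `chi`, `mean_n_occ`,
#'   `n_samples`.
#' @export
temperature_scan <- function(params, T_grid, replicates = 1,
                             min_occupancy = 0.5, burn_in_frac = 0.2) {
  if (any(diff(T_grid) <= 0) || any(T_grid <= 0))
    abort("`T_grid` must be strictly increasing and positive.",
          class = "cpim_config_error")
  combos <- expand.grid(T = T_grid, replicate = seq_len(replicates))
  rows <- purrr::pmap(combos, function(T, replicate) {
    p <- params
    p$T <- T
    p$stop_at_edge <- FALSE
    p$snapshot_every <- 0L
    p$seed <- params$seed + 7919L * (replicate - 1L) +
      match(T, T_grid) * 104729L
    sim <- run_simulation(p)
    bi <- cpim_burn_in_sweep(sim$observables, p, min_occupancy,
                             burn_in_frac)
    keep <- sim$observables$sweep > bi
    if (!any(keep & is.finite(sim$observables$m_per_occupied))) {
      # e.g. an extinct colony: report the run, not an error
      warn(sprintf("no usable samples at T=%g (replicate %d); %s",
                   T, replicate,
                   "colony extinct or never reached the threshold"))
      return(tibble(T = T, L = p$L, replicate = replicate,
                    mean_abs_m = NA_real_, mean_m2 = NA_real_,
                    chi = NA_real_, mean_n_occ = NA_real_,
                    n_samples = 0L))
    }
    st <- magnetization_stats(sim$observables, burn_in = bi)
    tibble(T = T, L = p$L, replicate = replicate,
           mean_abs_m = st$mean_abs_m, mean_m2 = st$mean_m2,
           chi = susceptibility(sim$observables, T, burn_in = bi),
           mean_n_occ = mean(sim$observables$n_occupied[keep]),
           n_samples = st$n_samples)
  })
  out <- bind_rows(rows)
  class(out) <- c("cpim_tscan", class(out))
  out
}

# Vertex of the parabola through three points; used to interpolate the
# susceptibility peak off the T grid.
quad_peak <- function(x, y) {
  stopifnot(length(x) == 3)
  d21 <- x[2] - x[1]; d23 <- x[2] - x[3]
  num <- d21^2 * (y[2] - y[3]) - d23^2 * (y[2] - y[1])
  den <- d21 * (y[2] - y[3]) - d23 * (y[2] - y[1])
  if (abs(den) < 1e-300) return(list(x = x[2], y = y[2]))
  xs <- x[2] - 0.5 * num / den
  # parabola value at the vertex via Lagrange interpolation
  ys <- sum(y * c(
    (xs - x[2]) * (xs - x[3]) / ((x[1] - x[2]) * (x[1] - x[3])),
    (xs - x[1]) * (xs - x[3]) / ((x[2] - x[1]) * (x[2] - x[3])),
    (xs - x[1]) * (xs - x[2]) / ((x[3] - x[1]) * (x[3] - x[2]))))
  list(x = xs, y = ys)
}

scan_peak <- function(scan) {
  agg <- scan %>%
    group_by(.data$T) %>%
    summarise(chi = mean(.data$chi, na.rm = TRUE),
              mean_abs_m = mean(.data$mean_abs_m, na.rm = TRUE),
              mean_n_occ = mean(.data$mean_n_occ, na.rm = TRUE),
              .groups = "drop") %>%
    arrange(.data$T)
  k <- which.max(agg$chi)
  n <- nrow(agg)
  if (k == 1 || k == n) {
    warn("susceptibility peak at the edge of the T grid; no interpolation.")
    pk <- list(x = agg$T[k], y = agg$chi[k])
  } else {
    pk <- quad_peak(agg$T[(k - 1):(k + 1)], agg$chi[(k - 1):(k + 1)])
  }
  # magnetization and occupancy at the (interpolated) critical point
  m_c <- stats::approx(agg$T, agg$mean_abs_m, xout = pk$x, rule = 2)$y
  nocc_c <- stats::approx(agg$T, agg$mean_n_occ, xout = pk$x, rule = 2)$y
  tibble(L = scan$L[1], T_c = pk$x, chi_max = pk$y,
         mean_abs_m_c = m_c, mean_abs_M_c = m_c * nocc_c)
}

#' Finite-size scaling analysis of the susceptibility peak
#'
#' For each lattice size, extracts the susceptibility peak height
#' `chi_max`, its location `T_c(L)` (3-point quadratic interpolation
#' around the grid maximum) and the absolute magnetization at the
#' critical point, then fits log-log slopes of `chi_max` and
#' `<|M|>_c` against `L` and extrapolates the infinite-size critical
#' parameter `T_c` by a linear fit of `T_c(L)` against `1/L`.
#'
#' @param scans A `cpim_tscan` tibble covering at least 3 distinct
#'   lattice sizes (rows from several [temperature_scan()] calls bound
#'   together), or a list of such tibbles.
#' @return An object of class `cpim_fss`: list with `per_L` (tibble),
#'   `slope_chi`, `slope_M`, `T_c_extrapolated` and the underlying
#'   `lm` fits.
#' @export
finite_size_scaling <- function(scans) {
  if (is.list(scans) && !is.data.frame(scans)) scans <- bind_rows(scans)
  Ls <- sort(unique(scans$L))
  if (length(Ls) < 3)
    abort("need scans at >= 3 distinct lattice sizes.",
          class = "cpim_analysis_error")
  per_L <- bind_rows(lapply(Ls, function(l)
    scan_peak(scans[scans$L == l, ])))
  fit_chi <- lm(log(chi_max) ~ log(L), data = per_L)
  fit_M <- lm(log(mean_abs_M_c) ~ log(L), data = per_L)
  fit_Tc <- lm(T_c ~ I(1 / L), data = per_L)
  structure(list(per_L = per_L,
                 slope_chi = unname(coef(fit_chi)[2]),
                 slope_M = unname(coef(fit_M)[2]),
                 T_c_extrapolated = unname(coef(fit_Tc)[1]),
                 fits = list(chi = fit_chi, M = fit_M, T_c = fit_Tc)),
            class = "cpim_fss")
}

#' @export
print.cpim_fss <- function(x, ...) {
  cat("<cpim_fss> finite-size scaling of the susceptibility peak\n")
  print(x$per_L)
  cat(sprintf("log-log slope of chi_max vs L: %.3f\n", x$slope_chi))
  cat(sprintf("log-log slope of <|M|>_c vs L: %.3f\n", x$slope_M))
  cat(sprintf("extrapolated T_c: %.4f\n", x$T_c_extrapolated))
  invisible(x)
}

#' @rdname finite_size_scaling
#' @param x A `cpim_fss` object.
#' @param ... Unused.
#' @export
tidy.cpim_fss <- function(x, ...) {
  tibble(term = c("slope_chi_max", "slope_abs_M_c", "T_c_extrapolated"),
         estimate = c(x$slope_chi, x$slope_M, x$T_c_extrapolated))
}

#' @rdname finite_size_scaling
#' @export
glance.cpim_fss <- function(x, ...) {
  tibble(n_sizes = nrow(x$per_L),
         T_c_extrapolated = x$T_c_extrapolated,
         slope_chi_max = x$slope_chi,
         slope_abs_M_c = x$slope_M)
}
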