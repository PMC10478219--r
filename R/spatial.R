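#' Masked radial spatial autocorrelation of a two-state field
#'
#' Computes the spatial autocorrelation function (sACF) of a signed
#' two-state field over an arbitrary site mask: for each radial
#' distance bin, the normalized covariance between the mean-subtracted
#' state values of all in-mask site pairs separated by that distance.
#' Normalization is per-offset ("overlap-counted"): pairs with either
#' endpoint outside the mask are excluded, so embedding a pattern in a
#' larger vacant field leaves the sACF unchanged.  `C(0) = 1` by
#' construction; a value of +1/-1 at distance `r` means perfect
#' correlation/anticorrelation at that separation.
#'
#' Implemented with FFT cross-correlation of the zero-filled signed
#' field and of the mask (equivalent to, and tested against, direct
#' pair counting).
#'
#' @param grid A lattice of site codes (`0`, `2`, `+1`, `-1`), a
#'   binary 0/1 pattern, or a `+1`/`-1` matrix.  Code lattices are
#'   analysed over their differentiated sites; binary patterns are
#'   mapped to `2*v - 1` over the full frame (or the given mask).
#' @param mask Optional logical matrix selecting the sites to analyse;
#'   defaults to the differentiated sites of a code lattice, or all
#'   sites otherwise.
#' @param bin_width Radial bin width in lattice units; bins are
#'   centred on `0, bin_width, 2*bin_width, ...`.
#' @param max_r Largest distance reported; defaults to half the larger
#'   grid dimension.
#' @param center Value subtracted from the signed field before
#'   correlating.  The default (`NULL`) subtracts the in-mask mean of
#'   the pattern itself; for ensembles of near-critical snapshots pass
#'   `center = 0` (the ensemble mean under state symmetry), because
#'   per-image centering forces the correlations to sum to zero over
#'   the frame and biases the tail downward when the correlation
#'   length is comparable to the frame size.
#' @return A tibble of class `cpim_acf` with columns `r`, `C` and
#'   `n_pairs` (unordered in-mask pairs per bin).
#' @examples
#' cb <- make_fixture("checkerboard", 16)
#' radial_acf(cb)[1:3, ]
#' @export
radial_acf <- function(grid, mask = NULL, bin_width = 1, max_r = NULL,
                       center = NULL) {
  fm <- as_signed_field(grid, mask)
  s <- fm$field; mask <- fm$mask
  if (sum(mask) < 2)
    abort("mask must cover at least 2 sites.", class = "cpim_analysis_error")
  mu <- center %||% mean(s[mask])
  f <- (s - mu) * mask
  if (all(abs(f[mask]) < 1e-12))
    abort("field is constant inside the mask; sACF undefined.",
          class = "cpim_analysis_error")
  n1 <- nrow(s); n2 <- ncol(s)
  P1 <- stats::nextn(2L * n1); P2 <- stats::nextn(2L * n2)
  pad <- function(x) {
    out <- matrix(0, P1, P2)
    out[seq_len(n1), seq_len(n2)] <- x
    out
  }
  xcorr <- function(x) {
    Fx <- fft(pad(x))
    Re(fft(Fx * Conj(Fx), inverse = TRUE)) / (P1 * P2)
  }
  num <- xcorr(f)
  cnt <- xcorr(mask * 1.0)
  # offsets: index k (0-based) corresponds to displacement dk, with the
  # padded circular layout putting negative shifts at the top end
  d1 <- c(0:(P1 - 1)); d1 <- ifelse(d1 > P1 / 2, d1 - P1, d1)
  d2 <- c(0:(P2 - 1)); d2 <- ifelse(d2 > P2 / 2, d2 - P2, d2)
  r <- sqrt(outer(d1^2, d2^2, `+`))
  max_r <- max_r %||% (max(n1, n2) / 2)
  keep <- r <= max_r + bin_width / 2 & round(cnt) >= 1
  bins <- floor(r[keep] / bin_width + 0.5)
  num_b <- tapply(num[keep], bins, sum)
  cnt_b <- tapply(cnt[keep], bins, sum)
  var0 <- num[1, 1] / cnt[1, 1]
  rb <- as.numeric(names(num_b)) * bin_width
  Cb <- as.numeric(num_b / cnt_b) / var0
  npairs <- round(as.numeric(cnt_b))
  npairs[rb > 0] <- npairs[rb > 0] / 2  # unordered pairs
  out <- tibble(r = rb, C = Cb, n_pairs = npairs) %>% arrange(.data$r)
  class(out) <- c("cpim_acf", class(out))
  out
}

# Map a code lattice / binary pattern to a signed +-1 field plus mask.
as_signed_field <- function(grid, mask = NULL) {
  g <- unclass(grid)
  attributes(g) <- list(dim = dim(g))
  vals <- unique(as.vector(g))
  if (all(vals %in% c(0L, 1L)) && any(vals == 0L)) {
    # binary 0/1 pattern over the full frame
    s <- 2 * g - 1
    if (is.null(mask)) mask <- matrix(TRUE, nrow(g), ncol(g))
  } else if (all(vals %in% c(-1L, 1L))) {
    s <- g
    if (is.null(mask)) mask <- matrix(TRUE, nrow(g), ncol(g))
  } else if (all(vals %in% c(0L, 2L, -1L, 1L))) {
    # code lattice: analyse the signed field over differentiated sites
    s <- g
    s[!(g == 1L | g == -1L)] <- 0
    if (is.null(mask)) mask <- (g == 1L) | (g == -1L)
  } else {
    abort("grid values must be lattice codes, 0/1 or +1/-1.",
          class = "cpim_parse_error")
  }
  list(field = s * 1.0, mask = mask & TRUE)
}

nlsLM_ctrl <- function() minpack.lm::nls.lm.control(
  maxiter = 500, ftol = 1e-10, ptol = 1e-10)

# Tight tolerances give the cleanest parameter recovery, but the
# Levenberg-Marquardt wrapper can fail to assemble its result when a
# start is already (numerically) at a zero-residual optimum; fall back
# to the default control in that case.
nlsLM_fit <- function(formula, data, start, lower = NULL, upper = NULL,
                      weights = NULL) {
  args <- list(formula = formula, data = data, start = start)
  if (!is.null(lower)) args$lower <- lower
  if (!is.null(upper)) args$upper <- upper
  if (!is.null(weights)) args$weights <- weights
  tryCatch(do.call(minpack.lm::nlsLM, c(args, list(control = nlsLM_ctrl()))),
           error = function(e) do.call(minpack.lm::nlsLM, args))
}

#' Fit a one-phase exponential decay to an sACF
#'
#' Fits `C(r) = y0 * exp(-r / b) + C0` by nonlinear least squares.
#' The length constant `b` estimates the mean size of same-state
#' domains.
#'
#' @param acf A `cpim_acf` tibble (or any data frame with `r` and `C`).
#' @param fit_range Numeric `c(min, max)` distance range to fit;
#'   default the full range.
#' @param start Optional named list of starting values `y0`, `b`, `C0`.
#' @return An object of class `cpim_expfit` with elements `y0`, `b`,
#'   `C0` and the underlying `nls` fit.
#' @export
fit_acf_exponential <- function(acf, fit_range = NULL, start = NULL) {
  df <- acf[is.finite(acf$C), c("r", "C")]
  if (!is.null(fit_range))
    df <- df[df$r >= fit_range[1] & df$r <= fit_range[2], ]
  if (nrow(df) < 5)
    abort("need at least 5 sACF bins to fit.", class = "cpim_fit_error")
  if (is.null(start)) {
    C0 <- min(df$C)
    y0 <- max(df$C) - C0
    target <- C0 + y0 * exp(-1)
    below <- df$r[df$C <= target & df$r > 0]
    b0 <- if (length(below)) max(min(below), 1e-3) else max(df$r) / 3
    start <- list(y0 = y0, b = b0, C0 = C0)
  }
  fit <- tryCatch(
    nlsLM_fit(C ~ y0 * exp(-r / b) + C0, data = df, start = start,
              lower = c(-Inf, 1e-9, -Inf)),
    error = function(e) abort(paste0("exponential sACF fit failed: ",
                                     conditionMessage(e)),
                              class = "cpim_fit_error"))
  cf <- coef(fit)
  structure(list(y0 = unname(cf["y0"]), b = unname(cf["b"]),
                 C0 = unname(cf["C0"]), fit = fit,
                 fit_range = range(df$r)),
            class = "cpim_expfit")
}

#' @export
print.cpim_expfit <- function(x, ...) {
  cat(sprintf("<cpim_expfit> C(r) = %.4g * exp(-r/%.4g) + %.4g\n",
              x$y0, x$b, x$C0))
  invisible(x)
}

#' @rdname fit_acf_exponential
#' @param x A `cpim_expfit` object.
#' @param ... Unused.
#' @export
tidy.cpim_expfit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2])
}

#' Fit the critical power-law decay form to an sACF
#'
#' Fits `C(r) = A * exp(-r / B) / r^eta` by nonlinear least squares
#' over a range excluding `r = 0`.  At a critical point the
#' exponential cutoff `B` grows large and `eta` is the critical
#' exponent of the correlation function (0.25 for the 2-D Ising
#' universality class).
#'
#' @inheritParams fit_acf_exponential
#' @param fit_range Distance range used for the fit; default
#'   `c(1, max(r)/2)`.  Must exclude 0.
#' @return An object of class `cpim_plawacf` with elements `A`, `B`,
#'   `eta`, `eta_ci` (95% Wald interval) and the `nls` fit.
#' @export
fit_acf_powerlaw <- function(acf, fit_range = NULL, start = NULL) {
  fit_range <- fit_range %||% c(1, max(acf$r) / 2)
  if (fit_range[1] <= 0)
    abort("fit range must exclude r = 0.", class = "cpim_fit_error")
  df <- acf[acf$r >= fit_range[1] & acf$r <= fit_range[2] &
              is.finite(acf$C), c("r", "C")]
  if (nrow(df) < 4)
    abort("fewer sACF points than parameters.", class = "cpim_fit_error")
  if (is.null(start)) {
    pos <- df[df$C > 0, ]
    eta0 <- if (nrow(pos) >= 2)
      max(0.01, -coef(lm(log(C) ~ log(r), data = pos))[2]) else 0.25
    start <- list(A = max(df$C[1], 1e-3) * df$r[1]^eta0,
                  B = 10 * max(df$r), eta = eta0)
  }
  fit <- tryCatch(
    nlsLM_fit(C ~ A * exp(-r / B) / r^eta, data = df, start = start,
              lower = c(1e-12, 1e-6, 0), upper = c(Inf, Inf, 5)),
    error = function(e) abort(paste0("power-law sACF fit failed: ",
                                     conditionMessage(e)),
                              class = "cpim_fit_error"))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, 2], error = function(e)
    rep(NA_real_, 3))
  eta_ci <- unname(cf["eta"] + c(-1, 1) * qnorm(0.975) * se["eta"])
  structure(list(A = unname(cf["A"]), B = unname(cf["B"]),
                 eta = unname(cf["eta"]), eta_ci = eta_ci,
                 fit = fit, fit_range = fit_range),
            class = "cpim_plawacf")
}

#' @export
print.cpim_plawacf <- function(x, ...) {
  cat(sprintf(
    "<cpim_plawacf> C(r) = %.4g * exp(-r/%.4g) / r^%.4g  (eta 95%% CI %.3f..%.3f)\n",
    x$A, x$B, x$eta, x$eta_ci[1], x$eta_ci[2]))
  invisible(x)
}

#' @rdname fit_acf_powerlaw
#' @param x A `cpim_plawacf` object.
#' @param ... Unused.
#' @export
tidy.cpim_plawacf <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2])
}

#' Connected same-state clusters of a lattice or binary pattern
#'
#' Labels the connected components of each state separately (breadth-
#' first search) and returns their sizes.  Default 4-connectivity
#' matches the lattice adjacency; 8-connectivity joins diagonal
#' touches.
#'
#' @param grid Code lattice (clusters of `+1` and `-1`) or binary 0/1
#'   pattern (clusters of 0 and 1).
#' @param connectivity 4 or 8.
#' @param states Site values whose clusters are extracted; default
#'   `c(-1, 1)` for code lattices and `c(0, 1)` for binary patterns.
#' @param min_size Discard clusters smaller than this (default keeps
#'   all).
#' @return A list of class `cpim_clusters`: `labels` (integer matrix,
#'   0 = unlabelled), `sizes` (tibble `id`, `state`, `size`),
#'   `connectivity`, `min_size`.
#' @examples
#' label_clusters(make_fixture("checkerboard", 8))$sizes
#' @export
label_clusters <- function(grid, connectivity = 4, states = NULL,
                           min_size = 1) {
  if (!connectivity %in% c(4, 8))
    abort("connectivity must be 4 or 8.", class = "cpim_config_error")
  g <- unclass(grid); attributes(g) <- list(dim = dim(g))
  storage.mode(g) <- "integer"
  if (is.null(states)) {
    vals <- unique(as.vector(g))
    states <- if (all(vals %in% c(0L, 1L))) c(0L, 1L) else c(-1L, 1L)
  }
  res <- label_clusters_cpp(g, as.integer(connectivity),
                            as.integer(states))
  sizes <- tibble(id = seq_along(res$size), state = res$state,
                  size = res$size)
  sizes <- sizes[sizes$size >= min_size, ]
  structure(list(labels = res$labels, sizes = sizes,
                 connectivity = connectivity, min_size = min_size),
            class = "cpim_clusters")
}

#' @export
print.cpim_clusters <- function(x, ...) {
  cat(sprintf("<cpim_clusters> %d clusters (%d-connectivity), sizes %d..%d\n",
              nrow(x$sizes), x$connectivity,
              min(x$sizes$size), max(x$sizes$size)))
  invisible(x)
}

#' Empirical cluster-size distribution
#'
#' Normalized histogram of cluster sizes, either per exact size or
#' log-binned (geometric bins) for plotting and least-squares fitting.
#'
#' @param sizes A `cpim_clusters` object, its `sizes` tibble, or a
#'   plain integer vector of sizes.
#' @param log_bin Return a log-binned density instead of exact
#'   probabilities.
#' @param bin_ratio Geometric bin growth factor when `log_bin = TRUE`.
#' @return A tibble: `size`, `p` (probabilities summing to 1), or for
#'   the log-binned variant `size` (geometric bin centre), `density`
#'   (probability per unit size) and `count`.
#' @export
cluster_size_distribution <- function(sizes, log_bin = FALSE,
                                      bin_ratio = 2) {
  s <- extract_sizes(sizes)
  if (length(s) == 0)
    abort("empty cluster-size sample.", class = "cpim_analysis_error")
  n <- length(s)
  if (!log_bin) {
    tb <- table(s)
    return(tibble(size = as.numeric(names(tb)),
                  p = as.numeric(tb) / n))
  }
  kmax <- ceiling(log(max(s) + 1) / log(bin_ratio))
  edges <- unique(c(1, bin_ratio^seq_len(kmax + 1)))
  bin <- findInterval(s, edges, rightmost.closed = FALSE)
  cnt <- tabulate(bin, nbins = length(edges) - 1)
  width <- diff(edges)
  ctr <- sqrt(edges[-length(edges)] * edges[-1])
  keep <- cnt > 0
  tibble(size = ctr[keep], density = cnt[keep] / (n * width[keep]),
         count = cnt[keep])
}

extract_sizes <- function(sizes) {
  if (inherits(sizes, "cpim_clusters")) sizes <- sizes$sizes
  if (is.data.frame(sizes)) sizes <- sizes$size
  s <- as.numeric(sizes)
  if (any(s < 1)) abort("cluster sizes must be >= 1.",
                        class = "cpim_analysis_error")
  s
}
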