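lattice_df <- function(x) {
  g <- unclass(x); attributes(g) <- list(dim = dim(g))
  tibble(row = rep(seq_len(nrow(g)), times = ncol(g)),
         col = rep(seq_len(ncol(g)), each = nrow(g)),
         state = factor(as.vector(g), levels = c(0, 2, 1, -1),
                        labels = c("vacant", "undifferentiated",
                                   "+1", "-1")))
}

#' Plot a lattice state
#'
#' Raster view using the state palette: vacant white, undifferentiated
#' black, `+1` magenta, `-1` green.
#'
#' @param object A `cpim_lattice`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cpim_lattice <- function(object, ...) {
  df <- lattice_df(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$state)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(vacant = "white", undifferentiated = "black",
                 `+1` = "magenta", `-1` = "green3"),
      drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "state") +
    ggplot2::theme_minimal()
}

#' Plot a radial autocorrelation function
#'
#' @param object A `cpim_acf` tibble.
#' @param fit Optional `cpim_expfit` or `cpim_plawacf` overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cpim_acf <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$r, .data$C)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "distance r (sites)", y = "C(r)") +
    ggplot2::theme_classic()
  if (!is.null(fit)) {
    rr <- seq(max(min(object$r), 0.5), max(object$r), length.out = 200)
    yy <- if (inherits(fit, "cpim_expfit"))
      fit$y0 * exp(-rr / fit$b) + fit$C0
    else fit$A * exp(-rr / fit$B) / rr^fit$eta
    p <- p + ggplot2::geom_line(data = tibble(r = rr, C = yy),
                                colour = "red")
  }
  p
}

#' Plot a temperature scan
#'
#' Mean absolute magnetization and susceptibility per occupied site
#' against the coupling control parameter.
#'
#' @param object A `cpim_tscan` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cpim_tscan <- function(object, ...) {
  agg <- object %>%
    group_by(.data$T, .data$L) %>%
    summarise(mean_abs_m = mean(.data$mean_abs_m),
              chi = mean(.data$chi), .groups = "drop") %>%
    tidyr::pivot_longer(c("mean_abs_m", "chi"), names_to = "observable")
  ggplot2::ggplot(agg, ggplot2::aes(.data$T, .data$value,
                                    colour = factor(.data$L))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "control parameter T", y = NULL, colour = "L") +
    ggplot2::theme_classic()
}

#' Plot a finite-size scaling result
#'
#' Log-log susceptibility-peak height against lattice size with the
#' fitted scaling line.
#'
#' @param object A `cpim_fss` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cpim_fss <- function(object, ...) {
  ggplot2::ggplot(object$per_L,
                  ggplot2::aes(log(.data$L), log(.data$chi_max))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red") +
    ggplot2::labs(x = "log L", y = "log chi_max",
                  subtitle = sprintf("slope %.3f, extrapolated T_c %.3f",
                                     object$slope_chi,
                                     object$T_c_extrapolated)) +
    ggplot2::theme_classic()
}

#' Plot a cluster-size distribution with power-law fits
#'
#' @param object A `cpim_clusters` object or tibble of sizes.
#' @param fits Optional list of `cpim_powerlaw` fits to overlay.
#' @param ... Unused.
#' @return A ggplot object (log-log axes).
#' @export
plot_cluster_sizes <- function(object, fits = NULL, ...) {
  pdf <- cluster_size_distribution(object, log_bin = TRUE)
  p <- ggplot2::ggplot(pdf, ggplot2::aes(.data$size, .data$density)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cluster size S", y = "P(S)") +
    ggplot2::theme_classic()
  if (!is.null(fits)) {
    if (inherits(fits, "cpim_powerlaw")) fits <- list(fits)
    for (f in fits) {
      ss <- 10^seq(log10(f$x_min), log10(max(pdf$size)), length.out = 50)
      ref <- pdf$density[which.min(abs(pdf$size - f$x_min))]
      p <- p + ggplot2::geom_line(
        data = tibble(size = ss,
                      density = ref * (ss / f$x_min)^(-f$gamma)),
        colour = "red", linetype = if (f$estimator == "mle") 1 else 2)
    }
  }
  p
}

#' Plot a dose-response fit
#'
#' Measured normalized synthesis rates with the fitted promoter-
#' occupancy curve on a log concentration axis.
#'
#' @param object A `cpim_dosefit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cpim_dosefit <- function(object, ...) {
  cv <- object$curve
  Lr <- range(cv$L_molar[cv$L_molar > 0])
  grid <- 10^seq(log10(Lr[1]), log10(Lr[2]), length.out = 200)
  cf <- setNames(object$params$estimate, object$params$term)
  nn <- if (is.na(object$n_fixed)) cf["n"] else object$n_fixed
  pred <- p_on(grid, cf["n_beta_dE"], 10^cf["log10_Kd_on"],
               10^cf["log10_Kd_off"], nn)
  p <- ggplot2::ggplot(cv, ggplot2::aes(.data$L_molar, .data$rate_norm)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = tibble(L_molar = grid, rate_norm = pred),
                       colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[ligand] (M)", y = "normalized synthesis rate") +
    ggplot2::theme_classic()
  if ("sd" %in% names(cv))
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$rate_norm - .data$sd,
                   ymax = .data$rate_norm + .data$sd), width = 0.05)
  p
}
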