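#' Equilibrium promoter activation probability
#'
#' Two-state thermodynamic model of a dual-input promoter: the
#' probability of the active (ON) state at ligand concentration `L`
#' is
#' `p_on = (1 + ((1 + L/Kd_off) / (1 + L/Kd_on))^n * exp(-n_beta_dE))^-1`,
#' where `Kd_on` and `Kd_off` are the dissociation constants of the
#' ligand for the active and inactive promoter, `n` is a Hill
#' exponent for cooperative binding, and `n_beta_dE = n * beta * dE`
#' is the (dimensionless) energy gap term with
#' `dE = E_off - E_on`; `beta` and `dE` enter only through this
#' product, so they are fitted as one compound parameter.  `p_on` is
#' increasing in `L` when `Kd_on < Kd_off` (the ligand stabilises the
#' active state) and decreasing when `Kd_on > Kd_off`.
#'
#' @param L Ligand concentration(s), molar, `>= 0`.
#' @param n_beta_dE Compound energy-gap parameter `n*beta*dE`
#'   (positive values favour the ON state at `L = 0`).
#' @param Kd_on,Kd_off Dissociation constants, molar, `> 0`.
#' @param n Hill exponent, `> 0`.
#' @return Activation probabilities in `(0, 1)`.
#' @examples
#' p_on(0, n_beta_dE = 0, Kd_on = 1e-9, Kd_off = 1e-6)   # 0.5
#' p_on(0, n_beta_dE = -2, Kd_on = 1e-9, Kd_off = 1e-6)  # (1+e^2)^-1
#' @export
p_on <- function(L, n_beta_dE, Kd_on, Kd_off, n = 1) {
  if (any(L < 0)) abort("`L` must be non-negative.",
                        class = "cpim_domain_error")
  if (Kd_on <= 0 || Kd_off <= 0 || n <= 0)
    abort("Kd_on, Kd_off and n must be positive.",
          class = "cpim_config_error")
  ratio <- (1 + L / Kd_off) / (1 + L / Kd_on)
  1 / (1 + ratio^n * exp(-n_beta_dE))
}

#' Fit the promoter-occupancy model to a dose-response curve
#'
#' Weighted nonlinear least squares of [p_on()] against normalized
#' synthesis rates across a ligand titration.  Concentrations are
#' handled in log10 space internally (the dissociation constants are
#' fitted as `log10(Kd)`).  When replicate standard deviations are
#' present, weights `1/sd^2` are used by default.
#'
#' @param curve Data frame with columns `L_molar` (strictly
#'   increasing), `rate_norm` (in `[0, 1]`), optionally `sd`.
#' @param n Hill exponent: a fixed value (default 1), or `NA` to fit
#'   it.
#' @param init Optional named list of starting values (`n_beta_dE`,
#'   `log10_Kd_on`, `log10_Kd_off`, and `n` when fitted).
#' @param weighted Use `1/sd^2` weights when `sd` is available.
#' @return An object of class `cpim_dosefit`: fitted `params` (a
#'   tibble), `n_fixed`, `decreasing` (direction of the fitted curve),
#'   `kd_flagged` (TRUE when a Kd confidence interval spans more than
#'   3 decades, indicating non-identifiability), and the `nls` fit.
#' @export
fit_dose_response <- function(curve, n = 1, init = NULL, weighted = TRUE) {
  stopifnot(all(c("L_molar", "rate_norm") %in% names(curve)))
  if (nrow(curve) < 5 ||
      diff(range(log10(curve$L_molar[curve$L_molar > 0]))) < 3)
    abort("need >= 5 concentrations spanning >= 3 decades.",
          class = "cpim_usage_error")
  df <- data.frame(L = curve$L_molar, y = curve$rate_norm)
  w <- if (weighted && "sd" %in% names(curve) &&
           all(is.finite(curve$sd)) && all(curve$sd > 0))
    1 / curve$sd^2 else rep(1, nrow(df))
  fit_n <- is.na(n)
  lmid <- median(log10(df$L[df$L > 0]))
  increasing <- stats::cor(log10(pmax(df$L, min(df$L[df$L > 0]) / 10)),
                           df$y) >= 0
  if (is.null(init)) {
    init <- list(n_beta_dE = if (increasing) -2 else 2,
                 log10_Kd_on = if (increasing) lmid - 1 else lmid + 1,
                 log10_Kd_off = if (increasing) lmid + 1 else lmid - 1)
    if (fit_n) init$n <- 1
  }
  form <- if (fit_n)
    y ~ p_on(L, n_beta_dE, 10^log10_Kd_on, 10^log10_Kd_off, n)
  else
    substitute(y ~ p_on(L, n_beta_dE, 10^log10_Kd_on, 10^log10_Kd_off, nfx),
               list(nfx = n))
  lower <- c(-50, -15, -15); upper <- c(50, 0, 0)
  if (fit_n) { lower <- c(lower, 0.1); upper <- c(upper, 8) }
  fit <- tryCatch(
    nlsLM_fit(stats::as.formula(form), data = df, start = init,
              lower = lower, upper = upper, weights = w),
    error = function(e) abort(paste0("dose-response fit failed: ",
                                     conditionMessage(e)),
                              class = "cpim_fit_error"))
  sm <- summary(fit)$coefficients
  params <- tibble(term = rownames(sm), estimate = sm[, 1],
                   std.error = sm[, 2],
                   conf.low = sm[, 1] - qnorm(0.975) * sm[, 2],
                   conf.high = sm[, 1] + qnorm(0.975) * sm[, 2])
  kd <- params[params$term %in% c("log10_Kd_on", "log10_Kd_off"), ]
  kd_flagged <- any((kd$conf.high - kd$conf.low) > 3, na.rm = TRUE)
  pr <- predict(fit)
  structure(list(params = params, n_fixed = if (fit_n) NA else n,
                 decreasing = pr[length(pr)] < pr[1],
                 kd_flagged = kd_flagged, fit = fit,
                 curve = as_tibble(curve)),
            class = "cpim_dosefit")
}

#' @export
print.cpim_dosefit <- function(x, ...) {
  cat(sprintf("<cpim_dosefit> %s channel%s\n",
              if (x$decreasing) "decreasing (repressed)" else
                "increasing (induced)",
              if (isTRUE(x$kd_flagged))
                " [Kd pair poorly identified: CI spans > 3 decades]" else ""))
  print(x$params)
  invisible(x)
}

#' @rdname fit_dose_response
#' @param x A `cpim_dosefit` object.
#' @param ... Unused.
#' @export
tidy.cpim_dosefit <- function(x, ...) x$params

#' @rdname fit_dose_response
#' @export
glance.cpim_dosefit <- function(x, ...) {
  tibble(sigma = summary(x$fit)$sigma,
         decreasing = x$decreasing, kd_flagged = x$kd_flagged,
         n_obs = nrow(x$curve))
}

#' Generate a synthetic two-channel dose-response data set
#'
#' Emulates the titration of a two-state circuit with a single
#' coupling signal: the induced channel (RFP) follows [p_on()] and
#' the mutually exclusive channel (GFP) follows `1 - p_on`, so the
#' noiseless channels sum to 1 at every concentration.  Gaussian
#' noise is added per replicate, rates are clipped at 0 and each
#' channel is normalized by its own maximum (per-system max = 1).
#' The default parameters place the channel crossover near `1e-8` M,
#' the switching concentration of the ferromagnetic circuit.
#'
#' @param L_grid Ligand concentrations (molar), strictly increasing;
#'   default 12 log-spaced points over `1e-11 .. 1e-5` M.
#' @param n_beta_dE,Kd_on,Kd_off,n Model parameters of the induced
#'   channel (see [p_on()]).
#' @param noise_sd Gaussian noise standard deviation (on the rate
#'   scale), `>= 0`.
#' @param replicates Biological replicates per concentration.
#' @param seed RNG seed.
#' @param system Label stored in the `system` column.
#' @return A tibble with columns `L_molar`, `rate_norm`, `sd`,
#'   `channel` (`"RFP"`/`"GFP"`), `system`.
#' @export
simulate_dose_response <- function(L_grid = 10^seq(-11, -5, length.out = 12),
                                   n_beta_dE = log(0.1),
                                   Kd_on = 1e-9, Kd_off = 1e-7, n = 1,
                                   noise_sd = 0.03, replicates = 4,
                                   seed = 1, system = "ferro") {
  stopifnot(noise_sd >= 0, all(diff(L_grid) > 0))
  set.seed(seed)
  p <- p_on(L_grid, n_beta_dE, Kd_on, Kd_off, n)
  chans <- list(RFP = p, GFP = 1 - p)
  bind_rows(lapply(names(chans), function(ch) {
    reps <- replicate(replicates,
                      pmax(chans[[ch]] + rnorm(length(L_grid), 0, noise_sd), 0))
    mn <- rowMeans(reps)
    mx <- max(mn)
    tibble(L_molar = L_grid, rate_norm = mn / mx,
           sd = apply(reps, 1, sd) / mx, channel = ch, system = system)
  }))
}
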