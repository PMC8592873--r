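# Measurement models: pulsed-field-gradient diffusion decay, 4PL
# dose-response, two-state thermal melt, monomer-dimer exchange.

.H1_GAMMA <- 2.6752218744e8  # rad s^-1 T^-1

.fit_result <- function(fit, n, model, params = NULL, ci95 = NULL) {
  est <- stats::coef(fit)
  if (!is.null(params)) est <- est[params]
  se <- tryCatch(summary(fit)$coefficients[names(est), "Std. Error"],
                 error = function(e) rep(NA_real_, length(est)))
  df <- n - length(stats::coef(fit))
  if (is.null(ci95)) {
    tq <- stats::qt(0.975, df)
    ci95 <- cbind(lower = est - tq * se, upper = est + tq * se)
  }
  structure(list(estimates = est, se = se, ci95 = ci95,
                 rss = sum(stats::resid(fit)^2), n = n,
                 converged = isTRUE(fit$convInfo$isConv) ||
                   is.null(fit$convInfo),
                 model = model, fit = fit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit:", x$model, if (!x$converged) "(NOT CONVERGED)", "\n")
  tab <- data.frame(estimate = x$estimates, se = x$se,
                    ci95_lower = x$ci95[, 1], ci95_upper = x$ci95[, 2])
  print(format(tab, digits = 4))
  cat("RSS", format(x$rss, digits = 4), "on", x$n, "points\n")
  invisible(x)
}

#' Fit a pulsed-field-gradient diffusion decay
#'
#' Fits the BPP-LED attenuation
#' I(g) = I(0) exp(-D (gamma g delta)^2 (Delta - delta/3 - tau/2))
#' by nonlinear least squares, with the initial D taken from the
#' log-linear slope of I against the gradient factor.
#'
#' @param g Gradient strengths, strictly increasing.
#' @param intensity Signal intensities (> 0, arbitrary units).
#' @param delta Total bipolar gradient-pair duration delta (s); the
#'   instrument fixes each half, so delta = 2 x pulse duration.
#' @param Delta Diffusion delay (s).
#' @param tau Gradient stabilization delay (s).
#' @param gamma Gyromagnetic ratio (rad s^-1 T^-1), default 1H.
#' @param g_units `"G_per_cm"` (converted to T/m by x 0.01) or
#'   `"T_per_m"`.
#' @return A `fit_result` with estimates `I0` and `D` (m^2/s).
#' @export
fit_diffusion <- function(g, intensity, delta = 8.6e-3, Delta = 70e-3,
                          tau = 0.226e-3, gamma = .H1_GAMMA,
                          g_units = c("G_per_cm", "T_per_m")) {
  g_units <- match.arg(g_units)
  stopifnot(length(g) == length(intensity), length(g) >= 3L,
            all(diff(g) > 0), all(intensity > 0),
            delta > 0, Delta > 0, tau > 0)
  if (Delta <= delta / 3 + tau / 2)
    stop("invalid timing: Delta must exceed delta/3 + tau/2")
  if (g_units == "G_per_cm") g <- g * 0.01
  k <- (gamma * g * delta)^2 * (Delta - delta / 3 - tau / 2)
  if (min(intensity) / max(intensity) > 0.8)
    warning("decay spans less than 20% attenuation; D poorly determined")
  lin <- stats::lm(log(intensity) ~ k)
  start <- list(I0 = exp(stats::coef(lin)[[1]]),
                D = max(-stats::coef(lin)[[2]], 1e-14))
  fit <- minpack.lm::nlsLM(intensity ~ I0 * exp(-D * k), start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  D_hat <- stats::coef(fit)[["D"]]
  if (D_hat < 0 && abs(D_hat) * max(k) > 1e-6)
    stop("fitted diffusion coefficient is negative")
  res <- .fit_result(fit, length(g), "pfg_diffusion_decay")
  if (D_hat < 0) res$estimates[["D"]] <- 0  # flat decay: D is zero
  res
}

# 4PL on log10 concentration, Prism-style variable-slope form.
.fourpl <- function(logc, bottom, top, hill, logec50) {
  bottom + (top - bottom) / (1 + 10^((logec50 - logc) * hill))
}

.fourpl_start <- function(logc, response) {
  list(bottom = min(response), top = max(response), hill = 1,
       logec50 = stats::median(logc))
}

.fit_4pl_nls <- function(logc, response) {
  minpack.lm::nlsLM(response ~ .fourpl(logc, bottom, top, hill, logec50),
                    start = .fourpl_start(logc, response),
                    control = minpack.lm::nls.lm.control(maxiter = 500))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Fits response = bottom + (top - bottom) /
#' (1 + 10^((log10 EC50 - log10 c) * hill)) by nonlinear least squares
#' on log-concentration. The EC50 confidence interval is obtained by
#' likelihood profiling (falling back to a Wald interval if profiling
#' fails).
#'
#' @param conc Concentrations (> 0; e.g. micromolar).
#' @param response Measured response (e.g. percent activity).
#' @return A `fit_result` with estimates `ec50` (same units as `conc`),
#'   `hill`, `top`, `bottom`; `ec50_in_range` attribute flags whether
#'   the EC50 lies inside the tested concentration range.
#' @export
fit_ec50_4pl <- function(conc, response) {
  stopifnot(length(conc) == length(response), all(conc > 0))
  if (length(unique(conc)) < 5L)
    warning("fewer than 5 concentrations; EC50 poorly constrained")
  logc <- log10(conc)
  fit <- .fit_4pl_nls(logc, response)
  cf <- stats::coef(fit)
  ci_log <- tryCatch(
    suppressWarnings(suppressMessages(
      stats::confint(fit, parm = "logec50", level = 0.95))),
    error = function(e) NULL)
  n <- length(conc)
  if (is.null(ci_log) || anyNA(ci_log)) {
    se <- summary(fit)$coefficients["logec50", "Std. Error"]
    tq <- stats::qt(0.975, n - 4L)
    ci_log <- c(cf[["logec50"]] - tq * se, cf[["logec50"]] + tq * se)
  }
  est <- c(ec50 = 10^cf[["logec50"]], hill = cf[["hill"]],
           top = cf[["top"]], bottom = cf[["bottom"]])
  res <- .fit_result(fit, n, "dose_response_4pl")
  res$estimates <- est
  se <- summary(fit)$coefficients
  res$se <- c(ec50 = log(10) * est[["ec50"]] * se["logec50", "Std. Error"],
              hill = se["hill", "Std. Error"], top = se["top", "Std. Error"],
              bottom = se["bottom", "Std. Error"])
  tq <- stats::qt(0.975, n - 4L)
  res$ci95 <- rbind(
    ec50 = 10^as.numeric(ci_log),
    hill = cf[["hill"]] + c(-1, 1) * tq * se["hill", "Std. Error"],
    top = cf[["top"]] + c(-1, 1) * tq * se["top", "Std. Error"],
    bottom = cf[["bottom"]] + c(-1, 1) * tq * se["bottom", "Std. Error"])
  colnames(res$ci95) <- c("lower", "upper")
  attr(res, "ec50_in_range") <- est[["ec50"]] >= min(conc) &&
    est[["ec50"]] <= max(conc)
  res
}

#' Extra sum-of-squares F-test between shared and separate curve fits
#'
#' Compares the nested pair "one 4PL curve for all datasets" (shared)
#' against "an individual 4PL curve per dataset" (separate):
#' F = ((RSS_shared - RSS_separate)/(df_shared - df_separate)) /
#' (RSS_separate/df_separate), with the p-value from the F
#' distribution.
#'
#' @param conc_list List of concentration vectors, one per dataset.
#' @param response_list List of matching response vectors.
#' @param alpha Significance level used to name the preferred model.
#' @return List: `F`, `df1`, `df2`, `p_value`, `preferred`
#'   (`"separate"` or `"shared"`), `rss_shared`, `rss_separate`.
#' @export
compare_curves_ftest <- function(conc_list, response_list, alpha = 0.05) {
  stopifnot(is.list(conc_list), is.list(response_list),
            length(conc_list) == length(response_list),
            length(conc_list) >= 2L)
  logc_all <- log10(unlist(conc_list))
  y_all <- unlist(response_list)
  n <- length(y_all)
  shared <- .fit_4pl_nls(logc_all, y_all)
  rss_shared <- sum(stats::resid(shared)^2)
  rss_sep <- 0
  for (k in seq_along(conc_list)) {
    f <- .fit_4pl_nls(log10(conc_list[[k]]), response_list[[k]])
    rss_sep <- rss_sep + sum(stats::resid(f)^2)
  }
  p_shared <- 4L
  p_sep <- 4L * length(conc_list)
  df_shared <- n - p_shared
  df_sep <- n - p_sep
  if (df_sep <= 0) stop("not enough points for the separate-curves model")
  Fstat <- ((rss_shared - rss_sep) / (df_shared - df_sep)) / (rss_sep / df_sep)
  p <- stats::pf(Fstat, df_shared - df_sep, df_sep, lower.tail = FALSE)
  list(F = Fstat, df1 = df_shared - df_sep, df2 = df_sep, p_value = p,
       preferred = if (p <= alpha) "separate" else "shared",
       rss_shared = rss_shared, rss_separate = rss_sep)
}

#' Melting temperature from a thermal denaturation curve
#'
#' Savitzky-Golay smoothing/differentiation of the signal (ellipticity)
#' versus temperature, followed by local quadratic interpolation of the
#' derivative extremum. Requires a uniformly spaced, increasing
#' temperature grid.
#'
#' @param temperature Temperature grid (degrees C), uniform spacing.
#' @param signal Measured signal (e.g. ellipticity at 220 nm).
#' @param window Savitzky-Golay window length (odd number of points).
#' @param order Savitzky-Golay polynomial order.
#' @return List with `tm` (degrees C), `dsignal_dT` (smoothed
#'   derivative), `index` of the grid point nearest the transition.
#' @export
melt_tm <- function(temperature, signal, window = 11L, order = 3L) {
  stopifnot(length(temperature) == length(signal),
            length(temperature) > window, window %% 2L == 1L)
  h <- diff(temperature)
  if (any(h <= 0)) stop("temperature grid must be increasing")
  if (diff(range(h)) > 1e-6 * mean(h))
    stop("temperature grid must be uniformly spaced")
  h <- mean(h)
  d1 <- signal::sgolayfilt(signal, p = order, n = window, m = 1L, ts = h)
  half <- (window - 1L) / 2L
  interior <- seq(half + 1L, length(d1) - half)
  mag <- abs(d1)
  i <- interior[which.max(mag[interior])]
  if (i <= half + 1L || i >= length(d1) - half ||
      (mag[i] - stats::median(mag[interior])) < 10 * .Machine$double.eps)
    stop("no interior derivative extremum: no transition inside the scanned range")
  # quadratic vertex through the three points around the extremum
  y0 <- mag[i - 1L]; y1 <- mag[i]; y2 <- mag[i + 1L]
  denom <- y0 - 2 * y1 + y2
  off <- if (denom == 0) 0 else 0.5 * (y0 - y2) / denom
  list(tm = temperature[i] + off * h, dsignal_dT = d1, index = i)
}

#' Monomer-dimer equilibrium populations by mass action
#'
#' Solves 2M <-> M2 with dissociation constant `kd` = [M]^2 / [M2] at
#' total protomer concentration `total`: the monomer concentration is
#' the positive root of 2M^2 + Kd M - Kd T = 0.
#'
#' @param total Total protomer concentration(s).
#' @param kd Dimer dissociation constant (same units).
#' @return data.frame: total, monomer, dimer (in protomer units the
#'   dimer binds 2), fraction_dimer.
#' @export
dimer_monomer_fractions <- function(total, kd) {
  stopifnot(all(total > 0), kd >= 0)
  m <- if (kd == 0) rep(0, length(total))
       else (-kd + sqrt(kd^2 + 8 * kd * total)) / 4
  dimer <- (total - m) / 2
  data.frame(total = total, monomer = m, dimer = dimer,
             fraction_dimer = (total - m) / total)
}

#' Fit a dimer dissociation constant from an exchange titration
#'
#' Models the thermophoresis/fluorescence signal of a trace-labeled
#' protomer titrated with unlabeled protein as a linear interpolation
#' between free and dimer-bound plateaus, weighted by the fraction of
#' protomer in dimers under mass-action monomer-dimer equilibrium with
#' equal homo/heterodimer affinity.
#'
#' @param total_conc Total (titrant + labeled) protomer concentrations.
#' @param signal Normalized signal.
#' @return A `fit_result` with estimates `kd`, `s_free`, `s_bound`.
#' @export
fit_dimer_kd <- function(total_conc, signal) {
  stopifnot(length(total_conc) == length(signal))
  if (length(total_conc) < 8L) stop("need at least 8 titration points")
  ord <- order(total_conc)
  x <- total_conc[ord]; y <- signal[ord]
  frac <- function(T, kd) (T - (-kd + sqrt(kd^2 + 8 * kd * T)) / 4) / T
  # fit on log(Kd): keeps Kd positive and the gradient finite
  start <- list(lkd = log(stats::median(x)), s_free = y[1],
                s_bound = y[length(y)])
  fit <- minpack.lm::nlsLM(
    y ~ s_free + (s_bound - s_free) * frac(x, exp(lkd)), start = start,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  res <- .fit_result(fit, length(x), "dimer_exchange_kd")
  cf <- stats::coef(fit)
  kd <- exp(cf[["lkd"]])
  res$estimates <- c(kd = kd, s_free = cf[["s_free"]],
                     s_bound = cf[["s_bound"]])
  res$se <- c(kd = kd * res$se[["lkd"]], s_free = res$se[["s_free"]],
              s_bound = res$se[["s_bound"]])
  res$ci95 <- rbind(kd = exp(res$ci95["lkd", ]),
                    res$ci95[c("s_free", "s_bound"), , drop = FALSE])
  res
}
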