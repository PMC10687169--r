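#' ITC titration protocol
#'
#' Describes an isothermal titration calorimetry experiment: cell volume and
#' macromolecule concentration, syringe (ligand) concentration, and the
#' injection schedule. Defaults mirror a standard VP-ITC run: a 1400 uL cell,
#' 5 uL injections from a 300 uL syringe (so at most 60 injections).
#'
#' @param cell_conc macromolecule concentration in the cell (mol/L).
#' @param syringe_conc ligand concentration in the syringe (mol/L).
#' @param cell_volume cell volume in litres (default 1.4e-3).
#' @param injection_volume single injection volume in litres (default 5e-6).
#' @param syringe_volume total syringe volume in litres (default 3e-4).
#' @param n_injections number of injections; defaults to the maximum the
#'   syringe allows, \code{floor(syringe_volume / injection_volume)}.
#' @return list of class \code{itc_protocol}.
#' @export
itc_protocol <- function(cell_conc, syringe_conc, cell_volume = 1.4e-3,
                         injection_volume = 5e-6, syringe_volume = 3e-4,
                         n_injections = NULL) {
  if (any(c(cell_conc, syringe_conc, cell_volume, injection_volume) <= 0))
    stop("concentrations and volumes must be positive")
  if (is.null(n_injections))
    n_injections <- floor(syringe_volume / injection_volume + 1e-9)
  structure(list(cell_volume = cell_volume, cell_conc = cell_conc,
                 syringe_conc = syringe_conc,
                 injection_volumes = rep(injection_volume, n_injections)),
            class = "itc_protocol")
}

# Cell concentrations after cumulative injection, total-volume-constant
# displacement model (injected volume displaces an equal volume of cell
# contents; the overfill-cell convention used by Origin/MicroCal).
itc_concentrations <- function(protocol) {
  V0 <- protocol$cell_volume
  dvc <- cumsum(protocol$injection_volumes)
  list(Mt = protocol$cell_conc * (1 - dvc / (2 * V0)) / (1 + dvc / (2 * V0)),
       Xt = protocol$syringe_conc * (dvc / V0) / (1 + dvc / (2 * V0)),
       ratio = (protocol$syringe_conc * (dvc / V0)) /
         (protocol$cell_conc * (1 - dvc / (2 * V0))))
}

# Fraction of binding sites occupied, single-site mass action.
single_site_theta <- function(Xt, Mt, n, kd) {
  K <- 1 / kd
  b <- 1 + Xt / (n * Mt) + 1 / (n * K * Mt)
  (b - sqrt(pmax(b^2 - 4 * Xt / (n * Mt), 0))) / 2
}

#' Per-injection heats of a single-site ITC titration
#'
#' Computes the model heat (ucal) evolved by each injection for a single-site
#' binding isotherm with stoichiometry n, dissociation constant K_D and molar
#' enthalpy Delta-H, under the total-volume-constant displacement dilution
#' model. The heat of injection i is the change in cell heat content plus the
#' correction for displaced (partially saturated) cell liquid:
#' \code{dQ_i = Q_i - Q_{i-1} + (dV_i/V0) * (Q_i + Q_{i-1})/2}, with
#' \code{Q_i = n * theta_i * Mt_i * dH * V0}.
#'
#' @param n stoichiometry (sites per macromolecule), > 0.
#' @param kd dissociation constant (mol/L), > 0.
#' @param dh molar binding enthalpy (cal/mol).
#' @param protocol an \code{\link{itc_protocol}}.
#' @param baseline constant per-injection offset heat (ucal, default 0).
#' @return numeric vector of per-injection heats (ucal).
#' @export
itc_heats <- function(n, kd, dh, protocol, baseline = 0) {
  if (kd <= 0) stop("K_D must be positive")
  if (n <= 0) stop("stoichiometry n must be positive")
  conc <- itc_concentrations(protocol)
  theta <- single_site_theta(conc$Xt, conc$Mt, n, kd)
  Q <- n * theta * conc$Mt * dh * protocol$cell_volume  # cal
  Qprev <- c(0, Q[-length(Q)])
  dv <- protocol$injection_volumes
  dq <- Q - Qprev + (dv / protocol$cell_volume) * (Q + Qprev) / 2
  dq * 1e6 + baseline
}

#' Fit a single-site binding isotherm to ITC heats
#'
#' Levenberg-Marquardt nonlinear least squares of \code{\link{itc_heats}}
#' against observed per-injection heats, with multi-start over K_D decades
#' (1e-7 to 1e-2 M) and the lowest residual sum of squares kept. The first
#' injection is excluded by default (common ITC practice; its volume is still
#' used for dilution bookkeeping). Reports parameter estimates, standard
#' errors, a convergence flag, and the Wiseman c-value
#' (\code{n * cell_conc / K_D}); fits with c outside [0.1, 1000] carry a
#' low-confidence flag because K_D is poorly identifiable there.
#'
#' @param heats observed per-injection heats (ucal), aligned with
#'   \code{protocol$injection_volumes}.
#' @param protocol an \code{\link{itc_protocol}}.
#' @param init optional named list of starting values (n, kd, dh, baseline).
#' @param fix_n fix stoichiometry at \code{init$n} (default FALSE).
#' @param exclude_first drop injection 1 from the fitted residuals
#'   (default TRUE).
#' @return object of class \code{itc_fit}: estimates \code{n}, \code{kd},
#'   \code{dh}, \code{baseline}; \code{se} (named vector); \code{converged};
#'   \code{c_value}; \code{low_confidence}; \code{kd_identifiable};
#'   \code{rss}; \code{fitted} heats.
#' @export
fit_itc <- function(heats, protocol, init = NULL, fix_n = FALSE,
                    exclude_first = TRUE) {
  n_inj <- length(protocol$injection_volumes)
  if (length(heats) != n_inj)
    stop("length(heats) must match the injection schedule")
  if (n_inj < 8) stop("at least 8 injections are required for a fit")
  use <- if (exclude_first) 2:n_inj else 1:n_inj

  amp <- max(heats[use]) - min(heats[use])
  if (amp < .Machine$double.eps^0.5 * max(1, max(abs(heats)))) {
    # flat series: enthalpy ~ 0, K_D carries no information
    return(structure(list(n = init$n %||% 1, kd = NA_real_, dh = 0,
                          baseline = mean(heats[use]),
                          se = c(n = NA, kd = NA, dh = NA, baseline = NA),
                          converged = TRUE, c_value = NA,
                          low_confidence = TRUE, kd_identifiable = FALSE,
                          rss = sum((heats[use] - mean(heats[use]))^2),
                          fitted = rep(mean(heats[use]), n_inj)),
                     class = "itc_fit"))
  }

  dh0 <- init$dh %||% (sum(heats[use]) * 1e-6 /
                         (protocol$cell_conc * protocol$cell_volume))
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -1000
  n0 <- init$n %||% 1
  b0 <- init$baseline %||% 0
  kd_starts <- if (!is.null(init$kd)) init$kd else 10^seq(-7, -2, by = 1)

  resid_fun <- function(p) {
    n <- if (fix_n) n0 else exp(p[["logn"]])
    kd <- exp(p[["logkd"]])
    model <- itc_heats(n, kd, p[["dh"]], protocol, p[["baseline"]])
    model[use] - heats[use]
  }
  best <- NULL
  for (kd0 in kd_starts) {
    p0 <- c(logkd = log(kd0), dh = dh0, baseline = b0)
    if (!fix_n) p0 <- c(logn = log(n0), p0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best_rss) { best <- fit; best_rss <- rss }
  }
  if (is.null(best)) stop("ITC fit failed from every start")

  p <- best$par
  n_hat <- if (fix_n) n0 else exp(p[["logn"]])
  kd_hat <- exp(p[["logkd"]])
  dh_hat <- p[["dh"]]
  converged <- best$info %in% 1:3
  se <- c(n = NA_real_, kd = NA_real_, dh = NA_real_, baseline = NA_real_)
  sm <- tryCatch(summary(best), error = function(e) NULL)
  if (!is.null(sm)) {
    co <- sm$coefficients
    # delta-method back-transforms for the log-scale parameters
    if ("logkd" %in% rownames(co)) se["kd"] <- co["logkd", 2] * kd_hat
    if ("logn" %in% rownames(co)) se["n"] <- co["logn", 2] * n_hat
    if ("dh" %in% rownames(co)) se["dh"] <- co["dh", 2]
    if ("baseline" %in% rownames(co)) se["baseline"] <- co["baseline", 2]
  }
  c_value <- n_hat * protocol$cell_conc / kd_hat
  low_conf <- !is.finite(c_value) || c_value < 0.1 || c_value > 1000
  if (low_conf)
    warning(sprintf(
      "c-value %.3g outside [0.1, 1000]: K_D estimate is low-confidence",
      c_value), call. = FALSE)
  structure(list(n = n_hat, kd = kd_hat, dh = dh_hat,
                 baseline = p[["baseline"]], se = se, converged = converged,
                 c_value = c_value, low_confidence = low_conf,
                 kd_identifiable = TRUE, rss = best_rss,
                 fitted = itc_heats(n_hat, kd_hat, dh_hat, protocol,
                                    p[["baseline"]])),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf(
    "itc_fit: n = %.3f, K_D = %.3g M (%.1f uM), dH = %.0f cal/mol, c = %.3g%s\n",
    x$n, x$kd, x$kd * 1e6, x$dh, x$c_value,
    if (isTRUE(x$low_confidence)) " [low confidence]" else ""))
  invisible(x)
}

#' Gibbs energy from a dissociation constant
#'
#' \code{dG = R T ln(K_D)} with T defaulting to 298.15 K (25 C, the assay
#' temperature).
#'
#' @param kd dissociation constant (mol/L).
#' @param temperature Kelvin (default 298.15).
#' @return Gibbs energy of binding in cal/mol (negative for K_D < 1 M).
#' @export
binding_dg <- function(kd, temperature = 298.15) {
  1.98720425864083 * temperature * log(kd)
}

#' Boltzmann sigmoid melt model
#'
#' \code{S(T) = low + (high - low) / (1 + exp((Tm - T) / slope))}.
#'
#' @param temperature temperatures (deg C).
#' @param tm midpoint (deg C).
#' @param low,high pre- and post-transition plateaus (signal units).
#' @param slope transition width parameter (deg C), > 0.
#' @return model signal values.
#' @export
boltzmann_sigmoid <- function(temperature, tm, low, high, slope) {
  low + (high - low) / (1 + exp((tm - temperature) / slope))
}

# model-free Tm estimate: temperature of the steepest signal increase; the
# finite-difference derivative is smoothed (moving average, ~2 C window) so
# single-point noise spikes cannot win
tm_from_derivative <- function(temperature, signal) {
  d <- diff(signal) / diff(temperature)
  k <- min(9, length(d) - (1 - length(d) %% 2))
  if (k >= 3) {
    ds <- stats::filter(d, rep(1 / k, k))
    if (!all(is.na(ds))) d <- ifelse(is.na(ds), -Inf, ds)
  }
  mid <- (temperature[-1] + temperature[-length(temperature)]) / 2
  mid[which.max(d)]
}

#' Fit a thermal-shift melt curve
#'
#' Boltzmann sigmoid fit (Levenberg-Marquardt) of fluorescence signal versus
#' temperature; the derivative-maximum Tm estimator is reported alongside as
#' a model-free cross-check. Errors out when no melting transition lies
#' within the scanned temperature range.
#'
#' @param temperature temperatures (deg C), strictly increasing.
#' @param signal fluorescence signal (arbitrary units).
#' @return object of class \code{melt_fit}: \code{tm}, \code{low},
#'   \code{high}, \code{slope}, \code{se} (named, delta-method), \code{tm_derivative},
#'   \code{converged}, \code{fitted}.
#' @export
fit_melt <- function(temperature, signal) {
  if (length(temperature) != length(signal) || length(signal) < 10)
    stop("need matched temperature/signal vectors of length >= 10")
  if (any(diff(temperature) <= 0))
    stop("temperatures must be strictly increasing")
  if (diff(range(signal)) <= 0) stop("flat curve: no melt transition")
  tm0 <- tm_from_derivative(temperature, signal)
  low0 <- stats::quantile(signal, 0.02, names = FALSE)
  high0 <- stats::quantile(signal, 0.98, names = FALSE)
  try_fit <- function(tm_start)
    tryCatch(minpack.lm::nlsLM(
      signal ~ boltzmann_sigmoid(temperature, tm, low, high, slope),
      start = list(tm = tm_start, low = low0, high = high0, slope = 1.5),
      lower = c(tm = min(temperature), low = -Inf, high = -Inf,
                slope = 1e-3),
      upper = c(tm = max(temperature), low = Inf, high = Inf, slope = Inf),
      control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
      error = function(e) NULL)
  fit <- try_fit(tm0)
  if (is.null(fit)) fit <- try_fit(stats::median(temperature))
  if (is.null(fit)) stop("melt-curve fit failed to start")
  co <- summary(fit)$coefficients
  tm_hat <- co["tm", 1]
  amp <- abs(co["high", 1] - co["low", 1])
  resid_sd <- stats::sd(stats::residuals(fit))
  if (amp < 3 * resid_sd ||
      tm_hat <= min(temperature) + 1e-6 || tm_hat >= max(temperature) - 1e-6)
    stop("no resolvable melt transition within the temperature range")
  structure(list(tm = tm_hat, low = co["low", 1], high = co["high", 1],
                 slope = co["slope", 1],
                 se = stats::setNames(co[, 2], rownames(co)),
                 tm_derivative = tm0,
                 converged = fit$convInfo$isConv %||% TRUE,
                 fitted = stats::fitted(fit)),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("melt_fit: Tm = %.2f C (derivative estimate %.2f C)\n",
              x$tm, x$tm_derivative))
  invisible(x)
}

#' Melting-temperature shift between two fits
#'
#' \code{delta_tm(sample, reference) = Tm_sample - Tm_reference}; antisymmetric
#' in its arguments.
#'
#' @param fit,reference_fit \code{melt_fit} objects.
#' @return Tm shift in deg C.
#' @export
delta_tm <- function(fit, reference_fit) {
  stopifnot(inherits(fit, "melt_fit"), inherits(reference_fit, "melt_fit"))
  fit$tm - reference_fit$tm
}
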