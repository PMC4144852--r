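# Tracer-flux permeability: fluorescence calibration and P_app = (dQ/dt)/(A C0).

#' A tracer-flux time series
#'
#' @param times_h sampling times (h), strictly increasing, >= 0.
#' @param Q_nmol apical tracer amounts (nmol) at those times (after
#'   calibration).
#' @param area_cm2 membrane area (cm^2).
#' @param C0_mM basolateral (donor) tracer concentration (mM).
#' @return list of class `flux_series`.
#' @export
flux_series <- function(times_h, Q_nmol, area_cm2 = 1.12, C0_mM = 0.2) {
  stopifnot(length(times_h) == length(Q_nmol), length(times_h) >= 1L,
            all(times_h >= 0), !is.unsorted(times_h, strictly = TRUE),
            area_cm2 > 0, C0_mM > 0)
  structure(list(times_h = times_h, Q_nmol = Q_nmol, area_cm2 = area_cm2,
                 C0_mM = C0_mM),
            class = "flux_series")
}

#' Fit a linear fluorescence standard curve
#'
#' Ordinary least squares of fluorescence on known amount.
#' @param standards data.frame with columns `amount_nmol`, `fluorescence`.
#' @return object of class `calibration_curve`: `slope`, `intercept`, `r2`.
#' @export
fit_standard_curve <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("amount_nmol", "fluorescence") %in% names(standards)))
  x <- standards$amount_nmol
  y <- standards$fluorescence
  if (length(unique(x)) < 2L)
    stop("degenerate standards: need at least 2 distinct amounts")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) stop("non-positive calibration slope (", signif(slope, 4),
                       "): invalid standard curve")
  r2 <- if (stats::var(y) > 0)
    suppressWarnings(summary(fit)$r.squared) else 1
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r2 = r2),
            class = "calibration_curve")
}

#' Convert fluorescence to amount through a standard curve
#' @param curve a [fit_standard_curve()] result.
#' @param fluorescence numeric vector.
#' @return amounts in the standards' units (nmol).
#' @export
apply_calibration <- function(curve, fluorescence) {
  (fluorescence - curve$intercept) / curve$slope
}

#' Apparent permeability from a flux series
#'
#' `dQ/dt` is the least-squares slope of Q versus time (a single point is
#' fit through the origin); `P_app = (dQ/dt) / (A C0)` in cm/s, with the
#' slope converted from nmol/h to mol/s and C0 from mM to mol/cm^3.
#'
#' @param series a [flux_series()].
#' @return list with `P_app_cm_s`, `se_P_app_cm_s` (NA when not estimable),
#'   `slope_nmol_h`, `n`.  A negative fitted slope is returned signed, with
#'   a warning.
#' @examples
#' s <- flux_series(1:4, 2 * (1:4), area_cm2 = 1, C0_mM = 0.2)
#' dextran_papp(s)$P_app_cm_s  # (2e-9/3600)/2e-7
#' @export
dextran_papp <- function(series) {
  stopifnot(inherits(series, "flux_series"))
  t <- series$times_h
  q <- series$Q_nmol
  if (length(t) == 1L) {
    slope <- q / t
    se_slope <- NA_real_
  } else {
    fit <- stats::lm(q ~ t)
    slope <- unname(stats::coef(fit)[2])
    se_slope <- tryCatch(
      suppressWarnings(summary(fit)$coefficients["t", "Std. Error"]),
      error = function(e) NA_real_)
  }
  if (!is.na(slope) && slope < 0)
    warning("negative fitted flux slope (", signif(slope, 4),
            " nmol/h); returning the signed estimate")
  denom <- series$area_cm2 * series$C0_mM * 1e-6   # cm^2 * mol/cm^3
  conv <- 1e-9 / 3600                               # nmol/h -> mol/s
  list(P_app_cm_s = slope * conv / denom,
       se_P_app_cm_s = se_slope * conv / denom,
       slope_nmol_h = slope, n = length(t))
}

#' Specification of a simulated tracer-flux experiment
#'
#' Under the sink assumption (apical tracer << C0) the true transferred
#' amount is linear, `Q(t) = P_app A C0 t`; fluorescence is the linear
#' calibration of Q plus Gaussian noise.  Defaults emulate 0.2 mM
#' FITC-dextran in the basolateral bath with kinetic plate reads every
#' 10 min for 5 h.
#'
#' @param true_P_app ground-truth apparent permeability (cm/s).
#' @param area_cm2 membrane area.
#' @param C0_mM donor concentration (mM).
#' @param sample_times_h strictly increasing sampling times (h).
#' @param calib_slope,calib_intercept fluorescence per nmol, and offset.
#' @param fluorescence_noise_sd additive noise SD on fluorescence (AU).
#' @param n_standards number of (noiseless) calibration standards.
#' @param seed RNG seed.
#' @return validated list of class `flux_spec`.
#' @export
flux_spec <- function(true_P_app = 1e-6, area_cm2 = 1.12, C0_mM = 0.2,
                      sample_times_h = seq(1 / 6, 5, by = 1 / 6),
                      calib_slope = 500, calib_intercept = 5,
                      fluorescence_noise_sd = 2, n_standards = 6L,
                      seed = 1L) {
  stopifnot(true_P_app >= 0, area_cm2 > 0, C0_mM > 0,
            length(sample_times_h) >= 1L, all(sample_times_h >= 0),
            !is.unsorted(sample_times_h, strictly = TRUE),
            calib_slope > 0, fluorescence_noise_sd >= 0, n_standards >= 2L)
  structure(list(true_P_app = true_P_app, area_cm2 = area_cm2, C0_mM = C0_mM,
                 sample_times_h = sample_times_h, calib_slope = calib_slope,
                 calib_intercept = calib_intercept,
                 fluorescence_noise_sd = fluorescence_noise_sd,
                 n_standards = as.integer(n_standards),
                 seed = as.integer(seed)),
            class = "flux_spec")
}

#' Simulate a tracer-flux dataset with calibration standards
#'
#' @param spec a [flux_spec()].
#' @return list with `series` (times and raw `fluorescence`, plus assay
#'   geometry), `standards` (noiseless calibration points spanning the
#'   series range) and `truth` (the true amounts, nmol).
#' @export
generate_flux_dataset <- function(spec) {
  stopifnot(inherits(spec, "flux_spec"))
  q_true <- spec$true_P_app * spec$area_cm2 * (spec$C0_mM * 1e-6) *
    (spec$sample_times_h * 3600) * 1e9      # mol -> nmol
  top <- max(q_true, 1e-3) * 1.2
  standards <- data.frame(
    amount_nmol = seq(0, top, length.out = spec$n_standards))
  standards$fluorescence <- spec$calib_slope * standards$amount_nmol +
    spec$calib_intercept
  fl <- with_seed(spec$seed,
    spec$calib_slope * q_true + spec$calib_intercept +
      stats::rnorm(length(q_true), sd = spec$fluorescence_noise_sd))
  list(series = list(times_h = spec$sample_times_h, fluorescence = fl,
                     area_cm2 = spec$area_cm2, C0_mM = spec$C0_mM),
       standards = standards, truth = q_true)
}

#' Recover apparent permeability from a raw flux dataset
#'
#' Fits the standard curve, converts fluorescence to amounts and fits
#' `(dQ/dt)/(A C0)`: the complete analysis path for one insert.
#'
#' @param dataset a [generate_flux_dataset()] result, or any list with
#'   `series` and `standards` shaped the same way.
#' @return the [dextran_papp()] result, plus `calibration`.
#' @export
analyze_flux <- function(dataset) {
  curve <- fit_standard_curve(dataset$standards)
  q <- apply_calibration(curve, dataset$series$fluorescence)
  res <- dextran_papp(flux_series(dataset$series$times_h, q,
                                  dataset$series$area_cm2,
                                  dataset$series$C0_mM))
  res$calibration <- curve
  res
}
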