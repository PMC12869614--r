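#' Acquisition parameters for a dynamic SPGR series
#'
#' @param tr repetition time (s).
#' @param flip_angle flip angle in degrees, in (0, 90).
#' @param frame_interval time between dynamic volumes (s).
#' @param bolus_time time of contrast injection on the acquisition clock (s),
#'   i.e. seconds after the start of the first frame.
#' @param n_baseline number of pre-contrast frames averaged for the baseline
#'   signal S(0); `NULL` (default) means all frames acquired strictly before
#'   `bolus_time`.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(tr, flip_angle, frame_interval,
                               bolus_time = 0, n_baseline = NULL) {
  stopifnot(tr > 0, flip_angle > 0, flip_angle < 90, frame_interval > 0,
            bolus_time >= 0)
  if (!is.null(n_baseline) && n_baseline < 1)
    stop("'n_baseline' must be at least 1")
  structure(list(tr = tr, flip_angle = flip_angle,
                 frame_interval = frame_interval, bolus_time = bolus_time,
                 n_baseline = n_baseline),
            class = "acquisition_params")
}

# SPGR steady-state signal for longitudinal rate r1_t (s^-1), up to the
# proton-density/gain factor m0. theta in radians.
spgr_signal <- function(r1_t, tr, theta, m0 = 1) {
  e <- exp(-r1_t * tr)
  m0 * sin(theta) * (1 - e) / (1 - cos(theta) * e)
}

#' Convert SPGR signal to longitudinal relaxation rate
#'
#' Inverts the spoiled gradient-echo steady-state signal equation sample by
#' sample, using the ratio of the dynamic signal to the mean pre-contrast
#' baseline and a fixed pre-contrast T1. For each sample,
#' \deqn{a = \frac{S(t)}{S(0)} \cdot
#'   \frac{1 - e^{-R_1(0) TR}}{1 - \cos\theta \, e^{-R_1(0) TR}}, \qquad
#'   R_1(t) = -\frac{1}{TR}\ln\frac{1 - a}{1 - a\cos\theta}}
#' with \eqn{R_1(0) = 1000 / T_1(0)} for `t1_0` in ms. Samples where the
#' inversion is undefined (`a >= 1` or a non-positive log argument, possible
#' under noise near the bolus peak) are marked invalid rather than clamped, so
#' downstream steps can exclude them without biasing the peak.
#'
#' @param series a [signal_series()].
#' @param acq an [acquisition_params()].
#' @param t1_0 pre-contrast T1 of the tissue (ms).
#' @return A list with the fields of a series: `times`, `values` (R1 in
#'   s^-1), `valid`, plus `r1_0` (the pre-contrast rate, s^-1).
#' @export
signal_to_relaxation <- function(series, acq, t1_0) {
  stopifnot(inherits(series, "signal_series"), inherits(acq, "acquisition_params"))
  if (t1_0 <= 0) stop("'t1_0' must be positive (ms)")
  if (series$s0 <= 0) stop("baseline signal s0 must be positive")
  r1_0 <- 1000 / t1_0
  theta <- acq$flip_angle * pi / 180
  e0 <- exp(-r1_0 * acq$tr)
  a <- (series$values / series$s0) * (1 - e0) / (1 - cos(theta) * e0)
  num <- 1 - a
  den <- 1 - cos(theta) * a
  ok <- series$valid & is.finite(a) & a < 1 & num > 0 & den > 0
  r1 <- rep(NA_real_, length(a))
  r1[ok] <- -log(num[ok] / den[ok]) / acq$tr
  if (!any(ok))
    stop("signal-to-relaxation inversion failed at every sample of the series")
  list(times = series$times, values = r1, valid = ok, r1_0 = r1_0)
}

#' Relaxation-rate change to gadolinium concentration
#'
#' Applies the linear relaxivity model C(t) = (R1(t) - R1(0)) / r1 to a
#' relaxation-rate series, producing a tissue or blood concentration curve.
#' Negative values arising from noise are retained (not floored) so that
#' fitting objectives see unbiased residuals.
#'
#' @param r1_series output of [signal_to_relaxation()].
#' @param r1_0 pre-contrast relaxation rate (s^-1); defaults to the one
#'   stored in `r1_series`.
#' @param relaxivity in situ relaxivity r1 of the agent in this tissue
#'   (s^-1 mM^-1).
#' @param compartment compartment label for the result (`"Ct"`, `"Ca"`, `"Cv"`).
#' @return A [conc_series()]. Invalid input samples propagate as invalid.
#' @export
relaxation_to_concentration <- function(r1_series, relaxivity,
                                        compartment = "Ct",
                                        r1_0 = r1_series$r1_0) {
  if (relaxivity <= 0) stop("'relaxivity' must be positive")
  vals <- (r1_series$values - r1_0) / relaxivity
  vals[!r1_series$valid] <- NA_real_
  conc_series(r1_series$times, vals, compartment, valid = r1_series$valid)
}

#' Spleen relaxation change to EES concentration
#'
#' The reference-region model uses the spleen as a surrogate for the liver's
#' extravascular extracellular space (EES): Ce(t) =
#' (R1(t) - R1(0)) / (r1_spleen * ve_spleen).
#'
#' @param r1_series spleen output of [signal_to_relaxation()].
#' @param relaxivity spleen relaxivity (s^-1 mM^-1).
#' @param ve_spleen spleen EES volume fraction, in (0, 1); default 0.43.
#' @param r1_0 pre-contrast rate (s^-1).
#' @return A [conc_series()] labelled `"Ce"`.
#' @export
spleen_to_ees_concentration <- function(r1_series, relaxivity,
                                        ve_spleen = 0.43,
                                        r1_0 = r1_series$r1_0) {
  if (ve_spleen <= 0 || ve_spleen >= 1)
    stop("'ve_spleen' must be in (0, 1)")
  out <- relaxation_to_concentration(r1_series, relaxivity * ve_spleen,
                                     compartment = "Ct", r1_0 = r1_0)
  out$compartment <- "Ce"
  out
}

#' Intracellular liver concentration from tissue and EES curves
#'
#' Removes the extracellular contribution from the liver tissue
#' concentration: Ci(t) = (Ct(t) - ve * Ce(t)) / (1 - ve). Noisy samples may
#' go negative; they are kept as-is.
#'
#' @param ct liver tissue concentration (`conc_series`, compartment `"Ct"`).
#' @param ce EES concentration (`conc_series`, compartment `"Ce"`).
#' @param ve_liver liver EES volume fraction, in (0, 1); default 0.23.
#' @return A [conc_series()] labelled `"Ci"`; a sample is valid only when
#'   both inputs are valid there.
#' @export
liver_intracellular_concentration <- function(ct, ce, ve_liver = 0.23) {
  stopifnot(inherits(ct, "conc_series"), inherits(ce, "conc_series"))
  if (ve_liver <= 0 || ve_liver >= 1) stop("'ve_liver' must be in (0, 1)")
  stop_if_grid_mismatch(ct, ce, "Ct and Ce")
  valid <- ct$valid & ce$valid
  vals <- (ct$values - ve_liver * ce$values) / (1 - ve_liver)
  vals[!valid] <- NA_real_
  conc_series(ct$times, vals, "Ci", valid = valid)
}

#' Render a concentration curve as SPGR signal
#'
#' Exact inverse of the signal-to-concentration chain, used by the synthetic
#' study generator: R1(t) = R1(0) + r1 * C(t), then the SPGR steady-state
#' equation scaled so that C = 0 maps to the baseline signal `s0`.
#'
#' @param c a [conc_series()].
#' @param acq an [acquisition_params()].
#' @param t1_0 pre-contrast T1 (ms).
#' @param relaxivity agent relaxivity in this tissue (s^-1 mM^-1).
#' @param s0 baseline signal level the rendered series should have at C = 0.
#' @return A [signal_series()].
#' @export
concentration_to_signal <- function(c, acq, t1_0, relaxivity, s0) {
  stopifnot(inherits(c, "conc_series"), inherits(acq, "acquisition_params"))
  if (s0 <= 0) stop("'s0' must be positive")
  r1_0 <- 1000 / t1_0
  theta <- acq$flip_angle * pi / 180
  r1_t <- r1_0 + relaxivity * c$values
  if (any(r1_t[c$valid] <= 0))
    stop("concentration implies non-physical relaxation rate R1 <= 0")
  m0 <- s0 / spgr_signal(r1_0, acq$tr, theta)
  vals <- spgr_signal(r1_t, acq$tr, theta, m0)
  vals[!c$valid] <- NA_real_
  signal_series(c$times, vals, s0 = s0, valid = c$valid)
}

#' Baseline signal from pre-contrast frames
#'
#' Mean of the pre-bolus frames of a raw signal vector. With
#' `n_baseline = NULL`, every frame acquired strictly before the bolus is
#' used.
#'
#' @param values raw signal values.
#' @param times sample times relative to bolus (s); baseline frames have
#'   negative times.
#' @param n_baseline number of leading frames to average, or `NULL`.
#' @return The scalar baseline S(0).
#' @export
baseline_signal <- function(values, times, n_baseline = NULL) {
  idx <- if (is.null(n_baseline)) which(times < 0) else seq_len(n_baseline)
  if (length(idx) < 1L)
    stop("no pre-contrast frames available to estimate the baseline")
  mean(values[idx])
}
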