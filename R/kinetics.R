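#' Kinetic parameter containers
#'
#' `tristan_params()` holds the single-input reference-region model's
#' hepatocyte influx rate `k1` and efflux rate `k2` (both s^-1, each
#' constrained to [2^-52, 1]) and the hepatocyte volume fraction
#' `vh = 1 - ve_liver`. `berks_params()` holds the dual-input biexponential
#' model's impulse-response amplitudes `alpha_plus`, `alpha_minus` (s^-1),
#' decay rates `beta_plus`, `beta_minus` (s^-1), and arterial flow fraction
#' `fa` (dimensionless), each constrained to [2^-52, 1].
#'
#' @param k1,k2 influx and efflux rates (s^-1).
#' @param vh hepatocyte volume fraction, in (0, 1); default 1 - 0.23.
#' @return A named numeric vector of class `tristan_params` or
#'   `berks_params` (with `vh` kept as an attribute for the former).
#' @export
tristan_params <- function(k1, k2, vh = 1 - 0.23) {
  eps <- 2^-52
  k1 <- unname(k1); k2 <- unname(k2)
  stopifnot(k1 >= eps, k1 <= 1, k2 >= eps, k2 <= 1, vh > 0, vh < 1)
  structure(c(k1 = k1, k2 = k2), vh = vh, class = "tristan_params")
}

#' @rdname tristan_params
#' @param alpha_plus,alpha_minus impulse-response amplitudes (s^-1).
#' @param beta_plus,beta_minus impulse-response decay rates (s^-1).
#' @param fa arterial flow fraction (fraction of hepatic blood supply from
#'   the hepatic artery; the rest arrives via the portal vein).
#' @export
berks_params <- function(alpha_plus, beta_plus, alpha_minus, beta_minus, fa) {
  eps <- 2^-52
  p <- c(alpha_plus = unname(alpha_plus), beta_plus = unname(beta_plus),
         alpha_minus = unname(alpha_minus), beta_minus = unname(beta_minus),
         fa = unname(fa))
  stopifnot(all(p >= eps), all(p <= 1))
  structure(p, class = "berks_params")
}

# one-pole recursion s[n] = e * s[n-1] + x[n]  (s[1] = x[1])
onepole <- function(x, e) as.numeric(stats::filter(x, e, method = "recursive"))

# dt * sum_{m<=n} A * exp(-lambda * (n-m) * dt) * x[m], computed exactly by
# the one-pole recursion
exp_convolve <- function(x, amplitude, lambda, dt) {
  dt * amplitude * onepole(x, exp(-lambda * dt))
}

get_uniform_values <- function(series, what) {
  if (!all(is.finite(series$values[series$valid])))
    stop(sprintf("non-finite values in %s input", what))
  v <- series$values
  if (any(!series$valid)) {
    ok <- which(series$valid)
    if (length(ok) < 2L) stop(sprintf("%s input has fewer than 2 valid samples", what))
    v <- stats::approx(series$times[ok], v[ok], xout = series$times,
                       rule = 2)$y
  }
  v
}

#' Single-input reference-region (TRISTAN) forward model
#'
#' Predicts the intracellular liver concentration from the EES concentration
#' (spleen surrogate) by the discrete causal convolution
#' \deqn{C_i[n] = \Delta t \sum_{m=0}^{n} e^{-k_2 (t_n - t_m)/v_h}
#'   \frac{k_1}{v_h} C_e[m],}
#' the closed-form solution of \eqn{v_h \, dC_i/dt = k_1 C_e - k_2 C_i} on a
#' uniform grid. The whole grid (including pre-bolus samples, where the input
#' is ~0) participates, so the output stays ~0 before the bolus. Invalid
#' input samples are filled by linear interpolation between valid neighbours
#' before the convolution.
#'
#' @param params a [tristan_params()].
#' @param ce EES concentration [conc_series()] on a uniform grid.
#' @param dt grid spacing (s); inferred from `ce` when omitted.
#' @return A [conc_series()] labelled `"Ci"`, same grid as `ce`.
#' @export
tristan_forward <- function(params, ce, dt = frame_interval(ce)) {
  stopifnot(inherits(params, "tristan_params"), inherits(ce, "conc_series"))
  vh <- attr(params, "vh")
  x <- get_uniform_values(ce, "Ce")
  ci <- exp_convolve(x, params[["k1"]] / vh, params[["k2"]] / vh, dt)
  conc_series(ce$times, ci, "Ci")
}

#' Dual-input plasma concentration
#'
#' Flow-weighted mixture of arterial and portal-venous whole-blood
#' concentrations, converted to plasma by the hematocrit correction:
#' Cp = (fa * Ca + (1 - fa) * Cv) / (1 - Hct).
#'
#' @param ca,cv arterial and venous blood concentration [conc_series()] on a
#'   shared grid.
#' @param fa arterial flow fraction in [0, 1].
#' @param hct hematocrit, in (0, 1).
#' @return A [conc_series()] labelled `"Cp"`.
#' @export
plasma_input <- function(ca, cv, fa, hct) {
  stopifnot(inherits(ca, "conc_series"), inherits(cv, "conc_series"),
            fa >= 0, fa <= 1)
  if (hct < 0 || hct >= 1) stop("'hct' must be in [0, 1)")
  stop_if_grid_mismatch(ca, cv, "Ca and Cv")
  valid <- ca$valid & cv$valid
  vals <- (fa * ca$values + (1 - fa) * cv$values) / (1 - hct)
  vals[!valid] <- NA_real_
  conc_series(ca$times, vals, "Cp", valid = valid)
}

#' Dual-input biexponential (Berks) forward model
#'
#' Predicts the liver tissue concentration as the plasma input convolved
#' with a biexponential impulse response:
#' \deqn{C_t[n] = \Delta t \sum_{m=0}^{n}
#'   \left[\alpha^+ e^{-\beta^+ (t_n - t_m)} +
#'         \alpha^- e^{-\beta^- (t_n - t_m)}\right] C_p[m].}
#'
#' @param params a [berks_params()].
#' @param ca,cv arterial and venous blood concentrations on a shared uniform
#'   grid.
#' @param hct hematocrit, in (0, 1).
#' @param dt grid spacing (s); inferred when omitted.
#' @return A [conc_series()] labelled `"Ct"`.
#' @export
berks_forward <- function(params, ca, cv, hct, dt = frame_interval(ca)) {
  stopifnot(inherits(params, "berks_params"))
  cp <- plasma_input(ca, cv, params[["fa"]], hct)
  x <- get_uniform_values(cp, "Cp")
  ct <- exp_convolve(x, params[["alpha_plus"]], params[["beta_plus"]], dt) +
        exp_convolve(x, params[["alpha_minus"]], params[["beta_minus"]], dt)
  conc_series(ca$times, ct, "Ct")
}

#' Rate unit conversion for reporting
#'
#' Rates are fitted in s^-1 (matching the acquisition clock) and reported in
#' min^-1 (the field's convention): `to_per_minute(x)` is `60 * x`.
#'
#' @param rate rate(s) in s^-1 (`to_per_minute`) or min^-1 (`to_per_second`).
#' @return The converted rate(s).
#' @export
to_per_minute <- function(rate) {
  stopifnot(all(rate >= 0))
  rate * 60
}

#' @rdname to_per_minute
#' @export
to_per_second <- function(rate) {
  stopifnot(all(rate >= 0))
  rate / 60
}
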