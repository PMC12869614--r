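#' Synthetic study scenarios
#'
#' A scenario bundles everything needed to generate a complete synthetic
#' DCE-MRI liver study with known ground truth: species/agent (resolving the
#' constants registry), acquisition timing, kinetic ground-truth parameters
#' (reporting units, min^-1, converted internally), bolus shape, dispersion
#' time constants, hematocrit, and noise level. `synth_scenario(name)` loads
#' one of the packaged scenarios (`dog_eob`, `dog_gadovist`, `pig_eob`,
#' `pig_eob_nospleen`, `pig_bopta`); parameters can be overridden via `...`.
#'
#' @param name packaged scenario name, or `NULL` to build one from `...`
#'   alone.
#' @param ... overrides of scenario fields (e.g. `noise_sigma = 0`,
#'   `duration = 1800`, `seed = 7`).
#' @return An object of class `pk_scenario`.
#' @examples
#' synth_scenario("dog_eob", noise_sigma = 0)
#' @export
synth_scenario <- function(name = NULL, ...) {
  defaults <- list(name = name %||% "custom", species = "dog",
                   agent = "Gd-EOB-DTPA", frame_interval = 7.65,
                   duration = 3600, n_baseline = 8,
                   tristan = list(k1_per_min = 1.0, k2_per_min = 0.027),
                   berks = NULL,
                   aif = list(peak_amplitude = 2.5, t_peak = 45, shape = 3,
                              tail_amps = c(0.40, 0.12),
                              tail_taus = c(120, 2000), ramp_tau = 30),
                   fa = 0.25, hct = 0.40, portal_dispersion_tau = 20,
                   spleen_tau = 30, noise_sigma = 0.005,
                   s0 = c(liver = 100, spleen = 100, aorta = 100,
                          portal_vein = 100),
                   acq = list(tr = 0.005, flip_angle = 12),
                   spleen_in_fov = TRUE, seed = 1L)
  sc <- defaults
  if (!is.null(name)) {
    path <- system.file("extdata", "scenarios.yaml", package = "liverpk",
                        mustWork = TRUE)
    all <- yaml::read_yaml(path)
    if (!name %in% names(all))
      stop(sprintf("unknown scenario '%s'; packaged scenarios: %s", name,
                   paste(names(all), collapse = ", ")))
    sc[names(all[[name]])] <- all[[name]]
    sc$name <- name
  }
  dots <- list(...)
  sc[names(dots)] <- dots
  stopifnot(sc$duration >= 1800, sc$frame_interval >= 1,
            sc$frame_interval <= 30, sc$noise_sigma >= 0, sc$n_baseline >= 1)
  if (!is.null(sc$tristan) && !is_hepatospecific(sc$agent) &&
      sc$tristan$k1_per_min > 0.001)
    stop(sprintf(
      "inconsistent scenario: agent '%s' is not hepatospecific but ground-truth k1 = %g min^-1",
      sc$agent, sc$tristan$k1_per_min))
  class(sc) <- "pk_scenario"
  sc
}

#' @export
print.pk_scenario <- function(x, ...) {
  cat(sprintf("<pk_scenario:%s> %s / %s, dt = %g s, %g s, noise = %g%%, seed = %s\n",
              x$name, x$species, x$agent, x$frame_interval, x$duration,
              100 * x$noise_sigma, x$seed))
  invisible(x)
}

#' Synthetic arterial input function
#'
#' A smooth parametric stand-in for the measured aortic blood concentration:
#' a gamma-variate first-pass bolus peaking 30-90 s after injection plus a
#' slower biexponential recirculation/washout tail (ramped smoothly from
#' zero at the bolus). Identically zero before the bolus, nonnegative
#' everywhere, and exactly linear in the peak amplitude.
#'
#' @param times uniform time grid (s), t = 0 at bolus.
#' @param aif_params list with `peak_amplitude` (mM), `t_peak` (s), `shape`
#'   (gamma-variate shape), `tail_amps` (mM), `tail_taus` (s), `ramp_tau`
#'   (s).
#' @return A [conc_series()] labelled `"Ca"`.
#' @export
make_aif <- function(times,
                     aif_params = synth_scenario(NULL)$aif) {
  p <- aif_params
  t <- pmax(times, 0)
  gamma_var <- p$peak_amplitude * (t / p$t_peak)^p$shape *
    exp(p$shape * (1 - t / p$t_peak))
  tail <- (1 - exp(-t / p$ramp_tau)) *
    rowSums(sapply(seq_along(p$tail_amps),
                   function(i) p$tail_amps[i] * exp(-t / p$tail_taus[i])))
  vals <- ifelse(times < 0, 0, gamma_var + tail)
  if (any(vals < 0))
    stop("AIF parameters produce negative concentrations")
  conc_series(times, vals, "Ca")
}

# x convolved with the exponential kernel (1/tau) exp(-t/tau), with the
# discrete kernel normalized to exactly unit mass so the operation is
# mass-preserving on any grid and reduces to the identity as tau -> 0
disperse <- function(x, tau, dt) {
  e <- exp(-dt / tau)
  (1 - e) * onepole(x, e)
}

#' Dispersed portal-venous curve
#'
#' Models the portal vein as the arterial bolus dispersed through the
#' splanchnic bed: convolution with the normalized single-exponential kernel
#' (1/tau) exp(-t/tau). Mass-preserving in the long-duration limit, with a
#' delayed, lowered peak.
#'
#' @param ca arterial [conc_series()].
#' @param tau dispersion time constant (s), > 0.
#' @param dt grid spacing (s).
#' @return A [conc_series()] labelled `"Cv"`.
#' @export
make_portal <- function(ca, tau, dt = frame_interval(ca)) {
  stopifnot(tau > 0)
  conc_series(ca$times, disperse(ca$values, tau, dt), "Cv")
}

#' Synthetic spleen EES surrogate curve
#'
#' Models the spleen extracellular concentration as the plasma curve
#' equilibrating through a normalized exponential kernel with a fast time
#' constant (default 30 s).
#'
#' @param cp_like plasma-scaled input [conc_series()].
#' @param tau equilibration time constant (s), > 0.
#' @param dt grid spacing (s).
#' @return A [conc_series()] labelled `"Ce"`.
#' @export
make_spleen_ees <- function(cp_like, tau = 30, dt = frame_interval(cp_like)) {
  stopifnot(tau > 0)
  conc_series(cp_like$times, disperse(cp_like$values, tau, dt), "Ce")
}

#' Generate a complete synthetic study
#'
#' Builds ground-truth concentration curves for all compartments — arterial
#' (gamma-variate bolus + washout tail), portal-venous (dispersed), plasma
#' (flow-weighted, hematocrit-corrected), spleen EES surrogate
#' (equilibrated), and liver (intracellular curve from the reference-region
#' forward model for hepatospecific scenarios, or tissue curve from the
#' dual-input forward model when the scenario supplies biexponential ground
#' truth) — then renders each compartment to SPGR signal intensities with
#' the registry constants and adds zero-mean Gaussian noise of SD
#' `noise_sigma * s0` under the scenario seed. The generating parameters are
#' retained so that parameter-recovery experiments can compare against
#' truth.
#'
#' @param scenario a [synth_scenario()].
#' @param seed RNG seed for the rendering noise; defaults to the scenario's.
#' @return An object of class `synth_study`: `times`, ground-truth
#'   concentration curves (`ca`, `cv`, `cp`, `ce`, `ci`, `ct`), rendered
#'   `signals` (list of [signal_series()] per ROI), `truth` (parameter
#'   objects), and the scenario.
#' @export
make_study <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "pk_scenario"))
  sc <- scenario
  dt <- sc$frame_interval
  n_post <- ceiling(sc$duration / dt)
  times <- (seq_len(sc$n_baseline + n_post + 1L) - sc$n_baseline - 1L) * dt

  ca <- make_aif(times, sc$aif)
  cv <- make_portal(ca, sc$portal_dispersion_tau, dt)
  cp <- plasma_input(ca, cv, sc$fa, sc$hct)
  ce <- make_spleen_ees(cp, sc$spleen_tau, dt)

  const <- function(tissue) gd_constants(sc$species, sc$agent, tissue)
  ve_liver <- const("liver")$ve
  truth <- list()
  if (!is.null(sc$berks)) {
    b <- sc$berks
    truth$berks <- berks_params(b$alpha_plus, b$beta_plus, b$alpha_minus,
                                b$beta_minus, b$fa)
    ct <- berks_forward(truth$berks, ca, cv, sc$hct, dt)
    ci <- liver_intracellular_concentration(ct, ce, ve_liver)
  } else if (!is.null(sc$tristan)) {
    truth$tristan <- tristan_params(to_per_second(sc$tristan$k1_per_min),
                                    to_per_second(sc$tristan$k2_per_min),
                                    vh = 1 - ve_liver)
    ci <- tristan_forward(truth$tristan, ce, dt)
    ct <- conc_series(times, ve_liver * ce$values + (1 - ve_liver) * ci$values,
                      "Ct")
  } else stop("scenario must define tristan and/or berks ground truth")

  acq <- acquisition_params(sc$acq$tr, sc$acq$flip_angle, dt,
                            bolus_time = sc$n_baseline * dt)
  ve_spleen <- const("spleen")$ve
  render <- list(
    liver = list(c = ct, t1 = const("liver")$t1_0_ms, r1 = const("liver")$r1),
    spleen = list(c = ce, t1 = const("spleen")$t1_0_ms,
                  r1 = const("spleen")$r1 * ve_spleen),
    aorta = list(c = ca, t1 = const("blood")$t1_0_ms, r1 = const("blood")$r1),
    portal_vein = list(c = cv, t1 = const("blood")$t1_0_ms,
                       r1 = const("blood")$r1))
  if (!isTRUE(sc$spleen_in_fov)) render$spleen <- NULL

  set.seed(seed)
  signals <- lapply(names(render), function(nm) {
    r <- render[[nm]]
    s0 <- sc$s0[[nm]]
    sig <- concentration_to_signal(r$c, acq, r$t1, r$r1, s0)
    if (sc$noise_sigma > 0)
      sig$values <- sig$values + stats::rnorm(length(sig$values),
                                              0, sc$noise_sigma * s0)
    sig
  })
  names(signals) <- names(render)

  structure(list(times = times, ca = ca, cv = cv, cp = cp, ce = ce,
                 ci = ci, ct = ct, signals = signals, truth = truth,
                 acq = acq, scenario = sc, seed = seed),
            class = "synth_study")
}

#' @export
print.synth_study <- function(x, ...) {
  cat(sprintf("<synth_study:%s> %d samples (dt = %g s), ROIs: %s\n",
              x$scenario$name, length(x$times), x$scenario$frame_interval,
              paste(names(x$signals), collapse = ", ")))
  for (nm in names(x$truth)) {
    cat(sprintf("  truth[%s]: %s\n", nm,
                paste(sprintf("%s = %.4g", names(x$truth[[nm]]),
                              as.numeric(x$truth[[nm]])), collapse = ", ")))
  }
  invisible(x)
}

#' Export a synthetic study as a curves table
#'
#' @param study a [make_study()] result.
#' @return A data frame with columns `time_s` and one column per rendered
#'   ROI, suitable for [convert_study()] or [write_curves()].
#' @export
as_curves <- function(study) {
  stopifnot(inherits(study, "synth_study"))
  out <- data.frame(time_s = study$times)
  for (nm in names(study$signals)) out[[nm]] <- study$signals[[nm]]$values
  out
}

#' Paint a synthetic study into a small 4D phantom
#'
#' Builds a rectangular-region 4D volume whose organ/vessel voxels carry the
#' study's rendered signal time courses plus independent per-voxel Gaussian
#' noise, together with matching ROI masks — a minimal phantom for
#' exercising the segmentation-side utilities ([temporal_projections()],
#' [refine_vascular_roi()], [extract_roi_mean()]).
#'
#' @param study a [make_study()] result.
#' @param shape 3D spatial dims, at least c(16, 16, 4).
#' @param background baseline intensity of non-organ voxels.
#' @return A list with `volume` (a [dynamic_volume()]) and `masks` (named
#'   list of [roi_mask()]).
#' @export
make_phantom_4d <- function(study, shape = c(20, 20, 4), background = 20) {
  stopifnot(inherits(study, "synth_study"), length(shape) == 3L,
            all(shape >= c(16, 16, 4)))
  nt <- length(study$times)
  rois <- names(study$signals)
  # non-overlapping x-bands, one per ROI
  width <- floor(shape[1L] / length(rois))
  if (width < 3L) stop("phantom regions would overlap; enlarge 'shape'")
  vol <- array(background, c(shape, nt))
  masks <- list()
  sigma <- study$scenario$noise_sigma
  set.seed(study$seed + 1L)
  for (i in seq_along(rois)) {
    nm <- rois[i]
    xs <- ((i - 1L) * width + 2L):(i * width - 1L)
    ys <- 3:(shape[2L] - 2L)
    zs <- 2:(shape[3L] - 1L)
    m <- array(FALSE, shape)
    m[xs, ys, zs] <- TRUE
    masks[[nm]] <- roi_mask(m, label = nm)
    course <- study$signals[[nm]]$values
    nv <- sum(m)
    block <- matrix(rep(course, each = nv), nv, nt)
    if (sigma > 0)
      block <- block + stats::rnorm(nv * nt, 0, sigma * study$signals[[nm]]$s0)
    idx <- which(m)
    for (f in seq_len(nt))
      vol[idx + (f - 1L) * prod(shape)] <- block[, f]
  }
  list(volume = dynamic_volume(pmax(vol, 0), study$scenario$frame_interval,
                               bolus_frame = study$scenario$n_baseline + 1L),
       masks = masks)
}
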