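# Shared fixtures: small grids and a shortened study for the slower fits.

default_acq <- function(dt = 7.65, n_baseline = 8) {
  acquisition_params(tr = 0.005, flip_angle = 12, frame_interval = dt,
                     bolus_time = n_baseline * dt)
}

# uniform bolus-relative grid with pre-contrast frames
test_grid <- function(dt = 5, duration = 1200, n_baseline = 6) {
  (seq_len(n_baseline + ceiling(duration / dt) + 1L) - n_baseline - 1L) * dt
}

# smooth gamma-variate test input, zero pre-bolus
gamma_input <- function(times, amp = 2.5, tp = 60, shape = 3) {
  t <- pmax(times, 0)
  ifelse(times < 0, 0, amp * (t / tp)^shape * exp(shape * (1 - t / tp)))
}

# full synthetic scenario shortened for fast fits
quick_scenario <- function(name = "dog_eob", ...) {
  synth_scenario(name, duration = 1800, ...)
}

# generate -> convert -> TRISTAN fit, returning (fit, truth in min^-1)
recover_tristan <- function(scenario, seed = scenario$seed, criterion = "LAR",
                            filter = NULL, n_narrow = 20, n_wide = 80,
                            start_seed = 0L) {
  study <- make_study(scenario, seed = seed)
  ds <- convert_study(as_curves(study), study$acq, scenario$species,
                      scenario$agent, hct = scenario$hct, filter = filter)
  fit <- fit_pk(ds$ci, "tristan", list(ce = ds$ce, vh = 1 - ds$ve_liver),
                criterion = criterion,
                starts = start_spec("tristan", n_narrow, n_wide, start_seed))
  list(fit = fit, est = coef(fit, "per_min"),
       truth = 60 * as.numeric(study$truth$tristan), study = study)
}

# independent SPGR forward oracle (direct evaluation of the steady-state
# signal equation), used to cross-check the conversion chain
spgr_oracle <- function(r1, tr, flip_deg, s0, r1_0) {
  th <- flip_deg * pi / 180
  sig <- function(r) sin(th) * (1 - exp(-r * tr)) / (1 - cos(th) * exp(-r * tr))
  s0 * sig(r1) / sig(r1_0)
}
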