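#' Convert a study's ROI signal curves to concentration
#'
#' Takes the four ROI-mean signal time courses of a DCE-MRI liver exam
#' (liver, spleen, abdominal aorta, portal vein; any of the last three may be
#' absent) and produces the concentration curves the kinetic models consume:
#' liver tissue concentration Ct, intracellular concentration Ci, EES
#' surrogate Ce from the spleen, and arterial/venous blood concentrations
#' Ca/Cv. Noise filtering, when requested, is applied in the signal domain
#' before conversion. Constants (fixed pre-contrast T1, relaxivities, volume
#' fractions) are resolved from the registry by species and agent.
#'
#' @param curves a data frame with column `time_s` (seconds relative to
#'   bolus; negative = pre-contrast baseline frames) and any of `liver`,
#'   `spleen`, `aorta`, `portal_vein`.
#' @param acq an [acquisition_params()].
#' @param species,agent registry keys (see [gd_constants()]).
#' @param hct hematocrit, in (0, 1).
#' @param filter optional [filter_spec()]; `NULL` (default) leaves signals
#'   unfiltered.
#' @param registry optional constants registry override.
#' @return An object of class `dce_study`: concentration curves (`ct`, `ci`,
#'   `ce`, `ca`, `cv`, those whose source ROI is present), the raw
#'   [signal_series()] per ROI, and the study metadata.
#' @export
convert_study <- function(curves, acq, species, agent, hct = 0.40,
                          filter = NULL, registry = NULL) {
  stopifnot(is.data.frame(curves), inherits(acq, "acquisition_params"))
  if (!"time_s" %in% names(curves)) stop("'curves' must have a 'time_s' column")
  if (!"liver" %in% names(curves)) stop("'curves' must have a 'liver' column")
  if (hct <= 0 || hct >= 1) stop("'hct' must be in (0, 1)")
  times <- curves$time_s

  make_sig <- function(col) {
    v <- curves[[col]]
    s0 <- baseline_signal(v, times, acq$n_baseline)
    signal_series(times, v, s0 = s0)
  }
  rois <- intersect(c("liver", "spleen", "aorta", "portal_vein"), names(curves))
  signals <- lapply(rois, make_sig)
  names(signals) <- rois
  used <- signals
  if (!is.null(filter))
    used <- lapply(used, blended_median_filter, spec = filter)

  const <- function(tissue) gd_constants(species, agent, tissue, registry)
  cl <- const("liver")
  convert <- function(sig, tissue, compartment) {
    k <- const(tissue)
    r1s <- signal_to_relaxation(sig, acq, k$t1_0_ms)
    relaxation_to_concentration(r1s, k$r1, compartment)
  }

  ct <- convert(used$liver, "liver", "Ct")
  ce <- if ("spleen" %in% rois) {
    k <- const("spleen")
    r1s <- signal_to_relaxation(used$spleen, acq, k$t1_0_ms)
    spleen_to_ees_concentration(r1s, k$r1, ve_spleen = k$ve)
  }
  ci <- if (!is.null(ce)) liver_intracellular_concentration(ct, ce, cl$ve)
  ca <- if ("aorta" %in% rois) convert(used$aorta, "blood", "Ca")
  cv <- if ("portal_vein" %in% rois) convert(used$portal_vein, "blood", "Cv")

  structure(list(ct = ct, ci = ci, ce = ce, ca = ca, cv = cv,
                 signals = signals, species = species, agent = agent,
                 hct = hct, ve_liver = cl$ve, acq = acq,
                 filtered = !is.null(filter), filter = filter,
                 registry = registry),
            class = "dce_study")
}

#' @export
print.dce_study <- function(x, ...) {
  have <- names(Filter(Negate(is.null), x[c("ct", "ci", "ce", "ca", "cv")]))
  cat(sprintf("<dce_study> %s / %s, %d samples, hct = %.2f, %s; curves: %s\n",
              x$species, x$agent, length(x$ct), x$hct,
              if (x$filtered) "filtered" else "unfiltered",
              paste(have, collapse = ", ")))
  invisible(x)
}

refilter_study <- function(study, filter) {
  curves <- data.frame(time_s = study$ct$times)
  for (nm in names(study$signals)) curves[[nm]] <- study$signals[[nm]]$values
  convert_study(curves, study$acq, study$species, study$agent, study$hct,
                filter = filter, registry = study$registry)
}

#' Fit both kinetic models under the full criterion/filter grid
#'
#' Runs the published four-way protocol per model: each model is fit with
#' both the LAR and LSQ criteria, on unfiltered and on noise-filtered data
#' (filtering in the signal domain, then reconversion). The reference-region
#' (tristan) model is skipped with a recorded reason when the study has no
#' spleen curve — the model requires the spleen signal as the EES surrogate.
#'
#' @param study an unfiltered [convert_study()] result.
#' @param models which models to fit.
#' @param criteria which fitness criteria to use.
#' @param filter the [filter_spec()] used for the filtered arm.
#' @param seed RNG seed for the start draws.
#' @param n_narrow,n_wide optional overrides of the per-model start counts.
#' @param maxit local-optimizer iteration cap.
#' @return An object of class `pk_fit_grid`: a list of `pk_fit` objects and
#'   skip records, one per (model, criterion, filtered) cell, with an
#'   [as.data.frame()] method producing the results table.
#' @export
fit_suite <- function(study, models = c("tristan", "berks"),
                      criteria = c("LAR", "LSQ"), filter = filter_spec(),
                      seed = 0L, n_narrow = NULL, n_wide = NULL, maxit = 3000) {
  stopifnot(inherits(study, "dce_study"))
  if (study$filtered)
    stop("'study' must be the unfiltered conversion; fit_suite applies the filter itself")
  filtered_study <- refilter_study(study, filter)
  out <- list()
  for (model in models) {
    for (filt in c(FALSE, TRUE)) {
      st <- if (filt) filtered_study else study
      for (crit in criteria) {
        key <- paste(model, crit, if (filt) "filtered" else "unfiltered", sep = ".")
        if (model == "tristan" && is.null(st$ce)) {
          out[[key]] <- list(model = model, criterion = crit, filtered = filt,
                             skipped = TRUE,
                             reason = "spleen absent: no EES surrogate for the reference-region model")
          next
        }
        inputs <- if (model == "tristan")
          list(ce = st$ce, vh = 1 - st$ve_liver)
        else list(ca = st$ca, cv = st$cv, hct = st$hct)
        data <- if (model == "tristan") st$ci else st$ct
        out[[key]] <- fit_pk(data, model, inputs, criterion = crit,
                             starts = start_spec(model, n_narrow, n_wide, seed),
                             maxit = maxit, filtered = filt)
      }
    }
  }
  structure(out, class = "pk_fit_grid",
            species = study$species, agent = study$agent, seed = seed)
}

#' @export
print.pk_fit_grid <- function(x, ...) {
  cat(sprintf("<pk_fit_grid> %s / %s: %d cells (%d fit, %d skipped)\n",
              attr(x, "species"), attr(x, "agent"), length(x),
              sum(vapply(x, inherits, TRUE, "pk_fit")),
              sum(!vapply(x, inherits, TRUE, "pk_fit"))))
  print(as.data.frame(x))
  invisible(x)
}

#' Results table from a fit grid
#'
#' One row per (model, criterion, filtered) cell. Rates appear both in
#' reporting units (min^-1, columns `k1_per_min`, `k2_per_min`,
#' `beta_*_per_min`) and native fit units (s^-1); `fa` is dimensionless.
#' Skipped cells carry `skipped = TRUE` and the reason.
#'
#' @param x a `pk_fit_grid`.
#' @param ... unused.
#' @return A data frame.
#' @export
as.data.frame.pk_fit_grid <- function(x, ...) {
  rows <- lapply(names(x), function(key) {
    f <- x[[key]]
    base <- data.frame(model = f$model, criterion = f$criterion,
                       filtered = f$filtered,
                       species = attr(x, "species") %||% NA_character_,
                       agent = attr(x, "agent") %||% NA_character_,
                       k1_per_min = NA_real_, k2_per_min = NA_real_,
                       k1_per_s = NA_real_, k2_per_s = NA_real_,
                       alpha_plus = NA_real_, beta_plus = NA_real_,
                       alpha_minus = NA_real_, beta_minus = NA_real_,
                       fa = NA_real_, objective = NA_real_,
                       seed = attr(x, "seed") %||% NA_integer_,
                       skipped = !inherits(f, "pk_fit"),
                       reason = if (inherits(f, "pk_fit")) "" else f$reason)
    if (inherits(f, "pk_fit")) {
      p <- f$par
      base$objective <- f$objective
      if (f$model == "tristan") {
        base$k1_per_s <- p[["k1"]]; base$k2_per_s <- p[["k2"]]
        base$k1_per_min <- 60 * p[["k1"]]; base$k2_per_min <- 60 * p[["k2"]]
      } else {
        base$alpha_plus <- p[["alpha_plus"]]; base$beta_plus <- p[["beta_plus"]]
        base$alpha_minus <- p[["alpha_minus"]]; base$beta_minus <- p[["beta_minus"]]
        base$fa <- p[["fa"]]
      }
    }
    base
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
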