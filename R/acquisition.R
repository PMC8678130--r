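# Data containers: single relaxation acquisitions, multi-field datasets,
# gadolinium agent specification.

#' A single relaxation acquisition
#'
#' One (tau, signal) curve with its acquisition metadata. Delays must be
#' strictly increasing, non-negative, and there must be at least 8 of them
#' for a curve to be fittable.
#'
#' @param tau_s Delays, s; strictly increasing, all >= 0, length >= 8.
#' @param signal Signal magnitudes, a.u.; same length as `tau_s`.
#' @param field_mhz Relaxation field, MHz proton Larmor frequency.
#' @param sequence_type One of `"IR"` (inversion recovery), `"NP"`
#'   (non-polarized), `"PP"` (pre-polarized).
#' @param temperature_c Sample temperature, degrees C (metadata only).
#' @param meta Named list of labels (sample id, dose, arm, timepoint,
#'   embedded ground truth for synthetic data, ...).
#' @return Object of class `relax_acquisition`.
#' @export
relax_acquisition <- function(tau_s, signal, field_mhz = NA_real_,
                              sequence_type = c("IR", "NP", "PP"),
                              temperature_c = NA_real_, meta = list()) {
  sequence_type <- match.arg(sequence_type)
  tau_s <- as.numeric(tau_s)
  signal <- as.numeric(signal)
  if (length(tau_s) < 8L) {
    stop("an acquisition needs at least 8 tau values", call. = FALSE)
  }
  if (length(signal) != length(tau_s)) {
    stop("`signal` and `tau_s` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(tau_s)) || any(!is.finite(signal))) {
    stop("tau and signal values must all be finite", call. = FALSE)
  }
  if (any(tau_s < 0)) stop("tau values must be >= 0", call. = FALSE)
  if (any(diff(tau_s) <= 0)) {
    stop("tau values must be strictly increasing", call. = FALSE)
  }
  structure(list(tau_s = tau_s, signal = signal, field_mhz = field_mhz,
                 sequence_type = sequence_type,
                 temperature_c = temperature_c, meta = meta),
            class = "relax_acquisition")
}

#' @exportS3Method
print.relax_acquisition <- function(x, ...) {
  cat(sprintf("<relax_acquisition: %s, %d tau in [%g, %g] s, field %s MHz>\n",
              x$sequence_type, length(x$tau_s), min(x$tau_s), max(x$tau_s),
              format(x$field_mhz)))
  invisible(x)
}

#' Gadolinium agent specification
#'
#' A contrast agent confined to the extracellular space raises the
#' extracellular relaxation rate linearly with concentration via its
#' relaxivity. Used in vitro to create the intra/extracellular R1 contrast
#' the exchange measurement requires.
#'
#' @param relaxivity_r1 Longitudinal relaxivity, s^-1 mM^-1, at the working
#'   field and temperature (> 0).
#' @param concentration Agent concentration, mM (>= 0).
#' @param baseline_r1_ex Agent-free extracellular relaxation rate, s^-1 (> 0).
#' @return Object of class `gd_agent`.
#' @seealso [r1ex_with_agent()]
#' @export
gd_agent <- function(relaxivity_r1, concentration, baseline_r1_ex) {
  check_scalar(relaxivity_r1, "relaxivity_r1", positive = TRUE)
  check_scalar(concentration, "concentration", nonnegative = TRUE)
  check_scalar(baseline_r1_ex, "baseline_r1_ex", positive = TRUE)
  structure(list(relaxivity_r1 = relaxivity_r1,
                 concentration = concentration,
                 baseline_r1_ex = baseline_r1_ex),
            class = "gd_agent")
}

#' Extracellular relaxation rate in the presence of the agent
#'
#' Linear inner-sphere relaxivity model:
#' `r1_ex = baseline_r1_ex + relaxivity_r1 * concentration`.
#'
#' @param agent A [gd_agent()].
#' @return Extracellular relaxation rate, s^-1.
#' @export
r1ex_with_agent <- function(agent) {
  stopifnot(inherits(agent, "gd_agent"))
  agent$baseline_r1_ex + agent$relaxivity_r1 * agent$concentration
}

#' The standard set of relaxation fields for in-vivo dispersion profiles
#'
#' Seven proton Larmor frequencies (MHz) spanning the 0.01-1 MHz analysis
#' window of the fast field-cycling protocol.
#'
#' @return Numeric vector of 7 fields, MHz.
#' @export
default_nmrd_fields <- function() c(0.01, 0.02, 0.037, 0.07, 0.15, 0.39, 1)

#' Extracellular-volume-fraction bounds by tissue class
#'
#' Literature-based physiological ranges used as box constraints in the
#' global fit: (0.09, 0.19) for healthy mouse hind limb, (0.15, 0.5) for
#' tumor-bearing hind limb.
#'
#' @param tissue_class `"tumor"` or `"healthy"`.
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
vex_bounds <- function(tissue_class = c("tumor", "healthy")) {
  tissue_class <- match.arg(tissue_class)
  switch(tissue_class,
         healthy = c(0.09, 0.19),
         tumor = c(0.15, 0.5))
}

#' A multi-field dispersion dataset for one subject/timepoint
#'
#' Bundles per-field acquisitions with the Matrigel extracellular-rate table
#' that the global fit holds fixed, plus the tissue class selecting the
#' `v_ex` bounds.
#'
#' @param acquisitions List of [relax_acquisition()] objects at distinct
#'   relaxation fields (>= 3).
#' @param matrigel Data frame with columns `field_mhz`, `r1_ex`: the
#'   phantom-measured extracellular rates (see [matrigel_r1ex_lookup()]).
#' @param tissue_class `"tumor"` or `"healthy"`.
#' @param meta Named list (subject, arm, timepoint, ground truth, ...).
#' @param field_range Allowed field window, MHz (default the 0.01-1 MHz
#'   analysis window).
#' @return Object of class `nmrd_dataset`.
#' @export
nmrd_dataset <- function(acquisitions, matrigel,
                         tissue_class = c("tumor", "healthy"),
                         meta = list(), field_range = c(0.01, 1)) {
  tissue_class <- match.arg(tissue_class)
  if (!is.list(acquisitions) ||
      !all(vapply(acquisitions, inherits, logical(1), "relax_acquisition"))) {
    stop("`acquisitions` must be a list of relax_acquisition objects",
         call. = FALSE)
  }
  fields <- vapply(acquisitions, function(a) a$field_mhz, numeric(1))
  if (any(!is.finite(fields))) {
    stop("every acquisition needs a finite field_mhz", call. = FALSE)
  }
  if (length(unique(fields)) < 3L) {
    stop("need acquisitions at >= 3 distinct fields", call. = FALSE)
  }
  if (any(fields < field_range[1] - 1e-12 | fields > field_range[2] + 1e-12)) {
    stop(sprintf("acquisition fields must lie within [%g, %g] MHz",
                 field_range[1], field_range[2]), call. = FALSE)
  }
  matrigel <- validate_matrigel(matrigel)
  if (any(fields < min(matrigel$field_mhz) - 1e-12 |
          fields > max(matrigel$field_mhz) + 1e-12)) {
    stop("every acquisition field must be inside the Matrigel table range",
         call. = FALSE)
  }
  structure(list(acquisitions = acquisitions, matrigel = matrigel,
                 tissue_class = tissue_class, meta = meta),
            class = "nmrd_dataset")
}

#' @exportS3Method
print.nmrd_dataset <- function(x, ...) {
  fields <- vapply(x$acquisitions, function(a) a$field_mhz, numeric(1))
  cat(sprintf("<nmrd_dataset: %d fields (%s MHz), tissue: %s>\n",
              length(fields), paste(format(sort(fields)), collapse = ", "),
              x$tissue_class))
  invisible(x)
}

validate_matrigel <- function(matrigel) {
  matrigel <- as.data.frame(matrigel)
  if (!all(c("field_mhz", "r1_ex") %in% names(matrigel))) {
    stop("Matrigel table needs columns `field_mhz` and `r1_ex`",
         call. = FALSE)
  }
  if (nrow(matrigel) < 2L) {
    stop("Matrigel table needs at least 2 rows", call. = FALSE)
  }
  if (any(!is.finite(matrigel$field_mhz)) || any(matrigel$field_mhz <= 0) ||
      any(!is.finite(matrigel$r1_ex)) || any(matrigel$r1_ex <= 0)) {
    stop("Matrigel fields and rates must be finite and positive",
         call. = FALSE)
  }
  matrigel <- matrigel[order(matrigel$field_mhz), c("field_mhz", "r1_ex")]
  if (any(diff(matrigel$field_mhz) <= 0)) {
    stop("Matrigel fields must be distinct", call. = FALSE)
  }
  rownames(matrigel) <- NULL
  matrigel
}

#' Convert between magnetic field in tesla and proton Larmor frequency
#'
#' Uses the proton gyromagnetic ratio, 42.577 MHz/T.
#'
#' @param tesla,mhz Field in tesla / frequency in MHz.
#' @return The converted value.
#' @export
tesla_to_mhz <- function(tesla) tesla * 42.577

#' @rdname tesla_to_mhz
#' @export
mhz_to_tesla <- function(mhz) mhz / 42.577
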