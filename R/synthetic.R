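# Synthetic-data generators with embedded ground truth: in-vitro
# inversion-recovery curves, in-vivo multi-field dispersion datasets, and
# treated-vs-control cohorts. The generators share the forward model with
# the fitters (no private math), so noiseless output is exactly what the
# fit objectives predict.

#' Synthetic intracellular dispersion truth
#'
#' A smooth, positive, decreasing intracellular rate profile
#' `r1_in(nu) = amplitude / (1 + (nu / nu_c)^2) + offset` (Lorentzian plus
#' offset), standing in for a measured tissue dispersion, together with a
#' Matrigel extracellular-rate table. Both are synthetic stand-ins for
#' phantom/tissue measurements and are labelled as such in every manifest.
#'
#' @param amplitude Low-field dispersion amplitude `A`, s^-1.
#' @param nu_c Corner frequency, MHz.
#' @param offset High-field plateau `B`, s^-1.
#' @param matrigel Matrigel table (`field_mhz`, `r1_ex`); defaults to
#'   [matrigel_default()].
#' @return Object of class `dispersion_truth` with elements `r1_in_at`
#'   (function of field in MHz), the parameters, and `matrigel`.
#' @export
dispersion_truth <- function(amplitude = 6, nu_c = 0.1, offset = 1.5,
                             matrigel = matrigel_default()) {
  check_scalar(amplitude, "amplitude", positive = TRUE)
  check_scalar(nu_c, "nu_c", positive = TRUE)
  check_scalar(offset, "offset", positive = TRUE)
  matrigel <- validate_matrigel(matrigel)
  structure(list(
    r1_in_at = function(field_mhz) {
      amplitude / (1 + (field_mhz / nu_c)^2) + offset
    },
    amplitude = amplitude, nu_c = nu_c, offset = offset,
    matrigel = matrigel, synthetic = TRUE), class = "dispersion_truth")
}

#' Synthetic default Matrigel extracellular-rate table
#'
#' A SYNTHETIC stand-in for phantom-measured extracellular rates (the real
#' values belong to a separate phantom experiment): a gently dispersive
#' Lorentzian-plus-offset profile evaluated at the analysis fields.
#'
#' @param fields Fields at which to tabulate, MHz.
#' @return Data frame with columns `field_mhz`, `r1_ex`.
#' @export
matrigel_default <- function(fields = default_nmrd_fields()) {
  data.frame(field_mhz = fields,
             r1_ex = 1 / (1 + (fields / 0.3)^2) + 0.5)
}

#' Generate a synthetic inversion-recovery acquisition
#'
#' Simulates the in-vitro pellet experiment: a 64-point (by default)
#' log-spaced inversion-recovery curve from the two-site exchange forward
#' model, plus seeded noise. The ground truth travels in the returned
#' acquisition's `meta$truth`.
#'
#' @param truth A [two_site_params()]; its `r1_ex` should already include
#'   any agent contribution (see [r1ex_with_agent()]).
#' @param n_tau Number of delays (>= 8; default 64, the standard pellet
#'   protocol).
#' @param tau_range Delay range, s (log-spaced grid).
#' @param noise_sd Gaussian noise SD as a fraction of `m_inf` (>= 0).
#' @param noise_model `"gaussian"` (signed signal) or `"rician"`
#'   (magnitude-folded).
#' @param inv_eff Inversion efficiency of the simulated sequence.
#' @param field_mhz Relaxation field recorded in metadata (default 21.3
#'   MHz, i.e. 0.5 T).
#' @param seed Seed; required whenever `noise_sd > 0`.
#' @param meta Extra metadata merged into the acquisition (dose, sample id,
#'   ...).
#' @return A [relax_acquisition()] of type IR with `meta$truth` carrying
#'   the generating parameters.
#' @export
gen_ir_dataset <- function(truth, n_tau = 64, tau_range = c(1e-3, 5),
                           noise_sd = 0.01,
                           noise_model = c("gaussian", "rician"),
                           inv_eff = 1, field_mhz = tesla_to_mhz(0.5),
                           seed = NULL, meta = list()) {
  stopifnot(inherits(truth, "two_site_params"))
  noise_model <- match.arg(noise_model)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("`noise_sd` must be a single number >= 0", call. = FALSE)
  }
  if (n_tau < 8L) stop("`n_tau` must be >= 8", call. = FALSE)
  if (noise_sd > 0 && is.null(seed)) {
    stop("`seed` is required when noise_sd > 0", call. = FALSE)
  }
  tau <- exp(seq(log(tau_range[1]), log(tau_range[2]), length.out = n_tau))
  sol <- exchange_eigensystem(truth)
  clean <- ir_signal(tau, sol, m_inf = truth$m_inf, inv_eff = inv_eff)
  signal <- if (noise_sd == 0) clean else with_seed(seed, {
    sdv <- noise_sd * truth$m_inf
    switch(noise_model,
           gaussian = clean + rnorm(n_tau, 0, sdv),
           rician = sqrt((clean + rnorm(n_tau, 0, sdv))^2 +
                           rnorm(n_tau, 0, sdv)^2))
  })
  relax_acquisition(
    tau, signal, field_mhz = field_mhz, sequence_type = "IR",
    temperature_c = 25,
    meta = c(meta, list(
      truth = list(r1_in = truth$r1_in, r1_ex = truth$r1_ex,
                   k_io = truth$k_io, v_ex = truth$v_ex,
                   m_inf = truth$m_inf, inv_eff = inv_eff),
      noise_sd = noise_sd, noise_model = noise_model, seed = seed)))
}

#' Generate a synthetic multi-field dispersion dataset
#'
#' Simulates the in-vivo field-cycling acquisition: one pre-polarized decay
#' per relaxation field, 32 log-spaced delays whose upper end is drawn
#' per-field from the 2.8-4 s window, with the intracellular rate from a
#' [dispersion_truth()] profile and the extracellular rate from its
#' Matrigel table. The starting magnetization is normalized to 1
#' (polarization at 13 MHz) and the equilibrium level scales with the
#' relaxation field (`m_inf = field / 13`). Noise is multiplicative
#' Gaussian at the stated fraction (the relaxometer's ~2% rate
#' uncertainty).
#'
#' @param dispersion A [dispersion_truth()].
#' @param v_ex True extracellular volume fraction.
#' @param k_io True efflux rate constant, s^-1 (0 = no exchange,
#'   `tau_ex = Inf`).
#' @param fields Relaxation fields, MHz (distinct; default the 7-field
#'   protocol).
#' @param n_tau Delays per curve (>= 8; default 32).
#' @param tau_window Range, s, from which each field's longest delay is
#'   drawn.
#' @param tau_min Shortest delay, s.
#' @param noise Multiplicative noise fraction (default 0.02).
#' @param tissue_class Tissue class recorded on the dataset.
#' @param seed Seed; required whenever `noise > 0` (also seeds the per-field
#'   window draw).
#' @param meta Extra metadata (subject, arm, timepoint, ...).
#' @return An [nmrd_dataset()] with `meta$truth` carrying the generating
#'   parameters.
#' @export
gen_nmrd_dataset <- function(dispersion, v_ex = 0.30, k_io = 0.8,
                             fields = default_nmrd_fields(), n_tau = 32,
                             tau_window = c(2.8, 4), tau_min = 0.004,
                             noise = 0.02,
                             tissue_class = c("tumor", "healthy"),
                             seed = NULL, meta = list()) {
  stopifnot(inherits(dispersion, "dispersion_truth"))
  tissue_class <- match.arg(tissue_class)
  if (anyDuplicated(fields)) stop("fields must be distinct", call. = FALSE)
  if (n_tau < 8L) stop("`n_tau` must be >= 8", call. = FALSE)
  if (!is.numeric(noise) || length(noise) != 1L || noise < 0) {
    stop("`noise` must be a single number >= 0", call. = FALSE)
  }
  if (is.null(seed)) {
    if (noise > 0) stop("`seed` is required when noise > 0", call. = FALSE)
    seed <- 0  # windows still need a deterministic draw
  }
  mg <- dispersion$matrigel
  if (any(fields < min(mg$field_mhz) - 1e-12 |
          fields > max(mg$field_mhz) + 1e-12)) {
    stop("a requested field lies outside the Matrigel table range",
         call. = FALSE)
  }
  fields <- sort(fields)
  acqs <- with_seed(seed, {
    windows <- runif(length(fields), tau_window[1], tau_window[2])
    lapply(seq_along(fields), function(f) {
      fld <- fields[f]
      tau <- exp(seq(log(tau_min), log(windows[f]), length.out = n_tau))
      r1_in <- dispersion$r1_in_at(fld)
      r1_ex <- matrigel_r1ex_lookup(mg, fld)
      sol <- exchange_eigensystem(two_site_params(
        r1_in = r1_in, r1_ex = r1_ex, k_io = k_io, v_ex = v_ex))
      m_inf <- fld / 13      # equilibrium scales with the relaxation field
      clean <- ffc_decay_signal(tau, sol, m_start = 1, m_inf = m_inf)
      signal <- if (noise > 0) clean * (1 + rnorm(n_tau, 0, noise)) else clean
      relax_acquisition(tau, signal, field_mhz = fld, sequence_type = "PP",
                        temperature_c = 25,
                        meta = list(r1_in_true = r1_in, r1_ex_true = r1_ex,
                                    m_start_true = 1, m_inf_true = m_inf))
    })
  })
  nmrd_dataset(acqs, mg, tissue_class = tissue_class,
               meta = c(meta, list(
                 truth = list(v_ex = v_ex, k_io = k_io,
                              tau_ex = if (k_io > 0)
                                1 / influx_from_efflux(k_io, v_ex) else Inf,
                              dispersion = list(
                                amplitude = dispersion$amplitude,
                                nu_c = dispersion$nu_c,
                                offset = dispersion$offset,
                                synthetic = TRUE)),
                 noise = noise, seed = seed)))
}

#' Ground-truth specification for a synthetic treatment cohort
#'
#' States the world a simulated study lives in: two arms of `n_per_arm`
#' animals, timepoints (days relative to first treatment: baseline plus one
#' acquisition three days after each of three treatments), arm-by-timepoint
#' multipliers on the efflux rate and the extracellular volume fraction,
#' and between-animal variability. The default treated-arm pattern encodes
#' the expected biology: `k_io` drops ~40% at the first post-treatment
#' timepoint and returns to baseline, while `v_ex` first decreases then
#' increases as cell death permeabilizes membranes.
#'
#' In-vivo efflux defaults are ~25x smaller than the in-vitro pellet scale.
#'
#' @param n_per_arm Animals per arm (>= 2; default 7).
#' @param timepoints Acquisition days relative to first treatment.
#' @param k_io_base,v_ex_base Control-arm means.
#' @param k_io_mult_treated,v_ex_mult_treated Treated-arm multipliers, one
#'   per timepoint (> 0).
#' @param k_io_cv Between-animal lognormal coefficient of variation on
#'   `k_io`.
#' @param v_ex_sd Between-animal Gaussian SD on `v_ex` (draws are kept
#'   inside the tumor physiological range).
#' @param noise Multiplicative signal noise fraction per curve.
#' @param seed Master seed for the whole cohort.
#' @return Object of class `cohort_truth`.
#' @export
cohort_truth <- function(n_per_arm = 7, timepoints = c(0, 3, 6, 9),
                         k_io_base = 0.8, v_ex_base = 0.30,
                         k_io_mult_treated = c(1, 0.6, 1, 1),
                         v_ex_mult_treated = c(1, 0.85, 1.15, 1.3),
                         k_io_cv = 0.25, v_ex_sd = 0.04,
                         noise = 0.02, seed = 1) {
  if (n_per_arm < 2L) stop("`n_per_arm` must be >= 2", call. = FALSE)
  nt <- length(timepoints)
  if (length(k_io_mult_treated) != nt || length(v_ex_mult_treated) != nt) {
    stop("multiplier vectors must match the number of timepoints",
         call. = FALSE)
  }
  if (any(k_io_mult_treated <= 0) || any(v_ex_mult_treated <= 0)) {
    stop("multipliers must be > 0", call. = FALSE)
  }
  if (any(v_ex_base * v_ex_mult_treated >= 1)) {
    stop("v_ex after multiplication must stay inside (0, 1)", call. = FALSE)
  }
  structure(list(n_per_arm = as.integer(n_per_arm), timepoints = timepoints,
                 k_io_base = k_io_base, v_ex_base = v_ex_base,
                 k_io_mult_treated = k_io_mult_treated,
                 v_ex_mult_treated = v_ex_mult_treated,
                 k_io_cv = k_io_cv, v_ex_sd = v_ex_sd,
                 noise = noise, seed = seed),
            class = "cohort_truth")
}

#' Generate a synthetic treated-vs-control cohort
#'
#' Hierarchical sampling: each animal draws a baseline `(k_io, v_ex)`
#' around the arm means (lognormal on `k_io`, truncated Gaussian on
#' `v_ex`), the arm-by-timepoint multipliers are applied, and one
#' [gen_nmrd_dataset()] is generated per animal x timepoint. Everything is
#' reproducible from the master seed.
#'
#' @param truth A [cohort_truth()].
#' @param dispersion A [dispersion_truth()] shared by all animals.
#' @param fields,n_tau,tau_window Passed to [gen_nmrd_dataset()].
#' @return List with `datasets` (list of [nmrd_dataset()], each with
#'   `meta$animal`, `meta$arm`, `meta$timepoint`) and `manifest` (the
#'   configured arm x timepoint means — exact bookkeeping, not estimates —
#'   the per-animal draws, and the seed; the dispersion template is
#'   labelled synthetic).
#' @export
gen_cohort <- function(truth, dispersion = dispersion_truth(),
                       fields = default_nmrd_fields(), n_tau = 32,
                       tau_window = c(2.8, 4)) {
  stopifnot(inherits(truth, "cohort_truth"),
            inherits(dispersion, "dispersion_truth"))
  nt <- length(truth$timepoints)
  arms <- c("control", "treated")
  # configured cell means (exact bookkeeping)
  cell_means <- do.call(rbind, lapply(arms, function(a) {
    km <- if (a == "treated") truth$k_io_mult_treated else rep(1, nt)
    vm <- if (a == "treated") truth$v_ex_mult_treated else rep(1, nt)
    data.frame(arm = a, timepoint = truth$timepoints,
               mean_k_io = truth$k_io_base * km,
               mean_v_ex = truth$v_ex_base * vm,
               stringsAsFactors = FALSE)
  }))

  sdlog <- sqrt(log(1 + truth$k_io_cv^2))
  draws <- with_seed(truth$seed, {
    d <- expand.grid(arm = arms, animal = seq_len(truth$n_per_arm),
                     stringsAsFactors = FALSE)
    d$k_io_rel <- rlnorm(nrow(d), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    d$v_ex_dev <- rnorm(nrow(d), 0, truth$v_ex_sd)
    d$sub_seed <- sample.int(2^30, nrow(d) * nt) |>
      matrix(nrow = nrow(d)) |> asplit(1)
    d
  })

  datasets <- list()
  for (i in seq_len(nrow(draws))) {
    a <- draws$arm[i]
    km <- if (a == "treated") truth$k_io_mult_treated else rep(1, nt)
    vm <- if (a == "treated") truth$v_ex_mult_treated else rep(1, nt)
    for (j in seq_len(nt)) {
      k_ij <- truth$k_io_base * km[j] * draws$k_io_rel[i]
      v_ij <- truth$v_ex_base * vm[j] + draws$v_ex_dev[i]
      v_ij <- min(max(v_ij, 0.16), 0.49)  # keep inside tumor bounds
      id <- sprintf("%s_%02d", a, draws$animal[i])
      datasets[[length(datasets) + 1L]] <- gen_nmrd_dataset(
        dispersion, v_ex = v_ij, k_io = k_ij, fields = fields,
        n_tau = n_tau, tau_window = tau_window, noise = truth$noise,
        tissue_class = "tumor", seed = draws$sub_seed[[i]][j],
        meta = list(animal = id, arm = a,
                    timepoint = truth$timepoints[j]))
    }
  }
  list(datasets = datasets,
       manifest = list(cell_means = cell_means,
                       animal_draws = draws[c("arm", "animal", "k_io_rel",
                                              "v_ex_dev")],
                       n_per_arm = truth$n_per_arm,
                       timepoints = truth$timepoints,
                       noise = truth$noise, seed = truth$seed,
                       dispersion = list(amplitude = dispersion$amplitude,
                                         nu_c = dispersion$nu_c,
                                         offset = dispersion$offset,
                                         synthetic = TRUE)))
}
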