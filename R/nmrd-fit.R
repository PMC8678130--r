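# In-vivo pipeline: global constrained fit of multi-field field-cycling
# decays, sharing the extracellular volume fraction and extracellular water
# lifetime across fields with the extracellular rate fixed per field to the
# Matrigel phantom values.

#' Interpolate the Matrigel extracellular rate at a relaxation field
#'
#' Linear interpolation in log(field): dispersion profiles live on
#' log-frequency axes, so this is the natural rule between table nodes. The
#' lookup is exact at the nodes and refuses to extrapolate.
#'
#' @param table Data frame with columns `field_mhz`, `r1_ex` (>= 2 rows).
#' @param field_mhz Query field, MHz; must lie within the table's range.
#' @return Interpolated `r1_ex`, s^-1 (vectorized over `field_mhz`).
#' @export
matrigel_r1ex_lookup <- function(table, field_mhz) {
  table <- validate_matrigel(table)
  if (any(!is.finite(field_mhz)) || any(field_mhz <= 0)) {
    stop("query fields must be finite and positive", call. = FALSE)
  }
  lo <- min(table$field_mhz)
  hi <- max(table$field_mhz)
  if (any(field_mhz < lo - 1e-12) || any(field_mhz > hi + 1e-12)) {
    stop(sprintf("query field outside the Matrigel table range [%g, %g] MHz (no extrapolation)",
                 lo, hi), call. = FALSE)
  }
  approx(log(table$field_mhz), table$r1_ex, xout = log(field_mhz),
         rule = 1)$y
}

# Crude per-curve rate estimate (1/e crossing of the normalized decay) used
# only to initialize the per-field intracellular rates.
crude_rate <- function(tau, y) {
  n <- length(y)
  s_inf <- mean(y[max(1L, n - 2L):n])
  denom <- y[1L] - s_inf
  if (abs(denom) < 1e-12 * max(abs(y), 1)) return(1)
  frac <- (y - s_inf) / denom
  idx <- which(frac < exp(-1))[1L]
  if (is.na(idx) || tau[idx] <= 0) return(1 / max(tau[n], 1))
  1 / tau[idx]
}

#' Global two-site exchange fit of a multi-field dispersion dataset
#'
#' Fits all per-field decays of an [nmrd_dataset()] simultaneously: a single
#' least-squares objective sums the residuals of every curve under the
#' two-site exchange forward model ([ffc_decay_signal()]), sharing the
#' extracellular volume fraction `v_ex` and the extracellular water lifetime
#' `tau_ex` across fields, with one free intracellular rate `r1_in` per
#' field and the extracellular rate fixed per field to the Matrigel table
#' (log-field interpolation). Per-field amplitudes (`m_inf`, and `m_start`
#' for pre-polarized curves) are profiled out exactly by linear least
#' squares at every objective evaluation, so they remain free parameters
#' without burdening the optimizer.
#'
#' `v_ex` is constrained to the physiological range of the dataset's tissue
#' class (see [vex_bounds()]); an estimate pinned at a bound is flagged.
#' The efflux biomarker is reported as
#' `k_io = kio_from_tau_ex(tau_ex, v_ex)`.
#'
#' The objective is weighted least squares. The default `weights =
#' "relative"` (each residual scaled by 1/signal) matches the relaxometer's
#' multiplicative (~constant percentage) amplitude uncertainty and keeps the
#' low-signal tail of each decay — where the exchange information lives —
#' from being drowned out by the large early-decay amplitudes. Use
#' `weights = "none"` for plain unweighted least squares.
#'
#' Uncertainties are linearized (Jacobian) by default; pass `n_boot > 0`
#' with a `seed` for a per-curve residual bootstrap instead (slower, more
#' honest near bounds).
#'
#' @param data An [nmrd_dataset()].
#' @param v_ex_bounds Optional `c(lower, upper)` overriding the tissue-class
#'   bounds.
#' @param tau_ex_bounds Bounds on the extracellular lifetime, s.
#' @param r1_in_bounds Bounds on every per-field intracellular rate, s^-1.
#' @param starts Optional list of named vectors `c(v_ex =, tau_ex =)`
#'   replacing the default deterministic start grid.
#' @param weights `"relative"` (default; residuals scaled by 1/signal,
#'   matching multiplicative noise) or `"none"` (unweighted).
#' @param n_boot Number of residual-bootstrap replicates (0 = linearized
#'   errors only).
#' @param seed Seed for the bootstrap (required when `n_boot > 0`).
#' @param compute_se Compute standard errors / CIs (default TRUE).
#' @param control Optimizer control overrides (`maxit`, `factr`).
#' @return A `waterex_fit` with shared estimates (`v_ex`, `tau_ex`, derived
#'   `k_io`), per-field `r1_in`/`m_inf`/`m_start`, a `dispersion` data frame
#'   (`field_mhz`, `r1_in`, `r1_ex`, `r1_obs` — the effective
#'   monoexponential rate for profile plots), active-bound flags and the
#'   multi-start trace.
#' @export
fit_nmrd_global <- function(data, v_ex_bounds = NULL,
                            tau_ex_bounds = c(1e-3, 100),
                            r1_in_bounds = c(1e-3, 100),
                            starts = NULL, weights = c("relative", "none"),
                            n_boot = 0, seed = NULL,
                            compute_se = TRUE, control = list()) {
  weights <- match.arg(weights)
  stopifnot(inherits(data, "nmrd_dataset"))
  acqs <- data$acquisitions
  ord <- order(vapply(acqs, function(a) a$field_mhz, numeric(1)))
  acqs <- acqs[ord]
  fields <- vapply(acqs, function(a) a$field_mhz, numeric(1))
  seq_types <- vapply(acqs, function(a) a$sequence_type, character(1))
  if (any(seq_types == "IR")) {
    stop("the global dispersion fit handles NP/PP acquisitions only",
         call. = FALSE)
  }
  is_pp <- seq_types == "PP"
  r1ex_f <- matrigel_r1ex_lookup(data$matrigel, fields)
  if (is.null(v_ex_bounds)) v_ex_bounds <- vex_bounds(data$tissue_class)

  tau <- unlist(lapply(acqs, function(a) a$tau_s), use.names = FALSE)
  y <- unlist(lapply(acqs, function(a) a$signal), use.names = FALSE)
  w <- if (weights == "relative") {
    # floor at 1% of the curve maximum so near-zero tails cannot dominate
    flo <- unlist(lapply(acqs, function(a)
      rep(0.01 * max(abs(a$signal)), length(a$tau_s))), use.names = FALSE)
    1 / pmax(abs(y), flo)^2
  } else {
    rep(1, length(y))
  }
  lens <- vapply(acqs, function(a) length(a$tau_s), integer(1))
  field_start <- as.integer(cumsum(c(0L, lens[-length(lens)])))
  field_len <- as.integer(lens)
  nf <- length(fields)

  r1_init <- mapply(function(a) {
    min(max(crude_rate(a$tau_s, a$signal), r1_in_bounds[1] * 1.01),
        r1_in_bounds[2] * 0.99)
  }, acqs)
  par_names <- c("v_ex", "tau_ex", paste0("r1_in_", seq_len(nf)))
  lower <- c(v_ex_bounds[1], tau_ex_bounds[1], rep(r1_in_bounds[1], nf))
  upper <- c(v_ex_bounds[2], tau_ex_bounds[2], rep(r1_in_bounds[2], nf))
  names(lower) <- names(upper) <- par_names

  if (is.null(starts)) {
    vg <- v_ex_bounds[1] + c(0.3, 0.7) * diff(v_ex_bounds)
    tg <- c(0.1, 0.5, 2)
    starts <- list()
    for (v0 in vg) for (t0 in tg) {
      starts[[length(starts) + 1L]] <- c(v_ex = v0, tau_ex = t0)
    }
  }
  full_starts <- lapply(starts, function(s) {
    p <- c(s[["v_ex"]], min(max(s[["tau_ex"]], tau_ex_bounds[1]),
                            tau_ex_bounds[2]), r1_init)
    names(p) <- par_names
    p
  })

  fn <- function(p) cpp_nmrd_rss(p, tau, y, w, field_start, field_len,
                                 r1ex_f, is_pp)
  parscale <- c(0.1, 0.5, pmax(r1_init, 0.1))
  opt <- multistart_optim(full_starts, fn, lower, upper, parscale,
                          control = control)

  if (is.null(opt$best)) {
    return(new_fit_result("nmrd_2sx_global",
                          estimates = setNames(rep(NA_real_, 2 + nf),
                                               par_names),
                          std_errors = NULL, ci = NULL, rss = NA_real_,
                          converged = FALSE,
                          active_bounds = setNames(rep(NA, 2 + nf),
                                                   par_names),
                          n_obs = length(y), n_starts = length(full_starts),
                          warnings = "no start converged", meta = data$meta,
                          extra = list(fields = fields, starts = opt$trace)))
  }

  p_hat <- opt$best$par
  names(p_hat) <- par_names
  prof <- cpp_nmrd_profile(p_hat, tau, y, w, field_start, field_len,
                           r1ex_f, is_pp)
  v_hat <- p_hat[["v_ex"]]
  t_hat <- p_hat[["tau_ex"]]
  k_hat <- kio_from_tau_ex(t_hat, v_hat)
  active <- active_bound_flags(p_hat, lower, upper)
  names(active) <- par_names

  # per-field effective monoexponential rate for the dispersion profile
  r1_obs <- vapply(seq_len(nf), function(f) {
    sol <- exchange_eigensystem(two_site_params(
      r1_in = p_hat[[2 + f]], r1_ex = r1ex_f[f], k_io = k_hat, v_ex = v_hat))
    effective_monoexp_r1(sol, acqs[[f]]$tau_s)
  }, numeric(1))
  dispersion <- data.frame(field_mhz = fields,
                           r1_in = unname(p_hat[-(1:2)]),
                           r1_ex = r1ex_f, r1_obs = r1_obs)

  std_errors <- NULL
  ci <- NULL
  if (compute_se) {
    resid_fn <- function(p) cpp_nmrd_profile(p, tau, y, w, field_start,
                                             field_len, r1ex_f,
                                             is_pp)$residuals
    J <- num_jacobian(resid_fn, p_hat)
    sj <- se_from_jacobian(J, opt$best$value, length(y))
    se <- setNames(sj$se, par_names)
    # delta method for k_io = v/((1-v) tau)
    g <- c(1 / (t_hat * (1 - v_hat)^2), -v_hat / ((1 - v_hat) * t_hat^2))
    cov_vt <- sj$cov[1:2, 1:2]
    k_se <- if (all(is.finite(cov_vt))) {
      sqrt(max(drop(t(g) %*% cov_vt %*% g), 0))
    } else Inf
    std_errors <- c(se, k_io = k_se)
    z <- qnorm(0.975)
    est_for_ci <- c(p_hat, k_io = k_hat)
    ci <- cbind(lower = est_for_ci - z * std_errors,
                upper = est_for_ci + z * std_errors)
    if (n_boot > 0) {
      if (is.null(seed)) {
        stop("the residual bootstrap requires a `seed`", call. = FALSE)
      }
      boot <- with_seed(seed, {
        raw_resid <- prof$residuals / sqrt(w)
        fitted <- y - raw_resid
        reps <- matrix(NA_real_, nrow = n_boot, ncol = 3,
                       dimnames = list(NULL, c("v_ex", "tau_ex", "k_io")))
        for (b in seq_len(n_boot)) {
          yb <- fitted
          for (f in seq_len(nf)) {
            idx <- field_start[f] + seq_len(field_len[f])
            yb[idx] <- fitted[idx] + sample(raw_resid[idx],
                                            field_len[f], replace = TRUE)
          }
          fnb <- function(p) cpp_nmrd_rss(p, tau, yb, w, field_start,
                                          field_len, r1ex_f, is_pp)
          ob <- tryCatch(
            optim(p_hat, fnb, method = "L-BFGS-B", lower = lower,
                  upper = upper,
                  control = list(maxit = 200L, parscale = parscale)),
            error = function(e) NULL)
          if (!is.null(ob)) {
            reps[b, ] <- c(ob$par[1], ob$par[2],
                           kio_from_tau_ex(ob$par[2], ob$par[1]))
          }
        }
        reps
      })
      ok <- stats::complete.cases(boot)
      if (sum(ok) >= 10L) {
        bse <- apply(boot[ok, , drop = FALSE], 2, sd)
        bci <- t(apply(boot[ok, , drop = FALSE], 2, stats::quantile,
                       probs = c(0.025, 0.975)))
        for (nm in colnames(boot)) {
          std_errors[[nm]] <- bse[[nm]]
          ci[nm, ] <- c(min(bci[nm, 1], est_for_ci[[nm]]),
                        max(bci[nm, 2], est_for_ci[[nm]]))
        }
      }
    }
  }

  est <- c(v_ex = v_hat, tau_ex = t_hat, k_io = k_hat,
           setNames(unname(p_hat[-(1:2)]), paste0("r1_in_", fields)),
           setNames(prof$m_inf, paste0("m_inf_", fields)),
           setNames(prof$m_start, paste0("m_start_", fields)))

  new_fit_result("nmrd_2sx_global", estimates = est,
                 std_errors = std_errors, ci = ci, rss = opt$best$value,
                 converged = opt$converged, active_bounds = active,
                 n_obs = length(y), n_starts = length(full_starts),
                 seed = if (is.null(seed)) NA else seed,
                 meta = data$meta,
                 extra = list(fields = fields, dispersion = dispersion,
                              r1_ex = r1ex_f, starts = opt$trace,
                              v_ex_bounds = v_ex_bounds, weights = weights))
}

#' Cohort summary of dispersion-fit biomarkers across arms and timepoints
#'
#' Groups converged global fits by arm x timepoint, reports mean +/- SD of
#' `k_io` and `v_ex` per cell, and runs Welch tests (treated vs control) on
#' both biomarkers at each timepoint. Non-converged fits are excluded and
#' counted; cells with fewer than 2 converged fits are flagged and their
#' contrasts omitted.
#'
#' @param fits List of `waterex_fit` objects from [fit_nmrd_global()],
#'   each with `meta$arm` (`"control"`/`"treated"`) and `meta$timepoint`.
#' @return Data frame with one row per (timepoint, arm): `n`, `n_excluded`,
#'   `mean_k_io`, `sd_k_io`, `mean_v_ex`, `sd_v_ex`, and on treated rows
#'   the Welch `p_k_io` / `p_v_ex` against the same timepoint's control
#'   cell; a `note` records omitted cells.
#' @export
longitudinal_summary <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  arm <- vapply(fits, function(f) as.character(f$meta$arm %||% NA), character(1))
  tp <- vapply(fits, function(f) as.numeric(f$meta$timepoint %||% NA), numeric(1))
  if (any(is.na(arm)) || any(is.na(tp))) {
    stop("every fit needs meta$arm and meta$timepoint", call. = FALSE)
  }
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  kio <- vapply(fits, function(f) unname(f$estimates["k_io"]), numeric(1))
  vex <- vapply(fits, function(f) unname(f$estimates["v_ex"]), numeric(1))
  rows <- list()
  for (t in sort(unique(tp))) {
    cell <- function(a) list(k = kio[tp == t & arm == a & conv],
                             v = vex[tp == t & arm == a & conv],
                             exc = sum(tp == t & arm == a & !conv))
    ctl <- cell("control")
    trt <- cell("treated")
    p_k <- p_v <- NA_real_
    if (length(ctl$k) >= 2L && length(trt$k) >= 2L) {
      p_k <- welch_test(trt$k, ctl$k)$p_value
      p_v <- welch_test(trt$v, ctl$v)$p_value
    }
    for (a in c("control", "treated")) {
      cc <- if (a == "control") ctl else trt
      note <- if (length(cc$k) < 2L) "fewer than 2 converged fits; contrasts omitted" else ""
      rows[[length(rows) + 1L]] <- data.frame(
        timepoint = t, arm = a, n = length(cc$k), n_excluded = cc$exc,
        mean_k_io = if (length(cc$k)) mean(cc$k) else NA_real_,
        sd_k_io = if (length(cc$k) >= 2L) sd(cc$k) else NA_real_,
        mean_v_ex = if (length(cc$v)) mean(cc$v) else NA_real_,
        sd_v_ex = if (length(cc$v) >= 2L) sd(cc$v) else NA_real_,
        p_k_io = if (a == "treated") p_k else NA_real_,
        p_v_ex = if (a == "treated") p_v else NA_real_,
        note = note, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
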