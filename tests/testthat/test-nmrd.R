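# In-vivo pipeline: Matrigel lookup, global multi-field fit, cohort
# summaries.

test_that("Matrigel lookup interpolates linearly in log-field", {
  tab <- data.frame(field_mhz = c(0.01, 0.1, 1), r1_ex = c(2, 1.5, 1))
  # exact at nodes
  expect_equal(matrigel_r1ex_lookup(tab, 0.1), 1.5)
  expect_equal(matrigel_r1ex_lookup(tab, c(0.01, 1)), c(2, 1))
  # constant table
  const <- data.frame(field_mhz = c(0.01, 1), r1_ex = c(10, 10))
  expect_equal(matrigel_r1ex_lookup(const, 0.2), 10)
  # geometric midpoint of a two-point table: arithmetic mean under the
  # log-field rule (hand-computable)
  two <- data.frame(field_mhz = c(0.01, 1), r1_ex = c(20, 10))
  expect_equal(matrigel_r1ex_lookup(two, 0.1), 15)
  # no extrapolation
  expect_error(matrigel_r1ex_lookup(two, 2), "outside")
  expect_error(matrigel_r1ex_lookup(two, 0.005), "outside")
  expect_error(matrigel_r1ex_lookup(data.frame(field_mhz = 1, r1_ex = 1), 1),
               "at least 2")
})

test_that("the C++ global objective equals the R-side weighted variable
           projection on random cases", {
  disp <- dispersion_truth()
  ds <- gen_nmrd_dataset(disp, v_ex = 0.3, k_io = 0.8, n_tau = 16,
                         noise = 0.02, seed = 5)
  acqs <- ds$acquisitions
  fields <- vapply(acqs, function(a) a$field_mhz, numeric(1))
  r1ex_f <- matrigel_r1ex_lookup(ds$matrigel, fields)
  y <- unlist(lapply(acqs, function(a) a$signal))
  tau <- unlist(lapply(acqs, function(a) a$tau_s))
  lens <- vapply(acqs, function(a) length(a$tau_s), integer(1))
  w_list <- lapply(acqs, function(a)
    1 / pmax(abs(a$signal), 0.01 * max(abs(a$signal)))^2)
  w <- unlist(w_list)
  fs <- as.integer(cumsum(c(0L, lens[-length(lens)])))
  set.seed(42)
  for (i in 1:5) {
    v <- runif(1, 0.16, 0.45)
    t_ex <- exp(runif(1, log(0.05), log(5)))
    r1f <- runif(7, 0.5, 10)
    rss_cpp <- waterex:::cpp_nmrd_rss(c(v, t_ex, r1f), tau, y, w, fs,
                                      as.integer(lens), r1ex_f,
                                      rep(TRUE, 7))
    rss_r <- r_nmrd_rss(v, t_ex, r1f, acqs, r1ex_f, w_list)
    expect_equal(rss_cpp, rss_r, tolerance = 1e-10)
  }
  # single-field reduction: the global objective on one curve is the
  # single-curve objective
  rss1 <- waterex:::cpp_nmrd_rss(c(0.3, 0.5, 2), acqs[[1]]$tau_s,
                                 acqs[[1]]$signal, w_list[[1]],
                                 0L, as.integer(lens[1]), r1ex_f[1], TRUE)
  expect_equal(rss1, r_nmrd_rss(0.3, 0.5, 2, acqs[1], r1ex_f[1], w_list[1]),
               tolerance = 1e-10)
})

test_that("noiseless global fits round-trip the shared parameters", {
  disp <- dispersion_truth()
  ds <- gen_nmrd_dataset(disp, v_ex = 0.30, k_io = 0.8, n_tau = 16,
                         noise = 0, seed = 1)
  fit <- fit_nmrd_global(ds, compute_se = FALSE)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["v_ex"]), 0.30, tolerance = 1e-3)
  tau_true <- 1 / influx_from_efflux(0.8, 0.30)
  expect_equal(unname(fit$estimates["tau_ex"]), tau_true, tolerance = 1e-3)
  # reported k_io is exactly the derived relation
  expect_equal(unname(fit$estimates["k_io"]),
               kio_from_tau_ex(unname(fit$estimates["tau_ex"]),
                               unname(fit$estimates["v_ex"])),
               tolerance = 1e-12)
  # per-field intracellular rates recovered too
  fields <- fit$dispersion$field_mhz
  expect_equal(fit$dispersion$r1_in, disp$r1_in_at(fields), tolerance = 1e-3)
  # dispersion profile r1_obs is bracketed by the slow/fast rates
  expect_true(all(fit$dispersion$r1_obs >= pmin(fit$dispersion$r1_in,
                                                fit$dispersion$r1_ex) - 1e-6))
})

test_that("dropping one field barely moves the over-determined shared
           parameters", {
  disp <- dispersion_truth()
  ds <- gen_nmrd_dataset(disp, v_ex = 0.30, k_io = 0.8, n_tau = 16,
                         noise = 0, seed = 2)
  fit7 <- fit_nmrd_global(ds, compute_se = FALSE)
  ds6 <- nmrd_dataset(ds$acquisitions[-4], ds$matrigel,
                      tissue_class = ds$tissue_class)
  fit6 <- fit_nmrd_global(ds6, compute_se = FALSE)
  expect_equal(unname(fit6$estimates["v_ex"]),
               unname(fit7$estimates["v_ex"]), tolerance = 1e-3)
  expect_equal(unname(fit6$estimates["tau_ex"]),
               unname(fit7$estimates["tau_ex"]), tolerance = 1e-3)
})

test_that("widening the volume-fraction bounds never worsens the optimum", {
  disp <- dispersion_truth()
  ds <- gen_nmrd_dataset(disp, v_ex = 0.30, k_io = 0.8, n_tau = 16,
                         noise = 0.02, seed = 3)
  narrow <- fit_nmrd_global(ds, v_ex_bounds = c(0.25, 0.35),
                            compute_se = FALSE)
  wide <- fit_nmrd_global(ds, v_ex_bounds = c(0.15, 0.5),
                          compute_se = FALSE)
  expect_lte(wide$rss, narrow$rss * (1 + 1e-8))
})

test_that("zero shutter-speed contrast leaves the lifetime unidentified,
           never confidently estimated", {
  # intracellular rates equal to the Matrigel rates at every field: the
  # decays carry no exchange information
  mg <- matrigel_default()
  flat <- dispersion_truth(amplitude = 1, nu_c = 0.3, offset = 0.5,
                           matrigel = mg)
  ds <- gen_nmrd_dataset(flat, v_ex = 0.30, k_io = 0.8, n_tau = 16,
                         noise = 0, seed = 4)
  fit <- fit_nmrd_global(ds)
  at_bound <- isTRUE(fit$active_bounds[["tau_ex"]]) ||
    isTRUE(fit$active_bounds[["v_ex"]])
  ci_width <- diff(fit$ci["tau_ex", ]) / max(fit$estimates[["tau_ex"]], 1e-6)
  expect_true(at_bound || !is.finite(ci_width) || ci_width > 10)
})

test_that("the bootstrap needs a seed and returns usable uncertainty", {
  disp <- dispersion_truth()
  ds <- gen_nmrd_dataset(disp, v_ex = 0.30, k_io = 0.8, n_tau = 12,
                         noise = 0.02, seed = 6)
  expect_error(fit_nmrd_global(ds, n_boot = 10), "seed")
  fit <- fit_nmrd_global(ds, n_boot = 25, seed = 11)
  expect_true(is.finite(fit$std_errors[["k_io"]]))
  expect_gt(fit$std_errors[["k_io"]], 0)
  expect_true(fit$ci["k_io", "lower"] <= fit$estimates[["k_io"]])
  expect_true(fit$ci["k_io", "upper"] >= fit$estimates[["k_io"]])
})

test_that("longitudinal summary reports cell means, exclusions and Welch
           contrasts", {
  mk_fit <- function(kio, vex, arm, tp, conv = TRUE) {
    waterex:::new_fit_result("nmrd_2sx_global",
                             estimates = c(k_io = kio, v_ex = vex),
                             std_errors = NULL, ci = NULL, rss = 0,
                             converged = conv, active_bounds = logical(),
                             n_obs = 10L, n_starts = 1L,
                             meta = list(arm = arm, timepoint = tp))
  }
  fits <- c(lapply(c(0.8, 0.9, 1.0), mk_fit, vex = 0.3, arm = "control",
                   tp = 0),
            lapply(c(0.8, 0.9, 1.0), mk_fit, vex = 0.3, arm = "treated",
                   tp = 0))
  s <- longitudinal_summary(fits)
  expect_equal(nrow(s), 2L)
  # identical arms: difference zero, p = 1
  expect_equal(s$mean_k_io[1], s$mean_k_io[2])
  expect_equal(s$p_k_io[s$arm == "treated"], 1)

  # non-converged fits are excluded and counted; sparse cells flagged
  fits2 <- c(fits, list(mk_fit(5, 0.4, "treated", 3, conv = FALSE),
                        mk_fit(0.7, 0.3, "control", 3),
                        mk_fit(0.75, 0.3, "control", 3)))
  s2 <- longitudinal_summary(fits2)
  tr3 <- s2[s2$arm == "treated" & s2$timepoint == 3, ]
  expect_equal(tr3$n, 0L)
  expect_equal(tr3$n_excluded, 1L)
  expect_true(grepl("omitted", tr3$note))
  expect_true(is.na(tr3$p_k_io))
})
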