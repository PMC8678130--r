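# Core two-site exchange machinery: parameter relations, closed-form
# eigensolution, forward signal models, numerical oracle.

test_that("population fractions and flux relations obey mass balance", {
  expect_equal(population_fractions(0.5), c(p_i = 0.5, p_o = 0.5))
  expect_equal(population_fractions(0.2), c(p_i = 0.8, p_o = 0.2))
  # lower bound of the tumor constraint range
  expect_equal(population_fractions(0.15), c(p_i = 0.85, p_o = 0.15))
  expect_error(population_fractions(0), "inside \\(0, 1\\)")
  expect_error(population_fractions(1), "inside \\(0, 1\\)")

  expect_equal(influx_from_efflux(2, 0.2), 8)
  expect_equal(influx_from_efflux(0, 0.3), 0)
  expect_equal(influx_from_efflux(5, 0.5), 5)

  expect_equal(kio_from_tau_ex(1, 0.5), 1)
  expect_equal(kio_from_tau_ex(0.5, 0.2), 0.5)
  expect_error(kio_from_tau_ex(0, 0.3), "positive")
  expect_error(kio_from_tau_ex(-1, 0.3), "positive")

  # inverse identity over a grid of (k, v)
  for (k in c(0.3, 2, 40)) {
    for (v in c(0.07, 0.2, 0.5, 0.9)) {
      expect_equal(kio_from_tau_ex(1 / influx_from_efflux(k, v), v), k,
                   tolerance = 1e-12)
      # detailed balance p_i k_io = p_o k_oi
      expect_equal((1 - v) * k, v * influx_from_efflux(k, v),
                   tolerance = 1e-12)
    }
  }
})

test_that("two_site_params derives populations, influx and lifetime", {
  p <- two_site_params(r1_in = 1, r1_ex = 30, k_io = 2, v_ex = 0.2)
  expect_equal(p$k_oi, 8)
  expect_equal(p$tau_ex, 1 / 8)
  expect_equal(p$p_i + p$p_o, 1)
  p0 <- two_site_params(1, 30, 0, 0.2)
  expect_identical(p0$tau_ex, Inf)
  expect_error(two_site_params(-1, 30, 2, 0.2), "> 0")
  expect_error(two_site_params(1, 30, -2, 0.2), ">= 0")
  expect_error(two_site_params(1, 30, 2, 1.2), "inside \\(0, 1\\)")
})

test_that("closed-form eigensolution matches the independent eigen oracle", {
  # reference case: values frozen from eigen() decomposition of the 2x2
  # exchange matrix and matrix-exponential propagation
  p <- two_site_params(r1_in = 1, r1_ex = 30, k_io = 2, v_ex = 0.2)
  sol <- exchange_eigensystem(p)
  expect_equal(sol$r1_fast, 38.451323071, tolerance = 1e-9)
  expect_equal(sol$r1_slow, 2.548676929, tolerance = 1e-9)
  expect_equal(sol$a_fast, 0.1184125274, tolerance = 1e-8)
  expect_equal(sol$a_slow, 1 - sol$a_fast)

  # recompute the oracle in place: eigen-decompose A and project the
  # population-proportional initial deviation onto its modes
  A <- matrix(c(-(1 + 2), 2, 8, -(30 + 8)), 2, 2)
  ev <- eigen(A)
  expect_equal(sort(-ev$values), sort(c(sol$r1_fast, sol$r1_slow)),
               tolerance = 1e-12)
  coef <- solve(ev$vectors) %*% (-2 * c(0.8, 0.2))
  amps <- colSums(ev$vectors) * as.vector(coef)
  a_fast_oracle <- amps[which.min(ev$values)] / sum(amps)
  expect_equal(sol$a_fast, a_fast_oracle, tolerance = 1e-10)
})

test_that("eigensolution limits: no exchange and equal intrinsic rates", {
  # k_io = 0: rates are intrinsic, amplitudes are population fractions
  sol0 <- exchange_eigensystem(two_site_params(1, 30, 0, 0.2))
  expect_equal(sol0$r1_fast, 30)
  expect_equal(sol0$r1_slow, 1)
  expect_equal(sol0$a_fast, 0.2)
  expect_equal(sol0$a_slow, 0.8)

  # equal intrinsic rates with exchange: conservation forces a_fast = 0,
  # the observed recovery is monoexponential at the common rate
  sole <- exchange_eigensystem(two_site_params(3, 3, 7, 0.3))
  expect_equal(sole$a_fast, 0, tolerance = 1e-12)
  expect_equal(sole$r1_slow, 3, tolerance = 1e-12)

  # true degeneracy (k_io = 0, equal rates): monoexponential limit, no error
  sold <- exchange_eigensystem(two_site_params(3, 3, 0, 0.3))
  expect_equal(sold$a_fast, 0)
  expect_equal(sold$r1_slow, 3)
})

test_that("conservation, trace and determinant identities hold", {
  sets <- rand_param_sets(200, seed = 11)
  for (i in seq_len(nrow(sets))) {
    s <- sets[i, ]
    p <- two_site_params(s$r1_in, s$r1_ex, s$k_io, s$v_ex)
    sol <- exchange_eigensystem(p)
    wmean <- p$p_i * p$r1_in + p$p_o * p$r1_ex
    expect_equal(sol$a_fast * sol$r1_fast + sol$a_slow * sol$r1_slow,
                 wmean, tolerance = 1e-12)
    expect_equal(sol$r1_fast + sol$r1_slow,
                 p$r1_in + p$r1_ex + p$k_io + p$k_oi, tolerance = 1e-12)
    expect_equal(sol$r1_fast * sol$r1_slow,
                 p$r1_in * p$r1_ex + p$r1_in * p$k_oi + p$r1_ex * p$k_io,
                 tolerance = 1e-12)
    expect_true(sol$a_fast >= 0 && sol$a_fast <= 1)
    expect_true(sol$r1_fast >= sol$r1_slow && sol$r1_slow > 0)
  }
})

test_that("inversion-recovery signal has the stated endpoints and matches
           matrix-exponential propagation", {
  p <- two_site_params(r1_in = 1, r1_ex = 30, k_io = 2, v_ex = 0.2)
  sol <- exchange_eigensystem(p)
  expect_equal(ir_signal(0, sol, m_inf = 1, inv_eff = 1), -1)
  expect_equal(ir_signal(0, sol, m_inf = 2, inv_eff = 0.8), -1.6)
  # equilibrium once r1_slow * tau >= 20
  tau_eq <- 20 / sol$r1_slow
  expect_equal(ir_signal(tau_eq, sol), 1, tolerance = 1e-8)

  tau <- exp(seq(log(1e-3), log(3), length.out = 25))
  pr <- propagate_numeric(p, -2 * c(p$p_i, p$p_o), tau)
  expect_lt(max(abs(ir_signal(tau, sol) - pr$total)), 1e-10)

  expect_error(ir_signal(numeric(0), sol), "empty")
  expect_error(ir_signal(c(-1, 1), sol), ">= 0")
  expect_error(ir_signal(1, sol, inv_eff = 0), "\\(0, 1\\]")
  expect_error(ir_signal(1, sol, inv_eff = 1.5), "\\(0, 1\\]")
})

test_that("field-cycling decay model covers PP/NP initial conditions", {
  p <- two_site_params(r1_in = 2, r1_ex = 6, k_io = 1.5, v_ex = 0.3)
  sol <- exchange_eigensystem(p)
  tau <- seq(0, 3, length.out = 40)

  # no evolution when start equals equilibrium
  expect_equal(ffc_decay_signal(tau, sol, m_start = 0.7, m_inf = 0.7),
               rep(0.7, 40))
  # NP build-up endpoints
  np <- ffc_decay_signal(c(0, 20 / sol$r1_slow), sol, m_start = 0, m_inf = 0.4)
  expect_equal(np[1], 0)
  expect_equal(np[2], 0.4, tolerance = 1e-8)
  # algebraic consistency with the inversion-recovery form:
  # m_start = -m_inf reproduces perfect inversion
  expect_equal(ffc_decay_signal(tau, sol, m_start = -1, m_inf = 1),
               ir_signal(tau, sol, m_inf = 1, inv_eff = 1), tolerance = 1e-14)
  # m_start = 2 m_inf mirrors the NP curve around equilibrium
  expect_equal(ffc_decay_signal(tau, sol, m_start = 2, m_inf = 1),
               2 - ffc_decay_signal(tau, sol, m_start = 0, m_inf = 1),
               tolerance = 1e-14)
})

test_that("effective monoexponential rate matches the scan oracle", {
  sol <- exchange_eigensystem(
    two_site_params(r1_in = 1, r1_ex = 30, k_io = 2, v_ex = 0.2))
  tau <- exp(seq(log(0.001), log(3), length.out = 32))
  r_obs <- effective_monoexp_r1(sol, tau)
  # frozen from the 200k-point scan + quadratic refine oracle
  expect_equal(r_obs, 3.2023053, tolerance = 1e-5)
  expect_equal(r_obs, scan_monoexp_rate(sol$r1_fast, sol$r1_slow,
                                        sol$a_fast, tau),
               tolerance = 1e-6)
  expect_true(r_obs >= sol$r1_slow && r_obs <= sol$r1_fast)

  # exact limits
  expect_equal(effective_monoexp_r1(biexp_solution(5, 2, 0), tau), 2)
  expect_equal(effective_monoexp_r1(biexp_solution(5, 2, 1), tau), 5)
  expect_error(effective_monoexp_r1(sol, c(1, 1, 1)), "distinct")
})

test_that("effective rate is monotone in the efflux rate constant", {
  tau <- exp(seq(log(0.01), log(3), length.out = 24))
  r_prev <- -Inf
  for (k in c(0, 0.3, 1, 3, 10, 30)) {
    sol <- exchange_eigensystem(two_site_params(1, 8, k, 0.25))
    r_obs <- effective_monoexp_r1(sol, tau)
    expect_gte(r_obs, r_prev - 1e-10)
    r_prev <- r_obs
  }
})

test_that("numerical propagation is exact for the decoupled system and
           agrees with an independent RK4 integrator", {
  # k_io = 0: compartments decay independently at their own rates
  p0 <- two_site_params(1.5, 7, 0, 0.3)
  tau <- c(0.05, 0.2, 1)
  pr <- propagate_numeric(p0, c(-1.4, -0.6), tau)
  expect_equal(pr$dev_in, -1.4 * exp(-1.5 * tau), tolerance = 1e-12)
  expect_equal(pr$dev_ex, -0.6 * exp(-7 * tau), tolerance = 1e-12)

  # initial slope of the total deviation equals the population-weighted
  # intrinsic relaxation (exchange terms cancel in the column sums)
  p <- two_site_params(1, 30, 2, 0.2)
  h <- 1e-6
  pr2 <- propagate_numeric(p, -2 * c(p$p_i, p$p_o), c(0, h))
  slope <- (pr2$total[2] - pr2$total[1]) / h
  expect_equal(slope, (p$p_i * p$r1_in + p$p_o * p$r1_ex) * 2,
               tolerance = 1e-4)

  # cross-check against fine-step RK4
  tau3 <- c(0.01, 0.1, 0.5)
  pr3 <- propagate_numeric(p, -2 * c(p$p_i, p$p_o), tau3)
  oracle <- rk4_total_signal(1, 30, 2, 0.2, -2 * c(0.8, 0.2), tau3)
  expect_equal(pr3$total, oracle, tolerance = 1e-9)

  expect_error(propagate_numeric(p, c(1, NA), 1), "finite")
})
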