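#' Biophysical parameters of a two-site water-exchange system
#'
#' Bundles the longitudinal relaxation rates of the intra- and extracellular
#' water pools, the cellular water efflux rate constant and the extracellular
#' volume fraction, together with the derived quantities used throughout the
#' package: population fractions (`p_i`, `p_o`), the influx rate constant
#' `k_oi` (tied to `k_io` by detailed balance, see [influx_from_efflux()]),
#' and the extracellular water lifetime `tau_ex = 1/k_oi`.
#'
#' Water population fractions are taken equal to volume fractions (uniform
#' water density and NMR visibility across compartments). `k_oi` is always
#' derived, never free: `p_i * k_io = p_o * k_oi` holds exactly.
#'
#' @param r1_in Intracellular longitudinal relaxation rate, s^-1 (> 0).
#' @param r1_ex Extracellular longitudinal relaxation rate, s^-1 (> 0).
#' @param k_io Cellular water efflux rate constant, s^-1 (>= 0).
#' @param v_ex Extracellular volume fraction, in (0, 1).
#' @param m_inf Equilibrium magnetization, arbitrary units (default 1).
#' @return An object of class `two_site_params`: a list with the supplied
#'   fields plus `p_i`, `p_o`, `k_oi` and `tau_ex` (`Inf` when `k_io = 0`).
#' @seealso [exchange_eigensystem()], [propagate_numeric()]
#' @examples
#' p <- two_site_params(r1_in = 1, r1_ex = 30, k_io = 2, v_ex = 0.2)
#' p$k_oi    # 8: detailed balance with p_i/p_o = 4
#' @export
two_site_params <- function(r1_in, r1_ex, k_io, v_ex, m_inf = 1) {
  check_scalar(r1_in, "r1_in", positive = TRUE)
  check_scalar(r1_ex, "r1_ex", positive = TRUE)
  check_scalar(k_io, "k_io", nonnegative = TRUE)
  check_scalar(m_inf, "m_inf")
  if (!is.numeric(v_ex) || length(v_ex) != 1L || !is.finite(v_ex) ||
      v_ex <= 0 || v_ex >= 1) {
    stop("`v_ex` must be a single number strictly inside (0, 1)", call. = FALSE)
  }
  p_i <- 1 - v_ex
  p_o <- v_ex
  k_oi <- k_io * p_i / p_o
  structure(
    list(r1_in = r1_in, r1_ex = r1_ex, k_io = k_io, v_ex = v_ex,
         m_inf = m_inf, p_i = p_i, p_o = p_o, k_oi = k_oi,
         tau_ex = if (k_oi > 0) 1 / k_oi else Inf),
    class = "two_site_params"
  )
}

#' @exportS3Method
print.two_site_params <- function(x, ...) {
  cat("Two-site exchange parameters\n")
  cat(sprintf("  r1_in = %g s^-1, r1_ex = %g s^-1\n", x$r1_in, x$r1_ex))
  cat(sprintf("  k_io  = %g s^-1 (k_oi = %g s^-1, tau_ex = %g s)\n",
              x$k_io, x$k_oi, x$tau_ex))
  cat(sprintf("  v_ex  = %g (p_i = %g, p_o = %g), m_inf = %g\n",
              x$v_ex, x$p_i, x$p_o, x$m_inf))
  invisible(x)
}

#' Water population fractions from the extracellular volume fraction
#'
#' Populations equal volume fractions under the package's uniform water
#' density assumption: `p_i = 1 - v_ex`, `p_o = v_ex`.
#'
#' @param v_ex Extracellular volume fraction, in (0, 1).
#' @return Named numeric vector `c(p_i = , p_o = )` summing to 1.
#' @examples
#' population_fractions(0.2)
#' @export
population_fractions <- function(v_ex) {
  if (!is.numeric(v_ex) || length(v_ex) != 1L || !is.finite(v_ex) ||
      v_ex <= 0 || v_ex >= 1) {
    stop("`v_ex` must be a single number strictly inside (0, 1)", call. = FALSE)
  }
  c(p_i = 1 - v_ex, p_o = v_ex)
}

#' Influx rate constant from the efflux rate constant
#'
#' Detailed balance of water flux across the membrane requires
#' `p_i * k_io = p_o * k_oi`, hence `k_oi = k_io * (1 - v_ex) / v_ex`.
#'
#' @param k_io Efflux rate constant, s^-1 (>= 0).
#' @param v_ex Extracellular volume fraction, in (0, 1).
#' @return Influx rate constant `k_oi`, s^-1.
#' @export
influx_from_efflux <- function(k_io, v_ex) {
  check_scalar(k_io, "k_io", nonnegative = TRUE)
  population_fractions(v_ex)  # validates v_ex
  k_io * (1 - v_ex) / v_ex
}

#' Efflux rate constant from the extracellular water lifetime
#'
#' `tau_ex` is the mean extracellular water lifetime, `1/k_oi`. Inverting
#' [influx_from_efflux()] gives `k_io = (1/tau_ex) * v_ex / (1 - v_ex)`.
#' This is the relation by which the multi-field global fit (which shares
#' `tau_ex`) reports the efflux biomarker.
#'
#' @param tau_ex Extracellular water lifetime, s (> 0).
#' @param v_ex Extracellular volume fraction, in (0, 1).
#' @return Efflux rate constant `k_io`, s^-1.
#' @export
kio_from_tau_ex <- function(tau_ex, v_ex) {
  if (!is.numeric(tau_ex) || length(tau_ex) != 1L || !is.finite(tau_ex) ||
      tau_ex <= 0) {
    stop("`tau_ex` must be a single positive number", call. = FALSE)
  }
  population_fractions(v_ex)
  (1 / tau_ex) * v_ex / (1 - v_ex)
}

# Vectorized closed form used by the R-side forward model. Returns a list of
# vectors (r1_fast, r1_slow, a_fast). The slow rate is computed from the
# determinant identity r1_fast * r1_slow = r1_in*r1_ex + r1_in*k_oi +
# r1_ex*k_io to avoid cancellation when the discriminant is close to the
# trace.
biexp_rates <- function(r1_in, r1_ex, k_io, v_ex) {
  p_i <- 1 - v_ex
  p_o <- v_ex
  k_oi <- k_io * p_i / p_o
  tr <- r1_in + k_io + r1_ex + k_oi
  dif <- r1_in + k_io - r1_ex - k_oi
  disc <- sqrt(dif^2 + 4 * k_io * k_oi)
  r1_fast <- (tr + disc) / 2
  r1_slow <- (r1_in * r1_ex + r1_in * k_oi + r1_ex * k_io) / r1_fast
  a_fast <- ifelse(disc <= 1e-14 * tr,
                   0,
                   (p_i * r1_in + p_o * r1_ex - r1_slow) / (r1_fast - r1_slow))
  degen <- disc <= 1e-14 * tr
  if (any(degen)) {
    # equal eigenvalues only when k_io = 0 and r1_in = r1_ex: monoexponential
    r1_slow[degen] <- tr[degen] / 2
    r1_fast[degen] <- tr[degen] / 2
  }
  list(r1_fast = r1_fast, r1_slow = r1_slow, a_fast = a_fast)
}

#' Closed-form biexponential solution of the two-site exchange system
#'
#' Longitudinal magnetization of two exchanging water pools relaxes as the
#' sum of two exponentials whose apparent rates are the eigenvalues of the
#' 2x2 exchange-relaxation matrix:
#' `2 R1(+/-) = (r1_in + k_io + r1_ex + k_oi) +/- sqrt((r1_in + k_io - r1_ex
#' - k_oi)^2 + 4 k_io k_oi)`, with the fast-component signal fraction
#' `a_fast = (p_i r1_in + p_o r1_ex - r1_slow) / (r1_fast - r1_slow)`.
#'
#' The amplitudes apply when the initial magnetization deviation is shared
#' by both pools in proportion to their populations, which is the case for
#' inversion-recovery, pre-polarized and non-polarized acquisitions alike.
#' In the degenerate equal-eigenvalue case (`k_io = 0` and `r1_in = r1_ex`)
#' the monoexponential limit is returned (`a_fast = 0`, common rate in
#' `r1_slow`) rather than an error, so that fit objectives stay continuous.
#'
#' @param params A [two_site_params()] object.
#' @return An object of class `biexp_solution`: list with `r1_fast`,
#'   `r1_slow` (s^-1, `r1_fast >= r1_slow`), `a_fast`, `a_slow`
#'   (`a_fast + a_slow = 1`).
#' @examples
#' p <- two_site_params(r1_in = 1, r1_ex = 30, k_io = 2, v_ex = 0.2)
#' exchange_eigensystem(p)
#' @export
exchange_eigensystem <- function(params) {
  stopifnot(inherits(params, "two_site_params"))
  b <- biexp_rates(params$r1_in, params$r1_ex, params$k_io, params$v_ex)
  biexp_solution(b$r1_fast, b$r1_slow, b$a_fast)
}

#' Construct a biexponential solution object
#'
#' Rarely needed directly; produced by [exchange_eigensystem()].
#'
#' @param r1_fast,r1_slow Apparent relaxation rates, s^-1,
#'   `r1_fast >= r1_slow > 0`.
#' @param a_fast Signal fraction of the fast component, in `[0, 1]`.
#' @return Object of class `biexp_solution`.
#' @export
biexp_solution <- function(r1_fast, r1_slow, a_fast) {
  stopifnot(is.numeric(r1_fast), is.numeric(r1_slow), is.numeric(a_fast),
            length(r1_fast) == 1L, length(r1_slow) == 1L,
            length(a_fast) == 1L)
  if (!(r1_slow > 0) || r1_fast < r1_slow) {
    stop("need r1_fast >= r1_slow > 0", call. = FALSE)
  }
  if (a_fast < -1e-12 || a_fast > 1 + 1e-12) {
    stop("`a_fast` must lie in [0, 1]", call. = FALSE)
  }
  a_fast <- min(max(a_fast, 0), 1)
  structure(list(r1_fast = r1_fast, r1_slow = r1_slow,
                 a_fast = a_fast, a_slow = 1 - a_fast),
            class = "biexp_solution")
}

#' @exportS3Method
print.biexp_solution <- function(x, ...) {
  cat(sprintf("Biexponential solution: r1_fast = %g, r1_slow = %g s^-1; a_fast = %g, a_slow = %g\n",
              x$r1_fast, x$r1_slow, x$a_fast, x$a_slow))
  invisible(x)
}

# common decay factor a_f exp(-Rf t) + a_s exp(-Rs t)
biexp_decay <- function(tau, solution) {
  solution$a_fast * exp(-solution$r1_fast * tau) +
    solution$a_slow * exp(-solution$r1_slow * tau)
}

#' Inversion-recovery signal of a two-site exchange system
#'
#' `s(tau) = m_inf * (1 - (1 + inv_eff) * (a_fast e^(-r1_fast tau) +
#' a_slow e^(-r1_slow tau)))`. With perfect inversion (`inv_eff = 1`) the
#' signal starts at `-m_inf` and recovers to `m_inf`.
#'
#' @param tau_s Delays, s (>= 0).
#' @param solution A [biexp_solution()].
#' @param m_inf Equilibrium magnetization, a.u.
#' @param inv_eff Inversion efficiency, in (0, 1].
#' @return Numeric vector of signals, same length as `tau_s`.
#' @export
ir_signal <- function(tau_s, solution, m_inf = 1, inv_eff = 1) {
  stopifnot(inherits(solution, "biexp_solution"))
  if (length(tau_s) == 0L) stop("empty tau grid", call. = FALSE)
  if (any(!is.finite(tau_s)) || any(tau_s < 0)) {
    stop("all tau values must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(inv_eff) || length(inv_eff) != 1L || inv_eff <= 0 ||
      inv_eff > 1) {
    stop("`inv_eff` must lie in (0, 1]", call. = FALSE)
  }
  m_inf * (1 - (1 + inv_eff) * biexp_decay(tau_s, solution))
}

#' Field-cycling decay/build-up signal of a two-site exchange system
#'
#' `s(tau) = m_inf + (m_start - m_inf) * (a_fast e^(-r1_fast tau) + a_slow
#' e^(-r1_slow tau))`. The pre-polarized sequence (PP) starts from
#' `m_start > m_inf` (magnetization built up at the higher polarization
#' field); the non-polarized sequence (NP) starts from `m_start = 0` and
#' builds up towards `m_inf` at the relaxation field.
#'
#' @inheritParams ir_signal
#' @param m_start Magnetization at `tau = 0`, a.u.
#' @return Numeric vector of signals.
#' @export
ffc_decay_signal <- function(tau_s, solution, m_start, m_inf) {
  stopifnot(inherits(solution, "biexp_solution"))
  if (length(tau_s) == 0L) stop("empty tau grid", call. = FALSE)
  if (any(!is.finite(tau_s)) || any(tau_s < 0)) {
    stop("all tau values must be finite and >= 0", call. = FALSE)
  }
  m_inf + (m_start - m_inf) * biexp_decay(tau_s, solution)
}

#' Best monoexponential rate approximating a biexponential decay
#'
#' Finds the rate `R` minimizing `sum_j (D(tau_j) - exp(-R tau_j))^2` where
#' `D` is the noiseless normalized biexponential decay — the single `R1`
#' value a per-field dispersion plot would report. The minimizing rate lies
#' in `[r1_slow, r1_fast]`.
#'
#' @param solution A [biexp_solution()].
#' @param tau_s At least 3 distinct non-negative delays, s.
#' @return Scalar effective rate, s^-1.
#' @export
effective_monoexp_r1 <- function(solution, tau_s) {
  stopifnot(inherits(solution, "biexp_solution"))
  tau_s <- as.numeric(tau_s)
  if (length(unique(tau_s)) < 3L) {
    stop("need at least 3 distinct tau values", call. = FALSE)
  }
  if (any(!is.finite(tau_s)) || any(tau_s < 0)) {
    stop("all tau values must be finite and >= 0", call. = FALSE)
  }
  if (solution$a_fast <= 0) return(solution$r1_slow)
  if (solution$a_fast >= 1) return(solution$r1_fast)
  d <- biexp_decay(tau_s, solution)
  obj <- function(r) sum((d - exp(-r * tau_s))^2)
  # coarse log grid guards against optimize() missing a narrow basin
  grid <- exp(seq(log(solution$r1_slow), log(solution$r1_fast),
                  length.out = 64))
  v <- vapply(grid, obj, numeric(1))
  i <- which.min(v)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  if (lo == hi) return(grid[i])
  optimize(obj, lower = lo, upper = hi,
           tol = .Machine$double.eps^0.5 * max(1, hi))$minimum
}

#' Matrix-exponential propagation of the two-site exchange system
#'
#' Brute-force reference solution used to validate the closed form: the
#' per-compartment magnetization deviation from equilibrium obeys
#' `d Delta / d tau = A Delta` with
#' `A = [[-(r1_in + k_io), k_oi], [k_io, -(r1_ex + k_oi)]]`,
#' propagated exactly by `expm(A tau)`. Intended for validation, not for
#' fitting (it is orders of magnitude slower than the closed form).
#'
#' @param params A [two_site_params()].
#' @param init_deviation Length-2 numeric: initial deviation from
#'   equilibrium of (intracellular, extracellular) magnetization, a.u. For
#'   an inversion-recovery experiment with efficiency `e` this is
#'   `-(1 + e) * m_inf * c(p_i, p_o)`.
#' @param tau_s Delays, s (>= 0).
#' @return A data frame with columns `tau_s`, `dev_in`, `dev_ex`
#'   (per-compartment deviations) and `total` (total signal,
#'   `m_inf + dev_in + dev_ex`).
#' @export
propagate_numeric <- function(params, init_deviation, tau_s) {
  stopifnot(inherits(params, "two_site_params"))
  if (length(init_deviation) != 2L || any(!is.finite(init_deviation))) {
    stop("`init_deviation` must be a finite length-2 numeric", call. = FALSE)
  }
  if (any(!is.finite(tau_s)) || any(tau_s < 0)) {
    stop("all tau values must be finite and >= 0", call. = FALSE)
  }
  A <- matrix(c(-(params$r1_in + params$k_io), params$k_io,
                params$k_oi, -(params$r1_ex + params$k_oi)),
              nrow = 2, ncol = 2)
  dev <- vapply(tau_s, function(t) {
    as.numeric(Matrix::expm(A * t) %*% init_deviation)
  }, numeric(2))
  data.frame(tau_s = as.numeric(tau_s),
             dev_in = dev[1, ], dev_ex = dev[2, ],
             total = params$m_inf + dev[1, ] + dev[2, ])
}

# internal scalar validators -------------------------------------------------

check_scalar <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (nonnegative && x < 0) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}
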