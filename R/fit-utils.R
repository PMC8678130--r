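# Shared fitting machinery: seeded RNG scope, numerical Jacobians,
# linearized standard errors, bound diagnostics, Welch tests, fit results.

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. All package randomness flows through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Central-difference Jacobian of a vector-valued function at x.
num_jacobian <- function(fn, x, eps = 1e-6) {
  f0 <- fn(x)
  J <- matrix(NA_real_, nrow = length(f0), ncol = length(x))
  for (j in seq_along(x)) {
    h <- eps * max(abs(x[j]), 1e-3)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

# Linearized standard errors from a residual Jacobian. Directions in which
# the Jacobian is numerically rank deficient (the parameter does not move
# the model) get infinite standard errors instead of a spuriously confident
# value.
se_from_jacobian <- function(J, rss, n_obs) {
  p <- ncol(J)
  dof <- max(n_obs - p, 1L)
  sigma2 <- rss / dof
  sv <- svd(J)
  tol <- max(sv$d) * 1e-8
  keep <- sv$d > tol
  if (!any(keep)) {
    return(list(se = rep(Inf, p), cov = matrix(Inf, p, p)))
  }
  dinv2 <- ifelse(keep, 1 / sv$d^2, 0)
  cov <- sigma2 * sv$v %*% (dinv2 * t(sv$v))
  se <- sqrt(pmax(diag(cov), 0))
  # rank-deficient directions: any parameter with weight on a dropped
  # singular vector is unidentified
  if (any(!keep)) {
    dead <- rowSums(sv$v[, !keep, drop = FALSE]^2) > 1e-6
    se[dead] <- Inf
  }
  list(se = se, cov = cov)
}

# Flags estimates sitting on a box bound (within a small fraction of the
# bound width).
active_bound_flags <- function(est, lower, upper, tol_frac = 1e-5) {
  width <- upper - lower
  width[!is.finite(width)] <- pmax(abs(est[!is.finite(width)]), 1)
  tol <- tol_frac * width
  (abs(est - lower) <= tol) | (abs(est - upper) <= tol)
}

# Welch two-sample test tolerant of degenerate (constant) groups.
welch_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  if (sd(x) == 0 && sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(list(statistic = 0, p_value = 1))
    }
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, p_value = 0))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value)
}

# Common fit-result container. `estimates` is a named numeric vector;
# std_errors/ci cover the subset with measured uncertainty.
new_fit_result <- function(model, estimates, std_errors, ci, rss, converged,
                           active_bounds, n_obs, n_starts, seed = NA,
                           warnings = character(), meta = list(),
                           extra = list()) {
  res <- c(list(model = model,
                estimates = estimates,
                std_errors = std_errors,
                ci = ci,
                rss = rss,
                converged = converged,
                reportable = isTRUE(converged),
                active_bounds = active_bounds,
                n_obs = n_obs,
                n_starts = n_starts,
                seed = seed,
                warnings = warnings,
                meta = meta),
           extra)
  structure(res, class = "waterex_fit")
}

#' @exportS3Method
print.waterex_fit <- function(x, ...) {
  cat(sprintf("<waterex_fit: %s>  converged: %s  n_obs: %d  RSS: %.4g\n",
              x$model, x$converged, x$n_obs, x$rss))
  show <- intersect(c("k_io", "tau_ex", "v_ex", "r1_in", "m_inf", "inv_eff"),
                    names(x$estimates))
  for (nm in show) {
    se <- if (nm %in% names(x$std_errors)) x$std_errors[[nm]] else NA
    flag <- if (isTRUE(x$active_bounds[nm])) " [at bound]" else ""
    cat(sprintf("  %-8s %.5g (se %.3g)%s\n", nm, x$estimates[[nm]], se, flag))
  }
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  if (!x$reportable) cat("  NOTE: fit did not converge; estimates are not reportable\n")
  invisible(x)
}

# Multi-start bounded least squares driver. starts: list of named numeric
# vectors (same names/order as lower/upper). Ties in the objective are
# broken by the value of tie_break_on (smallest wins) when given.
multistart_optim <- function(starts, fn, lower, upper, parscale,
                             tie_break_on = NULL, control = list()) {
  best <- NULL
  trace <- vector("list", length(starts))
  # ndeps default (1e-3) limits achievable precision through gradient
  # truncation error; 1e-5 reaches the noiseless optimum to ~1e-7.
  ctrl <- modifyList(list(maxit = 1000L, factr = 1e3, ndeps = 1e-5), control)
  for (i in seq_along(starts)) {
    p0 <- pmin(pmax(starts[[i]], lower), upper)
    res <- tryCatch(
      optim(p0, fn, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = ctrl$maxit, factr = ctrl$factr,
                           parscale = parscale,
                           ndeps = rep(ctrl$ndeps, length(p0)))),
      error = function(e) NULL)
    trace[[i]] <- list(start = p0,
                       value = if (is.null(res)) NA_real_ else res$value,
                       convergence = if (is.null(res)) 99L else res$convergence)
    if (is.null(res)) next
    if (is.null(best)) {
      best <- res
    } else {
      rel <- abs(res$value - best$value) / max(best$value, 1e-300)
      better <- res$value < best$value && rel > 1e-10
      tie <- rel <= 1e-10
      if (better) {
        best <- res
      } else if (tie && !is.null(tie_break_on) &&
                 res$par[[tie_break_on]] < best$par[[tie_break_on]]) {
        best <- res
      }
    }
  }
  list(best = best, trace = trace,
       converged = !is.null(best) && best$convergence == 0L)
}
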