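---
title: "Two-site water-exchange relaxometry: model, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-site water-exchange relaxometry: model, fitting and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waterex)
```

## The model

Tissue water lives in two exchanging pools — intracellular (volume
fraction $v_{in} = 1 - v_{ex}$, longitudinal relaxation rate $R_{1in}$)
and extracellular ($v_{ex}$, $R_{1ex}$) — coupled by transcytolemmal
exchange with efflux rate constant $k_{io}$ (the inverse of the mean
intracellular water lifetime) and influx rate constant $k_{oi}$. The
longitudinal magnetization deviation from equilibrium,
$\Delta = (\Delta_{in}, \Delta_{ex})$, obeys the coupled linear
(Bloch–McConnell) system

$$\frac{d\Delta}{d\tau} = A\,\Delta,\qquad
A = \begin{pmatrix} -(R_{1in}+k_{io}) & k_{oi} \\
                     k_{io} & -(R_{1ex}+k_{oi})\end{pmatrix},$$

whose solution is biexponential in the total observed signal. The
apparent rates are the (negated) eigenvalues of $A$,

$$2R_1^{\pm} = (R_{1in}+k_{io}+R_{1ex}+k_{oi}) \pm
\sqrt{(R_{1in}+k_{io}-R_{1ex}-k_{oi})^2 + 4\,k_{io}k_{oi}},$$

and when the initial deviation is shared by the pools in proportion to
their populations (true for inversion recovery and for both
field-cycling preparations), the fast-component signal fraction is

$$a_{fast} = \frac{p_i R_{1in} + p_o R_{1ex} - R_1^{-}}{R_1^{+}-R_1^{-}},
\qquad a_{slow} = 1 - a_{fast}.$$

`exchange_eigensystem()` implements this closed form;
`propagate_numeric()` implements the matrix-exponential solution of the
same system and serves as the package's internal oracle — the test suite
checks agreement to better than $10^{-8}$ over a thousand random
parameter sets, alongside the conservation identity
$a_{fast}R_1^{+} + a_{slow}R_1^{-} = p_iR_{1in} + p_oR_{1ex}$ and the
trace/determinant identities, at $10^{-12}$.

Assumptions worth stating:

* **Populations equal volume fractions.** Water density and NMR
  visibility are taken uniform across compartments, so $p_i = v_{in}$,
  $p_o = v_{ex}$. This is the simplest closure consistent with using
  $v_{ex}$ interchangeably as a population and a volume fraction.
* **Detailed balance is structural.** $k_{oi}$ is never a free
  parameter: $p_i k_{io} = p_o k_{oi}$ always, so
  $k_{oi} = k_{io}(1-v_{ex})/v_{ex}$ and
  $\tau_{ex} = 1/k_{oi}$. This removes a non-identifiable degree of
  freedom from every fit.
* **Degenerate eigenvalues return the monoexponential limit** rather
  than raising an error, keeping fit objectives continuous. True
  degeneracy occurs only at $k_{io}=0$ with $R_{1in}=R_{1ex}$.
* Units throughout: rates in s$^{-1}$, delays in s, fields in MHz proton
  Larmor frequency (1 T $\approx$ 42.577 MHz).

The exchange measurement is only informative under the *shutter-speed
condition*: the rate difference $|R_{1in}-R_{1ex}|$ must be comparable
to or larger than $k_{io}+k_{oi}$. In vitro this contrast is created by
a gadolinium agent confined to the extracellular space
(`r1ex_with_agent()`: $R_{1ex}$ rises linearly with concentration); in
vivo it arises intrinsically at very low magnetic fields, which is why
the in-vivo analysis uses fast field-cycling acquisitions between 0.01
and 1 MHz.

## The in-vitro fit

`fit_ir_2sx()` fits the signed inversion-recovery signal

$$s(\tau) = M_\infty\left[1 - (1+\eta)\left(a_{fast}e^{-R_1^{+}\tau} +
a_{slow}e^{-R_1^{-}\tau}\right)\right]$$

by unweighted least squares (the pellet acquisition noise is well
approximated as additive and homoscedastic), with $R_{1ex}$ fixed from
the agent specification or a supernatant measurement and, by default,
$(k_{io}, R_{1in}, v_{ex}, M_\infty, \eta)$ free inside box bounds.
A deterministic multi-start grid ($\eta \in \{0.8, 1\}$,
$k_{io} \in \{0.5, 5, 50\}$ s$^{-1}$, $v_{ex} \in \{0.1, 0.3\}$) guards
against local minima; ties are broken towards the smallest $k_{io}$.
Default bounds — $k_{io} \in [0, 200]$ s$^{-1}$,
$v_{ex} \in [0.01, 0.6]$, $\eta \in [0.5, 1]$ — describe physically
plausible pellet geometry and are all configurable.

### Identifiability, and why the recovery experiment fixes $v_{ex}$

With all five parameters free, $k_{io}$, $R_{1in}$ and $v_{ex}$ are
nearly collinear in their effect on a single inversion-recovery curve.
The linearized information analysis below makes this concrete: it
computes the Cramér–Rao lower bound on the $k_{io}$ standard error at
the reference pellet conditions (64 log-spaced delays, $R_{1ex} = 35.5$
s$^{-1}$, 1% noise), first with all five parameters free, then with
$v_{ex}$ known.

```{r crb}
tau <- exp(seq(log(1e-3), log(5), length.out = 64))
crb_kio <- function(free, p0 = c(5, 0.6, 0.2, 1, 1), noise = 0.01) {
  model <- function(p) {
    sol <- exchange_eigensystem(two_site_params(
      r1_in = p[2], r1_ex = 35.5, k_io = p[1], v_ex = p[3]))
    ir_signal(tau, sol, m_inf = p[4], inv_eff = p[5])
  }
  J <- sapply(free, function(j) {
    h <- 1e-6 * max(abs(p0[j]), 1e-3)
    pp <- pm <- p0; pp[j] <- p0[j] + h; pm[j] <- p0[j] - h
    (model(pp) - model(pm)) / (2 * h)
  })
  noise * sqrt(solve(crossprod(J))[1, 1])
}
c(all_free = crb_kio(1:5), v_ex_known = crb_kio(c(1, 2, 4, 5)))
```

The bound with everything free is several times too wide for $k_{io}$
to be a useful per-sample measurement, and no estimator can beat it;
with $v_{ex}$ known it tightens by almost an order of magnitude. Since
the pellet extracellular fraction is set by the preparation
(centrifugation) and can be measured independently, the package's
parameter-recovery experiment — and our recommendation for real pellet
data — fixes $v_{ex}$ via the `fixed` argument while keeping the
all-free fit available as the default API. Even so, recovery degrades
as exchange gets fast: once $k_{io}+k_{oi}$ exceeds the
$|R_{1in}-R_{1ex}|$ contrast (around $k_{io} \approx 20$ s$^{-1}$ at
these conditions) the shutter-speed condition fails and the information
bound itself exceeds a 10% target. The acceptance suite asserts the
target at every truth value regardless, so that regime shows up as an
expected, documented failure rather than being quietly excluded.

Per-fit uncertainties are linearized (Jacobian) standard errors;
directions in which the Jacobian is numerically rank-deficient get
infinite standard errors instead of spuriously confident values, which
is how a zero-contrast dataset reports "unidentifiable". Estimates
sitting on a bound are flagged (`active_bounds`), and a fit whose fixed
$R_{1ex}$ lands within 3$\times$ of the fitted $R_{1in}$ records an
identifiability warning.

## The in-vivo global fit

`fit_nmrd_global()` fits all per-field decays of one subject
simultaneously under

$$s_f(\tau) = M_{\infty,f} + (M_{0,f} - M_{\infty,f})
\left(a_{fast,f}e^{-R^{+}_{1,f}\tau} + a_{slow,f}e^{-R^{-}_{1,f}\tau}\right),$$

sharing $v_{ex}$ and $\tau_{ex}$ across fields, with one free
$R_{1in}(f)$ per field (no dispersion shape is imposed on it), and
$R_{1ex}(f)$ fixed to the Matrigel phantom table interpolated linearly
in $\log f$ (profiles are conventionally viewed on log-frequency axes;
the rule is exact at table nodes and refuses to extrapolate). The
pre-polarized (PP) preparation has $M_0 > M_\infty$, the non-polarized
(NP) one $M_0 = 0$; all seven analysis fields ($\le 1$ MHz) default to
PP, matching the relaxometer's sequence switch-over. The efflux
biomarker is reported as
$k_{io} = v_{ex}/[(1-v_{ex})\,\tau_{ex}]$, exactly consistent with the
shared parameters by construction.

Numerical choices:

* **Amplitudes are profiled out (variable projection).** For fixed
  nonlinear parameters the model is linear in
  $(M_{\infty,f}, M_{0,f})$, so each objective evaluation solves those
  2$\times$2 weighted least-squares problems exactly. The amplitudes
  remain genuinely free per acquisition — the relaxometer's gain
  differs between segments — but the optimizer only sees $2 + F$
  nonlinear parameters, which makes the thousands of fits in the
  simulation studies tractable.
* **Weighted objective.** The default weights are $1/s^2$ (relative
  residuals, floored at 1% of each curve's maximum), matching the
  relaxometer's constant-percentage amplitude uncertainty. This is not
  cosmetic: with unweighted residuals the large early-decay amplitudes
  drown out the low-signal tails that carry most of the exchange
  information, and $k_{io}$ recovery degrades several-fold.
  `weights = "none"` restores plain least squares.
* **Constraints.** $v_{ex}$ is box-constrained to literature
  physiological ranges by tissue class — $(0.09, 0.19)$ for healthy
  mouse hind limb, $(0.15, 0.5)$ for tumor — and estimates pinned at a
  bound are flagged rather than hidden, mirroring constrained-fit
  practice.
* **Optimization.** Bounded quasi-Newton (`L-BFGS-B`) from a
  deterministic grid of $(v_{ex}, \tau_{ex})$ starts, with per-field
  rates initialized from each curve's $1/e$ crossing. The
  finite-difference step is tightened to $10^{-5}$ (the `optim`
  default of $10^{-3}$ stalls noiseless round trips at $\sim 10^{-4}$
  relative through gradient truncation error).
* **Uncertainties.** Linearized standard errors by default, with
  $k_{io}$ by the delta method from the $(v_{ex}, \tau_{ex})$
  covariance. A per-curve residual bootstrap (`n_boot`, seed required)
  is available and preferable near active bounds, but is too slow to be
  the default inside Monte-Carlo studies that refit thousands of
  datasets.

`effective_monoexp_r1()` reduces a fitted biexponential to the single
best least-squares monoexponential rate on the acquisition's own delay
grid — the scalar that a dispersion profile plot reports per field —
and the fit result carries a ready-made `dispersion` table
(field, $R_{1in}$, $R_{1ex}$, $R_{1,obs}$).

## The synthetic world

No measured data ship with the package, so the generators emulate the
study's acquisition structure with known ground truth embedded in every
object's metadata:

* `gen_ir_dataset()`: 64 log-spaced delays in $[10^{-3}, 5]$ s, additive
  Gaussian noise (default SD 1% of $M_\infty$) on the signed signal;
  Rician magnitude folding available but off by default, since only a
  percentage-level uncertainty is stated for the instrument.
* `gen_nmrd_dataset()`: the seven standard fields (0.01–1 MHz), 32
  log-spaced delays per curve with the longest delay drawn per field
  from 2.8–4 s, multiplicative Gaussian noise (default 2%, the stated
  instrument uncertainty). The intracellular dispersion truth is a
  Lorentzian-plus-offset template
  $R_{1in}(\nu) = A/(1+(\nu/\nu_c)^2) + B$ with defaults $A = 6$
  s$^{-1}$, $\nu_c = 0.1$ MHz, $B = 1.5$ s$^{-1}$ — a smooth, decreasing
  profile of realistic low-field magnitude. The shipped Matrigel table
  is likewise a synthetic Lorentzian template. Both are stand-ins for
  phantom/tissue measurements that exist only in the authors' earlier
  work, and both are labelled `synthetic` in manifests. Signals are
  normalized to the polarized magnetization, so $M_0 = 1$ and
  $M_\infty = f/13$ (polarization at 13 MHz).
* `gen_cohort()`: two arms of 7 animals, timepoints at days 0, 3, 6, 9
  (baseline plus three days after each of three treatments). The
  treated-arm defaults encode the expected pharmacodynamics: $k_{io}$
  multiplier $(1, 0.6, 1, 1)$ — a 40% drop at the first post-treatment
  point, returning to baseline — and $v_{ex}$ multiplier
  $(1, 0.85, 1.15, 1.3)$ — an initial decrease followed by a rise as
  cell death permeabilizes membranes. The in-vivo baseline
  ($k_{io} = 0.8$ s$^{-1}$) is $\sim$25-fold below the in-vitro pellet
  scale, reflecting the reported in-vivo reduction. Between-animal
  variability is lognormal with 25% CV on $k_{io}$ and Gaussian SD 0.04
  on $v_{ex}$ (clamped to stay inside the tumor bounds), chosen to
  produce group SDs of realistic visual magnitude without asserting
  unpublished numbers. Each animal's random effect is drawn once and
  carried across its timepoints.

What a green simulation establishes — and what it does not: the
generators share the package's own forward model (a test asserts the
noiseless output is bit-identical to it), so round-trip recovery
validates the estimation machinery, not the biophysical model itself.
Features of real data deliberately absent include field-switching
transients, $B_1$/coil inhomogeneity, physiological drift and motion,
partial-volume mixtures beyond two sites, and any field dependence of
the extracellular rate other than the phantom template.

## Cohort statistics

`dose_response_table()` and `longitudinal_summary()` report group
mean $\pm$ SD per cell and Welch two-sample tests (treated vs control,
or dose vs zero dose), excluding and counting non-converged fits, and
omitting contrasts for cells with fewer than two converged fits. The
degenerate case of two identical constant groups is defined to give
statistic 0 and $p = 1$. Under the simulated null (equal arms), the
empirical type-I error of the fitted-$k_{io}$ Welch test at nominal
0.05 is verified to lie in $[0.02, 0.09]$ over 500 seeded cohorts, and
the 40% effect at $n = 7$/arm is detected with $\ge 80$% power — both
computed by the acceptance suite, at reduced per-curve delay counts (12
rather than 32) purely for runtime.

## Known limitations

* Transverse ($T_2$) exchange effects, more than two compartments, and
  radiofrequency pulse imperfections beyond a scalar inversion
  efficiency are out of scope.
* The agent model is linear inner-sphere relaxivity; agent leakage into
  cells during the measurement window is not modelled.
* $R_{1in}(f)$ is fitted independently per field; the optional
  smoothness penalty across fields was considered and rejected as a
  default because the shared-parameter structure already
  over-determines $(v_{ex}, \tau_{ex})$ (removing any single field
  moves them by $<10^{-3}$ in the noiseless round trip).
* In the fast-exchange regime the efflux rate is intrinsically poorly
  determined (see the information analysis above); the package reports
  honest wide or infinite standard errors there rather than refusing to
  fit.
* Animal temperature is carried as metadata only; no temperature
  correction is applied.
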