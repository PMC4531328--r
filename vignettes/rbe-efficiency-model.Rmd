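---
title: "An energy-transfer efficiency model for ion-beam RBE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An energy-transfer efficiency model for ion-beam RBE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbelet)
```

## The model and its assumptions

`rbelet` predicts the relative biological effectiveness (RBE) of a
charged-particle beam from four inputs: the ion charge $Z$, the linear
energy transfer $LET_x$ (keV/µm), the dose (or target surviving
fraction), and the linear-quadratic (LQ) radiosensitivities
$\alpha_L$ (Gy$^{-1}$), $\beta_L$ (Gy$^{-2}$) of the tissue under the
low-LET reference radiation. It rests on three assumptions, each an
empirical regularity of published multi-ion survival experiments:

1. **Saturation of the turnover LET with charge.** The LET at which cell
   killing per gray is maximal, $LET_U$, increases with $Z$ but with
   diminishing increments. Treating $Z$ as continuous, the rate equation
   $dLET_U/dZ = S - k\,LET_U$ integrates to
   $$LET_U(Z) = LET_U(1) + \frac{S}{k}\left(1 - e^{-k(Z-1)}\right),$$
   anchored at the proton value $LET_U(1) = 30.5$ keV/µm.

2. **Saturation of the turnover radiosensitivities.** The maximum
   radiosensitivities $\alpha_U$, $\beta_U$ attained at $LET_U$ saturate
   with their low-LET counterparts: radio-resistant systems (small
   $\alpha_L$) gain the most. For $\alpha$ the default is the linear
   no-intercept ion-beam regression $\alpha_U = 6.47\,\alpha_L$ (valid
   below $\alpha_L \approx 0.35$ Gy$^{-1}$); a nonlinear form
   $\alpha_U = (A/j)(1 - e^{-j\alpha_L})$ is available but requires
   user-supplied constants, because no ion-beam values of $A$, $j$ are
   published and this package does not invent them. For $\beta$ the
   default is nonlinear, $\beta_U = (R/u)(1 - e^{-u\beta_L})$ with
   $R = 2.5$, $u = 25$, i.e. a ceiling of $R/u = 0.1$ Gy$^{-2}$; a
   constant mode $\beta_U = \beta_L$ is provided for low-dose work where
   $\beta$-mediated kill is negligible. Fast-neutron regression presets
   ship in `neutron_presets()` but are flagged as unusable for ion-beam
   RBE: the neutron LET spectrum does not sit at the ion turnover point,
   so its maxima underestimate $\alpha_U$, $\beta_U$.

3. **Symmetry of the LET response in $\alpha$ and $\beta$.** Both
   coefficients are scaled along LET by the *same* efficiency function
   with the *same* $LET_U$. This is what keeps the position of the RBE
   peak independent of dose and survival level, as observed; if
   $\alpha$ and $\beta$ turned over at different LETs the peak would
   drift with dose.

The efficiency itself is biphasic. Below the turnover it rises linearly
from 0 at the control LET $LET_C$ to 1 at $LET_U$:
$$\mathrm{eff}(LET_x) = \frac{LET_x - LET_C}{LET_U - LET_C},
  \qquad LET_C \le LET_x \le LET_U,$$
and $\alpha_H = \alpha_L + \mathrm{eff}\cdot(\alpha_U - \alpha_L)$
(likewise $\beta_H$). Above the turnover, energy beyond $LET_U$ is
wasted ("overkill") and efficiency declines; see *Numerical and design
choices* for the exact form. RBE at dose $d_H$ then follows from the LQ
iso-effect equation
$\alpha_L d_L + \beta_L d_L^2 = \alpha_H d_H + \beta_H d_H^2$, solved
for $d_L$ by the positive quadratic root, with the closed-form dose
limits $RBE_{max} = \alpha_H/\alpha_L$ and
$RBE_{min} = \sqrt{\beta_H/\beta_L}$. Fractionation iso-effects equate
biologically effective doses:
$$n\,d_L\!\left(1 + \frac{d_L}{(\alpha/\beta)_L}\right)
  = m\,d_H\!\left[RBE_{max} + RBE_{min}^2\,
    \frac{d_H}{(\alpha/\beta)_L}\right].$$
The right-hand side is the standard high-LET BED; it is the only
dimensionally consistent reading of the relation and the one this
package implements.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `anchor_let` | keV/µm | 30.5 | proton turnover LET anchoring the $Z$ relation |
| `S`, `k` | keV/µm per unit $Z$; per unit $Z$ | fitted | no published values; calibrated at first use to the bundled table (see below) |
| `alpha_c` | – | 6.47 | published ion-beam no-intercept slope, $\alpha_L < 0.35$ Gy$^{-1}$ |
| `R`, `u` | –, Gy$^2$ | 2.5, 25 | published $\beta$ saturation; ceiling 0.1 Gy$^{-2}$ |
| `let_c` | keV/µm | 1.2 | representative megavoltage-photon LET; no canonical value exists, so it is configurable |
| `post_turnover` | – | `"reciprocal"` | see below |

The bundled calibration table (`z_letu_calibration()`) holds the four
ion species whose turnover points the pooled experimental literature
localises acceptably: protons 30.5, helium 103.4, carbon 208 and neon
233 keV/µm. Fitting the anchored relation to it gives
$k \approx 0.423$, $S/k \approx 205$, hence predicted turnover LETs of
about 211 (carbon), 231 (neon) and 236 (argon) keV/µm:

```{r calibration}
cal <- z_letu_calibration()
fit <- fit_z_saturation(cal$z, cal$let_u)
fit$params
round(predict(fit, c(6, 10, 18)))
```

These fitted constants are the package defaults wherever a `model_config`
leaves `S`, `k` unset. They are a calibration, not published constants,
and refitting with better data is a one-liner.

## Numerical and design choices

**Post-turnover efficiency.** The biphasic model admits two readings of
the decline beyond $LET_U$. The displayed inefficiency formula,
$1 - (LET_x - LET_U)/LET_U$, goes negative beyond $2\,LET_U$ —
an unphysical $\alpha_H$ below $\alpha_L$ and eventually below zero.
The worked numerical examples of the source model instead divide the
wasted energy by $LET_x$, giving
$\mathrm{eff} = LET_U/LET_x$: a reciprocal decline to zero that matches
the physical picture (track count per cell falls reciprocally with LET
at fixed dose). The reciprocal form is the default; `"strict"`
reproduces the displayed formula with efficiency clamped at 0. Both
equal 1 exactly at $LET_U$, so the curve is continuous there (the kink
in the derivative is accepted). Below $LET_C$ the model is undefined
and evaluation is an error rather than an extrapolation.

**Solvers.** The LQ and BED equations are quadratics in the unknown
dose; the positive root is taken in closed form and back-substitution
is tested to 1e-10 relative. The test suite cross-checks both solvers
against bisection oracles (1e-9 Gy over 1000 random parameter draws for
the LQ solver).

**Fitting.** All saturation fits profile the residual sum of squares
down to one dimension: for a fixed rate constant the optimal amplitude
is a closed-form linear solve, so the scan is over the rate alone — a
log-spaced grid from $10^{-3}$ to $10^2$ (161 points) followed by a
bracketed golden-section/parabolic polish (tolerance 1e-12). The grid's
upper end is set an order of magnitude above the largest rate constant
the model works with ($u = 25$), so no realistic fit can pin at the
edge; an edge solution is still flagged `converged = FALSE` rather than
silently returned. The scheme is fully deterministic — no starting
values, no stochastic restarts — and the profiled optimum is the exact
joint least-squares optimum. The proton anchor is held fixed during
$Z$-fits, matching the anchored construction of the relation;
`fix_anchor = FALSE` frees it as a second linear coefficient. Fits are
unweighted by default; per-point weights are accepted. LQ survival
curves are fitted on the log scale ($-\ln SF$ regressed on $d$ and
$d^2$ without intercept), the standard radiobiology practice, with both
coefficients bounded at zero (L-BFGS-B refinement from the clamped
unconstrained solution when a bound is active; coefficients within
1e-12 of the bound are snapped to exactly zero).

**Degenerate inputs.** Surviving fraction 1 in `rbe_at_sf()` returns
the analytic zero-dose limit $RBE_{max}$, flagged `limit = TRUE`,
because the low-dose envelope is needed when tabulating RBE against
survival level; all-unity survival data, coincident doses, and
underdetermined calibrations are validation errors with condition class
`rbelet_validation_error` (the CLI maps them to exit code 2, and
numerical non-convergence to 3).

## The synthetic survival generator

`generate_synthetic_survival()` stands in for unpublished raw
clonogenic data. It emulates an LQ assay: true survival
$e^{-\alpha d - \beta d^2}$ at each dose, perturbed per replicate by
mean-preserving multiplicative lognormal noise whose coefficient of
variation is the `noise_cv` argument ($\sigma = \sqrt{\log(1+cv^2)}$,
factor $e^{\sigma Z - \sigma^2/2}$) — the natural noise structure for
a ratio of colony counts. A seed is mandatory whenever noise is
requested, so every simulated table is reproducible. What it does *not*
emulate: Poisson colony-counting error at low survival, plating
efficiency drift between experiments, LET-spectrum mixing within a
beam, or between-laboratory assay differences. Passing recovery tests
on this generator therefore shows the fitters are correct and
well-calibrated under clean multiplicative noise, not that real
historical data sets would be recovered equally well.

## Problem sizes

The property tests run 1000 random draws against the LQ bisection
oracle, 100-200 draws for the BED round-trip and monotonicity checks,
25-50 draws for the turnover-position invariants on grids of a few
thousand LET points, and 200 replicate fits for the bias check of the
LQ fitter — sizes chosen so the full suite completes in well under a
minute while keeping Monte-Carlo standard errors far below the asserted
tolerances.

## Known limitations

* Single effective LET per calculation: no dose-averaged versus
  track-averaged distinction and no mixed-LET spectra, so clinical
  spread-out Bragg peaks need an external effective-LET reduction.
* The linear $\alpha_U$ scaling is a regression valid below
  $\alpha_L \approx 0.35$ Gy$^{-1}$; outside that range supply nonlinear
  constants or pin $\alpha_U$ directly.
* Well-oxygenated cells only; hypoxia modifies the underlying
  radiosensitivities and is out of scope.
* The four-point turnover calibration is sparse and pooled across
  laboratories and cell systems; individual data sets can prefer
  different turnover LETs (alpha particles fitted alone suggest a
  higher value than the pooled $Z$ relation yields for helium), and the
  model is sensitive to its LQ inputs. It is a second-order check, not
  a replacement for mechanistic treatment-planning models.
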