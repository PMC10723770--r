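---
title: "Methods: recruitability from sequential EELV measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recruitability from sequential EELV measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recrin)
```

## The measurement model

A decremental PEEP trial ventilates the patient at PEEP 15, 13, 10, 8 and
5 cm H2O. At every step the ventilator reports plateau pressure, total PEEP,
tidal volume and the end-expiratory lung volume (EELV) by nitrogen dilution,
measured twice (wash-out and wash-in). The package treats each step as:

- driving pressure $\Delta P = P_{plat} - PEEP_{tot}$,
- respiratory-system compliance $C_{rs} = V_T / \Delta P$,
- EELV = wash-pair mean, accepted only when the pair differs by less than
  20% of the mean.

A single slow breath from PEEP 5 to 0 measures the volume held by 5 cm H2O of
PEEP ($V_{PEEP5}$ = exhaled − inspired $V_T$), giving the functional residual
capacity $FRC = EELV_{PEEP5} - V_{PEEP5}$ without ventilating at zero PEEP,
which is avoided because derecruitment at ZEEP can be dangerous in ARDS.

Over a PEEP range the EELV change splits exactly into predicted inflation and
recruitment:

$$V_{REC} = (EELV_{high} - EELV_{low}) - (PEEP_{high} - PEEP_{low})\,C_{rs,low},$$

$$C_{rec} = \frac{V_{REC}}{\Delta PEEP}, \qquad
R/I = \frac{C_{rec}}{C_{rs,low}}.$$

The R/I ratio measures how much volume PEEP recruits per unit of the volume
it would inflate into the already-open ("baby") lung. It is computed globally
(15 → 5) and granularly (15 → 13, 13 → 10, 10 → 8, 8 → 5, 5 → 0). The 5 → 0
range has no measured compliance at ZEEP; the package substitutes the PEEP-5
compliance and flags the row `crs_substituted`. Whether that range enters the
fit is configurable (`include_zeep_step`, default `TRUE`: the extra low-PEEP
point anchors the linear coefficient and the protocol measures it anyway).

Strain indices at each PEEP level use the aerated volume
$A(p) = FRC + \text{cumulative } V_{REC}$ from ZEEP up to $p$: dynamic strain
$V_T/A$, static strain $(EELV(p) - A(p))/A(p)$, total strain their sum.
Reading "recruitment at a PEEP level" as cumulative recruitment from ZEEP
makes static strain identically 0 at ZEEP, as it must be.

Two deliberate data-handling choices: pairs failing the 20% rule invalidate
the step and every range that touches it (conservative propagation rather
than silent averaging), and negative recruited volumes are retained and
flagged rather than clipped — clipping would bias cohort medians upward.

## The R/I-versus-PEEP model

Granular R/I values are regressed on the arithmetic mid-PEEP of their range
with a parabola constrained through the origin,

$$RI(P) = b_1 P + b_2 P^2,$$

because there is no recruitment at zero pressure, recruitment must fade as
the pressure–volume envelope flattens at high PEEP, and a maximum should lie
in between. Although the literature calls this a nonlinear regression, the
model is linear in $(b_1, b_2)$; the package solves the normal equations on
the basis $\{P, P^2\}$ in closed form — the same minimizer, with no
convergence ambiguity. A brute-force grid search over the coefficient box is
kept in the test suite as an independent check that the closed form attains
the optimum.

**Weighting.** Each point's uncertainty is propagated from a configured EELV
measurement SD $\sigma$ (default 25 ml per wash draw): the wash-pair mean
carries $\sigma^2/2$, a range's volume difference $\sigma^2$, so
$\sigma_{RI} = \sigma / (\Delta PEEP \cdot C_{rs,low})$. Adjacent ranges
share the EELV node at their common step, which makes their errors
negatively correlated (covariance $-\sigma^2/2$, scaled); the 5 → 0 point is
built from the independent single-breath volume. The pipeline therefore fits
by generalized least squares with the full propagated covariance
(`weight_mode = "covariance"`); `fit_ri_curve()` called directly accepts
per-point sigmas (diagonal weighting) or the full matrix. The distinction
matters for calibration: with the covariance, the chi-square goodness-of-fit
gate rejects true-model simulations at ≈ 5.5%; with diagonal weights the
shared-node correlation inflates rejection to ≈ 11%.

**Gates.** The chi-square statistic (weighted residual sum, $n-2$ degrees of
freedom) gates the fit at $\alpha = 0.05$; fits whose vertex
$-b_1/(2 b_2)$ exceeds 20 cm H2O, or whose predicted $|R/I|$ exceeds 20
anywhere on $[0, 20]$, are flagged implausible. Only fits passing both gates
are usable for prediction (`predict_ri()` refuses otherwise, and refuses
extrapolation beyond 20 cm H2O). Shape is `saturating` when $b_2 < 0$ and
the vertex lies within the observed mid-PEEP span extended by the largest
gap between consecutive mid-PEEPs, `ever_increasing` when $b_2 \ge 0$ or the
vertex lies beyond, `indeterminate` when the goodness-of-fit gate fails. The
$\alpha = 0.05$ level and the propagated-noise chi-square construction are
package choices; the clinical source of the gate does not state them.

**Quadrature bias.** The R/I measured over a range is the *integral mean* of
the underlying law, not its value at mid-PEEP: for a quadratic law the two
differ by exactly $b_2 \Delta P^2 / 12$. With the ladder's range widths
(2, 3, 2, 3, 5 cm H2O) this is at most $\approx 0.02$ for typical $b_2$. The
package places points at mid-PEEP and does **not** correct the bias — the
bedside procedure doesn't either — but the generator's ground truth carries
the exact term and the test suite asserts it, so the bias is documented and
measured rather than hidden. A consequence worth knowing: even noise-free
data do not return the generating $(b_1, b_2)$ exactly (the deviation is
~$3\times10^{-3}$ on $b_1$), and the noise-free $R^2$ is 0.99998 rather
than 1.

**Numerical tie-breaks.** A fitted $|b_2|$ below $10^{-12}\max(1, |b_1|)$ is
snapped to zero so that exactly linear data classify as ever-increasing
instead of acquiring a machine-noise vertex; designs with fewer than 3
points or a single distinct mid-PEEP are rejected.

## Eligibility screening

Patients with intrinsic PEEP above 2 cm H2O or airway closure with an airway
opening pressure (AOP) above 5 cm H2O are excluded; both thresholds are
strict inequalities. AOP is detected on the low-flow inflation curve with a
continuous two-segment piecewise-linear fit across candidate breakpoints
(the interior sample pressures), calling closure when the lower-segment
slope is below 10% of the upper-segment slope. The changepoint construction
is a package choice: the clinical screening maneuver is standard but its
detection algorithm is not specified in the methodological sources. Missing
screening inputs skip the corresponding screen (recorded, never a failure).

## The synthetic-patient generator

Ground truth is parameterized directly on the fitted object: a patient *is*
an R/I law $(b_1, b_2)$ plus $FRC$, a baby-lung compliance $C_{baby}$
(constant over PEEP), a tidal volume and an EELV noise SD. Since
$C_{rec}(P) = C_{baby} \cdot RI(P)$, the true EELV has the closed form

$$EELV(p) = FRC + C_{baby}\left(p + \frac{b_1 p^2}{2} + \frac{b_2 p^3}{3}\right).$$

Wash-out and wash-in are independent draws $N(EELV(p), \sigma^2)$; the
derecruitment breath releases $EELV(5) - FRC$ plus one draw; plateau
pressures are back-computed from the target measured compliance and emitted
at 0.1 cm H2O (ventilator display resolution — this alone perturbs measured
compliance by ~0.3%, visible in file-round-trip recovery tests).

**Measured-compliance profile.** The default (`crs_mode = "constant"`) emits
the baby-lung compliance at every step. This is the self-consistent choice:
the EELV law above has increments
$C_{baby}\,\Delta p\,(1 + \overline{RI})$, so subtracting
$\Delta p \cdot C_{rs,low}$ with $C_{rs,low} = C_{baby}$ makes the measured
granular R/I reproduce the generating law exactly (up to the quadrature
term). An alternative profile (`crs_mode = "recruited"`,
$C_{rs}(p) = C_{baby}(1 + RI(p))$) models recruited tissue adding tidal
compliance; under it the measured low-PEEP compliance absorbs most of the
EELV change, the measured granular R/I collapses toward the *increment* of
the law, and granular recruited volumes no longer sum to the global value —
it exists precisely to exercise that non-additivity, not as a default.

Cohorts mix five archetypes (high/low recruiters, parabolic-saturating,
linear-increasing, non-recruiters) with per-archetype coefficient ranges and
FRC 900–1750 ml, compliance 28–52 ml/cm H2O, predicted body weight 55–85 kg
(6 ml/kg tidal volume). The default mix (0.30/0.25/0.25/0.10/0.10) was
chosen once so that a default cohort reproduces the clinical picture this
kind of trial reports: global R/I median ≈ 1.3 with IQR ≈ [0.5, 1.9], most
usable fits parabolic, and a strongly negative correlation between global
R/I and the PEEP-induced dynamic-strain change. The 25 ml EELV noise default
is an assumption — monitors do not publish their EELV error — and is echoed
into every simulation log.

What the generator does **not** emulate: time-dependent (de)recruitment
within a step, hysteresis between inflation and deflation limbs, gas
exchange, hemodynamics, chest-wall/lung strain partitioning, and any
EELV error structure beyond i.i.d. Gaussian wash draws. Passing tests
therefore validate the computational chain and its statistical behavior
under the stated error model, not the clinical accuracy of the nitrogen
dilution technique itself.

## Estimator precision

With the five-point ladder, $\sigma = 25$ ml and a 40 ml/cm H2O compliance,
the GLS coefficient covariance gives $sd(b_2) \approx 0.0034$; by the delta
method the vertex estimate $-\hat b_1/(2\hat b_2)$ then carries
$sd \approx 2.5$ cm H2O around a true vertex of 15, i.e. a median absolute
error near 1.7 cm H2O. This is an information limit of the design (five
points, two parameters, shared-node noise), not of the solver: no weighting
scheme improves it materially. The curvature *sign*, by contrast, is
recovered in over 99% of gate-passing fits under the same conditions. In
practice this means the parabola reliably distinguishes saturating from
ever-increasing responders, while the exact PEEP of maximal recruitment
should be read with a ±2–3 cm H2O mental error bar.

## Cohort statistics

Summaries are median [IQR] with linearly interpolated quartiles
(`quantile` type 7, stated so IQRs reproduce bit-for-bit). Intraindividual
variability is the coefficient of variability ($100 \cdot sd/mean$, $n-1$
denominator) over the four narrow ranges. Strain changes are percent changes
referenced to the **low-PEEP** state (the comparator state throughout the
protocol). Correlation endpoints report Pearson r and the OLS slope with a
95% t-interval, descriptively only: the quantities on both axes share
measured components, so inferential p-values would be invalid and are not
produced. Paired hypothesis tests across PEEP steps are out of scope by
design.

## Problem sizes used in validation

The test suite validates the decomposition identity on 1,000 generated
trials, file round-trips on 100, stochastic coefficient recovery on 200
patients at $\sigma = 25$ ml, goodness-of-fit calibration on 2,000 simulated
fits, and the endpoint correlation structure on a 100-patient mixed cohort;
noise-scaling monotonicity uses 120 patients per noise level. These sizes
give sampling error well below the asserted margins while keeping the suite
fast.

## Known limitations

- The AOP changepoint rule and the goodness-of-fit error model are package
  choices standing in for unspecified clinical procedures; both are
  configurable at the interfaces where they act.
- The mid-PEEP quadrature bias is documented, not corrected; fits inherit a
  coefficient deviation of order $b_2 \Delta P^2/12$.
- The vertex (PEEP of maximal recruitment) is intrinsically imprecise at
  realistic noise (see above).
- Derecruitment data are interpreted as recruitment, as the protocol's
  stabilization phase justifies; the package cannot test that equivalence.
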