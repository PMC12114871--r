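---
title: "Methods: sequential PK/PD modeling of tumor growth inhibition in xenograft mice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential PK/PD modeling of tumor growth inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenopkpd)
```

## The scientific problem

`xenopkpd` implements a sequential pharmacokinetic/pharmacodynamic (PK/PD)
analysis of an EGFR tyrosine-kinase inhibitor (afatinib-like, "AFT") given
daily by oral gavage to tumor-bearing mice, alone or together with an herbal
adjuvant, in a four-arm xenograft design (vehicle control, drug alone,
adjuvant alone, combination). The questions the analysis answers are
quantitative: how much drug exposure does a 10 mg/kg/day regimen produce at
steady state; how strongly does that exposure divert proliferating tumor
cells into death; and by what factor does the adjuvant amplify the drug's
potency (synergy).

## The PK model

Serum kinetics follow a one-compartment model with first-order absorption
and elimination,

$$\frac{dA_1}{dt} = -K_a A_1, \qquad
  \frac{dA_2}{dt} = K_a A_1 - K_{el} A_2,$$

with $A_1(0) = \mathrm{Dose}$, $A_2(0) = 0$ and
$C(t) = 1000\,A_2(t)/(V_d/F)$ in ng/mL for a dose in mg/kg and a volume in
L/kg. The closed-form (Bateman) solution is used everywhere; an ODE
integration with depot resets exists in the test suite as an independent
oracle. Because the model is linear, repeated dosing is evaluated by
superposition; the day-30 profile is numerically indistinguishable from the
analytic steady state (geometric accumulation), which the tests verify to
0.1%.

Two numerical facts matter here:

* **Flip-flop kinetics.** At the reference estimates ($K_a$ = 0.2 h⁻¹,
  $K_{el} = CL/V_d \approx$ 0.44 h⁻¹) absorption is rate-limiting. The
  Bateman function is exactly symmetric under swapping $K_a$ and $K_{el}$
  (with $V_d$ rescaled), so $K_a$ and $V_d/F$ are only *locally* identified;
  clearance, which controls average exposure, is invariant under the swap.
  With 6 animals per arm and 4 samples each this makes $K_a$ and $V_d/F$
  genuinely hard to pin down — the analysis reflects that honestly in their
  standard errors rather than constraining it away.
* **The removable singularity** at $K_a = K_{el}$ is evaluated by its limit
  $1000\,D\,K_a t\,e^{-K_a t}/V_d$.

Inter-individual variability (IIV) is log-normal on CL and Vd only, and the
residual error is proportional, matching what is estimable from a sparse
four-point design.

## Noncompartmental exposure metrics

AUC to the last steady-state sample uses the **linear trapezoid** with a
(0, 0) anchor prepended when the first sample is post-dose — a deliberate
dialect choice (several NCA tools default to linear-up/log-down; with
samples stopping at 8 h of a 24 h interval the difference is small but
documented). Cmax is the observed maximum with no interpolation. Group
comparison uses the two-sided Mann–Whitney U test, exact for combined
n ≤ 20 without ties; a full permutation enumeration backs it in the tests.

## The tumor-growth-inhibition model

Unperturbed growth follows the Simeoni form: exponential at rate
$\lambda_0$ (day⁻¹) while the proliferating volume $X_1$ is small, linear at
rate $\lambda_1$ (mm³/day) once it is large, blended smoothly by a shape
factor $\phi$ fixed at 20:

$$f(X_1) = \frac{\lambda_0 X_1}
  {\left[1 + \left(\tfrac{\lambda_0}{\lambda_1} X_1\right)^{\phi}\right]^{1/\phi}}.$$

The switching threshold is $W_{th} = \lambda_1/\lambda_0$ (≈ 224 mm³ at the
reference values). The denominator is computed on the log scale
(log-sum-exp), so $\phi = 20$ cannot overflow even at $10^6$ mm³. The
$\phi \to \infty$ piecewise model (exponential then linear) agrees with the
smooth curve within 2% at the reference values, which is a test.

Drug effect: exposure moves proliferating cells into a chain of three
transit ("death") compartments at rate
$K \,(1 + \alpha_{syn}\,\mathrm{flag})\, C(t)$, with transit rate $K_1$
between compartments, and observed volume
$V = X_1 + X_2 + X_3 + X_4$ (computed as the sum, never integrated, so the
identity is exact at every output point):

$$\dot X_1 = f(X_1) - K^{*} C(t) X_1,\quad
  \dot X_2 = K^{*} C(t) X_1 - K_1 X_2,\quad
  \dot X_3 = K_1 (X_2 - X_3),\quad
  \dot X_4 = K_1 (X_3 - X_4).$$

The combination arm sets the flag to 1, so $(1 + \alpha_{syn})$ *is* the
potency fold of the adjuvant. Two secondary parameters summarize the
dynamics: the stasis/eradication threshold concentration
$C_T = \lambda_0 / K$ (a sustained concentration above $C_T$ shrinks the
tumor to extinction, below it the tumor approaches a stable size — verified
numerically in the tests), and $W_{th}$ above.

We use the proliferating volume $X_1$ in the growth-saturation denominator,
exactly as the model equations are written; the original Simeoni
formulation uses total volume $V$ there. The choice matters only under
treatment (control dynamics have $V = X_1$): with total-volume saturation
the dead-cell mass also counts toward growth saturation, so treated arms
grow somewhat more slowly and cross volume thresholds later. This is a
known structural dialect; we follow the equations as stated.

Simulation uses `deSolve::lsoda` with rtol 1e-8 / atol 1e-10 (1e-7/1e-9 in
the lean path used inside fitting loops, where the concentration forcing is
tabulated on a 0.005-day grid and interpolated — the profile does not
depend on the PD parameters being optimized). Threshold-crossing times are
linearly interpolated between output points and also reported rounded to
whole days; times are on the study clock (t = 0 at inoculation; treatment
from day 7, when the typical tumor reaches the 80–100 mm³ randomization
window).

## Estimation

The workflow is sequential, mirroring how such analyses are built:

1. **PK mixed-effects fit.** The marginal likelihood of the nonlinear
   mixed-effects model is approximated by the **Laplace method at the
   conditional modes** of the per-animal random effects — the closest
   tractable analogue of first-order conditional estimation. The inner
   2-d mode search uses analytic gradients of the joint deviance; the
   conditional Hessian comes from central differences of that gradient.
   The method is validated against brute-force 21-node Gauss–Hermite
   quadrature (agreement within 0.5 deviance units on a 3-subject dataset —
   an acceptance check). Because this is a different algorithm than any
   specific commercial implementation, reference estimates are treated as
   *recovery targets on synthetic data*, not values to match bit-for-bit.
2. **Control-arm growth fit.** Pooled maximum likelihood (no random
   effects) of $\lambda_0, \lambda_1, V_0$ with $\phi$ fixed, proportional
   error. Pooling matches a design in which per-arm profiles are generated
   around a group-typical curve.
3. **Treated-arm TGI fit.** Joint pooled fit of $V_0, K_1, K, \alpha_{syn}$
   to the monotherapy and combination arms with $\lambda_0, \lambda_1$
   fixed from stage 2 and the typical (no-IIV) PK profile as input. The
   synergy factor is identified purely by the between-arm contrast, and is
   reported as not identifiable when only one treated arm is present.

All parameters are log-transformed (the synergy factor via
$\log(1+\alpha)$, keeping $\alpha > -1$). Optimization runs `nlminb` from
five deterministic multistart points (the heuristic start ± symmetric
log-scale perturbations — deterministic so a fit never consumes RNG state),
followed by Nelder–Mead polish rounds; convergence is declared when the
derivative-free polish cannot improve the objective by more than 0.05.
Standard errors come from the central-difference Hessian of the
−2 log-likelihood on the log scale (delta method back to natural scale);
empirical Bayes estimates and their shrinkage
$100(1 - \mathrm{SD}(\hat\eta)/\omega)$ are reported for the PK stage.
On noise-free data the proportional-error deviance is unbounded below in
$\sigma$; a floor of $10^{-6}$ keeps the optimum finite without affecting
the structural parameters.

Starting values are data heuristics: clearance from the pooled-mean AUC, a
small $(K_a, K_{el})$ grid on the mean profile, growth rates from early
log-slopes and late linear slopes of the day means, potency scaled so the
kill rate at the average steady-state exposure is comparable to $\lambda_0$.

## The synthetic-data generator

The generator *is* the study design: 2 PK arms × 6 mice sampled at 0.5, 2,
4, 8 h post-dose on day 30 of daily 10 mg/kg dosing; 4 PD arms × 100 tumor
profiles observed daily from day 7 to day 37; treatment from day 7. True
parameters default to the reference estimates. PK observations get
log-normal IIV on CL and Vd plus proportional normal noise (29%); tumor
profiles are the arm-typical model curve times proportional normal noise
(16.9% control-like arms, 21.5% treated arms), floored at 0.1 mm³. The
adjuvant-only arm follows control dynamics (its monotherapy effect was
minimal and it contributes no modeled drug input), so it is carried in the
data for schema completeness and ignored by the TGI fit.

One master seed drives deterministic per-arm child streams, so adding or
removing an arm never perturbs the draws of another. What the generator
does *not* emulate: per-animal tumor random effects (profiles vary only
through residual noise, matching the pooled PD model), caliper measurement
(volumes are generated directly), below-quantification censoring, and
drop-out. Passing recovery tests therefore demonstrate correctness of the
estimation machinery under the stated error model, not robustness to those
real-data features.

A note on information content: with 6 animals per PK arm and 4 samples
each, the sampling variability of $K_a$ and $V_d/F$ is large — the
flip-flop near-symmetry described above is the structural reason, and the
large reference RSEs for these two parameters say the same. Clearance — and with it average
exposure and everything downstream in the PD model — is well identified.
We size expectations accordingly: recovery assertions at the study design
are tight for CL and the PD parameters and loose for $K_a$/$V_d$.

## Model evaluation

The visual predictive check simulates replicate studies at the observation
design (default 1000 replicates; results carry a flag below 100), computes
per-bin 5th/50th/95th percentiles per replicate and reports the 2.5–97.5%
envelope of each statistic next to the observed percentiles. Percentiles
are type-7 (linear interpolation between order statistics) — dialects
differ between tools, so the choice is fixed and tested against a manual
implementation. PK replicates redraw IIV and residual error; tumor
replicates redraw residual error only, matching the pooled PD model. Bins
are exact nominal sample times (PK) and study days by arm (PD); no binning
heuristics are needed at this design. On model-true data the 90%
prediction band contains about 90% of observations (checked over 10 seeds
in the acceptance suite). Goodness-of-fit tables report population (and,
for PK, individual) predictions and standardized proportional residuals
per observation.

## Problem sizes and runtime

The default test-suite problem sizes are chosen so the whole suite runs in
minutes on a single core: recovery experiments use the study-sized default
design once (100 profiles per arm for the PD stages), oracle comparisons
use 3-subject datasets, and VPC calibration uses 200–300 replicates per
seed; the package defaults remain the full 1000-replicate VPC.

## Known limitations

* No tumor-site drug concentrations and no standalone kinetics for the
  adjuvant: its whole contribution is the scalar $\alpha_{syn}$ on potency.
* No covariates, no lag time, no nonlinear elimination, no BLQ handling.
* PD fitting is naive-pooled; if real per-animal profiles with
  between-animal growth variability were supplied, the residual error
  would absorb that variability.
* Reported threshold-crossing days depend on the rounding convention;
  interpolated raw crossings are always returned alongside, and values one
  day away under an alternative first-whole-day reading should not be
  over-interpreted.
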