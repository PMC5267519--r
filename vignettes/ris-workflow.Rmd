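---
title: "The RIS workflow: from induction wells to DDI risk calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The RIS workflow: from induction wells to DDI risk calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riscal)
```

## The problem

A drug that induces CYP3A4 expression accelerates the clearance of
co-administered "victim" drugs metabolized by that enzyme, lowering their
exposure (AUC) and potentially their efficacy. Regulators therefore expect
in vitro induction screening early in development. The quantitative
question is how to translate an in vitro concentration-response — fold
induction of CYP3A4 enzyme activity or mRNA in cultured hepatocytes across
eight concentrations of test compound — into a predicted percent decrease
of a victim drug's AUC in the clinic.

`riscal` implements the calibrated relative induction score (RIS) approach
to that extrapolation, end to end: replicate QC, Hill curve fitting, RIS
computation, calibration against observed clinical midazolam AUC changes,
cutoff derivation, and accuracy evaluation.

## The model chain

**Fold induction and fold increase.** For enzyme activity, fold induction
is the treated replicate mean over the solvent-vehicle replicate mean; for
mRNA it is $2^{-\Delta\Delta C_T}$. Curve fitting uses *fold increase* =
fold induction − 1, so a compound with no effect sits at 0.

**Replicate QC.** A concentration point enters curve fitting only when its
two or three replicates show a coefficient of variation (sample SD over
mean, computed on the raw replicate values) below 40%. Points known to be
compromised by toxicity or insolubility at high concentrations are
excluded with a recorded reason; they are input flags, not auto-detected,
because no detection rule generalizes across readouts.

**Induction curve.** Accepted points are fitted to the sigmoidal Hill
4-parameter model

$$y = E_{min} + \frac{E_{max} - E_{min}}{1 + (EC_{50}/x)^{b}},$$

with $y$ the fold increase, $x$ the concentration (µM), $E_{min}$ the
background, $E_{max}$ the maximal fold increase, $EC_{50}$ the
half-maximal concentration, and $b$ the slope. A fit is accepted only when
$R^2 = 1 - SS_{res}/SS_{tot} > 0.85$. A series is eligible for
$E_{max}$/$EC_{50}$ estimation only when it is concentration dependent
with maximum fold induction above 1.4; a compound is a *positive inducer*
when both endpoints exceed twofold with a concentration-dependent pattern.

**RIS and calibration.** The relative induction score weights in vitro
potency by clinical exposure:

$$RIS = \frac{E_{max} \cdot C_{max,ub}}{EC_{50} + C_{max,ub}},$$

with $C_{max,ub}$ the unbound plasma peak concentration of the inducer.
Per cell lot and endpoint, RIS for a small set of calibration compounds —
inducers with midazolam-probe clinical studies spanning weak to strong —
is regressed on the observed percent midazolam AUC change with a Hill
3-parameter function

$$f = \frac{a \, x^{b}}{c^{b} + x^{b}},$$

whose inversion at a 20% AUC change gives the RIS cutoff for flagging a
clinically relevant inducer in closed form,
$x = c\,(t/(a-t))^{1/b}$ at $t = 20$.

**Accuracy.** Predictions are compared with observed AUC changes via RMSE
on the fractional scale (percent/100) and the geometric mean fold error
$\mathrm{GMFE} = 10^{\overline{|\log_{10}(p/o)|}}$, stratified by whether
the clinical study used midazolam or another victim drug. Pairs with a
non-positive predicted or observed value have no defined fold error and
are excluded from GMFE with a logged reason.

## Tunable parameters

All thresholds live in `pipeline_config()` and are never hard-coded
downstream:

| parameter | default | meaning |
|---|---|---|
| `cv_threshold` | 0.40 | replicate CV above which a point is excluded |
| `r2_min` | 0.85 | minimum accepted curve-fit $R^2$ |
| `min_max_response` | 1.4 | fold-induction floor for fit eligibility |
| `positive_threshold` | 2.0 | fold induction defining positive induction |
| `auc_cutoff_pct` | 20 | AUC change (%) defining the RIS cutoff |
| `plateau_emax_ratio` | 1.2 | plateau test, fitted/observed $E_{max}$ ratio |
| `plateau_top_fraction` | 0.9 | plateau test, top-dose response fraction |

## Numerical choices

*Hill-4 optimization.* Nonlinear least squares (Levenberg–Marquardt with
box bounds, via `minpack.lm`) on log10-concentration — the same model,
much better conditioned across the 4–5 orders of magnitude a panel spans.
Multi-start: slope in {0.5, 1, 2, 4}, $EC_{50}$ at the geometric mean and
quartiles of the tested range, $E_{max}$ at the observed maximum,
$E_{min}$ at 0; bounds $E_{min} \in [0, \mathrm{obs max}]$,
$E_{max} \in (0, 5\times\mathrm{obs max}]$, $b \in (0.1, 10]$, $EC_{50}$
within two orders of magnitude of the tested range. The best start by
residual sum of squares wins; an essentially perfect fit short-circuits
the remaining starts.

*Plateau and the observed-maximum fallback.* A fitted $E_{max}$ far above
the data means the curve never flattened within the tested range and the
asymptote is an extrapolation. We call a plateau when fitted
$E_{max} \le 1.2 \times$ observed maximum fold increase *and* the fitted
response at the top concentration reaches ≥ 90% of fitted $E_{max}$;
otherwise $E_{max}$ is set to the observed maximum and $EC_{50}$ is
re-derived by refitting with $E_{max}$ fixed. Both constants are exposed
in the config. The refit is our resolution of an ambiguity — "derived
from the fitted curve" admits several readings — and is flagged as a
choice, not the only defensible one.

*Hill-3 calibration.* Multi-start on untransformed (RIS, %AUC) pairs:
$a$ starting at the maximum observed AUC change, $c$ at the median RIS,
$b$ in {1, 2, 4}; bounds $a \in (20, 120]$, $b \in (0.1, 10]$, $c > 0$.
At least 4 calibration points are required; negative observed AUC changes
(net inhibition) are allowed in evaluation but never in calibration.

*Concentration dependence* is not defined by the source methodology; we
operationalize it as a positive Spearman rank correlation between
concentration and fold increase over ≥ 3 accepted points, with the
maximum response occurring above the lowest tested concentration.

*Degenerate inputs.* All-equal responses, fewer than 4 accepted points,
or a vehicle mean ≤ 0 raise errors naming the problem; fits that converge
but fail the $R^2$ rule are returned with `accepted = FALSE` rather than
erroring, so non-fittable compounds can still be tabulated (`NI`/`NA`
sentinels in `collect_fit_table()`).

*Rounding.* Internal computation is full precision; report helpers round
RIS to 2–3 significant figures and %CV to integer percent, matching the
conventional display. Known consequence: summaries recomputed from
*displayed* (rounded) inputs can shift by 1–3 percentage points relative
to summaries of the unrounded values, and published tables assembled from
unrounded intermediates are not always exactly reproducible from their
own displayed entries.

## What the synthetic generator does and does not emulate

`generate_panel()` realizes a known truth: per compound, a Hill-4 fold
increase curve sampled at 8 log-spaced concentrations over its tested
range, 3 replicate wells, vehicle-control wells, and multiplicative
log-normal noise with unit mean and a chosen replicate CV (default 0.1 —
a typical intra-plate CV for LC-MS/MS activity or qPCR readouts; the
source methodology states no noise magnitude, so this is a modeling
choice). Noise is multiplicative because both readouts are positive and
heteroscedastic. An optional toxicity threshold collapses the signal to
~5% of vehicle above it, flagged in the output so exclusion behaviour is
testable. `generate_calibration_truth()` closes the loop: true RIS from
the truth parameters, pushed through a reference calibration model, gives
the "observed" AUC change a perfect pipeline should recover.

The generator does **not** emulate: plate-layout or edge effects,
LC-MS/MS peak integration, qPCR amplification efficiency (ΔΔCt values are
generated directly), lot-to-lot biological variation beyond independent
noise draws, correlated replicate errors, or partial toxicity. Passing
recovery tests therefore demonstrates the *statistical correctness of the
pipeline under its own assumptions* — not robustness to every failure
mode of real induction data.

## Problem sizes used in validation

Zero-noise recovery uses a 6-compound, 1-lot, 8-concentration, triplicate
panel whose true RIS spans 0.08–20 (foot to plateau of the calibration
curve); it recovers $E_{max}$, $EC_{50}$, and slope to better than 1e-4
relative error and the calibration parameters to better than 1e-3. The
stochastic recovery study uses 100 independent panels (3 compounds each)
at replicate CV 0.1, where the median relative error is about 7% for
$EC_{50}$ and 5% for $E_{max}$. The noise-model check pools ~10,000
wells. These sizes make the full suite run in well under a minute while
leaving the Monte-Carlo assertions comfortably away from their bounds.

## Known limitations

- Slope factors are estimated and reported but deliberately not used in
  prediction; RIS compresses the curve to $E_{max}$ and $EC_{50}$.
- A calibration built on midazolam studies predicts midazolam-substrate
  interactions well and systematically overestimates nonmidazolam ones;
  the stratified accuracy report makes this visible rather than
  correcting it.
- Nominal (not time-weighted) concentrations are assumed throughout.
- The RIS cutoff is lot- and assay-dependent: it must be re-derived from
  each laboratory's own calibration curve, not transplanted.

## A worked run

```{r example, eval = FALSE}
cmp <- default_panel_compounds()          # 13 compounds, realistic truth
cal <- calibration_model(a = 98, b_slope = 2, c_half = 0.4)
panel <- generate_panel(
  panel_spec(cmp, n_lots = 3, noise_cv = 0.1, seed = 1), cal = cal)
compounds <- tibble::tibble(
  compound = cmp$compound, cmax_ub_um = cmp$cmax_ub_um,
  observed_auc_pct = panel$observed_auc_change$observed_auc_change,
  substrate_class = "midazolam", in_calibration_set = TRUE)
res <- run_pipeline(panel, compounds)
res$cutoffs
```

The packaged reference tables can be re-analysed without any simulation
via `reproduce_reference()`; see the README for the numbers it prints.
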