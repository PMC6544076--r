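---
title: "Methods: additive benefit-risk analysis from swing-weighting preferences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: additive benefit-risk analysis from swing-weighting preferences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swingbra)
```

## The decision problem

Patients with severe aortic stenosis choosing between surgical (SAVR) and
transcatheter (TAVR) valve replacement trade off procedure invasiveness
against clinical risks (one-month mortality, disabling non-fatal stroke,
one-year pacemaker and dialysis risk), the probability of regaining
independence, and the number of years each procedure has been proven to
work. `swingbra` implements a quantitative benefit-risk analysis of that
choice: an additive multi-criteria value model whose weights come from
patients' stated indifference points, plus threshold and Monte Carlo
analyses of its conclusions. The machinery is generic — any attribute set
with a binary "anchor" attribute works — but the packaged configuration is
the TAVR/SAVR one.

## The value model

The overall value of alternative $x$ is

$$U(x) = \sum_i w_i \, v_i(x_i),$$

where $v_i$ is a **linear partial value function** anchored at the
attribute's model range: $v_i(\text{worst}) = 0$, $v_i(\text{best}) = 1$.
Linearity is an assumption, not an estimate; eliciting the shape of six
partial value functions would overburden respondents, and every downstream
quantity (weights, thresholds) is defined relative to this linear scale.
The ranges are fixed model constants spanning both alternatives' plausible
performance (e.g. mortality 0.5%–5.3%), *not* the per-pair observed spans:
thresholds extrapolate beyond the observed performance, which only makes
sense on a fixed scale. Levels outside the range are an error in strict
mode and extrapolated linearly otherwise (threshold analysis needs the
extrapolation).

Incremental value decomposes exactly by attribute:
$U(\Delta) = \sum_i w_i\,(v_i(x^{A}_i) - v_i(x^{B}_i))$, and the package
treats the identity $\sum_i PV_i = U(\Delta)$ as a hard invariant (tested
at $10^{-9}$).

## From indifference points to weights

The adaptive swing-weighting (ASW) exercise asks, per attribute, how large
a change a respondent would accept in exchange for swinging the procedure
from invasive to minimally invasive. The resulting **maximum acceptable
increase in risk** (MIR) or **maximum acceptable reduction in benefit**
(MRB) converts to a raw weight by

$$w_i = \frac{|\text{range}_i|}{\text{MIR}_i}, \qquad w_{\text{procedure}} = 1 .$$

A respondent tolerating a 2-percentage-point mortality increase on a
4.8-point model range weighs mortality $4.8/2 = 2.4$ times the procedure
swing. Weights are also reported normalised to sum to 100; the model and
all thresholds are invariant to that rescaling (tested).

**Group weights are range over the group-mean MIR**, not the mean of
individual weights. The distinction matters because $1/\text{MIR}$ is
convex: averaging individual weights would overweight risk-averse
respondents. Group-level reproduction of the published threshold table
requires the group-mean reading; individual-level weights are used where
heterogeneity itself is the object (Monte Carlo sampling). Per-attribute
sample sizes float with missingness — no imputation is performed for group
means, and a record enters the panel if at least one exercise is complete.

Censored indifference points from straight-lining respondents (all three
choices on the same side in every exercise) are retained at their censoring
bound by default; `exclude_straight_liners = TRUE` supports the
sensitivity analysis. Straight-lining can be a genuine extreme preference
rather than inattention, which is why retention is the default.

## The elicitation ladder

Each exercise is three pairwise choices. Offers follow a dyadic bisection
of $(0, \text{max\_change}]$: the first offer is the midpoint, and each
response moves the next offer by half the previous step toward the
indifference point. Three answers localise the indifference point to one of
eight adjacent intervals of width $\text{max\_change}/8$; the estimate is
the interval midpoint, so the deterministic-respondent error is at most
$\text{max\_change}/16$ for interior latents. The two all-same-side
patterns are censored (`at_max`, point set to the ladder maximum; `at_min`,
the lowest interval's midpoint). The grid is configurable per attribute so
a published level ladder can be substituted; the dyadic ladder is the
canonical three-iteration bisection consistent with offers that move toward
indifference after every answer.

Ladder maxima default to `default_max_change()` (mortality 12%, stroke
20%, independence 40%, pacemaker 24%, dialysis 20%, proven-to-work 60
years) — chosen once so the published mean indifference points sit well
interior to the grid, roughly mean + 2 SD rounded to display-friendly
levels.

The simulated respondent chooses the attribute improvement exactly when
the offer exceeds their latent indifference point; a logistic error model
(`plogis((offer - latent)/scale)`) adds response noise and converges to the
deterministic rule as the scale shrinks.

## Threshold analysis

The maximum acceptable risk (MAR) or minimum acceptable benefit (MAB) on
attribute $a$ is the level of the focal alternative's performance at which
the two alternatives' overall values would be equal:

$$\text{MAR}_a \;/\; \text{MAB}_a = x^{\mathrm{TAVR}}_a \pm
  \frac{U(\mathrm{TAVR}) - U(\mathrm{SAVR})}{w_a / |\text{range}_a|},$$

with the sign **direction-aware**: added for risks (the risk may rise
before indifference) and subtracted for benefits (the benefit may fall).
This is the only sign convention under which every threshold moves toward
worse focal-alternative performance, and it reproduces the entire
published threshold table. Thresholds are clamped to feasibility
(probabilities to $[0,1]$, years floored at 0) with the unclamped value
retained, so the indifference identity $U(\mathrm{TAVR}) =
U(\mathrm{SAVR})$ at the raw threshold can always be verified — the
package tests it at $10^{-9}$ over random configurations. With group-mean
weights the displacement simplifies to $U(\Delta) \times
\overline{\text{MIR}}_a$, which is a useful hand-check.

```{r thresholds}
cfg <- tavr_savr_config()
fit <- bra(cfg, weights = mir_weights(reference_mir("whole"),
                                      cfg$attributes, "group-mean"))
summary(fit)
```

One subgroup caveat: reproducing the published 60-and-over column from the
published rounded subgroup means leaves residual discrepancies of a couple
of tenths of a percentage point on some attributes, unlike the whole-sample
and under-60 columns, which reproduce essentially exactly. The likely cause
is rounding of the subgroup summary inputs; the package makes no attempt to
force agreement there.

## Monte Carlo simulation

`run_mcs()` propagates two uncertainty sources simultaneously:

* **Performance**: each probability attribute's level is drawn from a
  normal centred at its mean with SE = (CI width)/(2 × 1.959964),
  truncated to the feasible bounds. Truncation uses the inverse-CDF
  transform rather than rejection: it is exact, vectorised, and consumes a
  fixed number of uniforms per draw, which keeps the random stream layout
  stable and runs bit-reproducible under a seed. Attributes without a CI
  (proven-to-work, the binary procedure attribute) are point masses.
* **Preference**: the default `respondent` scheme bootstraps whole
  respondents, preserving within-person correlation across attributes;
  missing attributes are filled from the respondent's age-group mean. The
  `attribute` scheme resamples each attribute's MIR independently from the
  empirical marginal. The study's description is compatible with either;
  the scheme is recorded in the output metadata rather than guessed away.

Each iteration ranks the alternatives by $U$; exact ties split 0.5/0.5
(they arise only in degenerate, variance-free settings). Reported
alongside the first-place probabilities: the Monte Carlo standard error
$\sqrt{p(1-p)/n}$, the seed, the subgroup, and any exclusions. With all
variance switched off the simulation agrees exactly with the sign of the
deterministic incremental value (tested).

## The synthetic panel generator

`panel_spec()`'s defaults are the study conditions: 219 respondents, 132
under 60; latent indifference points per attribute and age group with the
published means and SDs; 8.68% straight-liners; per-attribute missingness
equal to one minus the published response counts over 219 (an
`assignment` mode instead gives each respondent 3 or 4 of the six
exercises, mimicking the survey design).

Latents are truncated normal on $(0, \text{max\_change}]$ (a
moment-matched lognormal is available, since the true shape is not
reported). Two calibrations keep the *observed* panel faithful to the
published summaries:

1. The published means describe the observed panel, which retains
   straight-liners at their censoring bounds. The generator therefore backs
   the non-straight-liner target mean out of the mixture (50/50
   procedure-side at the ladder maximum vs attribute-side at the lowest
   midpoint — the side split is not reported, so it is fixed at one half)
   before drawing.
2. Truncation at zero would inflate a truncated normal's mean above its
   location parameter, so the parent location is solved (by `uniroot`) so
   that the truncated mean equals the target.

What the generator does *not* emulate: between-attribute correlation of
indifference points (not reported; latents are independent given age
group), covariates beyond age and straight-lining, and response-order or
anchoring effects. Passing recovery tests therefore show the pipeline is
correct under these stylised conditions, not that real panels satisfy
them. One realistic side effect is deliberate: genuine latents can fall in
the outermost grid intervals, so deterministic elicitation produces a
small excess of classified straight-liners over the planted fraction —
exactly the ambiguity the straight-liner sensitivity switch exists for.

## Numerical and testing choices

* Probabilities are proportions internally; reports render percentages at
  one decimal. Years stay years.
* Decomposition conservation, threshold self-consistency and
  normalisation invariance are asserted at $10^{-9}$.
* Property tests run on modest, fixed-seed problem sizes chosen as
  routine for this kind of survey analysis: exhaustive enumeration of the
  8 ladder patterns, a 200-point latent sweep, panels of 2000 for
  parameter-recovery checks (per-cell tolerance 3 standard errors, with
  the single ~3-sigma excursion expected across 12 attribute-by-group
  cells allowed), and Monte Carlo runs of a few thousand iterations
  compared at four combined standard errors.
* The pipeline (`run_pipeline()`) is staged; failures abort with the stage
  name. Reports are pure renderings of the results object, so every
  printed number is recoverable from `results.json`.

## Limitations

The model inherits the linearity and additivity assumptions of the
underlying analysis; attributes must be preferentially independent and
non-overlapping. Thresholds extrapolate the linear partial value functions
beyond observed performance. Group-mean weights summarise a skewed weight
distribution by design, which is why the Monte Carlo analysis — not the
point model — carries the heterogeneity story. The elicitation engine
assumes error-free responses in its deterministic mode; the logistic mode
exists precisely because respondents near indifference plausibly answer
inconsistently.
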