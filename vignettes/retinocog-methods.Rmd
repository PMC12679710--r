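---
title: "Pointwise retina–cognition analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pointwise retina–cognition analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinocog)
```

## The scientific problem

The retinal nerve fibre layer is an unmyelinated extension of the central
nervous system that can be measured non-invasively at micrometre resolution.
Circumpapillary OCT scans sample its thickness (cpRNFLT) at 768 equidistant
angular locations on a circle around the optic nerve head. **retinocog**
implements a location-resolved analysis of how this profile relates to
cognitive performance in an ageing population cohort: pointwise
mass-univariate regression maps for six DSM-5 cognitive domains,
norm-referenced stratification into mild cognitive impairment (MCI) and mild
neurocognitive disorder (NCD), permutation-calibrated discrimination models,
sector-combination classifiers, and hippocampal-volume group comparisons.

Because individual-level clinical cohort data of this kind cannot be shared,
the package ships a synthetic-cohort generator that reproduces the
*statistical structure* the analysis assumes. Every stage of the pipeline is
exercised and tested against data from this generator.

## Profile geometry and orientation

Profiles are indexed 0–767; location $j$ sits at angle
$\theta_j = 360 j / 768$ degrees from the temporal midline, increasing in
TSNIT order (temporal → superior → nasal → inferior → temporal). Six
anatomical sectors use the standard 90/45/45/90/45/45-degree widths
(T $[-45,45)$, TS $[45,90)$, NS $[90,135)$, N $[135,225)$, NI $[225,270)$,
TI $[270,315)$); a finer scheme uses 24 sectors of 15°, with `S1` straddling
the temporal midline. Both boundaries and offsets are configurable because
published sector conventions differ between devices and groups.

Left and right eyes are mirror images. `align_orientation()` maps every eye
into the common TSNIT frame by mirroring left-eye profiles about the temporal
midline. Whether a device exports left eyes already mirrored is not
universal, so the mirroring rule is a configurable assumption
(`mirror_left`), and alignment is idempotent: an `oriented` flag guarantees
that aligning twice equals aligning once.

## Quality control

Three per-eye reliability rules are applied: signal-to-noise ratio ≥ 20 dB,
≥ 50 averaged B-scans, and at most 5 % of the 768 locations missing or
unreliable. The 5 % rule is read strictly by fraction: 38 masked points of
768 (4.95 %) pass, 39 (5.08 %) fail. Individual measurements are flagged
unreliable when they lie *strictly* outside the pooled empirical 0.5 %–99.5 %
band of all acquisition-present values (inclusive linear-interpolation
percentiles; boundary ties are not flagged). The pool always uses
acquisition-present values, including previously flagged ones, which makes
the flagging operation idempotent. Raw values are never overwritten — flags
live in a separate mask — so every exclusion is auditable.

## Cognitive domains, norms and stratification

Raw tests map onto six domains: attention (TMT-A time), executive function
(TMT B/A ratio), learning/memory (word-list learning), perceptual-motor
ability (visuoconstruction copy), language (semantic verbal fluency) and
social cognition (RMET). Timed measures are sign-inverted before
standardisation, so a higher z-score always means better performance.

Norms are sample-derived per stratum of age band × sex × CASMIN education
level. Age bands default to 5-year bins over 60–80 — a conventional choice;
the binning is an argument, not a constant — and strata below a minimum size
(default 20) are merged with the nearest adjacent band of the same
sex/education cell, so every participant always finds a stratum.

A domain *deficit* is a norm-referenced z in $[-2, -1)$: the band is closed
at −2 and open at −1, with deviations strictly below −2 treated as
dementia-range exclusions. The MCI / mild-NCD diagnosis requires
(i) subjective decline, (ii) at least one deficit domain, (iii) preserved
daily-living independence (SIDAM-ADL ≤ 1) and (iv) no dementia-range
deviation. The amnestic subtype requires learning/memory to be the *only*
deficit domain. MCI and mild NCD are operationally the same computable rule
with independently configurable parameter sets (`dx_criteria()`), because
the two nosologies share the four criteria but published group memberships
can differ slightly; representing the difference as configuration keeps a
single code path. Participants with missing required inputs are flagged
unclassifiable rather than silently counted as negative.

## Pointwise association models

At each location, `fit_pointwise_linear()` runs OLS with thickness as
outcome and the domain z-score, age, sex, scan radius (a proxy for ocular
magnification) and education as regressors. Eyes enter as independent rows —
both eyes of a participant are separate observations — matching the primary
analysis this package reproduces. Because within-person eye correlation is
real, a CR1 cluster-robust standard-error mode by subject is available
(`cluster_se = TRUE`); point estimates are identical, only inference
changes. A documented discrepancy in the source methodology (thickness as
outcome vs. cognitive score as outcome) is surfaced as a switch
(`direction`); thickness-as-outcome is the default.

Education is coded ordinally 1/2/3 by default with a dummy-coding option.
Missing or unreliable points drop an eye from that location's fit only.
Rank-deficient or otherwise unfittable locations are flagged `unfit`,
excluded from the multiple-testing family, and reported.

P-values are adjusted per family — the 768 locations of one domain × sample
× stratum analysis — with the Benjamini–Hochberg step-up procedure
(`p.adjust(method = "BH")`), significant at adjusted p < 0.05. Families are
never pooled across domains. Because it is ambiguous whether a "fraction of
significant locations" should be quoted out of 768 or out of the locations
actually fitted, `significant_fraction()` reports either denominator.

## Discrimination models and permutation calibration

`fit_pointwise_logistic()` fits the analogous maximum-likelihood logistic
model of a diagnosis flag on thickness plus covariates at every location.
Complete separation and non-convergence are detected (boundary fitted
probabilities, non-finite standard errors) and such locations are excluded
from the FDR family with a warning.

Discrimination is summarised by the AUC of the full model's predicted
probabilities, computed as the normalised Mann–Whitney U with 0.5 credit for
ties; `roc_curve()` builds the stepwise ROC whose trapezoidal area equals
that statistic to numerical precision. AUCs are in-sample: no train/test
split is used, matching the analysis being reproduced.

`permutation_auc_pvalue()` calibrates an observed AUC against an empirical
null built by shuffling the outcome labels (5000 times by default; tests use
fewer with fixed seeds) and *refitting the full model* — covariates included
— on every shuffle, recording each refit's in-sample AUC against its own
permuted labels. The empirical p-value is the fraction of null AUCs at or
above the observed one. Labels can be shuffled at the eye-row level
(default, matching eyes-as-rows fitting) or jointly per subject, which is
the exchangeability-correct choice when both eyes of a person carry the same
label.

One property of this construction deserves emphasis: **the in-sample null
AUC distribution does not centre at 0.5 in finite samples.** Every refit
enjoys the same overfitting optimism as the observed model, so the null
mean sits above 0.5 by an amount that grows with the ratio of parameters to
events — with five covariates, 200 rows and 20 % prevalence it is near 0.6,
and it approaches 0.5 only slowly as the event count grows. This is not a
defect but the point of the design: the observed (equally optimistic)
AUC is compared like-with-like against its null, which is what makes the
empirical p-value valid. Descriptions of such nulls as "centred around 0.5"
hold only approximately, at large cohort sizes. The package's acceptance
script computes this null mean explicitly at the desk scale above, and the
test-suite asserts the validity property that actually matters: under the
null, the empirical p-value's type-I error at 0.05 stays at or below 0.05
within Monte-Carlo error.

## Sector-combination models

`aggregate_sectors()` reduces each profile to unweighted per-sector means of
non-masked locations. `best_sector_subset()` searches sector combinations
for the logistic model minimising AIC ($2k - 2\ell$) or BIC
($k\ln n - 2\ell$), with covariates forced into every candidate model.
Forward stepwise search is the default (add the best sector, stop when the
criterion no longer improves or `max_k` is reached; ties break to the lower
sector index, so the search is deterministic); exhaustive enumeration is
available for schemes of up to 12 sectors and doubles as the oracle in the
test-suite. Signed per-sector coefficients are reported so mixed
thinning/thickening patterns remain visible. Externally specified sector
sets (e.g. from a published model) are evaluated by
`evaluate_fixed_subset()`, which deliberately takes the sector labels as
input rather than hard-coding any published set.

## Brain markers

Hippocampal volumes are head-size-corrected by the residual method,
$\mathrm{HCV}_{adj} = \mathrm{HCV}_{raw} - \beta\,(\mathrm{ICV}_{raw} -
\overline{\mathrm{ICV}})$, with $\beta$ the unstandardised slope of
hippocampal on intracranial volume in a reference set. The reference set
defaults to the full analysis sample (whether the slope should be estimated
on controls only is a modelling choice; it is an argument). Left and right
hippocampus are adjusted and tested separately. Group comparisons default to
Welch's unequal-variance t-test, with Student's pooled test as an option.

## The synthetic cohort generator

`generate_cohort()` simulates, per participant: age uniform on the
configured range (the emulated cohort design is age-stratified; uniform is
the neutral stand-in), sex Bernoulli, CASMIN education categorical,
subjective-decline and daily-living flags, and raw cognitive scores; per
eye: scan radius, signal-to-noise ratio, B-scan count, missing-point mask
and a 768-point thickness profile

$$y(\theta) = \mathrm{baseline}(\theta) + \beta_{age}(age - 70)
  + \beta_{sex}\,male + \beta_{rad}(r - 1.73) + \beta_{edu}(e - 2)
  + \textstyle\sum_d \delta_d(\theta)\, z_d + \varepsilon(\theta).$$

The baseline is a constant plus circular Gaussian bumps giving the familiar
double-hump TSNIT shape (peaks near 75° and 285°, ~130 µm at the poles,
~70–90 µm temporally/nasally). Covariate effects default to −0.2 µm/yr,
+2 µm for males, −15 µm/mm of scan radius and +0.5 µm per education level —
magnitudes in the range reported for population OCT samples. Cognitive
effects $\delta_d(\theta)$ are non-zero only on configured angular
intervals; the default embeds +1.5 µm per attention z-unit on $[45°,135°)$,
i.e. a location-restricted association in the superior arc. Diagnosis
effects (`dx_effect_map`) add a constant thickness offset for flag carriers
on configured arcs, which is how case–control signal is embedded.

The noise $\varepsilon$ has four per-eye components: white measurement noise
(SD 2 µm), a short-range local anatomical component (SD 4 µm, 5°
correlation length), a regional smooth component (SD 3 µm, 15°) and a
global offset (SD 6 µm). The smooth components are built by circular
Gaussian-kernel convolution of white noise, rescaled to unit marginal
variance. A single smooth component is not enough: with only one
correlation scale, sector means span a low-dimensional noise space and a
multi-sector classifier can linearly cancel the noise of a signal sector
using its neighbours, producing in-sample separation that real anatomically
variable retinas do not show. The four-scale mixture keeps the per-point SD
(~8 µm) and global-mean SD (~6 µm) in the realistic range and leaves a
~2 µm conditional residual per sector. The angular covariance of real
cpRNFLT is not publicly tabulated, so these correlation lengths are free
simulation parameters, not estimates.

Trail-making times are log-normal. The latent log TMT-A and log B/A-ratio
share a configurable correlation (`cor_a_ratio`, default −0.21), so slower
simple processing speed co-occurs with a relatively smaller B/A ratio; the
sample correlation of the raw quantities reproduces the configured value to
within sampling error. Remaining scores are Gaussian with small age and
education slopes, rounded and clamped to instrument ranges.

Two structural decisions keep the generator honest. First, diagnosis labels
are *not* drawn independently: they are produced by running the package's
own norm-referenced classifier on the simulated scores, so simulator and
classifier cannot drift apart, and simulated prevalence responds to the
criteria exactly as real prevalence would. Second, all randomness flows
through per-participant substreams derived from one seed, so cohorts are
bit-reproducible and stable under participant reordering. Both-eye profiles
share their participant's covariates and embedded effects but have
independent noise realisations; this keeps eye-level rows independent,
which is what makes the eyes-as-rows p-values in the test-suite exactly
valid. It also means the generator understates within-person eye
correlation — a deliberate simplification, and the reason the
cluster-robust mode exists for real data.

What passing tests on this generator do *not* show: robustness to
segmentation failures beyond a missing-point mask, longitudinal
visit-to-visit structure, floor/ceiling pathologies of real
neuropsychological scores, or within-person inter-eye correlation. Results
on real cohorts additionally depend on those features.

## Numerical choices and degenerate inputs

* Percentiles: R quantile type 7 (inclusive linear interpolation); strict
  inequalities at the flagging boundaries.
* OLS: one shared normal-equations solve (Cholesky) for all locations
  without missing data; per-location refits otherwise; failures flagged
  `unfit`, never silently dropped.
* Logistic: IRLS via `glm.fit`; separation detected from boundary fitted
  probabilities; non-converged permutation refits are counted, reported and
  excluded from the null sample.
* AUC ties: midranks (0.5 credit), making the Mann–Whitney and trapezoidal
  ROC computations agree to 1e-12.
* Forward-selection ties break to the lower sector index; exhaustive
  enumeration requires strict criterion improvement, so earlier (smaller,
  lower-indexed) subsets win ties. Both searches are deterministic.
* Zero-variance domains, empty norm strata, single-class outcomes, constant
  outcomes and degenerate t-test inputs raise errors naming the offending
  quantity (identical groups compare with t = 0, p = 1).
* YAML round-trips of configurations write named vectors as maps and keep
  15 significant digits; regenerated cohorts agree to that precision.

## Problem sizes used by the test-suite

The suite exercises the study conditions at sizes chosen to give stable
Monte-Carlo behaviour: pooled-slope recovery at 2000 participants;
TMT-correlation checks at n = 5000; null-calibration of the pointwise maps
with 300 within-cohort permutations of the domain score; false-discovery
control over 200 simulated null cohorts of ~300 eyes; recovery of the
embedded attention effect at ~1300 eyes; sector-combination recovery over
50 replicate cohorts of 1000 eyes; and permutation-AUC calibration at 200
rows × 1000 shuffles. Oracle checks (normal equations, likelihood grids,
brute-force AUC and subset enumeration, hand-computed BH and Welch
examples) run on toy inputs of ≤ 150 rows.

## Known limitations

In-sample AUCs overstate out-of-sample discrimination; the permutation
calibration corrects the *inference*, not the effect-size estimate.
Norm-referenced classification with sample-derived norms is circular at the
cohort level (the norms include the to-be-classified participants), which
mirrors the emulated design but differs from using external normative data.
The generator's angular noise covariance is plausible rather than
estimated. Sector schemes are device-convention defaults; published sector
identities from other instruments may be rotated relative to them.
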