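# retinocog

Pointwise analysis of circumpapillary retinal nerve fibre layer thickness
(cpRNFLT) and cognition in ageing cohorts.

The retinal nerve fibre layer is directly continuous with the central
nervous system and measurable at micrometre resolution by optical coherence
tomography. `retinocog` asks *where* on the 768-point circumpapillary scan
circle thickness relates to cognitive performance, instead of collapsing the
profile to a single mean. It provides, as one tested R pipeline:

* **Quality control** of TSNIT profiles — signal-to-noise, B-scan count and
  missing-fraction filters, pooled-percentile flagging of unreliable
  measurements, and left/right orientation standardisation;
* **Norm-referenced stratification** into MCI and mild neurocognitive
  disorder (DSM-5) from raw neuropsychological scores, using sample-derived
  age/sex/education norms and configurable deficit criteria;
* **Pointwise mass-univariate regression**: at each of the 768 locations,
  OLS of thickness on a cognitive domain z-score plus age, sex, scan radius
  and education, with Benjamini–Hochberg FDR control per 768-location
  family, sector summaries and global-mean models;
* **Discrimination models**: pointwise logistic regression of diagnosis
  flags, Mann–Whitney AUC / ROC curves, and permutation-calibrated
  empirical p-values (labels shuffled, full model refit per shuffle);
* **Sector-combination classifiers**: forward or exhaustive AIC/BIC search
  over 24 × 15° (or 6 anatomical) sector means, plus evaluation of fixed,
  externally specified sector sets;
* **Brain markers**: residual-method ICV adjustment of hippocampal volumes
  and Welch group comparisons;
* **A synthetic cohort generator** reproducing the statistical structure of
  such data — double-hump TSNIT baseline, covariate effects,
  location-restricted cognitive effects, multi-scale angular noise,
  log-normal trail-making scores with a negative TMT-A vs B/A correlation,
  and diagnosis labels produced by the package's own classifier — so the
  whole pipeline is testable without access to restricted cohort data.

The pointwise model at location $j$ (angle $\theta_j$ from the temporal
midline, TSNIT direction) is

$$\mathrm{RNFLT}_{ij} = \beta_{0j} + \beta_{1j} z_i^{(d)}
 + \beta_{2j}\,\mathrm{age}_i + \beta_{3j}\,\mathrm{sex}_i
 + \beta_{4j}\,\mathrm{radius}_i + \beta_{5j}\,\mathrm{edu}_i
 + \varepsilon_{ij},$$

with eyes as rows and BH-FDR over $j = 1,\dots,768$; the logistic analogue
swaps outcome and regressor roles for a diagnosis flag.

## Worked example

```r
library(retinocog)

cfg <- sim_config(n_participants = 500, seed = 42)
coh <- generate_cohort(cfg)
coh <- flag_unreliable(align_orientation(coh))
samples <- build_samples(coh, qc_filter(coh))
A <- samples$sample_A
A
#> cpRNFLT cohort: 480 participants, 760 eyes
#>   oriented to TSNIT frame: 760 / 760 eyes
#>   masked points: 1785 missing, 2916 flagged unreliable

res <- fit_pointwise_linear(A, "attention")
significant_fraction(res)        # % of fitted locations with q < 0.05
#> [1] 25
sector_summary(res)
#>   label n_locations n_fitted n_significant frac_significant mean_coefficient
#> 1     T         192      192             0                0        0.1056331
#> 2    TS          96       96            96                1        1.5652479
#> 3    NS          96       96            96                1        1.7144984
#> 4     N         192      192             0                0        0.1098417
#> 5    NI          96       96             0                0        0.2621768
#> 6    TI          96       96             0                0        0.1716540

gm <- fit_global_mean(A, "attention")
sprintf("global mean: beta = %.3f um/z, p = %.3g", gm$beta, gm$p_value)
#> [1] "global mean: beta = 0.514 um/z, p = 0.00835"

best_sector_subset(A, "dx_mci", criterion = "AIC")
#> Sector logistic model (AIC, forward search)
#>   sectors: S17, S11, S8, S10
#>   AUC 0.647 | AIC 605.34 | BIC 647.04 | logLik -293.67 | n 760 | k 9
```

Reading the output: the generator's default configuration embeds a
+1.5 µm per attention-z effect on the superior arc [45°, 135°); the
pointwise map recovers it — all 192 locations of the TS and NS sectors are
FDR-significant with mean coefficients near 1.5–1.7 µm/z, while the other
sectors stay null. The global-mean regression dilutes the localised effect
across the whole circle (β ≈ 0.51 µm/z), which is exactly why the pointwise
analysis exists. The sector search then looks for the diagnosis signal; with
none embedded here it settles on a weakly discriminating combination
(AUC 0.65), typical of pre-dementia cohorts.

A thin command-line front end over the same functions is installed at
`system.file("cli/retinocog", package = "retinocog")` with verbs
`simulate`, `qc`, `score`, `classify`, `associate`, `discriminate`,
`sectors`, `brain` and `run-all`, all configured by YAML
(`run_pipeline()` / `read_run_config()` from R).

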