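# salisense

Chemometric analysis of paper-based colorimetric sensor arrays for
non-invasive diabetes screening from saliva.

A 12-spot paper sensor (porphyrazines, pH-indicator dye mixtures, and
coated silver nanoparticles) is scanned before and after exposure to a
saliva sample.  Each sample becomes a 36-element response vector — the
absolute per-spot changes in mean red, green and blue intensity,
`x = (|ΔR₁|, |ΔG₁|, |ΔB₁|, …, |ΔB₁₂|)` — and the analysis chain is:

* **Imaging** — circular-ROI spot means and before/after difference
  vectors from 8-bit RGB scans (`extract_spot_means()`,
  `compute_response_vector()`, `make_color_map()`).
* **Condition scoring** — the discrimination ability function
  `DAF = MSB/MSW` (inter- over intra-group variance, the one-way ANOVA
  F ratio; trace-of-scatter ratio for vector responses) to rank
  fabrication/measurement conditions (`daf()`, `rank_conditions()`).
* **Total response** — the Euclidean norm `‖x‖₂` per sample, a pooled
  two-sample t-test between groups, and a grand-mean threshold
  classifier: `‖x‖₂ > threshold ⇒ diabetic` (`total_response_summary()`,
  `threshold_classify()`).
* **Pattern recognition** — mean-centred PCA followed by a two-class
  Fisher discriminant `w ∝ S_W⁻¹(μ₁ − μ₂)`, cross-validated with the PCA
  refitted in every fold (`pca_fit()`, `lda_fit()`, `crossvalidate()`).
* **Correlation / reproducibility** — Pearson r between receptor
  responses and fasting blood glucose (FBG), and replicate
  `RSD% = 100·s/x̄` (`pearson()`, `rsd_percent()`).

The original clinical dataset is not public, so the package includes a
**synthetic-data generator** (`generator_config()`, `generate_cohort()`,
`generate_responses()`, `render_sensor_image()`) whose defaults are
calibrated to the published study conditions: 45 + 45 participants with
the published demographics, group norm distributions 358.31 (±27.98) vs
328.47 (±31.60), receptor–FBG correlations 0.871 (TMA-AgNPs) and 0.726
(MR+TBOH on binned FBG), and replicate RSDs 6.03%/6.71%.  See the
methods vignette (`vignettes/salisense-methods.Rmd`) for the model.

## Worked example

Simulate a default 90-sample study and analyse it end to end:

```r
library(salisense)
cfg <- run_config(render_images = FALSE)        # generator seed 1
res <- cmd_simulate(cfg, "run")
rep <- cmd_analyze(res$response_data, res$cohort_data, cfg, outdir = "run/analysis")

rep$total_response$group_stats
#>         group  n     mean       sd
#> 1    diabetic 45 371.6148 23.61853
#> 2 nondiabetic 45 333.4473 31.05240
round(c(grand_mean = rep$total_response$grand_mean,
        t = rep$total_response$t), 2); signif(rep$total_response$p, 3)
#> grand_mean          t
#>     352.53       6.56
#> [1] 3.53e-09
c(norm_rule = rep$total_response$accuracy,
  pca_lda_loo = rep$discrimination$accuracy)
#>   norm_rule pca_lda_loo
#>    70.00000    92.22222
round(c(r_tma_fbg = rep$correlations$tma_agnp_fbg$r,
        r_mr_fbg_binned = rep$correlations$mr_tboh_fbg_binned$r), 3)
#>       r_tma_fbg r_mr_fbg_binned
#>           0.903           0.656
```

Reading the output: the two groups' total responses separate strongly
(pooled t = 6.56, p ≈ 4·10⁻⁹).  The univariate grand-mean threshold rule
reaches 70% accuracy — close to its closed-form ceiling under the two
norm distributions — while the multivariate PCA-LDA classifier, which
also sees *which* receptors responded, reaches 92% here (mean ≈ 89%
across seeds).  Per-cohort statistics fluctuate at n = 45/group: this
seed's diabetic norm mean (371.6) sits about 3 standard errors above the
configured 358.31, and single-cohort correlations scatter around the
configured 0.871/0.726.  The report also writes `norms.csv`,
`scores.csv`, a PC1/PC2 score plot and `report.json` under
`run/analysis/`.

A thin command-line front end wraps the same three stages:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/salisense", package = "salisense"))')
Rscript "$CLI" simulate --out run --seed 1
Rscript "$CLI" extract  --images run/images --layout run/layout.yaml --out run/extracted.csv
Rscript "$CLI" analyze  --responses run/responses.csv --cohort run/cohort.csv --out run/analysis
```

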