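# lipidflux

Condition-contrast shotgun lipidomics turns raw lipid-identification
exports — one row per identified lipid ion, with per-sample peak areas —
into biological statements: which lipid classes drive the separation
between a stress and a control condition, which species appear only under
stress, and how fatty-acyl composition and unsaturation are remodeled.
`lipidflux` implements that analysis as a tested, reusable R pipeline for
two-batch, two-condition designs (the motivating system is plant-root
hypoxia, where triacylglycerols accumulate and unusually polyunsaturated
16:4-containing species appear), together with a synthetic-data generator
that plants known effects so every stage can be verified without any
external download.

## What the pipeline computes

**Preprocessing** (per polarity): identification-quality filtering (grades
A/B, |ppm| ≤ 5), technical-replicate averaging, summation of adduct rows
per species, blank exclusion (species kept only if the mean biological
intensity is ≥ 5× the mean blank intensity), class-wise internal-standard
normalization, median normalization, and a presence filter (detected in
both sets and in ≥ 50 % of the samples of at least one condition).

**Ordination and enrichment.** Species detected in ≥ 50 % of all samples
are completed (half-minimum), batch-adjusted with the parametric
empirical-Bayes location/scale model (ComBat) preserving the condition
covariate, and decomposed by PCA on centered, unit-scaled log2
intensities. The contribution of species *i* to dimension *d* is its
squared-loading share

```
contrib[i, d] = loading[i, d]^2 / sum_j loading[j, d]^2 ,
```

and a species *spans* a dimension when `contrib > 2/p` (p = number of
species). For each lipid class the 2×2 table spanning×membership is
tested with Fisher's exact test (two-sided, minimum-likelihood rule,
odds ratio ad/bc) on the dimension that best separates the conditions.

**Differential statistics.** Condition-exclusive species (≥ 50 % of one
condition's samples in at least one set, zero detections in the other
condition), double-bond histograms per class, fatty-acyl abundance
profiles (a species counts once per distinct acyl), Shapiro–Wilk
normality flags, and two-sided Welch t-tests on log2 abundances with
Holm–Šídák step-down correction:

```
p_adj(i) = max_{j <= i} [ 1 - (1 - p_(j))^(m - j + 1) ]   (sorted order)
```

## Worked example

```r
library(lipidflux)

sim <- generate_lipidomics(synth_config(seed = 7))
res <- run_pipeline(sim$records, sim$samples,
                    sim$blank_records, sim$standard_map)
print(res)
#> <lipid_pipeline>
#>   raw_records                  628
#>   quality_filtered_records     608
#>   merged_species               459
#>   blank_filtered_species       445
#>   presence_filtered_species    428
#>   pca_species                  427
#>   spanning_species             76
#>   hypoxia_exclusive            11
#>   significant_units            10
#>   separating dimension: PC1 (12.2% variance)

res$enrichment[res$enrichment$class_code == "TG", ]
#>    class_code  a  b  c   d odds_ratio      p_value direction
#> 17         TG 63 13 81 270   16.15385 1.311234e-22  enriched
```

Reading: of 428 species surviving the filters, 76 span the
condition-separating dimension; TGs are 63 of those 76 (odds ratio 16.2,
Fisher p ≈ 1e-22) — the planted TG increase is recovered as class
enrichment. The 11 hypoxia-exclusive species are exactly the planted
16:4-containing TG and PE species (`truth_audit()` reports recall and
precision 1.0 for this run). `plot(res$pca)` draws the score plot;
`write_pipeline_outputs(res, "out/")` writes every stage table as TSV.

A thin command-line front end with `generate` and `run` subcommands is
installed at `inst/scripts/lipidflux-cli.R`.

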