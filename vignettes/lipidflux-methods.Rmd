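---
title: "Methods: from lipid identification tables to class-level remodeling statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from lipid identification tables to class-level remodeling statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidflux)
```

`lipidflux` analyzes condition-contrast shotgun lipidomics experiments in
which plants (or any organism) are grown in two independent sets
(batches), each set contributing biological replicates of a control and a
stress condition, and lipids are identified by an external search engine
whose export — one row per (species, adduct) ion with per-injection peak
areas — is this package's input. This vignette documents the statistical
model behind each stage, the tunable parameters, and the design decisions
taken where the underlying methodology is genuinely open.

## Nomenclature model

Shorthand names are parsed at two levels. A *sum composition* ("TG 54:7")
states only total acyl carbons and double bonds; a *molecular species*
("TG 16:0_18:2_18:3") resolves the individual chains. Underscores denote
unknown sn-position; because no positional information exists at this
annotation level, slash-separated names are rejected rather than silently
reinterpreted, chain order is canonicalized by sorting on (carbons,
double bonds), and species equality is order-insensitive. Oxidized and
ether chains (e.g. a "16:4-O" suffix) are outside the grammar and raise a
specific parse error. The class vocabulary — class code, category, and
expected chain count — ships as an editable TSV
(`inst/extdata/lipid_classes.tsv`), so classes can be added without code
changes; every class maps to exactly one of the five lipid categories
(glycerolipid, glycerophospholipid, sphingolipid, sterol lipid, prenol
lipid). Chains must satisfy `double_bonds <= carbons / 2`; molecular
species must satisfy the chain count of their class and their sum fields
are always recomputed from the chains.

## Preprocessing

Stages apply strictly in order — merge, blank exclusion,
internal-standard normalization, median normalization, presence filter —
and the stage tag of the intensity table enforces that order. Zero peak
areas are coerced to missing on construction: in peak-area exports a zero
is a non-detection, not a measured abundance. No stage ever imputes;
missingness propagates until the PCA branch explicitly completes it.

* **Quality filter.** Identification grades A and B are kept; the
  absolute mass error bound defaults to 5 ppm, matching the precursor
  search tolerance commonly used upstream. Both are configurable.
* **Technical replicates.** Injections named `<sample>.t<k>` are averaged
  over non-missing injections before any statistics, so the downstream
  unit is the biological replicate.
* **Adduct merging.** Areas of one species observed as different adducts
  are summed per sample with missing-aware semantics (`NA + x = x`,
  `NA + NA = NA`); total non-missing area is conserved. Names are
  canonicalized first, so chain-order variants merge too.
* **Blank exclusion.** A species is treated as contamination unless its
  mean intensity over biological samples is at least 5-fold its mean over
  blank runs (inclusive boundary). The aggregate over runs is the mean on
  both sides — the rule's source does not define the aggregate, and the
  mean is symmetric and stable for the small number of blank runs
  typically acquired. Removed species are reported with their ratios in a
  machine-readable filter log.
* **Internal standards.** One spiked labeled standard per class; every
  species is divided per sample by its class standard, making values
  unitless and cancelling per-sample extraction efficiency exactly (the
  operation is invariant to proportional drift of the standard). A class
  without a mapped standard is a configuration error, a standard missing
  in any sample an error naming the samples. Standards are removed from
  the species axis afterwards.
* **Median normalization.** Each sample is scaled so all per-sample
  medians equal the median of medians; the operation is idempotent.
* **Presence filter.** A species must be detected in at least one sample
  of *each* set and in at least 50 % of the samples within at least one
  condition. Condition fractions pool the two sets (18 samples per
  condition in the default design); the per-set reading would make the
  filter stricter than the stated rule implies.

Positive- and negative-mode data are processed as separate tables
end-to-end; a two-polarity study simply runs the pipeline twice. This
mirrors reporting separate ordinations per polarity and avoids inventing
a cross-polarity reconciliation rule that the data type does not define.

## Batch adjustment

The two sets are a batch factor. `batch_adjust()` implements the
parametric empirical-Bayes location/scale model (ComBat): per-species
standardization under a design containing batch indicators plus the
condition covariate (so the biological contrast is preserved), a normal
prior on per-batch location shifts, an inverse-gamma prior on per-batch
scale factors with method-of-moments hyperparameters, and posterior means
obtained by the standard fixed-point iteration (relative tolerance 1e-6,
at most 1000 iterations — tighter than typical defaults, at negligible
cost for a few hundred species). Values are log2-transformed internally
and back-transformed, so the table stays positive and its dimensions
never change. A single batch is the identity; species with zero variance
within every batch cannot be standardized and are left unadjusted and
flagged in the returned model, which also exposes the per-batch shifts,
scale factors, and shrinkage hyperparameters. The unit tests cross-check
the whole adjustment against the independent reference implementation in
the `sva` package.

One property worth stating precisely: empirical-Bayes shrinkage pulls
each species' batch-shift estimate toward the prior mean, so after
adjustment the *per-species* batch means still differ by a term of the
order of the sampling noise — that is the intended behaviour, not a
defect, and the reference implementation leaves the same residual. The
planted shift itself is removed: in the near-noise-free limit the
residual between-batch shift vanishes (the test suite verifies < 1e-6 at
noise sd 1e-6), and under realistic noise the *condition* effect is
recovered within 10 % across 100 simulations despite a confounding batch
shift twice its size.

## PCA and class enrichment

Missing values surviving the PCA presence filter (detection in ≥ 50 % of
all samples, inclusive) are completed by half the species' minimum
observed value — the conventional choice for left-censored MS
intensities; `zero` and `row_median` alternatives are available and every
completion is flagged. PCA is the SVD of the centered, per-species
unit-scaled log2 matrix; unit scaling prevents high-abundance storage
lipids from dominating the decomposition purely by magnitude and can be
turned off. Loadings have unit norm, explained variance fractions are the
eigenvalue shares, and the *contribution* of a species to a dimension is
its squared-loading share — the standard contribution measure of the PCA
literature, adopted here as the definition of a species' "weight" on a
dimension, which is otherwise not formally defined. A species spans a
dimension when its contribution strictly exceeds twice the uniform
expectation 1/p; at exactly the threshold it does not span.

The condition-separating dimension is chosen as the one maximizing the
absolute difference of condition score means — the quantitative
counterpart of reading the separation off a score plot. Classes are then
tested one-vs-rest: the 2×2 table of spanning status against class
membership goes into Fisher's exact test, two-sided by the
minimum-likelihood rule (both enrichment and depletion are of interest),
with the sample odds ratio ad/bc (infinite when bc = 0). P-values are
exact hypergeometric tail sums; a tie tolerance of one part in 1e7
guards against floating-point loss of exactly tied table probabilities.
No correction is applied across classes by default — the class family is
small and directions are reported descriptively — but a
Benjamini–Hochberg column is available.

## Differential statistics

* **Exclusive species**: detected in ≥ 50 % of one condition's samples in
  at least one set and in zero samples of the other condition. The
  threshold deliberately mirrors the presence filter, since "exclusively
  detected" otherwise has no stated cutoff; the two exclusive sets are
  disjoint by construction.
* **Double-bond profiles** count distinct detected species per total
  double-bond number and condition.
* **Acyl profiles** sum, per sample, the abundance of all species of a
  class containing a given acyl. A species with a repeated chain
  (TG 16:0_18:2_18:2) contributes once to 18:2, matching counts of
  "species esterified with" an acyl; a multiplicity-weighted mode is
  available.
* **Testing**: two-sided Welch t-tests on log2 abundances per unit
  (species, or any profile matrix), hypoxia against control. Welch is
  chosen because no variance-homogeneity assumption is checked anywhere
  upstream. P-values are adjusted across the family with the Holm–Šídák
  step-down (sorted `1 - (1-p)^(m-j+1)` with running maximum, clipped at
  1), which controls the family-wise error rate and is uniformly more
  powerful than Holm's Bonferroni variant under independence. Units with
  fewer than two non-missing values per group, or zero spread in both
  groups, are skipped and flagged rather than guessed at. Shapiro–Wilk
  normality is computed per group where defined (n ≥ 3, non-constant) and
  reported as a flag; failing units are still tested but marked, as no
  non-parametric fallback is part of the procedure. The two sets are
  pooled at this stage — the batch signal has either been removed
  (PCA branch) or enters symmetrically in both conditions under the
  balanced design.

## The synthetic-data generator

`generate_lipidomics()` emulates the data type's statistical structure so
that parameter recovery is testable: log2 intensities are normal around
class baselines (log-normal areas — the standard model for MS
intensities), with between-species spread 1.2, biological noise 0.5 and
injection noise 0.1 log2 units; two sets of 9+9 replicates with an
additive log2 batch shift (0.75 by default); logistic intensity-dependent
dropout (midpoint 11, scale 1.5 log2 units, giving a few percent overall
missingness concentrated in low-abundance species); ~440 species across
the major classes with glycerolipids plus glycerophospholipids near 78 %
of the inventory; a planted hypoxia effect of log2-fold 0.6 on 60 % of TG
species plus smaller decreases on PC, LPC and MGDG and an increase on PA;
11 hypoxia-exclusive species (9 TG, 2 PE), each carrying a 16:4 acyl and
never emitted under control; blank contamination for 6 % of species,
planted half below and half above the 5-fold rule; a 30 % chance of a
species splitting into two adduct rows whose areas sum to the species
total; constant-level internal standards with 5–7 % multiplicative noise;
and deliberately low-quality rows that the quality filter must remove.
Named species of interest (TG 54:7, TG 54:8, PC 18:1_18:2,
MGDG 18:2_18:2, LPC 17:0, LPC 18:2, TG 16:3_16:4_18:2, 16:4-containing
PEs) are embedded verbatim. The seed fully determines the output, and a
`ground_truth` object records every planted effect for `truth_audit()`.

What the generator does *not* emulate — and therefore what passing tests
cannot certify about real data: retention-time or spectral artifacts,
isotope interference, correlated (pathway-level) abundance structure,
heavy-tailed or sample-specific noise, non-logistic missingness, and
misidentification by the upstream search engine. Recovery results on
synthetic data bound what the pipeline can do when its model assumptions
hold; they are not field performance guarantees.

```{r, fig.width = 5, fig.height = 4}
sim <- generate_lipidomics(synth_config(seed = 7))
res <- run_pipeline(sim$records, sim$samples,
                    sim$blank_records, sim$standard_map)
plot(res$pca, main = "Synthetic study, PCA after batch adjustment")
```

## Numerical choices and degenerate inputs

Fisher p-values are tail sums of `dhyper` terms, compared with a 1e-7
relative tie tolerance and capped at 1. The Holm–Šídák adjustment passes
`NA` through and excludes it from the family size. Zero-variance species
are centered but not scaled in the PCA (their loadings are zero) and left
unadjusted by ComBat. `fisher_exact(0,0,0,0)` and constant or too-short
inputs to the normality check are errors, not silent NAs. Welch tests on
two identical groups return t = 0, p = 1. All intensity tables reject
negative values; sample triplets (condition, set, replicate) must be
unique among non-blank samples.

## Verification scale

The test suite verifies exactness of the Fisher implementation on all
46,376 tables with total ≤ 30 against direct enumeration, the
Holm–Šídák formula on 1000 random vectors, batch-shift removal and
condition-effect recovery over 100 simulations, end-to-end TG-enrichment
recovery over 100 simulated studies at the default design with a
1000-resample null calibration of the class tests, exclusive-species
recall and precision over 100 simulations per dropout condition,
round-trip parsing on a 10,000-name corpus, and family-wise error
control of the testing path over 1000 null simulations with 60 units.
These sizes are the package's chosen verification scale: large enough for
stable rates, small enough to run routinely.

## Known limitations

The pipeline assumes a balanced two-condition design within each set;
unbalanced designs work but the separating-dimension heuristic and the
pooled t-tests lose their symmetry argument. Enrichment treats species as
exchangeable units — no abundance weighting within the spanning set. The
blank rule compares means, so a single wild blank run can mask or spare a
species. Annotation below the molecular-species level (sn-position,
double-bond geometry) is out of scope, as are raw-spectrum processing and
any cross-polarity merging beyond running the pipeline per polarity.
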