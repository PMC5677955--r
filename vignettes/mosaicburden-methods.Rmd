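---
title: "Methods: mosaic PTV detection and cancer burden analysis"
author: "mosaicburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mosaic PTV detection and cancer burden analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicburden)
```

## Scientific background

Clonal hematopoiesis — the age-related expansion of blood-cell clones
carrying somatic mutations — is marked by mosaic protein-truncating
variants (PTVs) in a small set of genes: *PPM1D*, *TET2*, *ASXL1* and
*DNMT3A*. Because the mutant clone is only a fraction of the blood, these
variants appear in blood-derived exome genotypes as heterozygous calls
whose allele balance (alternate reads over informative reads) sits well
below the germline expectation of 0.5. mosaicburden implements the
statistical machinery needed to (i) separate such mosaic genotypes from
ordinary germline heterozygotes, (ii) test whether mosaic-PTV *carrier
status* is associated with solid-tumor cancer in a case–control design
with unequal age and sequencing depth between cohorts, (iii) localise any
excess burden to particular cancer phenotypes and genes by age-matched
resampling, and (iv) check, in paired blood/tumor samples, that the
blood-detected mosaics are depleted from the tumors — the observation
that argues they are not tumor drivers.

Access-controlled cohort data cannot ship with a package, so a synthetic
cohort generator reproduces the *statistical structure* of the study
design and serves as the test bed for every stage.

## The mosaic caller

For a genotype with `a` alternate reads out of `n = ref + alt`
informative reads, the caller computes the lower binomial tail

$$p = P(X \le a), \qquad X \sim \mathrm{Binomial}(n, 0.5),$$

and flags the genotype mosaic when `p < alpha` **and** `n > depth_min`.
Defaults are `alpha = 0.001` and `depth_min = 20`, i.e. p &lt; 0.001 at
more than 20× coverage. Numerical and interpretive choices:

* **One-sided lower tail.** The mosaic signature is *low* allele
  balance; a two-sided option (`two_sided = TRUE`, minimum-likelihood
  convention) exists but is off by default.
* **Strict depth gate.** "More than 20× coverage" is read as
  `depth > 20`: 21 informative reads minimum. The p-value is reported
  even when the gate fails, so filtering decisions are auditable.
* **Depth from AD, not DP.** Depth is `ref + alt` from the genotype's
  allele depths — the reads that actually inform allele balance — rather
  than the VCF `DP` field, which may count uninformative reads.
* **No multiple-testing correction across sites.** The fixed `p < 0.001`
  cutoff is part of the operational definition of "mosaic" here, not an
  inference; changing it changes the carrier definition.

A sample is a *carrier* when it has at least one mosaic-flagged PTV
(stop-gain, essential splice site or frameshift) in the four candidate
genes.

## Case–control association

`fit_carrier_model()` fits a binomial GLM of case status on carrier
status, optionally adjusted for age and mean target coverage:

$$\operatorname{logit} P(\text{case}) = \beta_0 +
  \beta_1\,\text{carrier} + \beta_2\,\text{age} +
  \beta_3\,\text{coverage}.$$

Both adjustments matter by design: controls are on average about ten
years younger, and mosaic prevalence rises steeply with age; cases are
covered at ~33× versus ~29× for controls, and deeper sequencing detects
more mosaics. The reported odds ratio is `exp(beta_1)` with a Wald 95% CI
on the log-odds scale (the default; a profile-likelihood CI is available
via `ci_method = "profile"`). Age enters linearly in the log odds;
coverage is the per-sample mean depth over the candidate-gene target.
Complete separation is detected (coefficient standard errors blowing up)
and raised as an error recommending an exact or penalized fit rather than
silently reporting a meaningless Wald interval. Phenotype exclusions
(e.g. re-running without breast and ovarian cancers) drop samples before
fitting.

`population_contingency()` covers the population-register style analysis:
a 2×2 carrier-by-prior-cancer table with per-group event rates in
percent, the crude odds ratio (Haldane–Anscombe 0.5 correction, flagged,
when a cell is zero), and an optional age-adjusted logistic p-value when
per-sample data are available.

## Age-matched resampling burden test

For a phenotype with `N` cases, `phenotype_burden()` draws random sets of
`N` samples *without replacement* from the pool of all cancer cases
(including the target phenotype's own cases; `exclude_self` is a
sensitivity option) and keeps a set only when a two-sided Wilcoxon
rank-sum test finds no significant age difference from the target set
(`p > 0.05` by default). With `B` accepted sets, the empirical p-value is
the fraction whose carrier frequency strictly exceeds the target's. Both
the literal fraction and the add-one estimator `(x + 1) / (B + 1)` are
reported; the literal fraction is the default `empirical_p`. Design
notes:

* Sets are distinct samples (without replacement): a "set of samples"
  rather than a bootstrap.
* The acceptance threshold 0.05 operationalises "insignificant age
  difference"; it is configurable. When every age in pool and target is
  identical the Wilcoxon has no rank variance and the acceptance p is
  defined as 1 (every draw accepted).
* `B` defaults to 10⁴. The draw loop fails loudly — naming the
  phenotype — if no age-matched set is found in `max_draw_factor`
  attempts, rather than silently accepting mismatched sets.
* Carrier *status* (not variant multiplicity) is counted, consistent
  with the carrier model of the association stage. Per-gene tests
  restrict the carrier flag to mosaics in one gene and reuse the same
  accepted sets, since acceptance depends only on ages.
* The strict-`>` tie rule means a phenotype whose carrier frequency no
  resample can exceed gets a literal p of 0 (add-one: `1/(B+1)`). In the
  degenerate case of a carrier-free cohort *every* phenotype has that
  property; the add-one estimator or the `greater_or_equal` tie rule is
  the sensible reading there.

`burden_scan()` runs every phenotype (overall and per gene) and
recomputes the Bonferroni threshold `alpha / n_phenotypes` from the data
— 0.05/20 = 0.0025 at the study's phenotype count — rather than
hard-coding it.

## Paired blood/tumor depletion

`depletion_test()` is a one-sided paired Wilcoxon signed-rank test of
blood allele balance exceeding tumor allele balance at the same
sample/site. Pairs with zero tumor depth are dropped before testing and
zero differences are dropped per the standard signed-rank convention. For
up to 25 informative pairs the exact sign-flip null distribution is used;
it is built by convolution over doubled midranks, which keeps it correct
in the presence of tied |differences| (base R's `wilcox.test()` offers no
exact null with ties). Beyond 25 pairs the normal approximation with
continuity and tie corrections is used. The directional alternative
(blood &gt; tumor) reflects the depletion claim being tested; both pooled
and per-gene results are available because the gene panels can be read
either way. `coverage_comparison()` reports the paired depth comparison
that rules out a sensitivity artefact: tumors must be covered at least as
well as blood for the depletion to be meaningful.

## The synthetic cohort generator

`generate_cohort()` emulates the discovery design; its defaults are the
study conditions, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `n_cases`, `n_controls` | 7979 / 6177 | discovery cohort sizes |
| `case_depth_mean`, `control_depth_mean` | 33 / 29 reads | mean target coverage per cohort |
| `case_age_mean`, `control_age_mean` | 60 / 50 y (sd 12, truncated at 18) | only the ~10-year gap is documented; 60/50 with sd 12 is a realistic adult cancer-cohort spread |
| `carrier_base_rate` | 0.005 | carrier probability of a 50-year-old control; keeps overall prevalence under 1% |
| `carrier_age_slope` | 0.05 / y | log-odds increment per year, the order of magnitude reported for clonal hematopoiesis prevalence curves |
| `carrier_case_log_or` | log(1.26) | the conditional carrier–case odds ratio used for parameter-recovery simulations |
| `gene_weights` | 18:50:40:60 / 168 | proportional to observed mosaic PTV counts in PPM1D/TET2/ASXL1; DNMT3A set as the largest contributor, as in clonal-hematopoiesis cohorts |
| `mosaic_af_range` | (0.10, 0.20) | clonal fractions well below 0.5; uniform because the clone-size distribution is not documented |
| `tumor_depletion_af` | 0.02 | residual blood contamination of tumor DNA |
| `tumor_depth_factor` | 1.2 | tumors covered at least as well as blood |
| `germline_site_rate` | Poisson(1) per sample per gene | background heterozygous sites (true AF 0.5), ~10% of them PTV-class, to exercise the consequence filter and the caller's specificity |
| `exon_concentration` | 0.9 | mosaic PTVs concentrate in the last exon of PPM1D/ASXL1 (and exon 3 of the three-exon TET2 transcript); DNMT3A is uniform |

Carrier status is drawn per sample from
`logit P = logit(base) + slope (age - 50) + log OR · case`; each carrier
gets exactly one mosaic PTV (the analyses model carrier status, not
multiplicity). Per-site depth is Poisson around a per-sample mean
coverage (gamma-distributed around the cohort mean, CV 0.1, so the
coverage covariate is informative); a negative-binomial option provides
overdispersion for robustness checks. Alternate reads are binomial in
depth and true allele fraction. A site exists only if at least one
alternate read is observed: germline sites with zero alternate reads are
simply never called, while mosaic sites are redrawn so that every
simulated carrier's variant is observed (this is what makes
"one mosaic site per carrier" an exact invariant).

What the generator deliberately does **not** model: read-level error and
mapping artefacts, strand bias, contamination, multi-allelic sites,
clonal dynamics over time, per-phenotype carrier enrichment, and
realistic indel representation (frameshifts are written schematically as
1-bp deletions). Tests passing on this generator therefore validate the
statistical machinery — calibration, parameter recovery, exactness of the
combinatorial nulls — not robustness to sequencing artefacts, which
upstream QC must handle on real data.

## File interfaces

`write_fixtures()` emits VCF 4.2 (FORMAT `GT`, `AD`, `DP`; one biallelic
record per site; sample columns in metadata order; non-carrier samples
`0/0` with missing AD), a metadata TSV
(`sample_id/status/phenotype/age/mean_coverage`, controls' phenotype
written as `none`) and an annotation TSV pre-reduced to one row per site
(`site_id/gene/transcript/consequence/exon_rank/exon_total`). When sites
carry paired tumor reads a fourth file, `pairs.tsv`, preserves them so
the fixture set round-trips losslessly. `read_inputs()` parses the VCF
with `VariantAnnotation::readVcf()`, maps raw VEP-style consequence
strings (`splice_donor_variant`, `splice_acceptor_variant`, ...) onto the
controlled vocabulary through a fixed dictionary (logged), drops
genotypes with missing or zero-sum AD with a logged count, and errors
when more than 10% are unusable or when VCF samples are missing from the
metadata. Note the VCF is a dense site-by-sample matrix: the fixture
writer targets test- and demonstration-scale cohorts; full-scale
simulation studies should drive the analysis functions on the in-memory
tables, as `scripts/acceptance.R` does.

## Numerical choices and degenerate inputs

* Binomial tail probabilities come from `pbinom()` (exact to double
  precision; verified against direct pmf summation for all depths ≤ 50).
* GLMs are fitted with tightened convergence (`epsilon = 1e-12`) so the
  no-covariate carrier OR matches the closed-form 2×2 odds ratio to
  1e-9.
* Empty PTV sets give an `exon_enrichment` result with `total_ptv = 0`
  and an `NA` fraction flagged `undefined`, not an exception.
* "Not testable" is a first-class result (constant covariate, a cohort
  without carriers, all-tied paired differences), distinct from errors
  (unknown labels, inconsistent files, separation).
* The exon-position diagnostic test (optional) uses a uniform-across-
  exons null; exon *lengths* are not part of the annotation schema, so a
  length-weighted null is out of scope and the test is labelled a
  diagnostic extension.

## Test-suite problem sizes

The package's statistical guarantees are exercised at sizes chosen to
give tight Monte-Carlo error while keeping the default test run
comfortable: exhaustive enumeration of the binomial caller to depth 50;
resampling convergence on pools of ≤ 12 cases at B = 10⁵ against exact
subset enumeration; null calibration of the carrier GLM over 200
replicate cohorts of 5000 samples and of the burden test over 2000 null
cohorts at B = 2000; and parameter recovery at the full printed design
(7979/6177) over 100 replicate cohorts. Null-calibration cohorts use
equal depth means in both cohorts so that caller misclassification is
non-differential under the null, and the burden-calibration cohorts use
constant ages so the acceptance filter is exact; both choices isolate the
property being measured.

## Known limitations

* The caller assumes a clean diploid heterozygous null (AF 0.5); copy-
  number changes or contamination shift allele balance and would inflate
  mosaic calls. No CNV-aware modelling is attempted.
* The burden test conditions on the called carrier table; caller
  sensitivity (~80% at 33× for clonal fractions 0.10–0.20) attenuates
  phenotype contrasts accordingly.
* Tumor allele balances are used as-is; tumor purity and blood
  contamination of tumors are not deconvolved.
* The association model treats samples as independent; relatedness and
  ancestry structure must be handled upstream.
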