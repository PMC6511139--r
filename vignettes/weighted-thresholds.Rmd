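---
title: "Annotation-weighted significance thresholds: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-weighted significance thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annogwas)
```

This vignette documents the statistical model behind `annogwas`, the
assumptions it makes, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where the procedure left genuine freedom.

## The procedure

The pipeline turns a set of GWAS association signals into
annotation-category-specific significance thresholds in five steps:
conditional QTL detection, LD-based candidate extraction, category
classification, maximum-likelihood enrichment estimation, and weighted
Bonferroni correction. Each step is an exported function; `run_pipeline()`
chains them over TSV/VCF/BED files.

### Conditional QTL detection

Per chromosome, round 1 is an unconditional single-marker scan. If the
top variant ("lead SNP") exceeds the genome-wide threshold (on the
−log10 P scale), its dosage is added as a covariate and the chromosome is
rescanned; the process repeats until no new lead is significant. Two
guard rules apply:

* a round-k lead (k ≥ 2) is accepted only if it was also significant in
  round 1 — a conditional-only signal is treated as a stopping condition;
* a lead that is the *only* significant variant within ±1 Mb (window
  inclusive) is excluded from the QTL list as a probable artifact of
  mis-mapping or imputation error.

The excluded "lone" leads are still conditioned on by default
(`condition_on_lone = TRUE`); without that, the same lone lead would top
every subsequent round and the scan could not proceed past it. Setting
the flag to `FALSE` instead stops the chromosome scan at the first lone
lead.

### Candidate sets and their use

A QTL's candidates are the variants on the same chromosome with
r² > 0.2 to the lead (strict inequality) that are themselves round-1
significant, plus the lead. Round-1 p-values are used as the common
significance reference for all QTL, including leads found in later
rounds. When one variant qualifies for two QTL it is kept only in the
QTL where its r² is larger (its own lead always stays put), so that the
pooled counts feeding the estimator contain each variant at most once per
trait; across traits, occurrences are deliberately kept separate, since
each trait contributes an independent association signal.

### The enrichment model

Let `T_C` be the number of tested variants of category C, `f_C = T_C/T`,
and `n_qC` the number of candidates of category C in QTL q. The model
assumes each QTL harbors exactly one causal variant, and that a variant
of category C is causal with per-variant rate proportional to `λ_C`.
Candidates are treated as exchangeable within a QTL — LD with the lead is
used as a hard include/exclude filter, not as a weight. Marginalizing
the unknown causal variant gives

    L(λ) = Π_q Σ_C n_qC λ_C,   subject to  Σ_C λ_C f_C = 1.

The constraint anchors the genome-wide average per-variant rate at 1, so
`e_C = λ_C` reads directly as an enrichment: the probability that a
causal variant is of category C (`π_C = λ_C f_C`) divided by the
category's genomic frequency. The EM iteration is

* E-step: `r_qC = n_qC λ_C / Σ_C' n_qC' λ_C'`
* M-step: `π_C = mean_q r_qC`, `λ_C = π_C / f_C`

started from the uniform `λ = 1` point and stopped when
`max |Δλ| < 1e-8` (cap 10,000 iterations). The M-step keeps the
constraint satisfied exactly, and the log-likelihood is non-decreasing —
both are asserted in the test suite, and for two categories the EM
solution is checked against a 1-D grid search of the constrained
likelihood at 1e-6 resolution. Categories absent from every candidate
set get `π_C = e_C = 0` rather than NA, so the downstream `e ≤ 1` rule
applies uniformly.

Large candidate sets dilute themselves naturally (each candidate of a
QTL shares the single causal slot), so no cap on set size is imposed.

### Bootstrap confidence intervals

The QTL list is resampled with replacement (Q draws, 100 resamples by
default) and the estimator re-run per resample. The default 95% CI is
the normal approximation `ê ± 1.96·SD_boot`, which can produce a
negative lower bound for a near-zero enrichment; this is intentional —
it preserves the symmetric-interval behavior seen in published versions
of this analysis — and a `ci = "percentile"` option is available when
non-negative bounds are preferred. Resampling is unstratified across
traits.

### Weights and thresholds

With `P_bc = α/T`,

    w_C = e_C / ( (1/T) Σ_C' T_C' e_C' ),    P_wt,C = P_bc · w_C.

The normalizer sums over **all** categories, including non-enriched ones
(a `normalizer = "enriched-only"` switch restricts it). This makes
`Σ_C T_C P_wt,C = α` an exact identity, tested to relative 1e-9 on
randomized inputs. Categories with `e_C ≤ 1` are flagged and fall back
to `P_bc` — the trigger is the point estimate, not the CI. That fallback
makes the overall budget `Σ T_C·applied_C ≥ α`, i.e. slightly
anti-conservative; the inflation is visible in the threshold table and
reported rather than corrected, since the affected categories are by
construction the depleted ones where little probability mass sits.

Because `P_wt,A / P_wt,B = e_A / e_B` for any two thresholded
categories, a published threshold table can be reproduced from its
enrichment column and a single anchor threshold;
`recompute_reference_thresholds()` does exactly that against the bundled
reference tables (`inst/extdata/reference_enrichment_tables.tsv`), with
agreement limited only by the 3-significant-figure rounding of the
published values (worst relative deviation ≈ 0.4%).

## Default parameters

| parameter | default | meaning |
|---|---|---|
| `threshold_neglog10` | `"auto"` | QTL detection threshold; `"auto"` = −log10(α/T). For T = 16,503,508 this gives the conventional 8.5. |
| `r2_min` | 0.2 | LD cutoff for candidates (strict). |
| `maf_min` | 0.01 | variants with MAF < 1% excluded (boundary kept). |
| `hwe_min` | 1e-6 | HWE exclusion at P < 1e-6. |
| `alpha` | 0.05 | family-wise error rate. |
| `n_boot` | 100 | bootstrap resamples. |
| `window_bp` | 1e6 | lone-lead window, inclusive. |
| `model` | `"ols"` | association model; `"lmm"` adds a GRM-based variance component (EMMA-style eigen-rotated GLS with REML-profiled heritability). |

OLS is the default because at the package's design scale it is exact,
fast and calibrated (the null simulation holds the type-I rate in
[0.04, 0.06] over 10,000 tests); the mixed model is provided because
family structure in real breeding populations inflates OLS statistics.
Phenotypes are treated as homoskedastic — reliability weighting of
de-regressed proofs is out of scope.

Tukey outlier filtering (`tukey = TRUE`) removes phenotypes outside
`[Q1 − 1.5·IQR, Q3 + 1.5·IQR]`, fences inclusive, with quartiles by
linear interpolation of order statistics (`quantile(type = 7)`) — the
common statistical default, chosen because the procedure's description
does not pin down a quartile convention.

## Annotation classification

VEP consequence terms are reduced per variant to the highest impact
(HIGH > MODERATE > LOW > MODIFIER). Two deliberate departures from stock
VEP semantics, both configurable through the YAML impact map
(`inst/extdata/impact_map.yaml`):

* `upstream_gene_variant` / `downstream_gene_variant` are classed LOW,
  matching the category definitions this analysis uses;
* unknown terms map to MODIFIER with a warning instead of failing.

The eight-category precedence for MODIFIER variants is
UTR → OC → RE → ncRNA → NKI. Placing UTR *above* OC is the one place
where published category counts and the prose ordering of the source
tables disagree; the count arithmetic (the five-scheme OC count exceeds
the eight-scheme OC count by exactly the number of reassigned
UTR-overlap variants) forces UTR-first, and that order is used. Variants
with impact HIGH/MODERATE/LOW are never reassigned by intervals, in any
scheme. Open chromatin is the union of the ATAC-seq and histone-mark
interval sets. The census `T_C` is taken over all post-QC tested
variants, not candidates.

## The synthetic-data generator

The generator emulates exactly the statistical structure the analysis
consumes, at desk scale:

* **Genotypes** — a founder-copying model: each LD block carries
  `n_founders` (default 16) founder haplotypes; along a block each
  variant copies the previous variant's founder allele vector with
  probability `copy_prob` (default 0.9) or redraws it with an alt-allele
  count matched to a target MAF drawn from `maf_range` (clamped so
  founders are never monomorphic). Sample haplotypes copy a uniform
  founder per block. This yields high within-block r² (1 within a copy
  segment), near-zero between-block r², and controlled MAF — the three
  properties the QTL mapper and candidate extractor rely on.
  `copy_prob = 1` makes a block perfectly correlated;
  `ld_block_size = 1` makes all variants independent.
* **Annotations** — each variant draws an eight-scheme category from
  `category_frequencies`; consequence terms and 1-bp interval
  memberships are then emitted so that classification reproduces the
  drawn category exactly. A random 30% of UTR variants are additionally
  placed in open chromatin to exercise the UTR-over-OC precedence.
* **Phenotypes** — `n_causal` variants sampled without replacement with
  probability proportional to `causal_enrichment[category]`; effects
  standard normal, jointly rescaled so the genetic variance equals
  `heritability` (many small effects, one trait per call; a multi-trait
  study is emulated by running several seeds).

What it does **not** emulate: realistic demography or coalescent LD
decay, imputation dosage error, relatedness/stratification between
samples, reliability differences between pseudo-phenotypes, multi-allelic
sites. Passing tests therefore demonstrate the pipeline's internal
correctness and calibration under its own model assumptions, not
performance on real cattle data. No genetic-architecture calibration to
any real trait is implied; the defaults (5,000 variants, 300 samples, 10
causal variants, h² = 0.5) were chosen once as a plausible desk-scale
testbed.

## Numerical choices and degenerate inputs

* p-values are computed on the log scale
  (`pt(..., log.p = TRUE)`), so extreme signals do not underflow;
  a perfect fit is clamped at the smallest representable double and
  flagged `boundary`.
* Collinearity of a variant with the conditioning covariates (residual
  sum of squares below 1e-10 of its raw scale) yields p = 1 with a
  `collinear` flag — this is what terminates conditional scans past a
  fully explained signal. Monomorphic variants give flagged NA.
* Lead ties are broken by smaller position, then lexicographic id.
* HWE on fractional (imputed) dosages rounds to the nearest genotype
  for the test only; monomorphic sites return p = 1 by convention.
* Missing genotypes are mean-imputed per variant; variants with > 10%
  missingness are dropped (configurable).
* Internal coordinates are 1-based inclusive everywhere; BED's 0-based
  half-open convention is converted at the read/write boundary only.
* Bi-allelic records only; multi-allelic VCF rows are dropped with a
  warning.

## Problem sizes used in the tests

The test-suite and acceptance problem sizes were chosen as the smallest
that leave comfortable statistical margins: null calibration over 10,000
independent tests (n = 400); enrichment recovery from 200 simulated QTL
per seed over 20 seeds (median within ±30% of a true 10× enrichment at
1% category frequency); EM-vs-grid agreement on 100 random 2-category
problems; a 20-replicate end-to-end power experiment (n = 300, 5,000
variants split over 2 chromosomes, a 20×-enriched moderate category).
On these sizes the weighted regime recovers at least as many true causal
variants as the flat correction in every replicate; the mean power gain
is small, consistent with the reallocation argument — the budget moved
toward enriched categories is a small fraction of α unless enrichment is
extreme.

## Known limitations

* The one-causal-per-QTL assumption undercounts enrichment when a QTL
  holds several causal variants of the same category.
* Exchangeable candidates ignore fine-mapping information (LD strength,
  distance); a candidate in weak LD counts as much as a perfect proxy.
* The NA fallback's α-budget inflation is reported, not corrected.
* The mixed model estimates one global variance ratio on the null model;
  it does not do leave-one-chromosome-out GRMs.
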