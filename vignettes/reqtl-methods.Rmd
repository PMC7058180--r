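---
title: "RNA-level QTL mapping from variant allele fractions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RNA-level QTL mapping from variant allele fractions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The method

Classical eQTL mapping correlates a DNA-derived allele count (0/1/2) with
gene expression across individuals. This package implements the RNA-only
variant of that analysis (ReQTL): the genotype is replaced by the variant
allele fraction observed in the RNA itself,

$$\mathrm{VAF}_{RNA} = \frac{n_{var}}{n_{var} + n_{ref}},$$

where $n_{var}$ and $n_{ref}$ are filtered sequencing-read counts carrying
the variant and reference nucleotide at an expressed SNV position. Both the
predictor (VAF) and the response (expression) come from the same RNA-seq
experiment, which avoids matched-DNA requirements and DNA/RNA batch
structure, at the price of confining the analysis to expressed loci and to
samples with adequate read coverage.

The pipeline has four stages, each exposed as package functions and as CLI
subcommands:

1. **Counting** (`count_alleles`): per sample, every read overlapping an
   SNV position is classified by its aligned base. Reads failing any
   filter (mapping quality < 20, base quality at the position < 20, read
   length < 30 bp, optionally too many indel events; duplicate, secondary
   and supplementary alignments) contribute to no tally. A base other than
   the ref or alt nucleotide, or a deletion at the position, is tallied as
   `n_other`, which is reported for QC but never enters the VAF formula or
   its coverage test. Reads whose splice gap spans the position carry no
   aligned base there and are not counted at all. Overlapping mates of one
   fragment count once (the mate with the higher base quality wins).
2. **VAF matrix** (`build_vaf_matrix`, `filter_vaf_rows`): cells with
   fewer than 10 ref+var reads (configurable) are missing (`NA`); rows
   whose entries are missing or monoallelic (VAF exactly 0 or 1) in
   *strictly more than* 80% of samples are dropped. Both boundary rules
   are strict, so a row at exactly 80% is retained.
3. **Expression matrix** (`filter_genes`, `quantile_transform`):
   pseudogenes are removed, then genes below 1 TPM in strictly more than
   80% of samples. Columns (samples) are then quantile-transformed to the
   average empirical distribution: the value at rank $r$ in a sample is
   replaced by the mean of the $r$-th order statistics across all samples.
   Ties within a sample receive the mean of the reference values their
   tied ranks span, so the transform is rank-preserving and every column
   ends up with the same multiset of values.
4. **Association** (`run_reqtl`): every SNV row is tested against every
   gene row with the ordinary-least-squares model
   `expression ~ intercept + covariates + VAF`. The implementation uses
   the Frisch–Waugh residual-correlation identity,
   $t = r\sqrt{df/(1 - r^2)}$ with $df = n - k - 2$, where $r$ is the
   correlation of covariate-residualized VAF and expression on the SNV's
   support; this is algebraically identical to the full fit and is checked
   against `stats::lm` to 1e-8 in the test suite. Missing VAF entries are
   handled per pair as complete-case analysis with correspondingly reduced
   degrees of freedom. Covariates combine an external file (e.g. PEER
   factors, sex, ancestry encodings) with the top 3 principal components
   of the VAF (or genotype) matrix computed internally.

Associations are labelled **cis** when the SNV lies within 1 Mb of the
gene's strand-aware transcription start site (inclusive at the boundary),
or — in the alternative annotation mode motivated by the fact that VAF is
measured on transcripts — when the SNV falls inside the transcribed gene
span. All other pairs, including same-chromosome distal pairs, are
**trans**; no tested pair is dropped. Benjamini–Hochberg q-values are
computed separately within the cis family (cutoff 0.05) and the trans
family (cutoff 0.10), matching standard practice of controlling the two
searches at different rates. The engine can also emit unlabelled records
for deferred annotation; the two routes produce identical output.

A genotype mode converts allele counts 0/1/2 to fractions 0/0.5/1
(`genotype_to_fraction`) and runs the identical engine, so eQTL and ReQTL
analyses are directly comparable; when a VAF matrix numerically equals the
genotype fractions the two modes return byte-identical records.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_coverage` | 10 reads | minimum $n_{ref}+n_{var}$ for a VAF value; below it the cell is `NA`. Higher values increase VAF accuracy but retain fewer loci |
| `min_mapping_quality`, `min_base_quality` | 20, 20 (phred) | read filters at the counting stage |
| `min_read_length` | 30 bp | minimum read length |
| `max_uninformative_fraction` | 0.8 | strict row-exclusion threshold for missing-or-monoallelic signal |
| `min_tpm`, `max_low_fraction` | 1 TPM, 0.8 | strict gene-expression filter |
| `k` (PCs) | 3 | VAF/genotype principal components used as covariates |
| `cis_window_bp` | 1,000,000 | TSS distance defining cis, inclusive |
| `cis_fdr`, `trans_fdr` | 0.05, 0.10 | per-family significance cutoffs |

The read-filter defaults are conventional pileup settings; the original
counting tool's exact numeric filters are not published, so these are
package choices, all configurable.

## The synthetic-data generator

`simulate_dataset()` produces the fully synthetic cohorts used by the test
suite and the acceptance script. It emulates:

* diploid genotypes in Hardy–Weinberg equilibrium at allele frequencies
  Uniform(0.1, 0.5) — the common, expressed variants this analysis targets;
* true allele fractions equal to the genotype expectation (0, 0.5, 1),
  except at an `ase_fraction` (default 0.2) of loci whose heterozygote
  fraction is drawn Beta(2, 2) to emulate allele-specific expression, and
  a stray-read rate of 0.005 at homozygotes so the concordance classifier
  sees realistic near-monoallelic values;
* read coverage that is negative-binomial per cell (size 1.2) around
  log-normal per-locus means (median 20), so that roughly a third of
  cells fall below the 10-read threshold — matching the reported
  availability of VAF values in bulk tissue (about two thirds of samples
  per locus);
* gene expression on a TPM-like scale: latent Gaussian expression (two
  known covariates with Gaussian loadings plus unit noise) exponentiated
  with a log-scale factor of 0.5 around gene baselines drawn
  N(2, 1.5) on the natural-log scale;
* planted effects: a configurable fraction of SNVs influence their host
  gene (cis) or a random gene on another chromosome (trans). Effects live
  on the standardized scale: the covariate-adjusted correlation between
  true VAF and latent expression equals the planted beta exactly
  (residual = $\beta z + \sqrt{1-\beta^2}\,\varepsilon$), with magnitudes
  N(0.5, 0.1) and random signs. Planted loci are drawn among accessible
  loci (allele frequency ≥ 0.2, per-locus expected coverage at or above
  the median) and planted genes among clearly expressed genes, so that
  recovery measures association power rather than filter attrition — the
  same accessibility restriction the analysis itself imposes on its
  inputs.

Geometry is scaled down: 300 genes spread over five 100-Mb chromosomes,
every SNV inside a host gene. Gene density is therefore far sparser than a
real genome, which makes the cis family small (each SNV is usually cis
only to its host gene). The generator does **not** emulate linkage
disequilibrium, population structure, read-level error models, splicing,
or allele-mapping bias; passing tests therefore validate the statistical
engine and the filter semantics, not robustness to those phenomena.

Randomness is seeded once per stage (gene models, SNVs, genotypes,
coverage, effects, expression) from the configured seed, so enlarging one
component does not perturb the draws of another.

## Numerical choices and edge cases

* The quantile-transform tie rule (mean of spanned reference values)
  makes the transform deterministic and symmetric; a constant column maps
  to the grand mean of the reference distribution and is reported.
* PCA on a matrix with missing values uses row-mean imputation before the
  decomposition, the common choice in eQTL covariate computation; PCs are
  unit-normalized with the largest-magnitude entry made positive so signs
  are reproducible. A matrix of rank below `k` is rejected.
* A pair is untestable — and produces no record — when its support is
  smaller than `k + 3`, the design is singular on the support, or the
  residualized VAF has (numerically) zero variance.
* `t = r\sqrt{df/(1-r^2)}` is clamped at $r^2 = 1$; a perfect fit yields
  an underflowing p-value rather than `NaN`.
* Output records are sorted by (label, FDR, p, locus, gene) so repeated
  runs are byte-identical.
* Chromosome names are taken verbatim; an SNV chromosome absent from an
  alignment header yields zero counts with a warning rather than silent
  emptiness, and mismatched sample columns abort before computation.

## Calibration at desk scale

The test suite validates the engine at the package's documented study
scale: 200 samples, 300 SNVs × 300 genes. Against Gaussian expression the
engine's null p-values are exactly calibrated (the pooled
Kolmogorov–Smirnov distance sits at its theoretical iid level). On the
full TPM-scale pipeline a *slight* deviation from uniformity remains
detectable when ~70,000 p-values are pooled: the per-sample rank transform
preserves the skewed TPM shape, and an OLS t-test on skewed residuals at
n ≈ 135 complete cases is second-order accurate rather than exact. With
300 genes the transform also discretizes expression (a few dozen distinct
values per gene row), which sharpens the effect relative to a
transcriptome-wide analysis. In practice this means a pooled KS test at
α = 0.01 fails in roughly 5–7% of null replicates instead of the nominal
1% — a real property of analyzing TPM-scale data with a linear model at
this row count, not an engine defect; realized false-discovery control at
the BH cutoffs is unaffected (see the null-calibration and power tests).

## Problem sizes

The suite and `scripts/acceptance.R` use: 1,000 random instances for the
OLS-oracle comparison; 100 null replicates (200 × 300 × 300) for p-value
uniformity with false-discovery behaviour measured on 20 of them; one
fixed-seed planted run plus 20 replicates for power, effect-size ordering
and realized FDP; and constructed single-locus SAM fixtures for every
read-filter scenario. These sizes keep a full run within a few minutes on
one core while leaving each statistical check adequately powered.

## Known limitations

* Complete-case handling of missing VAF is exact but discards
  information; the documented consequence is reduced power at
  low-coverage loci (the mechanism behind the lower ReQTL yield relative
  to eQTL on the same samples). Mean imputation is available but off by
  default.
* PEER factor estimation is not re-implemented; hidden-confounder
  covariates enter via the external covariate file.
* Cis/trans annotation uses the TSS distance or transcribed-span overlap
  only; no LD-aware assignment is attempted.
* The counting stage expects coordinate-sorted, indexed BAM (SAM input is
  converted on the fly); CRAM and remote inputs are out of scope.
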