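# reqtl

RNA-level expression quantitative trait locus (ReQTL) mapping: correlating
the **variant allele fraction** observed in RNA-seq reads at expressed SNV
loci with gene expression from the *same* samples.

In a classical eQTL analysis the predictor is the DNA allele count
(0/1/2). Here it is

```
VAF_RNA = n_var / (n_var + n_ref)
```

the fraction of filtered sequencing reads carrying the variant nucleotide
at an SNV position. Because both VAF and expression come from one RNA-seq
experiment, the analysis needs no matched DNA and avoids DNA/RNA batch
structure; in exchange it is confined to expressed loci with adequate read
coverage. The package is aimed at transcriptomics researchers who have
coordinate-sorted RNA-seq alignments (or pre-computed allele-count
tables), a list of SNV positions, and a TPM matrix.

What it does:

* counts reference/variant reads per SNV and sample with configurable
  filters (MAPQ ≥ 20, base quality ≥ 20, read length ≥ 30 bp, duplicate /
  secondary / supplementary exclusion, once-per-fragment mate handling);
* builds a VAF matrix with `NA` below 10 ref+var reads and drops loci
  with missing-or-monoallelic signal in more than 80% of samples;
* filters expression (pseudogenes; TPM < 1 in more than 80% of samples)
  and quantile-transforms samples to the average empirical distribution;
* tests every SNV–gene pair with OLS
  (`expression ~ intercept + covariates + VAF`, complete-case over the
  SNV's non-missing samples), where covariates combine an external file
  with the top 3 VAF principal components;
* labels pairs cis (within 1 Mb of the TSS, or inside the transcribed
  gene in overlap mode) or trans, and controls Benjamini–Hochberg FDR
  separately per family (cis 0.05, trans 0.10);
* offers a genotype (eQTL) mode via the 0/1/2 → 0/0.5/1 conversion, and a
  seeded simulator that generates complete synthetic inputs with planted
  effects.

## Worked example

```r
library(reqtl)

# fully synthetic cohort: 200 samples, 300 SNVs, 300 genes,
# 20 planted cis and 5 planted trans effects
sim <- simulate_dataset(simulation_config(seed = 1))

vaf  <- build_vaf_matrix(sim$counts)          # NA below 10 reads
vaf  <- filter_vaf_rows(vaf)                  # drops uninformative loci
tpm  <- filter_genes(sim$tpm, sim$gene_models)
expr <- quantile_transform(tpm)
cov  <- assemble_covariates(colnames(vaf), external = sim$covariates,
                            pcs = compute_pcs(vaf, 3))

res <- run_reqtl(vaf, expr, cov, sim$gene_models)
head(res[res$significant, c("locus_id", "gene_id", "beta", "t_stat",
                            "p_value", "fdr", "label", "n_used")], 3)
```

```
           locus_id  gene_id      beta    t_stat      p_value          fdr label n_used
1 chr3:46475335_T>A GENE0041  24.81596 10.233710 2.558014e-19 1.268775e-16   cis    171
2 chr1:87235082_A>G GENE0219 -10.88149 -8.274767 1.096281e-13 2.718776e-11   cis    142
3 chr5:90036397_G>A GENE0119  10.36191  7.214183 3.904060e-11 5.530383e-09   cis    138
```

Each row is one SNV–gene association: `beta` is the expression change per
unit VAF on the transformed scale, `t_stat`/`p_value` the covariate-
adjusted test with `n_used - k - 2` degrees of freedom over the `n_used`
samples with a VAF value, `fdr` the q-value within the record's cis or
trans family, and `label` the annotation. On this dataset the run finds
20 significant cis associations (exactly the planted cis pairs) and 4
trans associations at the 0.05/0.10 family cutoffs.

The same stages are available from the shell:

```sh
reqtl simulate --seed 1 --outdir fixtures/
reqtl count --bam S1.bam --snvs snvs.vcf --min-reads 10 -o S1.counts.tsv
reqtl build-vaf --counts-dir counts/ -o vaf.tsv
reqtl build-exp --tpm tpm.tsv --gtf genes.gtf -o exp.tsv
reqtl covariates --vaf vaf.tsv --external cov.tsv --pcs 3 -o cov_full.tsv
reqtl run --vaf vaf.tsv --exp exp.tsv --cov cov_full.tsv --gtf genes.gtf -o reqtl.tsv
reqtl all --samplesheet samples.tsv --snvs snvs.vcf --tpm tpm.tsv --gtf genes.gtf -o out/
```

Every subcommand writes a JSON manifest (version, parameters, input
checksums, per-stage row counts) beside its output.

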