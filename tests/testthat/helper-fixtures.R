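# Shared fixture builders; everything is generated in code at test time.

toy_locus <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             id = sprintf("%s:%d_%s>%s", chrom, pos, ref, alt),
             stringsAsFactors = FALSE)
}

# A minimal sites-only VCF.
write_vcf_fixture <- function(path, records) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##contig=<ID=chr2>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    records
  ), path)
  path
}

# Random matrix with NAs and dimnames, for round-trip property tests.
random_matrix <- function(nr, nc, na_frac = 0.1) {
  m <- matrix(rnorm(nr * nc), nr, nc,
              dimnames = list(sprintf("row%02d", seq_len(nr)),
                              sprintf("S%02d", seq_len(nc))))
  m[runif(nr * nc) < na_frac] <- NA
  m
}

# Per-sample SAM cohort with sample-varying allele ratios at shared loci,
# for CLI end-to-end tests. Returns list(loci, sam_paths).
make_cohort_sams <- function(dir, n_samples = 12L, depth = 14L) {
  loci <- data.frame(
    chrom = "chr1", pos = c(150L, 500L, 900L, 1500L, 2500L, 4000L),
    ref = c("A", "C", "G", "T", "A", "C"),
    alt = c("G", "T", "A", "C", "T", "G"), stringsAsFactors = FALSE)
  loci$id <- sprintf("%s:%d_%s>%s", loci$chrom, loci$pos, loci$ref,
                     loci$alt)
  set.seed(20)
  vafs <- matrix(runif(nrow(loci) * n_samples, 0.15, 0.85), nrow(loci))
  paths <- character(n_samples)
  for (s in seq_len(n_samples)) {
    reads <- NULL
    for (l in seq_len(nrow(loci))) {
      n_var <- round(depth * vafs[l, s])
      alleles <- c(rep(loci$ref[l], depth - n_var),
                   rep(loci$alt[l], n_var))
      start <- pmax(1L, loci$pos[l] - (seq_len(depth) - 1L) %% 40L)
      seqs <- vapply(seq_len(depth), function(i) {
        b <- rep("T", 50L)
        b[loci$pos[l] - start[i] + 1L] <- alleles[i]
        paste(b, collapse = "")
      }, "")
      reads <- rbind(reads, data.frame(
        qname = sprintf("s%02d_l%d_r%03d", s, l, seq_len(depth)),
        flag = 0L, chrom = loci$chrom[l], pos = start, mapq = 60L,
        cigar = "50M", rnext = "*", pnext = 0L, tlen = 0L, seq = seqs,
        qual = strrep("I", 50L), stringsAsFactors = FALSE))
    }
    paths[s] <- file.path(dir, sprintf("S%02d.sam", s))
    write_sam(paths[s], reads, c(chr1 = 10000L))
  }
  list(loci = loci, sam_paths = paths, vafs = vafs)
}

# Small association problem with one strong planted pair, used across
# assoc tests.
toy_assoc_data <- function(n = 60L, seed = 5L) {
  set.seed(seed)
  samples <- sprintf("S%03d", seq_len(n))
  vaf <- matrix(runif(4 * n), 4, n,
                dimnames = list(c("chr1:100_A>G", "chr1:200_C>T",
                                  "chr2:100_G>A", "chr2:900_T>C"),
                                samples))
  expr <- matrix(rnorm(5 * n), 5, n,
                 dimnames = list(sprintf("G%d", 1:5), samples))
  expr["G1", ] <- 3 * vaf["chr1:100_A>G", ] + rnorm(n, 0, 0.3)
  models <- data.frame(
    gene_id = sprintf("G%d", 1:5),
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr3"),
    strand = c("+", "-", "+", "+", "-"),
    tss = c(150L, 1000000L, 120L, 2000000L, 500L),
    span_start = c(150L, 900000L, 120L, 2000000L, 400L),
    span_end = c(5000L, 1000000L, 800L, 2100000L, 500L),
    is_pseudogene = FALSE, stringsAsFactors = FALSE)
  list(vaf = vaf, expr = expr, models = models, samples = samples)
}

# Independent full-design OLS oracle via stats::lm.
lm_oracle <- function(snv, gene, covariates = NULL) {
  s <- !is.na(snv) & !is.na(gene)
  df <- data.frame(y = gene[s], x = snv[s])
  if (!is.null(covariates)) df <- cbind(df, t(covariates)[s, , drop = FALSE])
  fit <- lm(y ~ ., data = df)
  co <- summary(fit)$coefficients["x", ]
  list(beta = unname(co[1]), t_stat = unname(co[3]),
       p_value = unname(co[4]), n_used = sum(s))
}

# The standard analysis pipeline on a simulated dataset: build + filter the
# VAF matrix, filter + transform expression, covariates with 3 VAF PCs,
# then the association engine.
analyze_sim <- function(sim, config = test_config()) {
  vaf <- build_vaf_matrix(sim$counts)
  vaf <- suppressMessages(filter_vaf_rows(vaf))
  tpm <- suppressMessages(filter_genes(sim$tpm, sim$gene_models))
  expr <- quantile_transform(tpm)
  cov <- assemble_covariates(colnames(vaf), external = sim$covariates,
                             pcs = compute_pcs(vaf, 3))
  run_reqtl(vaf, expr, cov, sim$gene_models, config = config)
}

# Recovery of planted cis pairs and the Spearman agreement between planted
# standardized effects and their standardized estimates t/sqrt(t^2 + df).
planted_cis_summary <- function(sim, records, n_covariates = 5L) {
  truth <- sim$truth[sim$truth$label == "cis", ]
  sig <- records[records$significant & records$label == "cis", ]
  hit <- paste(truth$locus_id, truth$gene_id) %in%
    paste(sig$locus_id, sig$gene_id)
  m <- match(paste(truth$locus_id, truth$gene_id)[hit],
             paste(records$locus_id, records$gene_id))
  df <- records$n_used[m] - n_covariates - 2L
  r_est <- records$t_stat[m] / sqrt(records$t_stat[m]^2 + df)
  sp <- if (sum(hit) > 2) {
    cor(truth$true_beta[hit], r_est, method = "spearman")
  } else NA_real_
  fp <- !paste(records$locus_id, records$gene_id)[records$significant] %in%
    paste(sim$truth$locus_id, sim$truth$gene_id)
  list(recovery = mean(hit), spearman = sp,
       n_significant = sum(records$significant), n_false = sum(fp))
}
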