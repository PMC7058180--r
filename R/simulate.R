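#' Simulation configuration
#'
#' Defines the synthetic study the simulator emulates: a cohort of RNA-seq
#' samples with diploid genotypes at expressed SNV loci, read coverage drawn
#' per locus and sample, allele-specific expression at a fraction of loci,
#' and gene expression driven by two known covariates plus planted cis and
#' trans effects of the true allele fraction.
#'
#' @param n_samples Cohort size (default 200).
#' @param n_snvs,n_genes Numbers of SNV loci and genes (default 300 each).
#' @param n_chroms Number of chromosomes (100 Mb each) genes are spread
#'   over (default 5).
#' @param fraction_cis_effects,fraction_trans_effects Fractions of SNVs
#'   carrying a planted effect on, respectively, their host gene (cis) and
#'   a random gene on another chromosome (trans). Defaults 20/300 and
#'   5/300.
#' @param effect_size Standardized magnitude of planted effects
#'   (default 0.5).
#' @param effect_size_sd Spread of planted-effect magnitudes around
#'   `effect_size` (default 0.1); signs are random.
#' @param coverage_mean Median per-locus expected read coverage (default
#'   20; per-locus means are log-normal around it, and per-sample coverage
#'   is negative-binomial, so roughly a third of cells fall below the
#'   10-read threshold, matching typical bulk RNA-seq availability).
#' @param coverage_dispersion Negative-binomial `size` parameter
#'   (default 1.2).
#' @param ase_fraction Fraction of loci whose heterozygote allele fraction
#'   deviates from 0.5 (drawn Beta(2, 2); default 0.2).
#' @param hom_error_rate Per-read rate of stray opposite-allele reads at
#'   homozygous loci (default 0.005).
#' @param noise_sd Standard deviation of the Gaussian expression noise on
#'   the latent scale (default 1, the unit of standardized effects).
#' @param link_scale Multiplier taking latent expression to the log-TPM
#'   scale (default 0.5).
#' @param seed Integer seed; all draws are reproducible given it.
#' @return A list of class `reqtl_sim_config`.
#' @export
simulation_config <- function(n_samples = 200L, n_snvs = 300L,
                              n_genes = 300L, n_chroms = 5L,
                              fraction_cis_effects = 20 / 300,
                              fraction_trans_effects = 5 / 300,
                              effect_size = 0.5, effect_size_sd = 0.1,
                              coverage_mean = 20, coverage_dispersion = 1.2,
                              ase_fraction = 0.2, hom_error_rate = 0.005,
                              noise_sd = 1, link_scale = 0.5,
                              seed = 1L) {
  stopifnot(n_samples >= 10L, n_snvs >= 1L, n_genes >= 2L,
            fraction_cis_effects >= 0, fraction_cis_effects <= 1,
            fraction_trans_effects >= 0, fraction_trans_effects <= 1,
            effect_size >= 0, coverage_mean > 0, ase_fraction >= 0,
            ase_fraction <= 1)
  structure(list(
    n_samples = as.integer(n_samples), n_snvs = as.integer(n_snvs),
    n_genes = as.integer(n_genes), n_chroms = as.integer(n_chroms),
    fraction_cis_effects = fraction_cis_effects,
    fraction_trans_effects = fraction_trans_effects,
    effect_size = effect_size, effect_size_sd = effect_size_sd,
    coverage_mean = coverage_mean,
    coverage_dispersion = coverage_dispersion,
    ase_fraction = ase_fraction, hom_error_rate = hom_error_rate,
    noise_sd = noise_sd, link_scale = link_scale,
    seed = as.integer(seed)
  ), class = "reqtl_sim_config")
}

# Stage-specific sub-seed so draws for one matrix do not shift draws for
# another when sizes change.
stage_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + offset
}

#' Generate a fully synthetic ReQTL dataset
#'
#' Deterministic given `config$seed`. Genes are placed uniformly on
#' `n_chroms` chromosomes of 100 Mb; every SNV lies inside a host gene's
#' transcribed span. Genotypes are Hardy-Weinberg draws at allele
#' frequencies Uniform(0.1, 0.5); the true allele fraction is the genotype
#' expectation (0 / 0.5 / 1) except at ASE loci (heterozygote fraction ~
#' Beta(2, 2)) and for a small stray-read rate at homozygotes. Read counts
#' are Binomial(coverage, true VAF) with negative-binomial coverage.
#' Latent expression is covariate loadings + planted beta x standardized
#' true VAF + Gaussian noise, exponentiated to a TPM-like scale. Planted
#' effects go to common loci (allele frequency >= 0.2) and clearly
#' expressed genes so that recovery measures association power rather than
#' filter attrition.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `sample_ids`, `snv_loci`, `gene_models`,
#'   `genotypes` (0/1/2 matrix), `vaf_true` (true allele-fraction matrix),
#'   `counts` (named list of per-sample count tables), `tpm`
#'   (genes x samples), `covariates` (2 x samples: `sex`, `batch`), and
#'   `truth` (planted pairs: `locus_id`, `gene_id`, `true_beta`, `label`).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "reqtl_sim_config"))
  n_s <- config$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n_s))

  ## gene models -------------------------------------------------------
  set.seed(stage_seed(config$seed, 1L))
  chroms <- paste0("chr", seq_len(config$n_chroms))
  g_chrom <- sample(chroms, config$n_genes, replace = TRUE)
  g_tss <- as.integer(round(runif(config$n_genes, 1e6, 99e6)))
  g_len <- as.integer(pmin(pmax(round(rlnorm(config$n_genes, log(5e4),
                                             0.6)), 5e3), 3e5))
  g_strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  g_mu <- rnorm(config$n_genes, 2, 1.5)  # log-TPM baseline
  gene_models <- data.frame(
    gene_id = sprintf("GENE%04d", seq_len(config$n_genes)),
    chrom = g_chrom, strand = g_strand,
    tss = g_tss,
    span_start = ifelse(g_strand == "+", g_tss, g_tss - g_len),
    span_end = ifelse(g_strand == "+", g_tss + g_len, g_tss),
    is_pseudogene = FALSE, stringsAsFactors = FALSE
  )
  gene_models$span_start <- as.integer(gene_models$span_start)
  gene_models$span_end <- as.integer(gene_models$span_end)

  ## SNV loci ----------------------------------------------------------
  set.seed(stage_seed(config$seed, 2L))
  host <- sample.int(config$n_genes, config$n_snvs, replace = TRUE)
  pos <- integer(config$n_snvs)
  repeat {
    pos <- as.integer(round(runif(config$n_snvs,
                                  gene_models$span_start[host],
                                  gene_models$span_end[host])))
    key <- paste(gene_models$chrom[host], pos)
    if (!anyDuplicated(key)) break
  }
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, config$n_snvs, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), "")
  snv_loci <- data.frame(
    chrom = gene_models$chrom[host], pos = pos, ref = ref, alt = alt,
    id = make_locus_id(gene_models$chrom[host], pos, ref, alt),
    host_gene = gene_models$gene_id[host], stringsAsFactors = FALSE
  )
  ord <- locus_order(snv_loci$chrom, snv_loci$pos)
  snv_loci <- snv_loci[ord, , drop = FALSE]
  rownames(snv_loci) <- NULL

  ## genotypes and true VAF --------------------------------------------
  set.seed(stage_seed(config$seed, 3L))
  maf <- runif(config$n_snvs, 0.1, 0.5)
  genotypes <- matrix(rbinom(config$n_snvs * n_s, 2L, rep(maf, n_s)),
                      nrow = config$n_snvs, ncol = n_s,
                      dimnames = list(snv_loci$id, sample_ids))
  is_ase <- runif(config$n_snvs) < config$ase_fraction
  vaf_true <- genotypes / 2
  het <- genotypes == 1L
  ase_cells <- het & matrix(is_ase, config$n_snvs, n_s)
  vaf_true[ase_cells] <- rbeta(sum(ase_cells), 2, 2)
  vaf_true[genotypes == 0L] <- config$hom_error_rate
  vaf_true[genotypes == 2L] <- 1 - config$hom_error_rate

  ## read coverage and allele counts -----------------------------------
  set.seed(stage_seed(config$seed, 4L))
  mu_l <- rlnorm(config$n_snvs, log(config$coverage_mean), 0.5)
  coverage <- matrix(rnbinom(config$n_snvs * n_s,
                             mu = rep(mu_l, n_s),
                             size = config$coverage_dispersion),
                     nrow = config$n_snvs, ncol = n_s)
  n_var <- matrix(rbinom(config$n_snvs * n_s, as.vector(coverage),
                         as.vector(vaf_true)),
                  nrow = config$n_snvs, ncol = n_s)
  counts <- setNames(lapply(seq_len(n_s), function(s) {
    data.frame(locus_id = snv_loci$id,
               n_ref = coverage[, s] - n_var[, s],
               n_var = n_var[, s],
               n_other = 0L, stringsAsFactors = FALSE)
  }), sample_ids)

  ## planted effects ---------------------------------------------------
  set.seed(stage_seed(config$seed, 5L))
  n_cis <- round(config$fraction_cis_effects * config$n_snvs)
  n_trans <- round(config$fraction_trans_effects * config$n_snvs)
  expressed <- gene_models$gene_id[g_mu >= 1]
  # effects are planted at loci accessible to the analysis (common allele,
  # adequate expected coverage) and at clearly expressed genes, so that
  # recovery measures association power rather than filter attrition
  eligible_snv <- which(maf >= 0.2 & mu_l >= config$coverage_mean &
                          snv_loci$host_gene %in% expressed)
  if (n_cis + n_trans > length(eligible_snv)) {
    stop("more planted effects requested than eligible SNV loci")
  }
  # one planted effect per gene: cis SNVs must have distinct host genes
  shuffled <- sample(eligible_snv)
  cis_idx <- shuffled[!duplicated(snv_loci$host_gene[shuffled])][
    seq_len(n_cis)]
  trans_idx <- setdiff(shuffled, cis_idx)[seq_len(n_trans)]
  if (anyNA(cis_idx) || anyNA(trans_idx)) {
    stop("more planted effects requested than eligible SNV loci")
  }
  truth <- NULL
  if (n_cis + n_trans > 0L) {
    used_genes <- snv_loci$host_gene[cis_idx]
    trans_gene <- character(length(trans_idx))
    for (jj in seq_along(trans_idx)) {
      i <- trans_idx[jj]
      pool <- setdiff(expressed[gene_models$chrom[match(expressed,
                                                        gene_models$gene_id)] !=
                                  snv_loci$chrom[i]], used_genes)
      trans_gene[jj] <- sample(pool, 1L)
      used_genes <- c(used_genes, trans_gene[jj])
    }
    mag <- pmin(abs(rnorm(n_cis + n_trans, config$effect_size,
                          config$effect_size_sd)), 0.99)
    sgn <- sample(c(-1, 1), n_cis + n_trans, replace = TRUE)
    truth <- data.frame(
      locus_id = snv_loci$id[c(cis_idx, trans_idx)],
      gene_id = c(snv_loci$host_gene[cis_idx], trans_gene),
      true_beta = sgn * mag,
      label = rep(c("cis", "trans"), c(n_cis, n_trans)),
      stringsAsFactors = FALSE
    )
  }

  ## covariates and expression -----------------------------------------
  set.seed(stage_seed(config$seed, 6L))
  covariates <- rbind(
    sex = rbinom(n_s, 1L, 0.5),
    batch = rnorm(n_s)
  )
  colnames(covariates) <- sample_ids
  load_sex <- rnorm(config$n_genes, 0, 0.5)
  load_batch <- rnorm(config$n_genes, 0, 0.5)
  noise <- matrix(rnorm(config$n_genes * n_s), config$n_genes, n_s)
  residual <- noise
  if (!is.null(truth)) {
    # planted effects live on the standardized scale: the
    # covariate-adjusted correlation between true VAF and latent
    # expression equals true_beta exactly
    gi <- match(truth$gene_id, gene_models$gene_id)
    si <- match(truth$locus_id, snv_loci$id)
    for (r in seq_len(nrow(truth))) {
      b <- truth$true_beta[r]
      z <- as.vector(scale(vaf_true[si[r], ]))
      residual[gi[r], ] <- b * z + sqrt(1 - b^2) * noise[gi[r], ]
    }
  }
  latent <- outer(load_sex, covariates["sex", ]) +
    outer(load_batch, covariates["batch", ]) +
    config$noise_sd * residual
  tpm <- exp(g_mu + config$link_scale * latent)
  dimnames(tpm) <- list(gene_models$gene_id, sample_ids)

  list(sample_ids = sample_ids, snv_loci = snv_loci,
       gene_models = gene_models, genotypes = genotypes,
       vaf_true = vaf_true, counts = counts, tpm = tpm,
       covariates = covariates, truth = truth)
}

#' Write a synthetic single-locus SAM fixture
#'
#' Emits a syntactically valid SAM file whose reads overlap one SNV
#' position carrying specified alleles, mapping qualities and base
#' qualities, so that [count_alleles()] on the output returns known
#' tallies. Reads are plain `M`-CIGAR single-end alignments unless custom
#' reads are supplied.
#'
#' @param path Output `.sam` path.
#' @param locus One-row locus `data.frame` (`chrom`, `pos`, `ref`, `alt`).
#' @param n_ref,n_var Numbers of reference- and variant-carrying reads.
#' @param mapq_ref,mapq_var Mapping qualities for the two read groups.
#' @param base_quality Phred base quality written for every base.
#' @param read_length Read length in bp.
#' @param seed Seed for the background sequence.
#' @return `path`, invisibly.
#' @export
write_sam_fixture <- function(path, locus, n_ref, n_var,
                              mapq_ref = 60L, mapq_var = 60L,
                              base_quality = 35L, read_length = 50L,
                              seed = 1L) {
  stopifnot(n_ref >= 0L, n_var >= 0L, nrow(locus) == 1L)
  set.seed(seed)
  alleles <- c(rep(locus$ref, n_ref), rep(locus$alt, n_var))
  mapqs <- c(rep(mapq_ref, n_ref), rep(mapq_var, n_var))
  n <- length(alleles)
  reads <- NULL
  if (n > 0L) {
    offset <- (seq_len(n) - 1L) %% read_length
    start <- pmax(1L, locus$pos - offset)
    seqs <- vapply(seq_len(n), function(i) {
      s <- sample(c("A", "C", "G", "T"), read_length, replace = TRUE)
      s[locus$pos - start[i] + 1L] <- alleles[i]
      paste(s, collapse = "")
    }, "")
    reads <- data.frame(
      qname = sprintf("read%04d", seq_len(n)), flag = 0L,
      chrom = locus$chrom, pos = start, mapq = mapqs,
      cigar = paste0(read_length, "M"), rnext = "*", pnext = 0L,
      tlen = 0L, seq = seqs,
      qual = strrep(intToUtf8(base_quality + 33L), read_length),
      stringsAsFactors = FALSE
    )
  }
  write_sam(path, reads,
            chrom_lengths = setNames(locus$pos + read_length + 1000L,
                                     locus$chrom))
  invisible(path)
}

#' Write an arbitrary set of alignment records as a SAM file
#'
#' Low-level fixture writer used by [write_sam_fixture()] and by tests that
#' need precise control over flags, CIGAR strings, or mate information.
#'
#' @param path Output `.sam` path.
#' @param reads `data.frame` with columns `qname`, `flag`, `chrom`, `pos`,
#'   `mapq`, `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`; `NULL`
#'   writes a header-only file.
#' @param chrom_lengths Named integer vector of reference lengths for the
#'   `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(path, reads, chrom_lengths) {
  stopifnot(!is.null(names(chrom_lengths)))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  body <- character(0)
  if (!is.null(reads) && nrow(reads) > 0L) {
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                    reads$qname, as.integer(reads$flag), reads$chrom,
                    as.integer(reads$pos), as.integer(reads$mapq),
                    reads$cigar, reads$rnext, as.integer(reads$pnext),
                    as.integer(reads$tlen), reads$seq, reads$qual)
  }
  writeLines(c(header, body), path)
  invisible(path)
}
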