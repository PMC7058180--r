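#' Read-filter configuration for allele counting
#'
#' Thresholds applied to every alignment before it can contribute a base at
#' an SNV position. A read failing any filter contributes to no tally.
#'
#' @param min_mapping_quality Minimum MAPQ (phred). Default 20.
#' @param min_base_quality Minimum base quality (phred) of the base at the
#'   SNV position. Default 20. Deletions at the position carry no base
#'   quality and are exempt (they are tallied as `n_other`).
#' @param min_read_length Minimum read sequence length in bp. Default 30.
#' @param max_gap_events Maximum number of indel events (I/D CIGAR
#'   operations) in the alignment; `Inf` disables the filter.
#' @param exclude_duplicates Drop reads flagged as PCR/optical duplicates.
#' @param exclude_secondary_supplementary Drop secondary and supplementary
#'   alignments.
#' @param dedup_overlapping_mates When both mates of a fragment cover the
#'   position, count the fragment once (the mate with the higher base
#'   quality at the position wins).
#' @return A list of class `reqtl_read_filters`.
#' @export
read_filter_config <- function(min_mapping_quality = 20L,
                               min_base_quality = 20L,
                               min_read_length = 30L,
                               max_gap_events = Inf,
                               exclude_duplicates = TRUE,
                               exclude_secondary_supplementary = TRUE,
                               dedup_overlapping_mates = TRUE) {
  stopifnot(min_mapping_quality >= 0, min_base_quality >= 0,
            min_read_length >= 0, max_gap_events >= 0)
  structure(list(
    min_mapping_quality = as.integer(min_mapping_quality),
    min_base_quality = as.integer(min_base_quality),
    min_read_length = as.integer(min_read_length),
    max_gap_events = max_gap_events,
    exclude_duplicates = isTRUE(exclude_duplicates),
    exclude_secondary_supplementary = isTRUE(exclude_secondary_supplementary),
    dedup_overlapping_mates = isTRUE(dedup_overlapping_mates)
  ), class = "reqtl_read_filters")
}

# Ensure a coordinate-sorted, indexed BAM; SAM input is converted (and
# sorted/indexed) into a temporary BAM.
prepare_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = TRUE)
    return(bam)
  }
  bai <- paste0(path, ".bai")
  bai2 <- sub("\\.bam$", ".bai", path, ignore.case = TRUE)
  if (!file.exists(bai) && !file.exists(bai2)) {
    stop("missing BAM index for ", path,
         " (expected .bam.bai alongside the alignment)")
  }
  path
}

#' Count reference and variant reads at SNV positions in one alignment
#'
#' For each locus, every read overlapping the position is classified by the
#' aligned base it carries there: the reference nucleotide (`n_ref`), the
#' variant nucleotide (`n_var`), or any other nucleotide or a deletion
#' (`n_other`). Reads whose splice gap (`N` CIGAR operation) spans the
#' position have no aligned base there and are not counted. Reads failing
#' any filter in `filters` contribute to no tally, and with mate-overlap
#' deduplication a fragment contributes at most one base per locus.
#'
#' @param alignment Path to a coordinate-sorted BAM (with index) or a SAM
#'   file (converted and indexed on the fly).
#' @param loci SNV position list as returned by [read_snv_positions()].
#' @param filters A [read_filter_config()].
#' @return A `data.frame` with columns `locus_id`, `n_ref`, `n_var`,
#'   `n_other`, one row per locus in the input order.
#' @export
count_alleles <- function(alignment, loci, filters = read_filter_config()) {
  stopifnot(is.data.frame(loci),
            all(c("chrom", "pos", "ref", "alt", "id") %in% names(loci)))
  bam <- prepare_alignment(alignment)
  header_chroms <- names(Rsamtools::scanBamHeader(bam)[[1L]]$targets)

  n <- nrow(loci)
  out <- data.frame(locus_id = loci$id,
                    n_ref = integer(n), n_var = integer(n),
                    n_other = integer(n), stringsAsFactors = FALSE)
  absent <- setdiff(unique(loci$chrom), header_chroms)
  for (chr in absent) {
    warning("chromosome ", chr, " absent from alignment header of ",
            alignment, "; counts set to zero", call. = FALSE)
  }
  present <- loci$chrom %in% header_chroms
  if (!any(present)) return(out)

  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isDuplicate = if (filters$exclude_duplicates) FALSE else NA,
    isSecondaryAlignment =
      if (filters$exclude_secondary_supplementary) FALSE else NA,
    isSupplementaryAlignment =
      if (filters$exclude_secondary_supplementary) FALSE else NA
  )
  which <- GenomicRanges::GRanges(loci$chrom[present],
                                  IRanges::IRanges(loci$pos[present],
                                                   loci$pos[present]))
  param <- Rsamtools::ScanBamParam(
    flag = flag, which = which,
    what = c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual")
  )
  res <- Rsamtools::scanBam(bam, param = param)
  idx_present <- which(present)
  for (j in seq_along(res)) {
    i <- idx_present[j]
    tallies <- tally_locus(res[[j]], loci$pos[i], loci$ref[i], loci$alt[i],
                           filters)
    out$n_ref[i] <- tallies[["n_ref"]]
    out$n_var[i] <- tallies[["n_var"]]
    out$n_other[i] <- tallies[["n_other"]]
  }
  out
}

# Classify the reads returned by scanBam for one locus.
tally_locus <- function(reads, pos, ref, alt, filters) {
  zero <- c(n_ref = 0L, n_var = 0L, n_other = 0L)
  if (length(reads$pos) == 0L) return(zero)
  keep <- !is.na(reads$pos) & !is.na(reads$mapq) &
    reads$mapq >= filters$min_mapping_quality &
    Biostrings::width(reads$seq) >= filters$min_read_length
  if (is.finite(filters$max_gap_events)) {
    ops <- GenomicAlignments::explodeCigarOps(reads$cigar)
    gaps <- vapply(ops, function(o) sum(o %in% c("I", "D")), 0L)
    keep <- keep & gaps <= filters$max_gap_events
  }
  if (!any(keep)) return(zero)

  seqs <- GenomicAlignments::sequenceLayer(
    reads$seq[keep], reads$cigar[keep],
    from = "query", to = "reference", D.letter = "-", N.letter = "."
  )
  quals <- GenomicAlignments::sequenceLayer(
    Biostrings::BStringSet(as.character(reads$qual[keep])),
    reads$cigar[keep],
    from = "query", to = "reference", D.letter = "-", N.letter = "."
  )
  offs <- pos - reads$pos[keep] + 1L
  cover <- offs >= 1L & offs <= Biostrings::width(seqs)
  if (!any(cover)) return(zero)

  base <- substr(as.character(seqs[cover]), offs[cover], offs[cover])
  qchar <- substr(as.character(quals[cover]), offs[cover], offs[cover])
  qname <- reads$qname[keep][cover]
  phred <- vapply(qchar, function(ch) utf8ToInt(ch) - 33L, 0L,
                  USE.NAMES = FALSE)

  is_del <- base == "-"
  is_gap <- base == "."
  pass_bq <- is_del | (!is_gap & phred >= filters$min_base_quality)
  usable <- pass_bq & !is_gap
  if (!any(usable)) return(zero)
  base <- base[usable]
  qname <- qname[usable]
  phred <- ifelse(is_del[usable], -1L, phred[usable])

  if (filters$dedup_overlapping_mates && anyDuplicated(qname)) {
    ord <- order(qname, -phred)
    first <- !duplicated(qname[ord])
    sel <- sort(ord[first])
    base <- base[sel]
  }
  c(n_ref = sum(base == ref),
    n_var = sum(base == alt),
    n_other = sum(base != ref & base != alt))
}

#' Variant allele fraction from filtered allele counts
#'
#' VAF_RNA = n_var / (n_var + n_ref). Positions covered by fewer than
#' `min_coverage` ref+var reads are assigned `NA`; `n_other` never enters
#' the numerator, the denominator, or the coverage test.
#'
#' @param n_ref,n_var Non-negative integer vectors of filtered read counts.
#' @param min_coverage Minimum `n_ref + n_var` required for a value
#'   (default 10).
#' @return A `data.frame` with columns `value` (VAF in `[0, 1]` or `NA`) and
#'   `coverage` (`n_ref + n_var`).
#' @export
compute_vaf <- function(n_ref, n_var, min_coverage = 10L) {
  stopifnot(min_coverage >= 1, length(n_ref) == length(n_var),
            all(n_ref >= 0, na.rm = TRUE), all(n_var >= 0, na.rm = TRUE))
  coverage <- n_ref + n_var
  value <- ifelse(coverage >= min_coverage, n_var / coverage, NA_real_)
  data.frame(value = value, coverage = coverage)
}

#' Convert diploid allele counts to allele fractions
#'
#' Genotypes coded as the number of variant alleles (0 homozygous reference,
#' 1 heterozygous, 2 homozygous variant) are mapped to fractions 0, 0.5 and
#' 1 so that a genotype matrix can be analyzed with the same engine as a VAF
#' matrix (eQTL mode). Missing genotypes stay missing.
#'
#' @param genotype Numeric vector or matrix with values in `{0, 1, 2, NA}`.
#' @return Same shape as the input, values in `{0, 0.5, 1, NA}`.
#' @export
genotype_to_fraction <- function(genotype) {
  vals <- as.vector(genotype)
  bad <- !is.na(vals) & !vals %in% c(0, 1, 2)
  if (any(bad)) {
    where <- which(bad)[1L]
    locus <- sample_id <- "?"
    if (is.matrix(genotype) && !is.null(dimnames(genotype))) {
      rc <- arrayInd(where, dim(genotype))
      locus <- rownames(genotype)[rc[1L]]
      sample_id <- colnames(genotype)[rc[2L]]
    }
    stop("invalid genotype value ", vals[where], " (locus ", locus,
         ", sample ", sample_id, "); expected 0, 1, 2 or NA")
  }
  out <- genotype / 2
  out
}

#' Classify a VAF value as monoallelic, biallelic, or missing
#'
#' A VAF of exactly 0 shows only the reference allele, exactly 1 only the
#' variant allele; any intermediate value is biallelic.
#'
#' @param value Numeric vector of VAF values (`NA` = missing).
#' @return Character vector with values `"monoallelic_ref"`, `"biallelic"`,
#'   `"monoallelic_var"`, or `NA`.
#' @export
classify_allelic_state <- function(value) {
  out <- rep(NA_character_, length(value))
  ok <- !is.na(value)
  out[ok & value == 0] <- "monoallelic_ref"
  out[ok & value == 1] <- "monoallelic_var"
  out[ok & value > 0 & value < 1] <- "biallelic"
  out
}

#' Genotype / RNA allelic-state concordance
#'
#' Homozygous-reference genotypes are concordant with monoallelic-reference
#' VAF calls, homozygous-variant with monoallelic-variant, and heterozygous
#' with biallelic. A missing value on either side is unevaluable.
#'
#' @param genotype Vector with values in `{0, 1, 2, NA}`.
#' @param state Allelic-state vector from [classify_allelic_state()].
#' @return Character vector: `"concordant"`, `"discordant"`, or
#'   `"unevaluable"`.
#' @export
concordance <- function(genotype, state) {
  stopifnot(length(genotype) == length(state))
  expected <- c(`0` = "monoallelic_ref", `1` = "biallelic",
                `2` = "monoallelic_var")
  out <- rep("discordant", length(genotype))
  out[is.na(genotype) | is.na(state)] <- "unevaluable"
  idx <- which(!is.na(genotype) & !is.na(state))
  hit <- expected[as.character(genotype[idx])] == state[idx]
  out[idx[hit]] <- "concordant"
  out
}

#' Write / read a per-sample allele-count table
#'
#' Columns: `locus_id`, `n_ref`, `n_var`, `n_other`, `vaf` (`NA` below the
#' coverage threshold used at write time).
#'
#' @param counts `data.frame` from [count_alleles()].
#' @param path Output TSV path.
#' @param min_coverage Coverage threshold for the `vaf` column.
#' @export
write_counts <- function(counts, path, min_coverage = 10L) {
  vaf <- compute_vaf(counts$n_ref, counts$n_var, min_coverage)
  out <- cbind(counts[, c("locus_id", "n_ref", "n_var", "n_other")],
               vaf = vaf$value)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  tab <- data.table::fread(path, header = TRUE, sep = "\t", na.strings = "NA",
                           data.table = FALSE)
  need <- c("locus_id", "n_ref", "n_var", "n_other")
  if (!all(need %in% names(tab))) {
    stop("counts table must have columns ", paste(need, collapse = ", "),
         ": ", path)
  }
  tab
}
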