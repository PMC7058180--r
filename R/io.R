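#' Read a list of SNV positions from a VCF or TSV file
#'
#' Builds the SNV position list that drives allele counting. VCF input is
#' parsed with `VariantAnnotation`; multi-allelic records are expanded to one
#' locus per alternate allele, and indels or symbolic alleles are skipped
#' (their count is reported with a message). TSV input must carry columns
#' `chrom`, `pos`, `ref`, `alt`.
#'
#' @param path Path to a VCF (`.vcf`, sites-only acceptable) or a
#'   tab-separated file with columns `chrom`, `pos`, `ref`, `alt`.
#' @return A `data.frame` with columns `chrom` (character, verbatim), `pos`
#'   (1-based integer), `ref`, `alt` (single nucleotides) and `id`
#'   (`"chrom:pos_ref>alt"`), deduplicated and sorted by (chrom, pos).
#' @export
read_snv_positions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is_vcf_file(path)) {
    loci <- read_snv_vcf(path)
  } else {
    loci <- read_snv_tsv(path)
  }
  dup <- duplicated(loci$id)
  if (any(dup)) {
    message(sum(dup), " duplicate locus record(s) collapsed")
    loci <- loci[!dup, , drop = FALSE]
  }
  loci <- loci[locus_order(loci$chrom, loci$pos), , drop = FALSE]
  rownames(loci) <- NULL
  if (nrow(loci) == 0L) stop("no usable SNV loci in ", path)
  loci
}

is_vcf_file <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) return(TRUE)
  first <- readLines(path, n = 1L)
  length(first) == 1L && startsWith(first, "##fileformat=VCF")
}

read_snv_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  keep <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    message(n_skipped, " non-SNV record(s) (indel/symbolic) skipped")
  }
  rr <- rr[keep]
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    stringsAsFactors = FALSE,
    row.names = NULL
  ) -> out
  out$id <- make_locus_id(out$chrom, out$pos, out$ref, out$alt)
  out
}

read_snv_tsv <- function(path) {
  tab <- data.table::fread(path, header = TRUE, sep = "\t",
                           colClasses = list(character = "chrom"),
                           data.table = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(tab))) {
    stop("SNV TSV must have columns chrom, pos, ref, alt; found: ",
         paste(names(tab), collapse = ", "))
  }
  nt <- c("A", "C", "G", "T")
  bad <- !(tab$ref %in% nt) | !(tab$alt %in% nt) | tab$ref == tab$alt |
    is.na(tab$pos) | tab$pos < 1 | tab$pos != as.integer(tab$pos)
  if (any(bad)) {
    # +1 for the header line so the number matches the file
    stop("malformed SNV record at line ", which(bad)[1L] + 1L, " of ", path)
  }
  data.frame(
    chrom = as.character(tab$chrom), pos = as.integer(tab$pos),
    ref = tab$ref, alt = tab$alt,
    id = make_locus_id(tab$chrom, tab$pos, tab$ref, tab$alt),
    stringsAsFactors = FALSE
  )
}

#' Read gene models (TSS and transcribed span) from a GTF or TSV file
#'
#' Gene-level records are extracted (features of type `"gene"`; if the file
#' has none, the union of each `gene_id`'s features is used). The
#' transcription start site is strand-aware: the leftmost coordinate of the
#' span for `+` genes and the rightmost for `-` genes. Genes listed in
#' `pseudogene_ids` are flagged so downstream expression filtering can drop
#' them.
#'
#' @param path GTF/GFF file, or a tab-separated file with columns `gene_id`,
#'   `chrom`, `strand`, `start`, `end` (1-based inclusive).
#' @param pseudogene_ids Optional character vector of gene ids to flag as
#'   pseudogenes.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `span_start`, `span_end`, `is_pseudogene`.
#' @export
read_gene_models <- function(path, pseudogene_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene")) {
      gr <- gr[gr$type == "gene"]
    }
    if (is.null(gr$gene_id)) stop("GTF has no gene_id attribute: ", path)
    df <- data.frame(
      gene_id = as.character(gr$gene_id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE
    )
    # collapse multi-feature genes to their overall span
    if (anyDuplicated(df$gene_id)) {
      dt <- data.table::as.data.table(df)
      df <- data.table::setDF(dt[, list(
        chrom = chrom[1L], strand = strand[1L],
        start = min(start), end = max(end)
      ), by = "gene_id"])
    }
  } else {
    df <- data.table::fread(path, header = TRUE, sep = "\t",
                            data.table = FALSE)
    need <- c("gene_id", "chrom", "strand", "start", "end")
    if (!all(need %in% names(df))) {
      stop("gene model TSV must have columns ",
           paste(need, collapse = ", "))
    }
    df$chrom <- as.character(df$chrom)
    if (anyDuplicated(df$gene_id)) {
      warning("duplicate gene_id(s); keeping widest span")
      df <- df[order(df$gene_id, -(df$end - df$start)), , drop = FALSE]
      df <- df[!duplicated(df$gene_id), , drop = FALSE]
    }
  }
  if (any(!df$strand %in% c("+", "-"))) {
    stop("gene(s) without strand: ",
         paste(head(df$gene_id[!df$strand %in% c("+", "-")], 5L),
               collapse = ", "))
  }
  out <- data.frame(
    gene_id = df$gene_id,
    chrom = df$chrom,
    strand = df$strand,
    tss = ifelse(df$strand == "+", df$start, df$end),
    span_start = as.integer(df$start),
    span_end = as.integer(df$end),
    is_pseudogene = df$gene_id %in% pseudogene_ids,
    stringsAsFactors = FALSE
  )
  out$tss <- as.integer(out$tss)
  stopifnot(all(out$span_start <= out$span_end))
  rownames(out) <- NULL
  out
}

#' Read and write feature-by-sample matrices
#'
#' All matrices in the pipeline (VAF, expression, covariates, genotypes)
#' share one tab-separated dialect: first column = row identifier, header =
#' sample ids, missing values written as the literal string `NA`. Values are
#' serialized with full precision so `read_matrix(write_matrix(m))`
#' reproduces `m`.
#'
#' @param path File path.
#' @return `read_matrix`: a numeric matrix with row and column names.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- data.table::fread(path, header = TRUE, sep = "\t", na.strings = "NA",
                           data.table = FALSE, colClasses = list(
                             character = 1L))
  if (ncol(tab) < 1L) stop("empty matrix file: ", path)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate row id(s) in ", path, ": ",
         paste(head(unique(ids[duplicated(ids)]), 5L), collapse = ", "))
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' @rdname read_matrix
#' @param m Numeric matrix with row and column names.
#' @param id_column Header name for the row-identifier column.
#' @export
write_matrix <- function(m, path, id_column = "id") {
  stopifnot(is.matrix(m), !is.null(colnames(m)))
  df <- data.frame(id = if (is.null(rownames(m))) character(0) else rownames(m),
                   stringsAsFactors = FALSE)
  names(df) <- id_column
  out <- cbind(df, as.data.frame(m, optional = TRUE))
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
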