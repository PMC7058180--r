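#' Assemble the VAF matrix from per-sample allele-count tables
#'
#' Each cell is the VAF at one locus in one sample, or `NA` when fewer than
#' `min_coverage` ref+var reads cover the position. Rows are loci sorted by
#' (chrom, pos); columns follow the order of `counts`.
#'
#' @param counts Named list of per-sample count tables (see
#'   [count_alleles()] / [read_counts()]); names are sample ids. All tables
#'   must share the same locus set.
#' @param min_coverage Minimum ref+var coverage for a non-missing VAF.
#' @return Numeric loci x samples matrix with `NA` for missing values.
#' @export
build_vaf_matrix <- function(counts, min_coverage = 10L) {
  stopifnot(is.list(counts), length(counts) > 0L, !is.null(names(counts)))
  samples <- names(counts)
  if (anyDuplicated(samples)) {
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  ids <- counts[[1L]]$locus_id
  loc <- parse_locus_id(ids)
  ord <- locus_order(loc$chrom, loc$pos)
  ids <- ids[ord]
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(samples),
              dimnames = list(ids, samples))
  for (s in samples) {
    tab <- counts[[s]]
    if (!setequal(tab$locus_id, ids) || nrow(tab) != length(ids)) {
      stop("count table for sample ", s,
           " does not share the common locus list")
    }
    tab <- tab[match(ids, tab$locus_id), , drop = FALSE]
    m[, s] <- compute_vaf(tab$n_ref, tab$n_var, min_coverage)$value
  }
  m
}

#' Drop SNV rows with mostly uninformative signal
#'
#' A cell is uninformative when it is missing or monoallelic (VAF exactly 0
#' or exactly 1, within `monoallelic_eps`). A row is dropped when its
#' uninformative fraction strictly exceeds `max_uninformative_fraction`
#' ("more than 80%" by default), so a boundary row at exactly the threshold
#' is retained.
#'
#' @param m VAF matrix (loci x samples).
#' @param max_uninformative_fraction Strict exclusion threshold, default 0.8.
#' @param monoallelic_eps Tolerance around 0/1 for calling a value
#'   monoallelic; default 0 (exact).
#' @return The filtered matrix; dropped row ids are reported via `message()`.
#' @export
filter_vaf_rows <- function(m, max_uninformative_fraction = 0.8,
                            monoallelic_eps = 0) {
  stopifnot(is.matrix(m), ncol(m) > 0L)
  uninf <- is.na(m) | m <= monoallelic_eps | m >= 1 - monoallelic_eps
  frac <- rowMeans(uninf)
  drop <- frac > max_uninformative_fraction
  if (any(drop)) {
    message(sum(drop), " SNV row(s) dropped as uninformative: ",
            paste(head(rownames(m)[drop], 10L), collapse = ", "),
            if (sum(drop) > 10L) ", ..." else "")
  }
  m[!drop, , drop = FALSE]
}

#' Filter the TPM expression matrix
#'
#' Removes pseudogene rows (per the gene models), then rows whose TPM is
#' below `min_tpm` in strictly more than `max_low_fraction` of the samples.
#' Gene ids without a model are retained with a warning.
#'
#' @param tpm Genes x samples TPM matrix.
#' @param models Gene models from [read_gene_models()], or `NULL` to skip
#'   pseudogene removal.
#' @param min_tpm Expression threshold, default 1 TPM.
#' @param max_low_fraction Strict exclusion threshold, default 0.8.
#' @return The filtered TPM matrix.
#' @export
filter_genes <- function(tpm, models = NULL, min_tpm = 1,
                         max_low_fraction = 0.8) {
  stopifnot(is.matrix(tpm), ncol(tpm) > 0L)
  if (!is.null(models)) {
    unresolved <- setdiff(rownames(tpm), models$gene_id)
    if (length(unresolved) > 0L) {
      warning(length(unresolved),
              " gene id(s) not in the gene models; retained: ",
              paste(head(unresolved, 5L), collapse = ", "))
    }
    pseudo <- models$gene_id[models$is_pseudogene]
    drop_pseudo <- rownames(tpm) %in% pseudo
    if (any(drop_pseudo)) {
      message(sum(drop_pseudo), " pseudogene row(s) dropped")
      tpm <- tpm[!drop_pseudo, , drop = FALSE]
    }
  }
  low <- rowMeans(tpm < min_tpm)
  drop <- low > max_low_fraction
  if (any(drop)) {
    message(sum(drop), " low-expression gene row(s) dropped")
  }
  tpm[!drop, , drop = FALSE]
}

#' Quantile-transform expression columns to the average empirical
#' distribution
#'
#' Within each sample (column), values are ranked and the value at rank r is
#' replaced by the mean over all samples of their r-th order statistics.
#' Ties within a column receive the mean of the reference values their tied
#' ranks span, so the transform is rank-preserving and, afterwards, every
#' column holds the same multiset of values (up to tie-averaging).
#'
#' @param m Numeric matrix (genes x samples) with no missing values and at
#'   least two columns.
#' @return Transformed matrix of the same shape and dimnames.
#' @export
quantile_transform <- function(m) {
  stopifnot(is.matrix(m), !anyNA(m), ncol(m) >= 2L, nrow(m) >= 1L)
  reference <- rowMeans(apply(m, 2L, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    o <- order(x)
    xs <- x[o]
    grp <- cumsum(c(TRUE, xs[-1L] != xs[-length(xs)]))
    mapped <- ave(reference, grp, FUN = mean)
    if (grp[length(grp)] == 1L && length(xs) > 1L) {
      message("constant column ", colnames(m)[j] %||% j,
              " mapped to the mean of the reference distribution")
    }
    out[o, j] <- mapped
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Top sample-space principal components of a VAF or genotype matrix
#'
#' Missing entries are imputed to the row mean, rows are centered, and the
#' first `k` right-singular vectors (sample-space principal component
#' scores) are returned, each unit-normalized with its largest-magnitude
#' entry made positive.
#'
#' @param m Loci x samples matrix, possibly with `NA`s.
#' @param k Number of components (default 3, as used for covariate
#'   correction).
#' @return A `k` x samples matrix with rownames `PC1..PCk`.
#' @export
compute_pcs <- function(m, k = 3L) {
  stopifnot(is.matrix(m), k >= 1L, k < min(nrow(m), ncol(m)))
  imputed <- m
  rm <- rowMeans(m, na.rm = TRUE)
  rm[is.nan(rm)] <- 0
  idx <- which(is.na(imputed), arr.ind = TRUE)
  if (nrow(idx) > 0L) imputed[idx] <- rm[idx[, 1L]]
  centered <- imputed - rowMeans(imputed)
  sv <- svd(centered, nu = 0L, nv = k)
  tol <- max(dim(centered)) * .Machine$double.eps * sv$d[1L]
  if (sum(sv$d > tol) < k) {
    stop("matrix rank ", sum(sv$d > tol), " is below the requested ", k,
         " principal components")
  }
  pcs <- t(sv$v)
  for (i in seq_len(k)) {
    if (pcs[i, which.max(abs(pcs[i, ]))] < 0) pcs[i, ] <- -pcs[i, ]
  }
  dimnames(pcs) <- list(paste0("PC", seq_len(k)), colnames(m))
  pcs
}

#' Stack external covariates and internal principal components
#'
#' Aligns the external covariate matrix (covariates x samples, numeric) to
#' the requested sample order, appends the PC rows, and rejects missing
#' values or rank deficiency.
#'
#' @param samples Character vector giving the sample order of the analysis.
#' @param external Optional covariates x samples numeric matrix.
#' @param pcs Optional PC rows from [compute_pcs()].
#' @return Covariates x samples matrix aligned to `samples`.
#' @export
assemble_covariates <- function(samples, external = NULL, pcs = NULL) {
  stopifnot(is.character(samples), length(samples) > 0L)
  parts <- list()
  if (!is.null(external)) {
    stopifnot(is.matrix(external))
    missing <- setdiff(samples, colnames(external))
    if (length(missing) > 0L) {
      stop("sample(s) missing from the covariate file: ",
           paste(missing, collapse = ", "))
    }
    parts$external <- external[, samples, drop = FALSE]
  }
  if (!is.null(pcs)) {
    stopifnot(is.matrix(pcs))
    missing <- setdiff(samples, colnames(pcs))
    if (length(missing) > 0L) {
      stop("sample(s) missing from the PC matrix: ",
           paste(missing, collapse = ", "))
    }
    parts$pcs <- pcs[, samples, drop = FALSE]
  }
  if (length(parts) == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = length(samples),
                  dimnames = list(NULL, samples)))
  }
  cov <- do.call(rbind, unname(parts))
  if (anyNA(cov)) stop("covariate matrix contains missing values")
  if (qr(t(cov))$rank < nrow(cov)) {
    stop("covariate matrix is rank-deficient (linearly dependent rows)")
  }
  cov
}
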