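#' Association-testing configuration
#'
#' @param cis_window_bp Cis window measured from the gene's TSS, inclusive
#'   at the boundary. Default 1 Mb.
#' @param cis_fdr,trans_fdr Significance cutoffs applied to the
#'   Benjamini-Hochberg q-values within the cis and trans families
#'   (defaults 0.05 and 0.10).
#' @param cis_mode `"tss"`: cis = same chromosome and |SNV - TSS| <=
#'   `cis_window_bp`; `"overlap"`: cis = SNV inside the transcribed gene
#'   span.
#' @param p_report_threshold Optional raw-p ceiling for emitting records
#'   (FDR is always computed over all tests before this filter).
#' @return A list of class `reqtl_test_config`.
#' @export
test_config <- function(cis_window_bp = 1e6, cis_fdr = 0.05,
                        trans_fdr = 0.10, cis_mode = c("tss", "overlap"),
                        p_report_threshold = NULL) {
  cis_mode <- match.arg(cis_mode)
  stopifnot(cis_window_bp > 0, cis_fdr > 0, trans_fdr > 0)
  structure(list(cis_window_bp = cis_window_bp, cis_fdr = cis_fdr,
                 trans_fdr = trans_fdr, cis_mode = cis_mode,
                 p_report_threshold = p_report_threshold),
            class = "reqtl_test_config")
}

#' Residualize matrix rows on a covariate design
#'
#' For each row, ordinary least squares of the row on an intercept plus the
#' covariates is fit on the row's non-missing samples; residuals replace the
#' values and missing entries stay missing. A row whose covariate design is
#' singular on its support is set entirely to `NA` and listed in the
#' `"untestable"` attribute.
#'
#' @param m Rows x samples matrix, possibly with `NA`s.
#' @param covariates Covariates x samples matrix (complete), or `NULL` for
#'   intercept-only centering.
#' @return Matrix of residuals with the same shape and dimnames.
#' @export
residualize <- function(m, covariates = NULL) {
  stopifnot(is.matrix(m))
  if (!is.null(covariates)) {
    stopifnot(is.matrix(covariates), !anyNA(covariates),
              ncol(covariates) == ncol(m))
  }
  design <- cbind(`(Intercept)` = rep(1, ncol(m)),
                  if (!is.null(covariates)) t(covariates))
  out <- m
  untestable <- character(0)
  for (i in seq_len(nrow(m))) {
    s <- !is.na(m[i, ])
    if (!any(s)) next
    X <- design[s, , drop = FALSE]
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) {
      out[i, ] <- NA_real_
      untestable <- c(untestable, rownames(m)[i] %||% as.character(i))
      next
    }
    out[i, s] <- qr.resid(qr_x, m[i, s])
  }
  attr(out, "untestable") <- untestable
  out
}

#' Covariate-adjusted linear association between one SNV and one gene
#'
#' Fits, on the samples where the SNV value is non-missing, the full
#' ordinary-least-squares model
#' `expression ~ intercept + covariates + vaf` and returns the VAF slope,
#' its Student t statistic with `n_used - k - 2` degrees of freedom (k =
#' number of covariates), and the two-sided p-value.
#'
#' @param snv Numeric vector of VAF (or genotype-fraction) values, `NA`
#'   allowed.
#' @param gene Numeric vector of (transformed) expression values, complete
#'   on the SNV's support.
#' @param covariates Covariates x samples matrix or `NULL`.
#' @return A list `(beta, t_stat, p_value, n_used)`, or `NULL` when the
#'   pair is untestable (support smaller than k + 3, singular design, or
#'   zero residual variance in the SNV).
#' @export
test_pair <- function(snv, gene, covariates = NULL) {
  stopifnot(length(snv) == length(gene))
  k <- if (is.null(covariates)) 0L else nrow(covariates)
  s <- !is.na(snv) & !is.na(gene)
  n <- sum(s)
  if (n < k + 3L) return(NULL)
  X <- cbind(1, if (k > 0L) t(covariates)[s, , drop = FALSE], snv[s])
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) return(NULL)
  coefs <- qr.coef(qr_x, gene[s])
  res <- qr.resid(qr_x, gene[s])
  df <- n - k - 2L
  if (df < 1L) return(NULL)
  sigma2 <- sum(res^2) / df
  xtx_inv <- solve(crossprod(X))
  se <- sqrt(sigma2 * xtx_inv[ncol(X), ncol(X)])
  if (!is.finite(se) || se == 0) return(NULL)
  beta <- coefs[[ncol(X)]]
  t_stat <- beta / se
  list(beta = beta, t_stat = t_stat,
       p_value = 2 * pt(abs(t_stat), df, lower.tail = FALSE),
       n_used = n)
}

#' Label SNV-gene pairs as cis or trans and control FDR per family
#'
#' In TSS-distance mode a pair is cis when the SNV lies on the gene's
#' chromosome within `cis_window_bp` of its TSS (inclusive); in overlap
#' mode, when the SNV falls inside the transcribed span. All other pairs
#' are trans. When the records carry p-values, Benjamini-Hochberg q-values
#' are computed separately within the cis and the trans family and each
#' record is marked significant against its family's cutoff; output is
#' sorted by (label, fdr, p, locus_id, gene_id).
#'
#' @param records `data.frame` with at least `locus_id` and `gene_id`
#'   (e.g. from [run_reqtl()] with `annotate = FALSE`).
#' @param models Gene models from [read_gene_models()]; every tested gene
#'   must be present.
#' @param config A [test_config()].
#' @return The records with `label` (`"cis"`/`"trans"`), `distance_bp`
#'   (signed SNV - TSS distance, `NA` across chromosomes), and, when
#'   p-values are present, `fdr` and `significant` columns.
#' @export
annotate_cis_trans <- function(records, models, config = test_config()) {
  stopifnot(is.data.frame(records),
            all(c("locus_id", "gene_id") %in% names(records)))
  missing <- setdiff(unique(records$gene_id), models$gene_id)
  if (length(missing) > 0L) {
    stop("gene(s) without a gene model: ",
         paste(head(missing, 5L), collapse = ", "))
  }
  records <- records[, setdiff(names(records), c("label", "distance_bp",
                                                 "fdr", "significant")),
                     drop = FALSE]
  loc <- parse_locus_id(records$locus_id)
  gi <- match(records$gene_id, models$gene_id)
  same_chrom <- loc$chrom == models$chrom[gi]
  distance <- ifelse(same_chrom, loc$pos - models$tss[gi], NA_real_)
  cis <- if (config$cis_mode == "tss") {
    same_chrom & abs(distance) <= config$cis_window_bp
  } else {
    same_chrom & loc$pos >= models$span_start[gi] &
      loc$pos <= models$span_end[gi]
  }
  cis[is.na(cis)] <- FALSE
  records$label <- ifelse(cis, "cis", "trans")
  records$distance_bp <- distance
  if ("p_value" %in% names(records)) {
    records$fdr <- NA_real_
    for (fam in c("cis", "trans")) {
      in_fam <- records$label == fam
      if (any(in_fam)) records$fdr[in_fam] <- bh_fdr(records$p_value[in_fam])
    }
    cutoff <- ifelse(records$label == "cis", config$cis_fdr,
                     config$trans_fdr)
    records$significant <- records$fdr < cutoff
    ord <- order(records$label, records$fdr, records$p_value,
                 records$locus_id, records$gene_id)
    records <- records[ord, , drop = FALSE]
    rownames(records) <- NULL
  }
  records
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  p.adjust(p, method = "BH")
}

#' Test every SNV-gene pair with the covariate-adjusted linear model
#'
#' The engine of the method: for each SNV row the samples with a
#' non-missing value form the support (complete-case analysis); expression
#' and covariates are residualized on the covariate design restricted to
#' that support, and every gene is tested through the residual correlation
#' `t = r * sqrt(df / (1 - r^2))` with `df = n_used - k - 2`, which equals
#' the full OLS fit of `expression ~ intercept + covariates + vaf`. With
#' `annotate = TRUE` the records are cis/trans-labelled and FDR-controlled
#' per family via [annotate_cis_trans()]; with `annotate = FALSE` unlabelled
#' records are returned for deferred annotation.
#'
#' @param vaf Loci x samples VAF (or genotype-fraction) matrix.
#' @param expression Genes x samples transformed expression matrix
#'   (complete).
#' @param covariates Covariates x samples matrix or `NULL`.
#' @param models Gene models (required when `annotate = TRUE`).
#' @param config A [test_config()].
#' @param annotate Label and FDR-control the records (default `TRUE`).
#' @param missing_policy `"complete_case"` (default): each pair is tested
#'   on the SNV's non-missing samples with correspondingly reduced degrees
#'   of freedom. `"mean_impute"`: missing VAF entries are replaced by the
#'   locus mean before testing, mimicking the imputation speed path of
#'   large matrix-eQTL implementations.
#' @return A `data.frame` of association records: `locus_id`, `gene_id`,
#'   `beta`, `t_stat`, `p_value`, `n_used`, plus `label`, `distance_bp`,
#'   `fdr`, `significant` when annotated.
#' @export
run_reqtl <- function(vaf, expression, covariates = NULL, models = NULL,
                      config = test_config(), annotate = TRUE,
                      missing_policy = c("complete_case", "mean_impute")) {
  missing_policy <- match.arg(missing_policy)
  if (missing_policy == "mean_impute" && anyNA(vaf)) {
    rm <- rowMeans(vaf, na.rm = TRUE)
    idx <- which(is.na(vaf), arr.ind = TRUE)
    vaf[idx] <- rm[idx[, 1L]]
    vaf[is.nan(vaf)] <- NA_real_  # all-missing rows stay untestable
  }
  stopifnot(is.matrix(vaf), is.matrix(expression))
  if (!identical(colnames(vaf), colnames(expression))) {
    stop("sample columns differ between the VAF and expression matrices: ",
         paste(union(setdiff(colnames(vaf), colnames(expression)),
                     setdiff(colnames(expression), colnames(vaf))),
               collapse = ", "))
  }
  if (!is.null(covariates)) {
    if (!identical(colnames(vaf), colnames(covariates))) {
      stop("sample columns differ between the VAF and covariate matrices")
    }
    if (anyNA(covariates)) stop("covariate matrix contains missing values")
  }
  if (anyNA(expression)) {
    stop("expression matrix contains missing values; filter and transform ",
         "it first")
  }
  k <- if (is.null(covariates)) 0L else nrow(covariates)
  n_genes <- nrow(expression)
  gene_ids <- rownames(expression)
  chunks <- vector("list", nrow(vaf))
  for (i in seq_len(nrow(vaf))) {
    v <- vaf[i, ]
    s <- !is.na(v)
    n <- sum(s)
    if (n < k + 3L) next
    X <- cbind(rep(1, n), if (k > 0L) t(covariates)[s, , drop = FALSE])
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) next
    Q <- qr.Q(qr_x)
    vs <- v[s]
    v_res <- vs - Q %*% crossprod(Q, vs)
    sv2 <- sum(v_res^2)
    if (sv2 <= n * .Machine$double.eps^0.5 * max(1, sum(vs^2))) next
    E <- expression[, s, drop = FALSE]
    E_res <- E - (E %*% Q) %*% t(Q)
    num <- as.vector(E_res %*% v_res)
    den2 <- rowSums(E_res^2)
    df <- n - k - 2L
    r2 <- num^2 / (den2 * sv2)
    r2 <- pmin(r2, 1)
    testable <- den2 > n * .Machine$double.eps
    t_stat <- sign(num) * sqrt(df * r2 / pmax(1 - r2, .Machine$double.eps))
    p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
    chunks[[i]] <- data.frame(
      locus_id = rep(rownames(vaf)[i], sum(testable)),
      gene_id = gene_ids[testable],
      beta = (num / sv2)[testable],
      t_stat = t_stat[testable],
      p_value = p[testable],
      n_used = rep(n, sum(testable)),
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, chunks[!vapply(chunks, is.null, TRUE)])
  if (is.null(records)) {
    records <- data.frame(locus_id = character(0), gene_id = character(0),
                          beta = numeric(0), t_stat = numeric(0),
                          p_value = numeric(0), n_used = integer(0),
                          stringsAsFactors = FALSE)
  }
  rownames(records) <- NULL
  if (annotate) {
    if (is.null(models)) stop("gene models are required when annotate = TRUE")
    records <- annotate_cis_trans(records, models, config)
  }
  if (!is.null(config$p_report_threshold)) {
    records <- records[records$p_value <= config$p_report_threshold, ,
                       drop = FALSE]
    rownames(records) <- NULL
  }
  records
}

#' Genotype (eQTL) mode
#'
#' Converts a 0/1/2 genotype matrix to allele fractions and runs the same
#' engine, enabling side-by-side eQTL comparison: when the VAF matrix
#' equals the genotype fractions exactly, the two modes return identical
#' records.
#'
#' @param genotypes Loci x samples matrix with values in `{0, 1, 2, NA}`.
#' @inheritParams run_reqtl
#' @return See [run_reqtl()].
#' @export
run_eqtl <- function(genotypes, expression, covariates = NULL, models = NULL,
                     config = test_config(), annotate = TRUE) {
  run_reqtl(genotype_to_fraction(genotypes), expression,
            covariates = covariates, models = models, config = config,
            annotate = annotate)
}
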