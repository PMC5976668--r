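# Matrix-level preprocessing: log2 transform, quantile normalization,
# batch-mean centering, and two-group ANOVA differential expression with
# Benjamini-Hochberg FDR control. These operate on an already-summarized
# genes x samples matrix (probe-level summarization is out of scope).

#' Log2-transform a linear-scale expression matrix
#'
#' @param x numeric genes x samples matrix of strictly positive
#'   linear-scale intensities.
#' @return the matrix of base-2 logarithms, identifiers preserved.
#' @export
log2_transform <- function(x) {
  check_expression_matrix(x)
  bad <- which(x <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("non-positive value at gene '%s', sample '%s' (%g); log2 needs strictly positive intensities",
          rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]], x[bad[1, 1], bad[1, 2]])
  }
  log2(x)
}

#' Quantile-normalize the samples of an expression matrix
#'
#' Forces every sample (column) onto a common distribution — the row-wise
#' mean of the sorted columns — so all columns share one sorted value
#' multiset, with ties resolved by average rank. This is the
#' quantile-normalization step of the RMA pipeline applied at matrix
#' level; it is idempotent. Delegates to
#' \code{limma::normalizeQuantiles()}.
#'
#' @param x numeric genes x samples matrix.
#' @return normalized matrix, identifiers preserved.
#' @export
quantile_normalize <- function(x) {
  check_expression_matrix(x)
  if (ncol(x) < 2) {
    warning("single-sample matrix: quantile normalization is a no-op", call. = FALSE)
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Remove additive batch effects by per-gene batch-mean centering
#'
#' For each gene, subtracts the batch mean from every sample of that batch
#' and adds the gene's grand mean back, so per-gene batch means are
#' equalized while the per-gene grand mean is preserved. This is the exact
#' least-squares correction for a one-factor batch model with no
#' covariates.
#'
#' @param x numeric genes x samples matrix.
#' @param batch per-sample batch assignment; either aligned with the
#'   columns of \code{x} or named by sample identifier.
#' @return corrected matrix.
#' @export
remove_batch_effects <- function(x, batch) {
  check_expression_matrix(x)
  if (!is.null(names(batch))) {
    unknown <- setdiff(colnames(x), names(batch))
    if (length(unknown)) {
      stopf("no batch assignment for sample(s): %s", paste(unknown, collapse = ", "))
    }
    extra <- setdiff(names(batch), colnames(x))
    if (length(extra)) {
      stopf("batch map references unknown sample(s): %s", paste(extra, collapse = ", "))
    }
    batch <- batch[colnames(x)]
  } else if (length(batch) != ncol(x)) {
    stopf("'batch' has %d entries but matrix has %d samples", length(batch), ncol(x))
  }
  b <- droplevels(as.factor(batch))
  grand <- rowMeans(x)
  out <- x
  for (lev in levels(b)) {
    idx <- which(b == lev)
    bm <- rowMeans(x[, idx, drop = FALSE])
    out[, idx] <- x[, idx, drop = FALSE] - bm + grand
  }
  out
}

#' Per-gene two-group differential expression (ANOVA + BH FDR)
#'
#' One-way two-group ANOVA per gene (the equal-variance F-test with 1 and
#' n-2 degrees of freedom, equivalent to the squared two-sided pooled
#' t-test), followed by Benjamini-Hochberg correction; genes with
#' adjusted q below \code{fdr} are flagged significant.
#'
#' Degenerate genes with zero within-group variance get p = 1 when the
#' group means are also equal (no evidence), and the smallest representable
#' positive p (with a warning) when the means differ.
#'
#' @param x numeric genes x samples matrix (log2 scale).
#' @param classes two-class labels aligned with the columns of \code{x}.
#' @param fdr significance threshold on the BH q-value; default 0.05.
#' @return data.frame with columns \code{gene_id}, \code{mean_class1},
#'   \code{mean_class2}, \code{p_value}, \code{fdr_q}, \code{significant},
#'   in the gene order of \code{x}.
#' @export
differential_expression <- function(x, classes, fdr = 0.05) {
  check_expression_matrix(x)
  cl <- check_labels(classes, x)
  i1 <- which(cl == levels(cl)[1]); i2 <- which(cl == levels(cl)[2])
  n1 <- length(i1); n2 <- length(i2); n <- n1 + n2
  if (n1 < 2 || n2 < 2) stopf("both classes need at least 2 samples")
  st <- class_stats(x, i1, i2)
  grand <- (n1 * st$m1 + n2 * st$m2) / n
  ss_between <- n1 * (st$m1 - grand)^2 + n2 * (st$m2 - grand)^2
  ss_within <- (n1 - 1) * st$v1 + (n2 - 1) * st$v2
  f <- ss_between / (ss_within / (n - 2))
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  # zero within-group variance
  degen <- ss_within == 0
  if (any(degen)) {
    equal <- degen & ss_between == 0
    p[equal] <- 1
    sep <- degen & ss_between > 0
    if (any(sep)) {
      warning(sprintf("%d gene(s) with zero within-group variance and unequal means; p set to the smallest positive double", sum(sep)), call. = FALSE)
      p[sep] <- .Machine$double.xmin
    }
  }
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene_id = rownames(x),
             mean_class1 = st$m1, mean_class2 = st$m2,
             p_value = p, fdr_q = q, significant = q < fdr,
             stringsAsFactors = FALSE, row.names = NULL)
}
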