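#' Fisher's ratio of a single feature in a two-class problem
#'
#' For one gene measured in two classes, Fisher's ratio is
#' \deqn{FR = (\mu_1 - \mu_2)^2 / (\sigma_1^2 + \sigma_2^2),}
#' the squared difference of class means over the sum of within-class
#' variances. Large values flag genes whose classes are far apart and
#' internally homogeneous. The ratio is invariant under a common location
#' shift and under rescaling by any nonzero constant, and symmetric under
#' swapping the classes.
#'
#' When both classes have zero variance the ratio is degenerate: equal
#' means give 0, unequal means give \code{Inf} ("infinite separability",
#' which sorts above every finite ratio).
#'
#' @param x1,x2 numeric vectors of the gene's values in class 1 and class 2
#'   (each of length >= 2).
#' @param var_type \code{"unbiased"} (n-1 denominator, default) or
#'   \code{"ml"} (n denominator) within-class variance.
#' @return a single non-negative number (possibly \code{Inf}).
#' @examples
#' fisher_ratio(c(1, 2, 3), c(4, 5, 6))  # (2-5)^2 / (1+1) = 4.5
#' @export
fisher_ratio <- function(x1, x2, var_type = c("unbiased", "ml")) {
  var_type <- match.arg(var_type)
  if (length(x1) < 2 || length(x2) < 2) {
    stopf("each class needs at least 2 values (got %d and %d)",
          length(x1), length(x2))
  }
  m1 <- mean(x1); m2 <- mean(x2)
  v1 <- stats::var(x1); v2 <- stats::var(x2)
  if (var_type == "ml") {
    v1 <- v1 * (length(x1) - 1) / length(x1)
    v2 <- v2 * (length(x2) - 1) / length(x2)
  }
  denom <- v1 + v2
  num <- (m1 - m2)^2
  if (denom == 0) {
    if (num == 0) return(0)
    return(Inf)
  }
  num / denom
}

#' Log2 fold change between two classes
#'
#' Difference of class means on already log2-transformed data, class 1
#' minus class 2 (here: fatigued minus non-fatigued). Antisymmetric under
#' swapping the classes.
#'
#' @inheritParams fisher_ratio
#' @return a single number in log2 units.
#' @export
fold_change <- function(x1, x2) {
  if (length(x1) == 0 || length(x2) == 0) stopf("both classes must be non-empty")
  mean(x1) - mean(x2)
}

#' Score every gene by Fisher's ratio and fold change
#'
#' Computes, per gene of a log2 expression matrix, the class means and
#' variances, Fisher's ratio, and log2 fold change (class 1 minus class 2),
#' then ranks genes in decreasing order of discriminatory power (descending
#' Fisher's ratio; ties broken by gene identifier so ranking is
#' deterministic).
#'
#' @param x numeric genes x samples matrix (log2 scale) with gene rownames
#'   and sample colnames.
#' @param classes two-class label vector aligned with \code{colnames(x)}
#'   (a level named \code{"fatigued"}, if present, is treated as class 1).
#' @param var_type variance estimator, see [fisher_ratio()].
#' @return data.frame of class \code{"gene_scores"} with columns
#'   \code{gene_id}, \code{fisher_ratio}, \code{fold_change}, \code{mu1},
#'   \code{mu2}, \code{var1}, \code{var2}, \code{rank}, ordered by rank.
#'   The variance estimator used is recorded in attribute
#'   \code{"var_type"}.
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 50, n_planted = 5, seed = 1))
#' head(score_genes(sim$matrix, sim$labels))
#' @export
score_genes <- function(x, classes, var_type = c("unbiased", "ml")) {
  var_type <- match.arg(var_type)
  check_expression_matrix(x)
  cl <- check_labels(classes, x)
  i1 <- which(cl == levels(cl)[1])
  i2 <- which(cl == levels(cl)[2])
  if (length(i1) < 2 || length(i2) < 2) {
    stopf("both classes need at least 2 samples (got %d and %d)",
          length(i1), length(i2))
  }
  st <- class_stats(x, i1, i2, var_type)
  denom <- st$v1 + st$v2
  num <- (st$m1 - st$m2)^2
  fr <- ifelse(denom > 0, num / denom, ifelse(num == 0, 0, Inf))
  ord <- order(-fr, rownames(x), method = "radix")
  rank <- integer(nrow(x)); rank[ord] <- seq_len(nrow(x))
  out <- data.frame(gene_id = rownames(x),
                    fisher_ratio = fr,
                    fold_change = st$m1 - st$m2,
                    mu1 = st$m1, mu2 = st$m2,
                    var1 = st$v1, var2 = st$v2,
                    rank = rank,
                    stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "var_type") <- var_type
  class(out) <- c("gene_scores", "data.frame")
  out
}

# Vectorized per-gene class means and variances.
class_stats <- function(x, i1, i2, var_type = "unbiased") {
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  v1 <- rowSums((x[, i1, drop = FALSE] - m1)^2)
  v2 <- rowSums((x[, i2, drop = FALSE] - m2)^2)
  if (var_type == "unbiased") {
    v1 <- v1 / (n1 - 1); v2 <- v2 / (n2 - 1)
  } else {
    v1 <- v1 / n1; v2 <- v2 / n2
  }
  list(m1 = m1, m2 = m2, v1 = v1, v2 = v2, n1 = n1, n2 = n2)
}

#' Fisher's-ratio / fold-change band filter
#'
#' A selection window on the Fisher's ratio-fold change plane: genes pass
#' when their ratio lies in \code{[fr_min, fr_max]} and their fold change
#' falls inside at least one of the fold-change bands. All intervals are
#' closed on both ends. The reference analysis this package reimplements
#' used FR in [0.70, 1.72] with fold-change bands
#' [-0.92, -0.15] and [0.09, 1.13].
#'
#' @param fr_min,fr_max Fisher's-ratio window bounds.
#' @param fc_bands list of length-2 numeric vectors, each a closed
#'   fold-change interval \code{c(lower, upper)}.
#' @return object of class \code{"band_filter"}.
#' @examples
#' band_filter(0.70, 1.72, list(c(-0.92, -0.15), c(0.09, 1.13)))
#' @export
band_filter <- function(fr_min, fr_max, fc_bands) {
  if (!is_number(fr_min) || !is_number(fr_max) || fr_min > fr_max) {
    stopf("need fr_min <= fr_max, both finite")
  }
  if (!is.list(fc_bands)) fc_bands <- list(fc_bands)
  for (b in fc_bands) {
    if (length(b) != 2 || !is.numeric(b) || anyNA(b) || b[1] > b[2]) {
      stopf("each fold-change band must be c(lower, upper) with lower <= upper")
    }
  }
  structure(list(fr_min = fr_min, fr_max = fr_max, fc_bands = fc_bands),
            class = "band_filter")
}

#' @export
print.band_filter <- function(x, ...) {
  bands <- vapply(x$fc_bands, function(b) sprintf("[%g, %g]", b[1], b[2]), "")
  cat(sprintf("Band filter: Fisher's ratio in [%g, %g]; fold change in %s\n",
              x$fr_min, x$fr_max, paste(bands, collapse = " or ")))
  invisible(x)
}

#' Apply a band filter to gene scores
#'
#' Keeps exactly those genes whose Fisher's ratio lies in the filter's
#' ratio window and whose fold change lies in at least one fold-change
#' band; rank order is preserved. An empty selection is a valid result.
#'
#' @param scores a \code{gene_scores} data.frame from [score_genes()].
#' @param filter a [band_filter()].
#' @return the selected subset of \code{scores}, same columns and ordering.
#' @export
select_band <- function(scores, filter) {
  if (!inherits(filter, "band_filter")) stopf("'filter' must be a band_filter")
  if (NROW(scores) == 0) stopf("'scores' is empty")
  fr_ok <- scores$fisher_ratio >= filter$fr_min &
    scores$fisher_ratio <= filter$fr_max
  fc_ok <- Reduce(`|`, lapply(filter$fc_bands, function(b) {
    scores$fold_change >= b[1] & scores$fold_change <= b[2]
  }), init = rep(FALSE, NROW(scores)))
  out <- scores[fr_ok & fc_ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}
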