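#' Leave-one-out cross-validated nearest-neighbor accuracy
#'
#' Each sample in turn is held out and classified by its nearest training
#' sample (k-nearest for odd \code{k}) in the space spanned by the selected
#' genes ("the reduced base"); the accuracy is the fraction of samples whose
#' predicted class matches their label, always an integer multiple of
#' 1/n_samples.
#'
#' Distances are Euclidean on the log2 values by default; no feature
#' rescaling is applied unless \code{scale = TRUE}, in which case each gene
#' is standardized using mean and standard deviation computed on the
#' training fold only. Distance ties are broken toward the
#' lower-indexed training sample.
#'
#' @param x numeric genes x samples matrix with dimnames.
#' @param classes two-class labels aligned with columns of \code{x}.
#' @param genes character vector of gene identifiers to use (default: all
#'   rows of \code{x}). All must be present in \code{rownames(x)}.
#' @param k odd number of neighbors (default 1).
#' @param metric \code{"euclidean"} (default) or \code{"correlation"}
#'   (distance 1 - Pearson correlation of sample profiles; needs >= 2 genes).
#' @param scale standardize genes on training folds only (default FALSE).
#' @return accuracy in [0, 1].
#' @examples
#' x <- matrix(c(0, 1, 10, 11), 1, dimnames = list("g1", paste0("s", 1:4)))
#' loocv_accuracy(x, c("A", "A", "B", "B"))  # 1.0
#' @export
loocv_accuracy <- function(x, classes, genes = NULL, k = 1,
                           metric = c("euclidean", "correlation"),
                           scale = FALSE) {
  metric <- match.arg(metric)
  check_expression_matrix(x)
  cl <- check_labels(classes, x)
  if (any(table(cl) < 2)) stopf("both classes need at least 2 samples")
  if (!is_count(k) || k < 1 || k %% 2 == 0) stopf("'k' must be a positive odd integer")
  if (is.null(genes)) genes <- rownames(x)
  if (length(genes) == 0) stopf("'genes' must be non-empty")
  missing <- setdiff(genes, rownames(x))
  if (length(missing)) {
    stopf("gene(s) absent from the matrix: %s", paste(missing, collapse = ", "))
  }
  xs <- x[genes, , drop = FALSE]
  pred <- loo_predictions(xs, cl, k = k, metric = metric, scale = scale)
  mean(pred == cl)
}

# LOO k-NN predictions for every sample; returns a factor like cl.
loo_predictions <- function(xs, cl, k = 1, metric = "euclidean", scale = FALSE) {
  n <- ncol(xs)
  if (metric == "correlation" && nrow(xs) < 2) {
    stopf("correlation metric needs at least 2 genes")
  }
  if (scale) {
    pred <- vapply(seq_len(n), function(i) {
      tr <- xs[, -i, drop = FALSE]
      mu <- rowMeans(tr)
      sd <- sqrt(rowSums((tr - mu)^2) / (n - 2))
      sd[sd == 0] <- 1  # constant-in-training genes carry no distance
      zi <- (xs[, i] - mu) / sd
      zt <- (tr - mu) / sd
      d <- if (metric == "euclidean") {
        colSums((zt - zi)^2)
      } else {
        1 - stats::cor(zi, zt)[1, ]
      }
      knn_vote(d, cl[-i], k)
    }, "")
    return(factor(pred, levels = levels(cl)))
  }
  D <- if (metric == "euclidean") {
    as.matrix(stats::dist(t(xs)))^2
  } else {
    1 - stats::cor(xs)
  }
  predict_from_sqdist(D, cl, k)
}

# Given a symmetric n x n distance matrix over the samples, predict each
# sample from its k nearest other samples. Lower index wins distance ties
# (order() is stable).
predict_from_sqdist <- function(D, cl, k = 1) {
  diag(D) <- Inf
  if (k == 1) {
    nn <- max.col(-D, ties.method = "first")
    return(factor(levels(cl)[as.integer(cl[nn])], levels = levels(cl)))
  }
  pred <- vapply(seq_len(ncol(D)), function(i) {
    knn_vote(D[, i], cl, k)  # self excluded via Inf diagonal
  }, "")
  factor(pred, levels = levels(cl))
}

knn_vote <- function(d, cl, k) {
  ord <- order(d)[seq_len(min(k, sum(is.finite(d))))]
  lev <- levels(cl)
  lev[1 + (sum(cl[ord] == lev[2]) > length(ord) / 2)]
}

# LOOCV accuracy of every top-k prefix of a ranked gene list.
# For the default metric the squared-distance matrix is built up gene by
# gene (cumulative sums), so the whole curve costs O(n_genes * n_samples^2).
prefix_accuracy_curve <- function(x, cl, ranked_genes, k = 1,
                                  metric = "euclidean", scale = FALSE) {
  m <- length(ranked_genes)
  n <- ncol(x)
  acc <- numeric(m)
  if (metric == "euclidean" && !scale) {
    D <- matrix(0, n, n)
    for (j in seq_len(m)) {
      g <- x[ranked_genes[j], ]
      D <- D + (outer(g, g, "-"))^2
      Dj <- D
      diag(Dj) <- Inf
      if (k == 1) {
        nn <- max.col(-Dj, ties.method = "first")
        acc[j] <- mean(cl[nn] == cl)
      } else {
        acc[j] <- mean(predict_from_sqdist(Dj, cl, k) == cl)
      }
    }
  } else {
    for (j in seq_len(m)) {
      xs <- x[ranked_genes[seq_len(j)], , drop = FALSE]
      if (metric == "correlation" && j < 2) {
        acc[j] <- NA_real_
        next
      }
      acc[j] <- mean(loo_predictions(xs, cl, k, metric, scale) == cl)
    }
  }
  acc
}

#' Minimum-size gene signature by recursive elimination
#'
#' Starting from a list of genes ranked by decreasing discriminatory power,
#' the lowest-ranked gene is eliminated one at a time, evaluating the LOOCV
#' nearest-neighbor accuracy of every prefix (top-k genes for
#' k = n, n-1, ..., 1). The returned signature is the smallest prefix
#' attaining the maximum observed accuracy — the rationale being that
#' high-ranked genes span the main features of the classification while
#' low-ranked ones only add detail. The search is deterministic.
#'
#' @inheritParams loocv_accuracy
#' @param ranked_genes character vector of gene identifiers in descending
#'   discriminatory order (e.g. from [score_genes()], optionally after
#'   [select_band()]).
#' @param scores optional \code{gene_scores} table to carry along for
#'   [summary.fr_signature()] and [coef.fr_signature()].
#' @return an object of class \code{"fr_signature"}; see [fr_signature()].
#' @export
minimal_signature <- function(x, classes, ranked_genes, k = 1,
                              metric = c("euclidean", "correlation"),
                              scale = FALSE, scores = NULL) {
  metric <- match.arg(metric)
  check_expression_matrix(x)
  cl <- check_labels(classes, x)
  if (length(ranked_genes) == 0) stopf("'ranked_genes' is empty")
  missing <- setdiff(ranked_genes, rownames(x))
  if (length(missing)) {
    stopf("gene(s) absent from the matrix: %s", paste(missing, collapse = ", "))
  }
  if (any(table(cl) < 2)) stopf("both classes need at least 2 samples")

  acc <- prefix_accuracy_curve(x, cl, ranked_genes, k, metric, scale)
  best <- max(acc, na.rm = TRUE)
  size <- which(acc == best)[1]  # smallest size attaining the maximum
  genes <- ranked_genes[seq_len(size)]
  x_sig <- x[genes, , drop = FALSE]
  pred <- loo_predictions(x_sig, cl, k, metric, scale)

  structure(list(
    genes = genes,
    loocv_accuracy = best,
    accuracy_curve = data.frame(size = seq_along(acc), accuracy = acc),
    loo_predictions = pred,
    classes = cl,
    x_signature = x_sig,
    scores = scores,
    k = k, metric = metric, scale = scale,
    n_samples = ncol(x),
    n_candidates = length(ranked_genes),
    call = match.call()
  ), class = "fr_signature")
}

#' Fit a minimum-size predictive gene signature
#'
#' The headline fitting function: scores every gene of a two-class log2
#' expression matrix by Fisher's ratio and fold change, optionally applies
#' a Fisher's-ratio / fold-change [band_filter()], ranks the surviving
#' genes by descending ratio, and searches for the minimum-size signature
#' whose leave-one-out cross-validated nearest-neighbor accuracy is
#' maximal (see [minimal_signature()]).
#'
#' @inheritParams loocv_accuracy
#' @param filter optional [band_filter()] restricting the candidate pool.
#' @param var_type variance estimator for Fisher's ratio, see
#'   [fisher_ratio()].
#' @return an object of class \code{"fr_signature"} with components
#'   \code{genes} (the signature, in rank order), \code{loocv_accuracy},
#'   \code{accuracy_curve} (data.frame of prefix size vs accuracy),
#'   \code{loo_predictions}, and the gene \code{scores}. Methods:
#'   \code{print}, \code{summary}, \code{coef} (Fisher's ratios of the
#'   signature genes), \code{predict} (nearest-neighbor classification of
#'   new samples), \code{fitted} (LOO predictions) and \code{plot}
#'   (accuracy curve).
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 200, n_planted = 5,
#'                                    effect_size = 2, sigma_within = 0.6,
#'                                    seed = 42))
#' fit <- fr_signature(sim$matrix, sim$labels)
#' fit
#' @export
fr_signature <- function(x, classes, filter = NULL, k = 1,
                         metric = c("euclidean", "correlation"),
                         scale = FALSE, var_type = c("unbiased", "ml")) {
  metric <- match.arg(metric)
  var_type <- match.arg(var_type)
  scores <- score_genes(x, classes, var_type)
  pool <- scores
  if (!is.null(filter)) {
    pool <- select_band(scores, filter)
    if (NROW(pool) == 0) stopf("band filter selected no genes")
  }
  fit <- minimal_signature(x, classes, pool$gene_id, k = k, metric = metric,
                           scale = scale, scores = scores)
  fit$filter <- filter
  fit$call <- match.call()
  fit
}

#' @export
print.fr_signature <- function(x, ...) {
  cat("Minimum-size gene signature (LOOCV ", x$k, "-NN, ", x$metric,
      " distance)\n", sep = "")
  cat(sprintf("  candidates ranked: %d; signature size: %d\n",
              x$n_candidates, length(x$genes)))
  cat(sprintf("  LOOCV accuracy: %.1f%% (%d/%d samples correct)\n",
              100 * x$loocv_accuracy,
              round(x$loocv_accuracy * x$n_samples), x$n_samples))
  shown <- utils::head(x$genes, 10)
  cat("  genes:", paste(shown, collapse = ", "),
      if (length(x$genes) > 10) sprintf("... (%d more)", length(x$genes) - 10) else "",
      "\n")
  invisible(x)
}

#' @export
summary.fr_signature <- function(object, ...) {
  conf <- table(observed = object$classes, predicted = object$loo_predictions)
  sc <- object$scores
  sig_scores <- if (!is.null(sc)) sc[match(object$genes, sc$gene_id), ] else NULL
  out <- list(fit = object, confusion = conf, signature_scores = sig_scores)
  class(out) <- "summary.fr_signature"
  out
}

#' @export
print.summary.fr_signature <- function(x, ...) {
  print(x$fit)
  cat("\nLeave-one-out confusion matrix:\n")
  print(x$confusion)
  if (!is.null(x$signature_scores)) {
    cat("\nSignature gene scores:\n")
    print(x$signature_scores, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.fr_signature <- function(object, ...) {
  if (is.null(object$scores)) {
    stats::setNames(rep(NA_real_, length(object$genes)), object$genes)
  } else {
    idx <- match(object$genes, object$scores$gene_id)
    stats::setNames(object$scores$fisher_ratio[idx], object$genes)
  }
}

#' @export
fitted.fr_signature <- function(object, ...) object$loo_predictions

#' Classify new samples with a fitted signature
#'
#' Nearest-neighbor classification of new samples against the training
#' samples, in the space of the signature genes. \code{newdata} must
#' contain all signature genes as rows.
#'
#' @param object an \code{fr_signature} fit.
#' @param newdata genes x samples numeric matrix on the same (log2) scale
#'   as the training data.
#' @param ... unused.
#' @return factor of predicted classes, one per column of \code{newdata}.
#' @export
predict.fr_signature <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$loo_predictions)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, ncol = 1,
                                               dimnames = list(names(newdata), "s1"))
  missing_genes <- setdiff(object$genes, rownames(newdata))
  if (length(missing_genes)) {
    stopf("newdata lacks signature gene(s): %s",
          paste(missing_genes, collapse = ", "))
  }
  tr <- object$x_signature
  nd <- newdata[object$genes, , drop = FALSE]
  cl <- object$classes
  pred <- vapply(seq_len(ncol(nd)), function(i) {
    d <- if (object$metric == "euclidean") {
      colSums((tr - nd[, i])^2)
    } else {
      1 - stats::cor(nd[, i], tr)[1, ]
    }
    knn_vote(d, cl, object$k)
  }, "")
  factor(pred, levels = levels(cl))
}

#' Plot the elimination accuracy curve of a signature fit
#'
#' LOOCV accuracy against signature (prefix) size, with the chosen
#' minimum-size signature marked.
#'
#' @param x an \code{fr_signature} fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fr_signature <- function(x, ...) {
  crv <- x$accuracy_curve
  graphics::plot(crv$size, crv$accuracy, type = "s",
                 xlab = "signature size (top-ranked genes)",
                 ylab = "LOOCV accuracy", ylim = c(0, 1), ...)
  graphics::abline(v = length(x$genes), lty = 2, col = "grey40")
  graphics::points(length(x$genes), x$loocv_accuracy, pch = 19, col = "red")
  invisible(x)
}
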