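# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so package functions never disturb user-level randomness.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Derive a per-stage child seed from a global seed; fixed affine map keeps
# results below 2^31 and distinct across stages.
derive_seed <- function(seed, stage_index) {
  (as.integer(seed) * 7919L + stage_index * 104729L) %% 2147483647L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x == round(x)
}

is_number <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)

# Validate a genes x samples numeric matrix with unique dimnames.
check_expression_matrix <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stopf("'%s' must be a numeric genes x samples matrix", arg)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stopf("'%s' must have gene identifiers as rownames and sample identifiers as colnames", arg)
  }
  if (anyDuplicated(rownames(x))) {
    stopf("duplicate gene identifiers in '%s': %s", arg,
          paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(x))) {
    stopf("duplicate sample identifiers in '%s'", arg)
  }
  if (anyNA(x)) stopf("'%s' contains missing values", arg)
  invisible(x)
}

# Coerce/validate a two-class label vector aligned with the matrix columns.
# Returns a factor whose first level is the "positive" class (fatigued).
check_labels <- function(classes, x = NULL) {
  if (is.null(names(classes)) && !is.null(x)) names(classes) <- colnames(x)
  cl <- as.factor(classes)
  if (nlevels(cl) != 2) {
    stopf("labels must contain exactly two classes, got %d", nlevels(cl))
  }
  if (!is.null(x)) {
    if (length(cl) != ncol(x)) {
      stopf("labels have %d entries but matrix has %d samples", length(cl), ncol(x))
    }
    if (!is.null(names(classes)) && !all(names(classes) %in% colnames(x))) {
      bad <- setdiff(names(classes), colnames(x))
      stopf("labels reference unknown samples: %s", paste(bad, collapse = ", "))
    }
  }
  # Conventional ordering: "fatigued" is class 1 when present.
  if ("fatigued" %in% levels(cl)) cl <- stats::relevel(cl, "fatigued")
  cl
}
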