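# Independent brute-force oracles, written with explicit loops so they stay
# structurally independent of the package implementations they check.

brute_fisher_ratio <- function(x1, x2) {
  m1 <- sum(x1) / length(x1)
  m2 <- sum(x2) / length(x2)
  v1 <- sum((x1 - m1)^2) / (length(x1) - 1)
  v2 <- sum((x2 - m2)^2) / (length(x2) - 1)
  (m1 - m2)^2 / (v1 + v2)
}

# Hold-one-out 1-NN by direct enumeration; squared Euclidean distance,
# distance ties resolved toward the lower training-sample index.
brute_loocv_1nn <- function(x, classes) {
  classes <- as.character(classes)
  n <- ncol(x)
  correct <- 0
  for (i in seq_len(n)) {
    best_d <- Inf
    best_j <- NA
    for (j in seq_len(n)[-i]) {
      d <- sum((x[, i] - x[, j])^2)
      if (d < best_d) {
        best_d <- d
        best_j <- j
      }
    }
    if (classes[best_j] == classes[i]) correct <- correct + 1
  }
  correct / n
}

# Exhaustive prefix search: LOOCV accuracy of every top-k prefix, maximum
# accuracy, smallest size attaining it.
brute_prefix_optimum <- function(x, classes, ranked_genes) {
  acc <- numeric(length(ranked_genes))
  for (k in seq_along(ranked_genes)) {
    acc[k] <- brute_loocv_1nn(x[ranked_genes[seq_len(k)], , drop = FALSE], classes)
  }
  best <- max(acc)
  list(size = which(acc == best)[1], accuracy = best, curve = acc)
}

withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("frsig-test-")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}

# Random labeled matrix with no class signal.
random_dataset <- function(n_genes, n1, n2, seed, sd = 1) {
  set.seed(seed)
  n <- n1 + n2
  x <- matrix(rnorm(n_genes * n, 7, sd), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n))))
  list(x = x, classes = rep(c("fatigued", "non-fatigued"), c(n1, n2)))
}
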