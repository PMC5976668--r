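test_that("loocv accuracy matches hand enumeration on the 4-sample line example", {
  x <- matrix(c(0, 1, 10, 11), 1, dimnames = list("g1", paste0("s", 1:4)))
  # held-out nearest neighbors: s1<->s2, s3<->s4
  expect_equal(loocv_accuracy(x, c("A", "A", "B", "B")), 1.0)
  expect_equal(loocv_accuracy(x, c("A", "B", "A", "B")), 0.0)

  # two tight separated clusters: perfect accuracy
  set.seed(1)
  xc <- matrix(c(rnorm(5, -10, 0.1), rnorm(5, 10, 0.1)), 1,
               dimnames = list("g1", paste0("s", 1:10)))
  expect_equal(loocv_accuracy(xc, rep(c("A", "B"), each = 5)), 1.0)
})

test_that("loocv accuracy validates its inputs", {
  x <- matrix(rnorm(20), 4, dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  cl <- c("A", "A", "B", "B", "B")
  expect_error(loocv_accuracy(x, cl, genes = c("g1", "g9")), "g9")
  expect_error(loocv_accuracy(x, cl, k = 2), "odd")
  expect_error(loocv_accuracy(x, c("A", "A", "A", "A", "B")), "at least 2")
})

test_that("loocv equals exhaustive hold-one-out enumeration over all labelings", {
  # every two-class labeling (>= 2 samples per class) of 6-sample 3-gene
  # random matrices, against the brute-force oracle
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(18), 3, dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
    for (size1 in 2:4) {
      for (idx in combn(6, size1, simplify = FALSE)) {
        cl <- rep("non-fatigued", 6)
        cl[idx] <- "fatigued"
        expect_equal(loocv_accuracy(x, cl), brute_loocv_1nn(x, cl))
      }
    }
  }
})

test_that("accuracy is a multiple of 1/n and invariant under joint sample permutation", {
  rd <- random_dataset(8, 5, 6, seed = 10)
  a <- loocv_accuracy(rd$x, rd$classes)
  expect_equal(a * 11, round(a * 11))
  perm <- sample(11)
  expect_equal(loocv_accuracy(rd$x[, perm], rd$classes[perm]), a)
})

test_that("minimal_signature returns the exhaustive prefix optimum with smallest-size ties", {
  for (seed in 1:8) {
    rd <- random_dataset(10, 4, 5, seed = 100 + seed)
    ranked <- score_genes(rd$x, rd$classes)$gene_id
    fit <- minimal_signature(rd$x, rd$classes, ranked)
    oracle <- brute_prefix_optimum(rd$x, rd$classes, ranked)
    expect_equal(length(fit$genes), oracle$size)
    expect_equal(fit$loocv_accuracy, oracle$accuracy)
    expect_equal(fit$accuracy_curve$accuracy, oracle$curve)
  }
})

test_that("a single perfectly separating top gene yields a size-1 signature", {
  rd <- random_dataset(12, 5, 5, seed = 44)
  x <- rd$x
  x["g001", ] <- ifelse(rd$classes == "fatigued", 20, -20) + rnorm(10, 0, 0.1)
  ranked <- score_genes(x, rd$classes)$gene_id
  expect_equal(ranked[1], "g001")
  fit <- minimal_signature(x, rd$classes, ranked)
  expect_equal(fit$genes, "g001")
  expect_equal(fit$loocv_accuracy, 1.0)
})

test_that("the accuracy curve covers every prefix and tops out at the returned accuracy", {
  rd <- random_dataset(15, 6, 6, seed = 3)
  ranked <- score_genes(rd$x, rd$classes)$gene_id
  fit <- minimal_signature(rd$x, rd$classes, ranked)
  expect_equal(nrow(fit$accuracy_curve), 15)
  expect_equal(max(fit$accuracy_curve$accuracy), fit$loocv_accuracy)
  expect_equal(fit$accuracy_curve$accuracy[length(fit$genes)], fit$loocv_accuracy)
  # the signature is the top-k prefix of the ranked list
  expect_equal(fit$genes, ranked[seq_along(fit$genes)])
})

test_that("permuted-label accuracy matches the 1-NN exchangeability expectation", {
  rd <- random_dataset(20, 12, 24, seed = 55)
  # with exchangeable labels the chance a sample's nearest neighbor shares
  # its label is (n1(n1-1) + n2(n2-1)) / (n(n-1))
  expected <- (12 * 11 + 24 * 23) / (36 * 35)
  set.seed(56)
  acc <- replicate(200, loocv_accuracy(rd$x, sample(rd$classes)))
  se <- sd(acc) / sqrt(200)
  expect_lt(abs(mean(acc) - expected), 3 * se)
})

test_that("fr_signature fits end to end, with working S3 methods", {
  sim <- simulate_dataset(sim_config(n_genes = 300, n_planted = 8,
                                     effect_size = 1.5, sigma_within = 0.8,
                                     seed = 12))
  fit <- fr_signature(sim$matrix, sim$labels)
  expect_s3_class(fit, "fr_signature")
  expect_true(fit$loocv_accuracy >= 0 && fit$loocv_accuracy <= 1)
  expect_output(print(fit), "LOOCV accuracy")
  summ <- summary(fit)
  expect_equal(sum(summ$confusion), 36)
  expect_named(coef(fit), fit$genes)
  expect_equal(as.character(fitted(fit)), as.character(fit$loo_predictions))

  # self-prediction agrees exactly for well-separated training data
  pred <- predict(fit, sim$matrix)
  expect_gte(mean(pred == sim$labels), fit$loocv_accuracy)

  # plotting works headlessly
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))

  # band-filtered fit restricts the candidate pool
  flt <- band_filter(0.5, 1e6, list(c(-3, 3)))
  expect_error(fr_signature(sim$matrix, sim$labels, filter = band_filter(100, 200, list(c(0, 1)))),
               "no genes")
  fit2 <- fr_signature(sim$matrix, sim$labels, filter = flt)
  expect_lte(fit2$n_candidates, 300)
})

test_that("k-NN, correlation metric and training-fold scaling variants run correctly", {
  sim <- simulate_dataset(sim_config(n_genes = 40, n_planted = 4,
                                     effect_size = 2, sigma_within = 0.5,
                                     seed = 6))
  a3 <- loocv_accuracy(sim$matrix, sim$labels, k = 3)
  expect_true(a3 >= 0 && a3 <= 1)
  acor <- loocv_accuracy(sim$matrix, sim$labels, metric = "correlation")
  expect_true(acor >= 0 && acor <= 1)
  expect_error(loocv_accuracy(sim$matrix, sim$labels, genes = rownames(sim$matrix)[1],
                              metric = "correlation"), "2 genes")
  az <- loocv_accuracy(sim$matrix, sim$labels, scale = TRUE)
  expect_true(az >= 0 && az <= 1)
  # scaling a feature's units must not change z-scored results
  x2 <- sim$matrix
  x2[1, ] <- x2[1, ] * 100
  expect_equal(loocv_accuracy(x2, sim$labels, scale = TRUE), az)
})
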