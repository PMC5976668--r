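test_that("fisher_ratio matches hand arithmetic and handles degenerate classes", {
  expect_equal(fisher_ratio(c(1, 2, 3), c(4, 5, 6)), 4.5)  # (2-5)^2 / (1+1)
  expect_equal(fisher_ratio(c(1, 3), c(2, 2)), 0)          # equal means
  expect_equal(fisher_ratio(c(2, 2), c(2, 2)), 0)          # all-constant, equal
  expect_identical(fisher_ratio(c(2, 2), c(5, 5)), Inf)    # infinite separability
  expect_error(fisher_ratio(1, c(1, 2)), "at least 2")
})

test_that("fisher_ratio agrees with a brute-force oracle on 1000 random instances", {
  set.seed(101)
  dev <- replicate(1000, {
    n1 <- sample(2:15, 1); n2 <- sample(2:15, 1)
    x1 <- rnorm(n1, rnorm(1), runif(1, 0.2, 3))
    x2 <- rnorm(n2, rnorm(1), runif(1, 0.2, 3))
    abs(fisher_ratio(x1, x2) - brute_fisher_ratio(x1, x2))
  })
  expect_lt(max(dev), 1e-12)
})

test_that("fisher_ratio is symmetric, location/scale invariant; fold_change antisymmetric", {
  set.seed(7)
  for (i in 1:50) {
    x1 <- rnorm(6); x2 <- rnorm(8, 1)
    a <- rnorm(1); c <- runif(1, 0.1, 5) * sample(c(-1, 1), 1)
    expect_equal(fisher_ratio(x1, x2), fisher_ratio(x2, x1))
    expect_equal(fisher_ratio(a + c * x1, a + c * x2), fisher_ratio(x1, x2),
                 tolerance = 1e-10)
    expect_equal(fold_change(x1, x2), -fold_change(x2, x1))
  }
  expect_equal(fold_change(c(6, 6), c(5, 5)), 1.0)
  expect_equal(fold_change(c(3, 4), c(3, 4)), 0)
})

test_that("ml variance option rescales the ratio as expected", {
  x1 <- c(1, 2, 3); x2 <- c(4, 5, 6)
  # n = 3 in both classes: ml variances are 2/3 of unbiased ones
  expect_equal(fisher_ratio(x1, x2, var_type = "ml"),
               fisher_ratio(x1, x2) * 3 / 2)
})

test_that("score_genes ranks by descending ratio with deterministic ties and order invariance", {
  rd <- random_dataset(30, 5, 7, seed = 3)
  sc <- score_genes(rd$x, rd$classes)
  expect_setequal(sc$rank, seq_len(30))
  expect_true(all(diff(sc$fisher_ratio[order(sc$rank)]) <= 0))
  expect_equal(attr(sc, "var_type"), "unbiased")

  # identical permutation of samples and labels leaves scores unchanged
  perm <- sample(ncol(rd$x))
  sc2 <- score_genes(rd$x[, perm], rd$classes[perm])
  expect_equal(sc2, sc, ignore_attr = TRUE)

  # a constant gene scores 0 on both axes
  x <- rd$x
  x["g001", ] <- 5
  sc3 <- score_genes(x, rd$classes)
  row <- sc3[sc3$gene_id == "g001", ]
  expect_equal(row$fisher_ratio, 0)
  expect_equal(row$fold_change, 0)

  # equal ratios break ties lexicographically by gene id
  xt <- rbind(gB = c(1, 2, 4, 5), gA = c(1, 2, 4, 5))
  colnames(xt) <- paste0("s", 1:4)
  st <- score_genes(xt, c("fatigued", "fatigued", "non-fatigued", "non-fatigued"))
  expect_equal(st$gene_id, c("gA", "gB"))
})

test_that("planted discriminatory genes dominate the top ranks across seeds", {
  # 20 planted genes, effect 1.5 log2 units, sigma 1, 12+24 samples:
  # population FR of planted genes is 1.5^2/2 = 1.125 vs 0 for the rest, so
  # planted genes hold the 20 largest population ratios; empirically at this
  # sample size simulation shows >= 13/20 in the top 20 and >= 17/20 in the
  # top 40 per seed, averaging >= 15 in the top 20.
  top20 <- top40 <- integer(20)
  for (s in 1:20) {
    sim <- simulate_dataset(sim_config(n_genes = 1000, n_planted = 20,
                                       effect_size = 1.5, sigma_within = 1,
                                       batch_sd = 0, seed = s))
    sc <- score_genes(sim$matrix, sim$labels)
    top20[s] <- sum(head(sc$gene_id, 20) %in% sim$planted_genes)
    top40[s] <- sum(head(sc$gene_id, 40) %in% sim$planted_genes)
  }
  expect_gte(min(top20), 13)
  expect_gte(mean(top20), 15)
  expect_gte(min(top40), 15)
})

test_that("select_band keeps exactly the genes inside the closed FR/FC windows", {
  scores <- data.frame(
    gene_id = paste0("g", 1:5),
    fisher_ratio = c(0.5, 0.8, 1.0, 1.8, 0.75),
    fold_change = c(0.5, -0.5, 0.05, 0.5, 0.2),
    mu1 = 0, mu2 = 0, var1 = 1, var2 = 1, rank = 1:5,
    stringsAsFactors = FALSE)
  class(scores) <- c("gene_scores", "data.frame")
  flt <- band_filter(0.70, 1.72, list(c(-0.92, -0.15), c(0.09, 1.13)))
  sel <- select_band(scores, flt)
  # g1 fails the FR floor, g3 misses both FC bands, g4 exceeds the FR ceiling
  expect_equal(sel$gene_id, c("g2", "g5"))

  # boundary values are included (closed intervals)
  edge <- scores
  edge$fisher_ratio <- c(0.70, 1.72, 0.70, 1.72, 1.0)
  edge$fold_change <- c(0.09, 1.13, -0.92, -0.15, 0.0)
  expect_equal(select_band(edge, flt)$gene_id, paste0("g", 1:4))

  # an impossible window selects nothing, without error
  expect_equal(NROW(select_band(scores, band_filter(2, 3, list(c(-1, 1))))), 0)
})

test_that("widening any filter band never shrinks the selection", {
  rd <- random_dataset(200, 6, 8, seed = 5)
  sc <- score_genes(rd$x, rd$classes)
  base <- band_filter(0.2, 0.8, list(c(-0.5, -0.1), c(0.1, 0.5)))
  n_base <- NROW(select_band(sc, base))
  wider <- list(
    band_filter(0.1, 0.8, base$fc_bands),
    band_filter(0.2, 1.5, base$fc_bands),
    band_filter(0.2, 0.8, list(c(-0.8, -0.1), c(0.1, 0.5))),
    band_filter(0.2, 0.8, c(base$fc_bands, list(c(0.6, 1)))))
  for (w in wider) expect_gte(NROW(select_band(sc, w)), n_base)
})
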