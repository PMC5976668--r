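#' Configuration for the synthetic two-class microarray generator
#'
#' Defaults emulate the study design the package is built around: 36
#' prostate-cancer patients profiled on Affymetrix HG U133 Plus 2.0 arrays
#' (54,675 probe sets), 12 of whom developed clinically significant
#' fatigue one year after radiotherapy and 24 of whom did not. Planted
#' discriminatory genes receive a class-mean shift of \code{effect_size}
#' log2 units; with the default \code{effect_size = 0.6} and
#' \code{sigma_within = 0.45} their population Fisher's ratio is
#' \eqn{0.6^2/(2 \cdot 0.45^2) \approx 0.89} and their population fold
#' change 0.6, inside the selection bands FR [0.70, 1.72] and
#' FC [0.09, 1.13] used in the reference analysis.
#'
#' @param n_genes number of genes (probe sets); default 54675.
#' @param n_class1 fatigued sample count; default 12.
#' @param n_class2 non-fatigued sample count; default 24.
#' @param n_planted number of planted discriminatory genes; default 420.
#' @param effect_size log2 class-mean shift of planted genes (class 1 minus
#'   class 2); default 0.6.
#' @param sigma_within within-class standard deviation, log2 units;
#'   default 0.45.
#' @param baseline_mean grand mean log2 intensity; default 7 (typical of
#'   RMA-summarized arrays).
#' @param n_batches number of processing batches; default 3.
#' @param batch_sd standard deviation of the additive per-batch offset,
#'   log2 units; default 0.2 (0 disables batch structure).
#' @param seed integer RNG seed.
#' @return a validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_genes = 54675, n_class1 = 12, n_class2 = 24,
                       n_planted = 420, effect_size = 0.6,
                       sigma_within = 0.45, baseline_mean = 7,
                       n_batches = 3, batch_sd = 0.2, seed = 1) {
  cfg <- list(n_genes = n_genes, n_class1 = n_class1, n_class2 = n_class2,
              n_planted = n_planted, effect_size = effect_size,
              sigma_within = sigma_within, baseline_mean = baseline_mean,
              n_batches = n_batches, batch_sd = batch_sd, seed = seed)
  for (f in c("n_genes", "n_class1", "n_class2", "n_batches")) {
    if (!is_count(cfg[[f]]) || cfg[[f]] < 1) {
      stopf("sim_config: '%s' must be a positive integer", f)
    }
  }
  if (!is_count(n_planted) || n_planted < 0) {
    stopf("sim_config: 'n_planted' must be a non-negative integer")
  }
  if (n_planted > n_genes) stopf("sim_config: 'n_planted' exceeds 'n_genes'")
  if (!is_number(sigma_within) || sigma_within <= 0) {
    stopf("sim_config: 'sigma_within' must be a positive number")
  }
  if (!is_number(batch_sd) || batch_sd < 0) {
    stopf("sim_config: 'batch_sd' must be non-negative")
  }
  for (f in c("effect_size", "baseline_mean")) {
    if (!is_number(cfg[[f]])) stopf("sim_config: '%s' must be a finite number", f)
  }
  if (!is_count(seed)) stopf("sim_config: 'seed' must be an integer")
  structure(cfg, class = "sim_config")
}

#' Simulate a two-class microarray dataset with planted signal
#'
#' Generates a genes x samples matrix of Gaussian log2 intensities.
#' Planted genes have class-1 mean \code{baseline_mean + effect_size} and
#' class-2 mean \code{baseline_mean}; all other genes have equal class
#' means. Samples are assigned round-robin to \code{n_batches} processing
#' batches, and each batch receives an additive offset (shared by all
#' genes of its samples) drawn from N(0, \code{batch_sd}^2). FACT-F
#' baseline / 1-year score pairs are generated so that applying the
#' >= 3-point-decrease rule reproduces the class labels exactly.
#' Identical configurations (including seed) give identical datasets.
#'
#' @param config a [sim_config()].
#' @return list of class \code{"synthetic_dataset"}:
#'   \item{matrix}{genes x samples log2 matrix ("g0001"... x "s01"...)}
#'   \item{labels}{factor, levels \code{c("fatigued", "non-fatigued")}}
#'   \item{planted_genes}{character vector of planted gene ids}
#'   \item{batch}{named per-sample batch factor}
#'   \item{factf}{data.frame subject_id, factf_baseline, factf_1yr, batch}
#'   \item{config}{the configuration used}
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 100, n_planted = 10, seed = 3))
#' dim(sim$matrix)
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) {
    stopf("'config' must come from sim_config()")
  }
  n <- config$n_class1 + config$n_class2
  gene_ids <- sprintf("g%0*d", max(4, nchar(config$n_genes)), seq_len(config$n_genes))
  sample_ids <- sprintf("s%0*d", max(2, nchar(n)), seq_len(n))
  labels <- factor(rep(c("fatigued", "non-fatigued"),
                       c(config$n_class1, config$n_class2)),
                   levels = c("fatigued", "non-fatigued"))
  names(labels) <- sample_ids
  # Round-robin batch assignment interleaves the classes across batches,
  # keeping batches approximately balanced with respect to phenotype.
  batch <- factor(sprintf("b%d", rep_len(seq_len(config$n_batches), n)))
  names(batch) <- sample_ids

  with_seed(config$seed, {
    x <- matrix(stats::rnorm(config$n_genes * n, mean = config$baseline_mean,
                             sd = config$sigma_within),
                nrow = config$n_genes,
                dimnames = list(gene_ids, sample_ids))
    planted <- gene_ids[seq_len(config$n_planted)]
    if (config$n_planted > 0) {
      x[planted, labels == "fatigued"] <-
        x[planted, labels == "fatigued"] + config$effect_size
    }
    if (config$batch_sd > 0) {
      offsets <- stats::rnorm(config$n_batches, 0, config$batch_sd)
      x <- sweep(x, 2, offsets[as.integer(batch)], "+")
    }
  })
  factf <- generate_factf(labels, seed = derive_seed(config$seed, 1L))
  factf$batch <- as.character(batch)

  structure(list(matrix = x, labels = labels, planted_genes = planted,
                 batch = batch, factf = factf, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Synthetic two-class expression dataset: %d genes x %d samples\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  classes: %d fatigued / %d non-fatigued; %d planted gene(s), effect %.2g log2\n",
              cfg$n_class1, cfg$n_class2, cfg$n_planted, cfg$effect_size))
  cat(sprintf("  batches: %d (sd %.2g); seed %d\n",
              cfg$n_batches, cfg$batch_sd, cfg$seed))
  invisible(x)
}

#' Generate FACT-F score pairs consistent with class labels
#'
#' For each subject, draws a baseline FACT-F total uniformly on the
#' integers 30-50 and a change consistent with the label: fatigued
#' subjects decrease by 3-8 points (a clinically significant worsening),
#' non-fatigued subjects change by -3 to +2 points. All totals stay within
#' the instrument's 16-53 range, so [classify_fatigue()] applied to the
#' output reproduces the input labels exactly.
#'
#' @param labels factor/character vector of classes
#'   (\code{"fatigued"} / \code{"non-fatigued"}), optionally named.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{subject_id},
#'   \code{factf_baseline}, \code{factf_1yr}.
#' @export
generate_factf <- function(labels, seed = 1) {
  if (length(labels) == 0) stopf("'labels' is empty")
  lab <- as.character(labels)
  if (!all(lab %in% c("fatigued", "non-fatigued"))) {
    stopf("labels must be 'fatigued' or 'non-fatigued'")
  }
  ids <- names(labels)
  if (is.null(ids)) ids <- sprintf("s%0*d", max(2, nchar(length(lab))), seq_along(lab))
  with_seed(seed, {
    baseline <- sample(30:50, length(lab), replace = TRUE)
    decrease <- ifelse(lab == "fatigued",
                       sample(3:8, length(lab), replace = TRUE),
                       sample(-3:2, length(lab), replace = TRUE))
  })
  one_year <- pmin(53, pmax(16, baseline - decrease))
  data.frame(subject_id = ids, factf_baseline = baseline,
             factf_1yr = one_year, stringsAsFactors = FALSE)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes the expression matrix (tab-delimited, genes as rows), the
#' subject table (CSV: subject_id, factf_baseline, factf_1yr, batch) and
#' the planted-gene truth list (one id per line) into a directory.
#'
#' @param sim a \code{synthetic_dataset} from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written file paths.
#' @export
write_dataset <- function(sim, dir) {
  if (!inherits(sim, "synthetic_dataset")) stopf("'sim' must be a synthetic_dataset")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "expression_matrix.tsv"),
             subjects = file.path(dir, "subjects.csv"),
             planted = file.path(dir, "planted_genes.txt"))
  write_expression_matrix(sim$matrix, paths[["matrix"]],
                          provenance = list(seed = sim$config$seed))
  utils::write.csv(sim$factf, paths[["subjects"]], row.names = FALSE)
  writeLines(sim$planted_genes, paths[["planted"]])
  invisible(paths)
}
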