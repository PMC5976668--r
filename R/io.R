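# File formats and end-to-end pipeline orchestration.
#
# Matrix dialect: tab-delimited text, genes as rows; first column holds the
# gene identifier, the header row the sample identifiers. Lines starting
# with '#' are provenance comments and are skipped on read. gzip input is
# read transparently.

#' Read an expression matrix from tab-delimited text
#'
#' @param path file path (plain or gzip).
#' @return numeric genes x samples matrix with dimnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, comment.char = "#",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      fill = FALSE, blank.lines.skip = TRUE),
    error = function(e) stopf("cannot parse '%s': %s", path, conditionMessage(e))
  )
  if (ncol(df) < 2) stopf("'%s': need a gene-id column plus at least one sample", path)
  ids <- as.character(df[[1]])
  dup <- which(duplicated(ids))
  if (length(dup)) {
    stopf("'%s': duplicate gene identifier '%s' (data line %d)",
          path, ids[dup[1]], dup[1])
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stopf("'%s': non-numeric value '%s' in column '%s' (data line %d)",
            path, col[bad], names(vals)[j], bad)
    }
  }
  x <- as.matrix(vals)
  rownames(x) <- ids
  if (anyNA(x)) stopf("'%s': missing values in the matrix", path)
  check_expression_matrix(x)
  x
}

#' Write an expression matrix as tab-delimited text
#'
#' Values are written with 15 significant digits so a write/read round
#' trip reproduces them to at least 12 significant digits. A provenance
#' comment block ('#'-prefixed) precedes the header.
#'
#' @param x numeric genes x samples matrix with dimnames.
#' @param path output file path.
#' @param provenance optional named list echoed into the comment block.
#' @return invisibly, \code{path}.
#' @export
write_expression_matrix <- function(x, path, provenance = NULL) {
  check_expression_matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(provenance), con)
  writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

provenance_lines <- function(provenance = NULL) {
  extra <- if (length(provenance)) {
    sprintf("# %s: %s", names(provenance),
            vapply(provenance, function(v) paste(format(v), collapse = ","), ""))
  } else character()
  c(sprintf("# frsig %s", as.character(utils::packageVersion("frsig"))), extra)
}

#' Read per-sample class labels from CSV
#'
#' Expects columns \code{subject_id} and \code{class} (as written by
#' [phenotype_from_file()]).
#'
#' @param path CSV file path.
#' @return named factor of classes.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "class") %in% names(df))) {
    stopf("'%s': need columns subject_id, class", path)
  }
  stats::setNames(factor(df$class), df$subject_id)
}

#' Pipeline configuration
#'
#' Bundles the file paths, preprocessing switches, band filter, classifier
#' settings and sampler settings of one end-to-end run. Inputs are checked
#' for existence at construction time.
#'
#' @param matrix_file expression-matrix path (tab-delimited dialect).
#' @param subjects_file subject CSV with FACT-F scores (subject_id,
#'   factf_baseline, factf_1yr, optionally batch).
#' @param out_dir output directory for stage artifacts and the manifest.
#' @param log2 apply [log2_transform()] first (set TRUE for linear-scale
#'   input); default FALSE (input already log2).
#' @param quantile apply [quantile_normalize()]; default TRUE.
#' @param batch_correct apply [remove_batch_effects()] using the
#'   \code{batch} column of the subject table; default TRUE when that
#'   column exists.
#' @param filter optional [band_filter()] for candidate-gene selection.
#' @param k,metric classifier settings (see [loocv_accuracy()]).
#' @param sampler_draws,sampler_size,sampler_retention sampler settings;
#'   \code{sampler_retention = NULL} defaults to the fitted signature's
#'   accuracy minus 1/n_samples. \code{sampler_draws = 0} skips the
#'   sampler stage.
#' @param seed global seed, fanned out to per-stage child seeds.
#' @return a list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(matrix_file, subjects_file, out_dir,
                            log2 = FALSE, quantile = TRUE,
                            batch_correct = NA, filter = NULL, k = 1,
                            metric = "euclidean", sampler_draws = 1000,
                            sampler_size = c(2, 20),
                            sampler_retention = NULL, seed = 1) {
  for (f in c(matrix_file, subjects_file)) {
    if (!file.exists(f)) stopf("input file not found: %s", f)
  }
  if (!is.null(filter) && !inherits(filter, "band_filter")) {
    stopf("'filter' must be a band_filter or NULL")
  }
  structure(list(matrix_file = matrix_file, subjects_file = subjects_file,
                 out_dir = out_dir, log2 = log2, quantile = quantile,
                 batch_correct = batch_correct, filter = filter, k = k,
                 metric = metric, sampler_draws = sampler_draws,
                 sampler_size = sampler_size,
                 sampler_retention = sampler_retention, seed = seed),
            class = "pipeline_config")
}

#' Run the full signature-discovery pipeline
#'
#' Executes the stages in flow-chart order — phenotype dichotomization,
#' preprocessing (optional log2, quantile normalization, batch-mean
#' centering), differential expression, Fisher's-ratio scoring and band
#' selection, minimum-size signature search, and the random network
#' sampler — writing each stage's artifact plus a JSON manifest with
#' parameter echo, seed, and md5 checksums of every output. Re-running
#' with the same config and inputs reproduces the checksums.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest as a list (also written to
#'   \code{manifest.json} in \code{out_dir}).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stopf("'config' must come from pipeline_config()")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # --- phenotype ---
  pheno <- stage("phenotype", {
    subj <- utils::read.csv(config$subjects_file, stringsAsFactors = FALSE)
    need <- c("subject_id", "factf_baseline", "factf_1yr")
    if (!all(need %in% names(subj))) {
      stopf("subject file lacks columns: %s",
            paste(setdiff(need, names(subj)), collapse = ", "))
    }
    cls <- classify_fatigue(subj$factf_baseline, subj$factf_1yr)
    labels_path <- file.path(config$out_dir, "labels.csv")
    utils::write.csv(data.frame(subject_id = subj$subject_id,
                                class = as.character(cls)),
                     labels_path, row.names = FALSE)
    summary_path <- file.path(config$out_dir, "cohort_summary.csv")
    utils::write.csv(cohort_summary(cls), summary_path, row.names = FALSE)
    outputs <<- c(outputs, labels_path, summary_path)
    list(classes = stats::setNames(cls, subj$subject_id), subjects = subj)
  })

  # --- preprocess ---
  x <- stage("preprocess", {
    x <- read_expression_matrix(config$matrix_file)
    if (!setequal(colnames(x), pheno$subjects$subject_id)) {
      stopf("matrix samples and subject table disagree")
    }
    if (isTRUE(config$log2)) x <- log2_transform(x)
    if (isTRUE(config$quantile)) x <- quantile_normalize(x)
    do_batch <- isTRUE(config$batch_correct) ||
      (is.na(config$batch_correct) && "batch" %in% names(pheno$subjects))
    if (do_batch) {
      if (!"batch" %in% names(pheno$subjects)) {
        stopf("batch correction requested but subject table has no 'batch' column")
      }
      x <- remove_batch_effects(
        x, stats::setNames(pheno$subjects$batch, pheno$subjects$subject_id))
    }
    path <- file.path(config$out_dir, "preprocessed_matrix.tsv")
    write_expression_matrix(x, path, provenance = list(seed = config$seed))
    outputs <<- c(outputs, path)
    x
  })
  classes <- pheno$classes[colnames(x)]

  # --- differential expression ---
  stage("differential_expression", {
    de <- differential_expression(x, classes)
    path <- file.path(config$out_dir, "differential_expression.csv")
    utils::write.csv(de, path, row.names = FALSE)
    outputs <<- c(outputs, path)
  })

  # --- scoring + band selection ---
  sel <- stage("select", {
    scores <- score_genes(x, classes)
    path <- file.path(config$out_dir, "gene_scores.csv")
    utils::write.csv(scores, path, row.names = FALSE)
    outputs <<- c(outputs, path)
    pool <- if (is.null(config$filter)) scores else select_band(scores, config$filter)
    if (NROW(pool) == 0) stopf("band filter selected no genes")
    list(scores = scores, pool = pool)
  })

  # --- minimal signature ---
  fit <- stage("signature", {
    fit <- minimal_signature(x, classes, sel$pool$gene_id, k = config$k,
                             metric = config$metric, scores = sel$scores)
    path <- file.path(config$out_dir, "signature.json")
    jsonlite::write_json(list(genes = fit$genes,
                              loocv_accuracy = fit$loocv_accuracy,
                              accuracy_curve = fit$accuracy_curve,
                              params = list(k = config$k, metric = config$metric,
                                            seed = config$seed)),
                         path, auto_unbox = TRUE, digits = NA)
    curve_path <- file.path(config$out_dir, "accuracy_curve.csv")
    utils::write.csv(fit$accuracy_curve, curve_path, row.names = FALSE)
    outputs <<- c(outputs, path, curve_path)
    fit
  })

  # --- sampler ---
  if (config$sampler_draws > 0) {
    stage("sampler", {
      retention <- config$sampler_retention
      if (is.null(retention)) {
        retention <- fit$loocv_accuracy - 1 / fit$n_samples
      }
      cfg <- sampler_config(
        pool = sel$pool$gene_id, n_draws = config$sampler_draws,
        size_min = config$sampler_size[1],
        size_max = min(config$sampler_size[2], NROW(sel$pool)),
        retention_accuracy = retention,
        seed = derive_seed(config$seed, 5L))
      res <- sample_networks(x, classes, cfg, k = config$k, metric = config$metric)
      path <- file.path(config$out_dir, "sampler_frequencies.csv")
      utils::write.csv(frequency_report(res), path, row.names = FALSE)
      json_path <- file.path(config$out_dir, "sampler_networks.json")
      jsonlite::write_json(
        list(n_retained = res$n_retained, n_draws = res$n_draws,
             retention_accuracy = retention,
             networks = lapply(res$networks, function(nw)
               list(genes = nw$genes, accuracy = nw$accuracy))),
        json_path, auto_unbox = TRUE, digits = NA)
      outputs <<- c(outputs, path, json_path)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("frsig")),
    seed = config$seed,
    inputs = list(matrix = config$matrix_file, subjects = config$subjects_file),
    parameters = list(log2 = config$log2, quantile = config$quantile,
                      k = config$k, metric = config$metric,
                      sampler_draws = config$sampler_draws),
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))),
    complete = TRUE
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
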