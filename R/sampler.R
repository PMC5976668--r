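#' Configuration of the random gene-network sampler
#'
#' The sampler explores the space of small gene subsets ("networks") drawn
#' from a pool of highly discriminatory genes: subset sizes are uniform on
#' \code{[size_min, size_max]}, genes within a draw are sampled uniformly
#' without replacement, and networks whose LOOCV nearest-neighbor accuracy
#' reaches \code{retention_accuracy} are retained.
#'
#' @param pool character vector of candidate gene identifiers.
#' @param n_draws number of random networks to draw; default 10000.
#' @param size_min,size_max network size range; defaults 2 and 20 (capped
#'   at the pool size).
#' @param retention_accuracy LOOCV accuracy threshold in [0, 1] for
#'   retaining a network. A natural choice is the minimal signature's
#'   accuracy minus 1/n_samples.
#' @param seed integer RNG seed.
#' @return a validated list of class \code{"sampler_config"}.
#' @export
sampler_config <- function(pool, n_draws = 10000, size_min = 2,
                           size_max = 20, retention_accuracy = 0.8,
                           seed = 1) {
  if (length(pool) == 0) stopf("sampler_config: 'pool' is empty")
  pool <- as.character(pool)
  if (anyDuplicated(pool)) stopf("sampler_config: duplicate genes in 'pool'")
  size_max <- min(size_max, length(pool))
  if (!is_count(n_draws) || n_draws < 1) stopf("sampler_config: 'n_draws' must be >= 1")
  if (!is_count(size_min) || !is_count(size_max) || size_min < 1 ||
      size_min > size_max) {
    stopf("sampler_config: need 1 <= size_min <= size_max <= |pool|")
  }
  if (!is.numeric(retention_accuracy) || length(retention_accuracy) != 1) {
    stopf("sampler_config: 'retention_accuracy' must be a number")
  }
  if (!is_count(seed)) stopf("sampler_config: 'seed' must be an integer")
  structure(list(pool = pool, n_draws = n_draws, size_min = size_min,
                 size_max = size_max,
                 retention_accuracy = retention_accuracy, seed = seed),
            class = "sampler_config")
}

#' Sample random gene networks and estimate posterior gene frequencies
#'
#' Draws \code{n_draws} random gene subsets from the pool, scores each by
#' leave-one-out cross-validated nearest-neighbor accuracy, retains those
#' at or above the retention threshold, and reports each pool gene's
#' posterior sampling frequency: the fraction of retained networks that
#' contain it — a stability measure of the gene's involvement in
#' high-accuracy networks. All draws are made from a single RNG stream
#' before any scoring, so results are reproducible for a given seed
#' regardless of how scoring is executed.
#'
#' @param x numeric genes x samples matrix (log2 scale).
#' @param classes two-class labels aligned with columns of \code{x}.
#' @param config a [sampler_config()]; all pool genes must be rows of
#'   \code{x}.
#' @param k,metric classifier settings passed to [loocv_accuracy()].
#' @return object of class \code{"sampler_result"}:
#'   \item{networks}{list of retained networks, each with \code{genes} and
#'     \code{accuracy}}
#'   \item{posterior_frequency}{named numeric vector over the pool}
#'   \item{n_retained, n_draws}{counts}
#'   \item{config}{the configuration used}
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 30, n_planted = 3,
#'                                    effect_size = 2, sigma_within = 0.5,
#'                                    seed = 9))
#' cfg <- sampler_config(rownames(sim$matrix)[1:10], n_draws = 200,
#'                       size_min = 1, size_max = 3,
#'                       retention_accuracy = 0.9, seed = 2)
#' res <- sample_networks(sim$matrix, sim$labels, cfg)
#' head(frequency_report(res))
#' @export
sample_networks <- function(x, classes, config, k = 1,
                            metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  if (!inherits(config, "sampler_config")) {
    stopf("'config' must come from sampler_config()")
  }
  check_expression_matrix(x)
  cl <- check_labels(classes, x)
  missing <- setdiff(config$pool, rownames(x))
  if (length(missing)) {
    stopf("pool gene(s) absent from the matrix: %s", paste(missing, collapse = ", "))
  }

  # Draw every network first, from one seeded stream; scoring consumes no
  # random state.
  draws <- with_seed(config$seed, {
    sizes <- sample(config$size_min:config$size_max, config$n_draws, replace = TRUE)
    lapply(sizes, function(s) sample(config$pool, s))
  })
  acc <- vapply(draws, function(genes) {
    loocv_accuracy(x, cl, genes = genes, k = k, metric = metric)
  }, numeric(1))

  keep <- which(acc >= config$retention_accuracy)
  networks <- lapply(keep, function(i) list(genes = draws[[i]], accuracy = acc[i]))
  freq <- stats::setNames(numeric(length(config$pool)), config$pool)
  if (length(keep)) {
    tab <- table(unlist(lapply(networks, `[[`, "genes")))
    freq[names(tab)] <- as.integer(tab) / length(keep)
  } else {
    message("no network reached the retention accuracy; all posterior frequencies are 0")
  }
  structure(list(networks = networks, posterior_frequency = freq,
                 n_retained = length(keep), n_draws = config$n_draws,
                 config = config, k = k, metric = metric),
            class = "sampler_result")
}

#' @export
print.sampler_result <- function(x, ...) {
  cat(sprintf("Gene-network sampler: %d / %d networks retained at accuracy >= %g\n",
              x$n_retained, x$n_draws, x$config$retention_accuracy))
  top <- utils::head(frequency_report(x), 5)
  cat("Top posterior sampling frequencies:\n")
  print(top[, c("gene_id", "posterior_frequency")], row.names = FALSE)
  invisible(x)
}

#' Ranked posterior-frequency table of a sampler run
#'
#' One row per pool gene, sorted by descending posterior sampling
#' frequency with ties broken by gene identifier; carries the retained
#' count and configuration echo for provenance.
#'
#' @param result a \code{sampler_result} from [sample_networks()].
#' @return data.frame with columns \code{gene_id},
#'   \code{posterior_frequency}, \code{n_retained}; attribute
#'   \code{"config"} echoes the sampler configuration.
#' @export
frequency_report <- function(result) {
  if (!inherits(result, "sampler_result")) stopf("'result' must be a sampler_result")
  f <- result$posterior_frequency
  ord <- order(-f, names(f), method = "radix")
  out <- data.frame(gene_id = names(f)[ord],
                    posterior_frequency = unname(f)[ord],
                    n_retained = result$n_retained,
                    stringsAsFactors = FALSE)
  attr(out, "config") <- result$config
  out
}
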