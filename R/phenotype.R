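#' Dichotomize fatigue from FACT-F change scores
#'
#' Applies the clinically significant worsening rule to pairs of FACT-F
#' (Functional Assessment of Cancer Therapy - Fatigue) totals: a subject is
#' classed \code{"fatigued"} when the score decreased by at least 3 points
#' from baseline to the 1-year follow-up, and \code{"non-fatigued"}
#' otherwise. Lower FACT-F totals mean worse fatigue, so a decrease is a
#' worsening. Totals on this instrument lie in the 16-53 range.
#'
#' @param baseline numeric vector of baseline FACT-F totals (16-53).
#' @param one_year numeric vector of 1-year FACT-F totals (16-53).
#' @param min_decrease minimal clinically important decrease; default 3.
#' @return factor with levels \code{c("fatigued", "non-fatigued")}, one
#'   entry per subject. Names are taken from \code{baseline} if present.
#' @examples
#' classify_fatigue(c(40, 40, 30), c(37, 38, 35))
#' @export
classify_fatigue <- function(baseline, one_year, min_decrease = 3) {
  if (length(baseline) != length(one_year)) {
    stopf("baseline and one_year scores differ in length (%d vs %d)",
          length(baseline), length(one_year))
  }
  check_factf_range(baseline, "baseline")
  check_factf_range(one_year, "one_year")
  if (any(baseline != round(baseline)) || any(one_year != round(one_year))) {
    warning("fractional FACT-F totals supplied; the instrument yields integers",
            call. = FALSE)
  }
  cls <- ifelse(baseline - one_year >= min_decrease, "fatigued", "non-fatigued")
  factor(cls, levels = c("fatigued", "non-fatigued"))
}

check_factf_range <- function(score, what) {
  if (anyNA(score) || !is.numeric(score)) {
    stopf("%s FACT-F scores must be numeric and non-missing", what)
  }
  bad <- which(score < 16 | score > 53)
  if (length(bad)) {
    stopf("%s FACT-F score out of the instrument range [16, 53] at position %d (value %g)",
          what, bad[1], score[bad[1]])
  }
  invisible(score)
}

#' Cohort summary of fatigue classification
#'
#' Counts and percentages per fatigue class, percentages reported to one
#' decimal place (e.g. 12 fatigued of 36 prints as 33.3).
#'
#' @param classes factor or character vector of per-subject classes, as
#'   returned by [classify_fatigue()].
#' @return data.frame with columns \code{class}, \code{n}, \code{percent}.
#' @examples
#' cohort_summary(rep(c("fatigued", "non-fatigued"), c(12, 24)))
#' @export
cohort_summary <- function(classes) {
  if (length(classes) == 0) stopf("empty cohort")
  cl <- factor(classes, levels = union(c("fatigued", "non-fatigued"),
                                       unique(as.character(classes))))
  cl <- droplevels(cl)
  n <- as.integer(table(cl))
  data.frame(class = levels(cl),
             n = n,
             percent = round(100 * n / length(cl), 1),
             stringsAsFactors = FALSE)
}

#' Read a subject table and write labels plus a cohort summary
#'
#' Reads a CSV with columns \code{subject_id}, \code{factf_baseline},
#' \code{factf_1yr} (extra columns pass through), applies
#' [classify_fatigue()], and optionally writes the labels and summary CSVs
#' consumed by the rest of the pipeline.
#'
#' @param subjects_file path to the subject CSV.
#' @param out_labels,out_summary optional output CSV paths.
#' @param ... passed on to [classify_fatigue()].
#' @return invisibly, a list with \code{labels} (data.frame subject_id,
#'   class) and \code{summary} (from [cohort_summary()]).
#' @export
phenotype_from_file <- function(subjects_file, out_labels = NULL,
                                out_summary = NULL, ...) {
  subj <- utils::read.csv(subjects_file, stringsAsFactors = FALSE)
  need <- c("subject_id", "factf_baseline", "factf_1yr")
  miss <- setdiff(need, names(subj))
  if (length(miss)) stopf("subject file lacks columns: %s", paste(miss, collapse = ", "))
  cls <- classify_fatigue(subj$factf_baseline, subj$factf_1yr, ...)
  labels <- data.frame(subject_id = subj$subject_id, class = as.character(cls),
                       stringsAsFactors = FALSE)
  summ <- cohort_summary(cls)
  if (!is.null(out_labels)) utils::write.csv(labels, out_labels, row.names = FALSE)
  if (!is.null(out_summary)) utils::write.csv(summ, out_summary, row.names = FALSE)
  invisible(list(labels = labels, summary = summ))
}
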