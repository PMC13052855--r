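#' Percent agreement between two cause-label lists
#'
#' 100 x (number of exact label matches) / (number of pairs);
#' `"undetermined"` matches only `"undetermined"`. When the reference is a
#' physician review, filter with [filter_for_reference_comparison()] first.
#'
#' @param reference,predicted equal-length non-empty paired label vectors.
#' @return percent in \[0, 100\].
#' @export
percent_agreement <- function(reference, predicted) {
  if (length(reference) != length(predicted)) {
    stop("paired label lists differ in length", call. = FALSE)
  }
  if (!length(reference)) stop("empty input", call. = FALSE)
  100 * mean(reference == predicted)
}

#' Per-cause sensitivity (true positive rate)
#'
#' For each cause j: `TP_j` = pairs where both methods assign j; `FN_j` =
#' pairs where the reference assigns j and the comparator does not;
#' sensitivity = `TP_j / (TP_j + FN_j)`. Undefined (NA, flagged) when the
#' reference contains no death of cause j.
#'
#' @param reference,predicted equal-length paired label vectors.
#' @param causes cause set to evaluate; default the causes present in the
#'   reference.
#' @return named numeric vector in \[0, 1\] with NA for undefined causes;
#'   attribute `"undefined"` lists them.
#' @export
sensitivity_by_cause <- function(reference, predicted, causes = NULL) {
  if (length(reference) != length(predicted)) {
    stop("paired label lists differ in length", call. = FALSE)
  }
  if (is.null(causes)) causes <- sort(unique(reference))
  out <- vapply(causes, function(j) {
    ref_j <- reference == j
    if (!any(ref_j)) return(NA_real_)
    sum(ref_j & predicted == j) / sum(ref_j)
  }, numeric(1))
  names(out) <- causes
  attr(out, "undefined") <- causes[is.na(out)]
  out
}

#' CSMF accuracy
#'
#' `1 - sum_j |CSMF_j^true - CSMF_j^pred| / (2 (1 - min_j CSMF_j^true))`:
#' 1 means the predicted cause-fraction distribution matches the reference
#' exactly, 0 is the maximal possible discrepancy given the reference. The
#' statistic is not symmetric in its arguments (the denominator depends on
#' the reference only).
#'
#' @param csmf_true reference cause-fraction vector (sums to 1).
#' @param csmf_pred predicted cause-fraction vector over the same causes.
#' @return value in \[0, 1\].
#' @export
csmf_accuracy <- function(csmf_true, csmf_pred) {
  if (length(csmf_true) != length(csmf_pred)) {
    stop("CSMF vectors differ in length", call. = FALSE)
  }
  if (!is.null(names(csmf_true)) && !is.null(names(csmf_pred)) &&
      !identical(names(csmf_true), names(csmf_pred))) {
    stop("CSMF vectors are over different cause lists", call. = FALSE)
  }
  for (v in list(csmf_true, csmf_pred)) {
    if (abs(sum(v) - 1) > 1e-6 || any(v < 0)) {
      stop("CSMF vectors must be probability vectors summing to 1",
           call. = FALSE)
    }
  }
  denom <- 2 * (1 - min(csmf_true))
  if (denom == 0) {                 # degenerate single-cause reference
    if (max(abs(csmf_true - csmf_pred)) <= 1e-12) return(1)
    stop("reference CSMF is degenerate (one cause has all mass) and the ",
         "prediction differs; accuracy undefined", call. = FALSE)
  }
  acc <- 1 - sum(abs(csmf_true - csmf_pred)) / denom
  # clip only pure floating noise
  if (acc < 0 && acc > -1e-12) acc <- 0
  if (acc > 1 && acc < 1 + 1e-12) acc <- 1
  acc
}

#' Spearman rank correlation of two CSMF vectors
#'
#' Pearson correlation of the rank vectors, ties receiving average ranks.
#' The published convention ranks the largest CSMF 1; rho is invariant to
#' applying that orientation flip to both vectors. Undefined (NA) when either
#' vector is constant (all ranks tied).
#'
#' @param csmf_a,csmf_b cause-fraction vectors over the same causes
#'   (length >= 2).
#' @return value in \[-1, 1\], or NA when undefined.
#' @export
spearman_rho <- function(csmf_a, csmf_b) {
  if (length(csmf_a) != length(csmf_b) || length(csmf_a) < 2) {
    stop("need two vectors of equal length >= 2", call. = FALSE)
  }
  ra <- rank(csmf_a)
  rb <- rank(csmf_b)
  if (stats::var(ra) == 0 || stats::var(rb) == 0) return(NA_real_)
  stats::cor(ra, rb)
}

#' Non-parametric bootstrap confidence interval
#'
#' Resamples the paired data (the individual death with its full set of
#' method labels) with replacement `B` times, recomputes the statistic, and
#' returns the equal-tailed percentile interval. Resamples on which the
#' statistic is undefined (NA) are dropped from the percentile pool (a
#' message reports the count); more than 50% undefined is an error.
#'
#' @param statistic function of one argument (the resampled data) returning a
#'   scalar.
#' @param data data frame (resampled by row) or vector/list resampled by
#'   element.
#' @param B number of bootstrap replicates (>= 1).
#' @param level confidence level.
#' @param seed integer seed; fixed seed reproduces the interval.
#' @return named vector `c(low, high)`, with attributes `B_used` (non-NA
#'   replicates) and `point` (statistic on the original data).
#' @export
bootstrap_ci <- function(statistic, data, B = 1000, level = 0.95, seed = 1L) {
  stopifnot(B >= 1)
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n < 1) stop("empty data", call. = FALSE)
  take <- if (is.data.frame(data)) {
    function(idx) data[idx, , drop = FALSE]
  } else {
    function(idx) data[idx]
  }
  set.seed(as.integer(seed))
  reps <- vapply(seq_len(B), function(b) {
    statistic(take(sample.int(n, n, replace = TRUE)))
  }, numeric(1))
  n_na <- sum(is.na(reps))
  if (n_na > B / 2) {
    stop("statistic undefined on ", n_na, " of ", B,
         " resamples; more data needed", call. = FALSE)
  }
  if (n_na > 0) {
    message(n_na, " resample(s) with undefined statistic dropped")
  }
  alpha <- (1 - level) / 2
  ci <- stats::quantile(reps[!is.na(reps)], c(alpha, 1 - alpha), names = FALSE)
  structure(stats::setNames(ci, c("low", "high")),
            B_used = B - n_na, point = statistic(data))
}

#' Assemble a metric result row
#'
#' Convenience constructor for the delimited metric output
#' (`stratum, reference, predicted, level, metric, point, ci_low, ci_high,
#' B, seed`).
#'
#' @param metric metric name.
#' @param reference,predicted method labels of the comparison pair.
#' @param stratum stratum label.
#' @param level cause-level label.
#' @param point point estimate.
#' @param ci optional output of [bootstrap_ci()].
#' @param B,seed bootstrap settings recorded with the row.
#' @return one-row data frame.
#' @export
metric_result <- function(metric, reference, predicted, stratum, level,
                          point, ci = NULL, B = 0L, seed = NA_integer_) {
  data.frame(stratum = stratum, reference = reference, predicted = predicted,
             level = level, metric = metric, point = point,
             ci_low = if (is.null(ci)) NA_real_ else ci[["low"]],
             ci_high = if (is.null(ci)) NA_real_ else ci[["high"]],
             B = B, seed = seed, stringsAsFactors = FALSE)
}
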