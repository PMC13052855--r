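#' Logit-transformed proportion confidence interval
#'
#' The interval behind the published CSMF tables: with `p = n_j / N`,
#' `se(p) = sqrt(p (1 - p) / N)`, the interval is computed on the logit scale,
#' `l = ln(p / (1 - p))`, `se_l = se(p) / (p (1 - p))`, with a t critical
#' value on `N - 1` degrees of freedom, and back-transformed. The interval is
#' undefined (NA bounds) for `n_j = 0` or `n_j = N`, matching the tables'
#' `"(-)"` rendering. A plain Wald interval is available for comparison.
#'
#' @param n_j count of deaths in the cause (vectorized).
#' @param N stratum denominator (>= 1).
#' @param level confidence level, default 0.95.
#' @param method `"logit_t"` (default) or `"wald"`.
#' @return matrix with columns `low`, `high`, in percent; NA rows where the
#'   interval is undefined.
#' @export
proportion_ci <- function(n_j, N, level = 0.95,
                          method = c("logit_t", "wald")) {
  method <- match.arg(method)
  if (any(N < 1)) stop("N must be >= 1", call. = FALSE)
  if (any(n_j < 0) || any(n_j > N)) stop("need 0 <= n_j <= N", call. = FALSE)
  p <- n_j / N
  defined <- n_j > 0 & n_j < N
  low <- high <- rep(NA_real_, length(p))
  se <- sqrt(p * (1 - p) / N)
  if (method == "logit_t") {
    crit <- stats::qt(1 - (1 - level) / 2, df = N - 1)
    l <- log(p / (1 - p))
    se_l <- se / (p * (1 - p))
    low[defined] <- 100 * stats::plogis((l - crit * se_l)[defined])
    high[defined] <- 100 * stats::plogis((l + crit * se_l)[defined])
  } else {
    crit <- stats::qnorm(1 - (1 - level) / 2)
    low[defined] <- 100 * (p - crit * se)[defined]
    high[defined] <- 100 * (p + crit * se)[defined]
  }
  cbind(low = low, high = high)
}

#' Cause-specific mortality fraction table
#'
#' One row per (stratum, cause), including zero-count causes. The denominator
#' is the number of deaths in the stratum; undetermined deaths stay in the
#' denominator and appear as their own category. Fractions are percents with
#' logit-t confidence intervals ([proportion_ci()]); `ci_defined` is `FALSE`
#' exactly for zero or full cells.
#'
#' @param assignments [va_assignments()]-style data frame with `top_cause`
#'   plus any stratum columns named in `by` (merge stratum columns in
#'   beforehand, e.g. from `cohort$records`).
#' @param causes cause list defining the table rows; default the observed
#'   labels. Supply the level's full label set to include zero rows.
#' @param by character vector of stratum column names (may be empty for one
#'   overall stratum).
#' @param level_label cause-level tag written into the table.
#' @param conf confidence level.
#' @param method CI method passed to [proportion_ci()].
#' @return data frame of class `va_csmf_table`: stratum columns, `method`,
#'   `level`, `cause`, `n`, `N`, `csmf_pct`, `ci_low_pct`, `ci_high_pct`,
#'   `ci_defined`.
#' @export
compute_csmf <- function(assignments, causes = NULL, by = character(),
                         level_label = "harmonized35", conf = 0.95,
                         method = "logit_t") {
  stopifnot(is.data.frame(assignments), "top_cause" %in% names(assignments))
  if (!all(by %in% names(assignments))) {
    stop("grouping column(s) missing: ",
         paste(setdiff(by, names(assignments)), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(causes)) causes <- sort(unique(assignments$top_cause))
  meth <- if ("method" %in% names(assignments)) {
    unique(assignments$method)
  } else "unknown"
  if (length(meth) > 1L) {
    stop("one method per table; split the assignments first", call. = FALSE)
  }
  groups <- if (length(by)) {
    split(assignments, assignments[by], drop = FALSE, sep = "\r")
  } else list(overall = assignments)
  rows <- lapply(names(groups), function(gname) {
    g <- groups[[gname]]
    N <- nrow(g)
    n <- as.integer(table(factor(g$top_cause, levels = causes)))
    if (N == 0L) {
      warning("empty stratum: ", gsub("\r", "/", gname), call. = FALSE)
      ci <- cbind(low = rep(NA_real_, length(causes)),
                  high = rep(NA_real_, length(causes)))
      pct <- rep(NA_real_, length(causes))
    } else {
      ci <- proportion_ci(n, N, level = conf, method = method)
      pct <- 100 * n / N
    }
    strat <- if (length(by)) {
      as.data.frame(as.list(stats::setNames(strsplit(gname, "\r")[[1]], by)),
                    stringsAsFactors = FALSE)
    } else data.frame(row.names = 1)
    cbind(strat[rep(1, length(causes)), , drop = FALSE],
          data.frame(method = meth, level = level_label, cause = causes,
                     n = n, N = N, csmf_pct = pct,
                     ci_low_pct = ci[, "low"], ci_high_pct = ci[, "high"],
                     ci_defined = N > 0 & n > 0 & n < N,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("va_csmf_table", "data.frame")
  out
}

#' Render a CSMF table the way the published tables print it
#'
#' Fractions to two decimals; undefined intervals rendered `"(-)"`.
#'
#' @param x a `va_csmf_table`.
#' @param ... unused.
#' @return data frame with a formatted `csmf` column.
#' @export
format.va_csmf_table <- function(x, ...) {
  fmt <- ifelse(
    x$ci_defined,
    sprintf("%d(%.2f: %.2f-%.2f)", x$n, x$csmf_pct, x$ci_low_pct,
            x$ci_high_pct),
    sprintf("%d(-)", x$n)
  )
  cbind(x[setdiff(names(x), c("n", "csmf_pct", "ci_low_pct", "ci_high_pct",
                              "ci_defined"))],
        data.frame(csmf = fmt, stringsAsFactors = FALSE))
}
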