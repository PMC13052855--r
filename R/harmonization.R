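#' Validate and construct a three-level cause map
#'
#' A cause map carries one row per detailed cause and its target at each
#' coarser level (`harmonized35` -> `who15` -> `broad6`). Validation enforces
#' totality (every detailed cause appears exactly once), nesting consistency
#' (a label at any level always maps to the same label at every coarser
#' level), and the convention that `"undetermined"` maps to `"undetermined"`
#' at every level (the row is added if absent).
#'
#' @param df data frame with columns `detailed`, `harmonized35`, `who15`,
#'   `broad6`.
#' @return object of class `va_cause_map` with elements `map` (the validated
#'   data frame) and `levels` (named list of level label sets).
#' @export
cause_map <- function(df) {
  req <- c("detailed", "harmonized35", "who15", "broad6")
  if (!is.data.frame(df) || !all(req %in% names(df))) {
    stop("cause map needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  df <- df[req]
  for (col in req) df[[col]] <- as.character(df[[col]])
  dup_rows <- duplicated(df)
  if (any(dup_rows)) {
    stop("cause map has duplicated rows: ",
         paste(df$detailed[dup_rows], collapse = ", "), call. = FALSE)
  }
  dup_src <- unique(df$detailed[duplicated(df$detailed)])
  if (length(dup_src)) {
    stop("detailed cause(s) mapped more than once: ",
         paste(dup_src, collapse = ", "), call. = FALSE)
  }
  if (!"undetermined" %in% df$detailed) {
    df <- rbind(df, data.frame(detailed = "undetermined",
                               harmonized35 = "undetermined",
                               who15 = "undetermined",
                               broad6 = "undetermined"))
  }
  u <- df[df$detailed == "undetermined", ]
  if (!all(u == "undetermined")) {
    stop("'undetermined' must map to 'undetermined' at every level",
         call. = FALSE)
  }
  # nesting consistency: each finer label determines a unique coarser label
  for (i in 1:3) {
    fine <- req[i + 1]; prev <- req[i]
    for (coarse in req[seq(i + 1, 4)][-1]) {
      tab <- unique(df[c(fine, coarse)])
      bad <- unique(tab[[fine]][duplicated(tab[[fine]])])
      if (length(bad)) {
        stop("inconsistent nesting: ", fine, " label(s) ",
             paste(bad, collapse = ", "), " map to multiple ", coarse,
             " targets", call. = FALSE)
      }
    }
  }
  structure(list(
    map = df,
    levels = lapply(stats::setNames(req, req), function(l) unique(df[[l]]))
  ), class = "va_cause_map")
}

#' @export
print.va_cause_map <- function(x, ...) {
  card <- vapply(x$levels, length, integer(1))
  cat("Cause map levels (label counts): ",
      paste(sprintf("%s=%d", names(card), card), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Load a cause map from delimited text
#'
#' @param path CSV with header `detailed,harmonized35,who15,broad6` (UTF-8,
#'   case-sensitive labels).
#' @return a validated `va_cause_map`.
#' @export
load_cause_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cause_map(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' The shipped 35-cause fixture map
#'
#' Thirty-five harmonized causes (34 substantive + undetermined) over 15
#' WHO-level categories (HIV and TB combined into one category) and 6 broad
#' categories. The map is fixture data modelled on the published tables, not
#' a reproduction of any ICD-10 mapping; replace it with your own file via
#' [load_cause_map()].
#'
#' @return a `va_cause_map`.
#' @export
default_cause_map <- function() {
  load_cause_map(system.file("extdata", "cause_map_harmonized35.csv",
                             package = "vaconcord", mustWork = TRUE))
}

# lookup: label at any level -> target label at `level`
map_lookup <- function(map, level) {
  df <- map$map
  pairs <- unique(do.call(rbind, lapply(names(map$levels), function(l) {
    data.frame(from = df[[l]], to = df[[level]], stringsAsFactors = FALSE)
  })))
  stats::setNames(pairs$to, pairs$from)
}

#' Collapse assignments to a coarser cause level
#'
#' Each death's cause is replaced by its target at `level`; the death count
#' is unchanged. When the assignments carry a per-cause probability matrix
#' (attribute `"probs"`), probabilities are summed within target categories
#' and remain normalized.
#'
#' @param assignments data frame from [va_assignments()] (column `top_cause`),
#'   or a bare character vector of labels.
#' @param map a `va_cause_map`.
#' @param level one of `"detailed"`, `"harmonized35"`, `"who15"`, `"broad6"`.
#' @return same shape as the input, with causes at the requested level.
#' @export
collapse_assignments <- function(assignments, map, level) {
  level <- match.arg(level, names(map$levels))
  lk <- map_lookup(map, level)
  relabel <- function(x) {
    hit <- lk[x]
    if (anyNA(hit)) {
      stop("cause(s) not in map: ",
           paste(unique(x[is.na(hit)]), collapse = ", "), call. = FALSE)
    }
    unname(hit)
  }
  if (is.character(assignments)) return(relabel(assignments))
  out <- assignments
  out$top_cause <- relabel(assignments$top_cause)
  probs <- attr(assignments, "probs")
  if (!is.null(probs)) {
    tgt <- relabel(colnames(probs))
    groups <- unique(tgt)
    collapsed <- vapply(groups, function(g) {
      rowSums(probs[, tgt == g, drop = FALSE])
    }, numeric(nrow(probs)))
    if (nrow(probs) == 1L) collapsed <- matrix(collapsed, nrow = 1,
                                               dimnames = list(NULL, groups))
    attr(out, "probs") <- collapsed
  }
  out
}

#' Drop physician-undetermined deaths from a paired comparison
#'
#' When the physician review is the reference, deaths it could not determine
#' lack a reference diagnosis and are excluded; algorithm-undetermined deaths
#' are retained and count against agreement.
#'
#' @param physician,algorithm equal-length paired cause labels.
#' @return data frame with columns `reference`, `predicted` (filtered pairs).
#' @export
filter_for_reference_comparison <- function(physician, algorithm) {
  if (length(physician) != length(algorithm)) {
    stop("paired label lists differ in length", call. = FALSE)
  }
  keep <- physician != "undetermined"
  if (!any(keep)) {
    warning("all reference labels undetermined; no pairs retained",
            call. = FALSE)
  }
  data.frame(reference = physician[keep], predicted = algorithm[keep],
             stringsAsFactors = FALSE)
}

#' Cross-tabulate algorithm causes among physician-undetermined deaths
#'
#' @param physician physician labels aligned with the assignments.
#' @param algorithm algorithm cause labels (or a [va_assignments()] data
#'   frame) aligned with `physician`.
#' @param map optional `va_cause_map`; with `level`, algorithm causes are
#'   collapsed before tabulation.
#' @param level target level when `map` is given.
#' @return data frame `cause, n, pct` over physician-undetermined deaths
#'   (empty when there are none); percentages sum to 100 within rounding.
#' @export
crosstab_undetermined <- function(physician, algorithm, map = NULL,
                                  level = "who15") {
  if (is.data.frame(algorithm)) algorithm <- algorithm$top_cause
  if (length(physician) != length(algorithm)) {
    stop("inputs not aligned", call. = FALSE)
  }
  sub <- algorithm[physician == "undetermined"]
  if (!is.null(map)) sub <- collapse_assignments(sub, map, level)
  if (!length(sub)) {
    return(data.frame(cause = character(), n = integer(), pct = numeric()))
  }
  tab <- sort(table(sub), decreasing = TRUE)
  data.frame(cause = names(tab), n = as.integer(tab),
             pct = 100 * as.integer(tab) / length(sub),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag maternal cause assignments on male records
#'
#' Maternal causes are only plausible for female deaths; this validation pass
#' flags (but does not delete) maternal assignments on male records.
#'
#' @param assignments [va_assignments()] data frame.
#' @param sex per-death sex labels aligned with the assignments.
#' @param map a `va_cause_map`.
#' @return logical vector, `TRUE` where a male death carries a maternal cause.
#' @export
flag_maternal_males <- function(assignments, sex, map) {
  broad <- collapse_assignments(assignments$top_cause, map, "broad6")
  flag <- broad == "Maternal" & sex == "male"
  if (any(flag)) {
    warning(sum(flag), " male death(s) assigned a maternal cause",
            call. = FALSE)
  }
  flag
}
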