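#' Simulation configuration for synthetic VA cohorts
#'
#' Bundles everything the cohort generator needs: the stratum layout
#' (site x sex x age group cells), per-stratum true cause-specific mortality
#' fractions (CSMFs), the informativeness of the symptom-cause-information
#' (SCI) matrix, the physician-review channel parameters, and the symptom
#' missingness rate.
#'
#' The physician channel is a noisy oracle: a review is "undetermined" with
#' probability `physician_undetermined_rate`; otherwise it returns the true
#' cause with probability `physician_accuracy`, and with the remaining
#' probability a draw from the confusion row of the true cause (diagonal
#' zeroed and the row renormalized).
#'
#' @param n_causes number of substantive causes (>= 2).
#' @param n_symptoms number of binary symptom items (>= 1).
#' @param strata data frame with columns `site`, `sex`, `age_group`, one row
#'   per stratum cell.
#' @param csmf_true matrix of true CSMFs, one row per stratum, one column per
#'   cause (each row sums to 1); a single vector is recycled across strata.
#' @param n_deaths deaths per stratum: a vector of length `nrow(strata)` or a
#'   scalar recycled.
#' @param sci_concentration positive Beta concentration controlling SCI
#'   informativeness (small = informative near-0/1 profiles, large = near-0.5
#'   uninformative; `Inf` = exactly 0.5 everywhere).
#' @param physician_accuracy probability the physician review returns the true
#'   cause, given it is not undetermined.
#' @param physician_undetermined_rate probability a review is undetermined.
#' @param physician_confusion row-stochastic cause x cause matrix used when
#'   the physician errs; default uniform over wrong causes.
#' @param missingness_rate per-symptom independent missingness probability.
#' @param cause_labels optional character labels for the causes.
#' @param years calendar years the interview year is drawn from.
#' @param seed integer seed stored with the config.
#' @return an object of class `va_sim_config`.
#' @seealso [default_sim_config()] for the study-mirroring default scenario.
#' @export
sim_config <- function(n_causes, n_symptoms, strata, csmf_true, n_deaths,
                       sci_concentration = 0.5,
                       physician_accuracy = 0.8,
                       physician_undetermined_rate = 0.27,
                       physician_confusion = NULL,
                       missingness_rate = 0.05,
                       cause_labels = NULL,
                       years = 2013:2021,
                       seed = 1L) {
  stopifnot(is.numeric(n_causes), length(n_causes) == 1L, n_causes >= 2,
            is.numeric(n_symptoms), length(n_symptoms) == 1L, n_symptoms >= 1)
  n_causes <- as.integer(n_causes)
  n_symptoms <- as.integer(n_symptoms)
  if (!is.data.frame(strata) ||
      !all(c("site", "sex", "age_group") %in% names(strata))) {
    stop("`strata` must be a data frame with columns site, sex, age_group",
         call. = FALSE)
  }
  n_strata <- nrow(strata)
  if (is.null(cause_labels)) {
    cause_labels <- sprintf("cause_%02d", seq_len(n_causes))
  }
  if (length(cause_labels) != n_causes || anyDuplicated(cause_labels)) {
    stop("`cause_labels` must be ", n_causes, " unique labels", call. = FALSE)
  }
  if ("undetermined" %in% cause_labels) {
    stop("'undetermined' is reserved for unassigned deaths and cannot be a ",
         "substantive cause label", call. = FALSE)
  }

  if (is.vector(csmf_true) && !is.list(csmf_true)) {
    csmf_true <- matrix(csmf_true, nrow = n_strata, ncol = n_causes,
                        byrow = TRUE)
  }
  csmf_true <- as.matrix(csmf_true)
  if (!all(dim(csmf_true) == c(n_strata, n_causes))) {
    stop("`csmf_true` must be ", n_strata, " strata x ", n_causes,
         " causes", call. = FALSE)
  }
  if (any(csmf_true < 0)) stop("`csmf_true` has negative entries", call. = FALSE)
  if (any(abs(rowSums(csmf_true) - 1) > 1e-9)) {
    stop("every `csmf_true` row must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  colnames(csmf_true) <- cause_labels

  n_deaths <- as.integer(rep_len(n_deaths, n_strata))
  if (any(n_deaths < 1)) stop("`n_deaths` must be positive", call. = FALSE)

  for (nm in c("physician_accuracy", "physician_undetermined_rate",
               "missingness_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop("`", nm, "` must be a probability in [0, 1]", call. = FALSE)
    }
  }
  if (!is.numeric(sci_concentration) || sci_concentration <= 0) {
    stop("`sci_concentration` must be positive", call. = FALSE)
  }

  if (is.null(physician_confusion)) {
    physician_confusion <- matrix(1 / n_causes, n_causes, n_causes,
                                  dimnames = list(cause_labels, cause_labels))
  }
  physician_confusion <- as.matrix(physician_confusion)
  if (!all(dim(physician_confusion) == n_causes)) {
    stop("`physician_confusion` must be ", n_causes, " x ", n_causes,
         call. = FALSE)
  }
  if (any(physician_confusion < 0) ||
      any(abs(rowSums(physician_confusion) - 1) > 1e-9)) {
    stop("`physician_confusion` rows must be probability vectors summing to 1",
         call. = FALSE)
  }

  structure(list(
    n_causes = n_causes, n_symptoms = n_symptoms,
    strata = strata, csmf_true = csmf_true, n_deaths = n_deaths,
    sci_concentration = sci_concentration,
    physician_accuracy = physician_accuracy,
    physician_undetermined_rate = physician_undetermined_rate,
    physician_confusion = physician_confusion,
    missingness_rate = missingness_rate,
    cause_labels = cause_labels, years = years,
    seed = as.integer(seed)
  ), class = "va_sim_config")
}

#' @export
print.va_sim_config <- function(x, ...) {
  cat("VA simulation configuration\n")
  cat(sprintf("  %d causes, %d symptoms, %d strata, %d deaths total\n",
              x$n_causes, x$n_symptoms, nrow(x$strata), sum(x$n_deaths)))
  cat(sprintf("  SCI concentration %.3g; missingness %.3g\n",
              x$sci_concentration, x$missingness_rate))
  cat(sprintf("  physician channel: accuracy %.3g, undetermined rate %.3g\n",
              x$physician_accuracy, x$physician_undetermined_rate))
  invisible(x)
}

#' Study-mirroring default simulation scenario
#'
#' Builds a two-site scenario shaped like the motivating HDSS study: sites
#' `A` (physician reviews available) and `B`, sexes male/female, age groups
#' 15-29 / 30-49 / 50+, with per-stratum sample sizes matching the published
#' deaths-with-VA counts and per-stratum true CSMFs obtained by spreading the
#' published broad-category fractions uniformly over the member causes of the
#' shipped harmonized cause list (maternal causes only for females).
#'
#' @param cause_map a `va_cause_map`; default the shipped 35-cause fixture.
#' @param n_deaths optional override for per-stratum sizes (scalar or vector
#'   of length 12, ordered as the returned `strata`).
#' @param ... further arguments passed to [sim_config()].
#' @return a `va_sim_config`.
#' @export
default_sim_config <- function(cause_map = default_cause_map(),
                               n_deaths = NULL, ...) {
  causes <- setdiff(cause_map$map$harmonized35, "undetermined")
  strata <- expand.grid(
    age_group = c("15-29", "30-49", "50+"),
    sex = c("male", "female"),
    site = c("A", "B"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("site", "sex", "age_group")]
  # deaths with a VA by site/sex/age in the motivating study
  sizes <- c(67, 176, 308, 59, 109, 318, 27, 45, 213, 19, 37, 186)
  if (is.null(n_deaths)) n_deaths <- sizes
  csmf <- t(vapply(seq_len(nrow(strata)),
                   function(i) default_csmf(cause_map,
                                            sex = strata$sex[i],
                                            site = strata$site[i]),
                   numeric(length(causes))))
  sim_config(n_causes = length(causes), n_symptoms = 50,
             strata = strata, csmf_true = csmf, n_deaths = n_deaths,
             cause_labels = causes, ...)
}

#' Default true CSMF over the harmonized cause list
#'
#' Spreads broad-category mortality fractions (taken from the published
#' sex-specific tables: site `A` uses the physician-review columns, site `B`
#' the second site's algorithm columns, renormalized over substantive causes)
#' uniformly across the member causes of each broad category. Maternal causes
#' receive zero mass for males.
#'
#' @param cause_map a `va_cause_map`.
#' @param sex `"male"` or `"female"`.
#' @param site `"A"` or `"B"`.
#' @return named probability vector over the substantive harmonized causes.
#' @export
default_csmf <- function(cause_map, sex = c("male", "female"),
                         site = c("A", "B")) {
  sex <- match.arg(sex)
  site <- match.arg(site)
  broad_frac <- switch(paste(site, sex),
    "A male"   = c("Other communicable" = 0.1485, "HIV/TB-related" = 0.1963,
                   "Non-communicable" = 0.4695, "Maternal" = 0,
                   "External" = 0.1857),
    "A female" = c("Other communicable" = 0.1754, "HIV/TB-related" = 0.1754,
                   "Non-communicable" = 0.5138, "Maternal" = 0.0708,
                   "External" = 0.0646),
    "B male"   = c("Other communicable" = 0.1263, "HIV/TB-related" = 0.1895,
                   "Non-communicable" = 0.4982, "Maternal" = 0,
                   "External" = 0.1474),
    "B female" = c("Other communicable" = 0.0992, "HIV/TB-related" = 0.1983,
                   "Non-communicable" = 0.5579, "Maternal" = 0.0496,
                   "External" = 0.0372)
  )
  broad_frac <- broad_frac / sum(broad_frac)
  map <- cause_map$map
  map <- map[map$harmonized35 != "undetermined", ]
  out <- numeric(nrow(map))
  names(out) <- map$harmonized35
  for (b in names(broad_frac)) {
    members <- map$harmonized35[map$broad6 == b]
    if (length(members)) out[members] <- broad_frac[[b]] / length(members)
  }
  out / sum(out)
}
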