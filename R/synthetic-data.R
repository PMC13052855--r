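#' Generate a synthetic symptom-cause-information (SCI) matrix
#'
#' The SCI matrix holds P(symptom = yes | cause), the likelihood core of
#' Bayes-type VA classifiers. Entries are drawn independently from a
#' symmetric Beta(`concentration`, `concentration`): small concentrations give
#' near-0/1 entries (informative, distinct cause profiles), large ones push
#' everything toward 0.5 (uninformative). `concentration = Inf` is the exact
#' uninformative limit (all entries 0.5). Entries are clamped to
#' `[1e-6, 1 - 1e-6]` so no cause can ever be analytically excluded.
#'
#' @param n_symptoms,n_causes matrix dimensions (`n_symptoms >= 1`,
#'   `n_causes >= 2`).
#' @param concentration positive Beta concentration (may be `Inf`).
#' @param seed integer seed; identical arguments and seed give a bitwise
#'   identical matrix.
#' @param symptom_labels,cause_labels optional dimnames.
#' @return numeric matrix (symptoms x causes) of class `va_sci`, with the
#'   sampling scheme recorded in attributes.
#' @export
generate_sci_matrix <- function(n_symptoms, n_causes, concentration,
                                seed = 1L,
                                symptom_labels = NULL, cause_labels = NULL) {
  if (!is.numeric(n_symptoms) || n_symptoms < 1 ||
      !is.numeric(n_causes) || n_causes < 2) {
    stop("need n_symptoms >= 1 and n_causes >= 2", call. = FALSE)
  }
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      is.na(concentration) || concentration <= 0) {
    stop("`concentration` must be a positive real", call. = FALSE)
  }
  n_symptoms <- as.integer(n_symptoms)
  n_causes <- as.integer(n_causes)
  if (is.null(symptom_labels)) {
    symptom_labels <- sprintf("s_%04d", seq_len(n_symptoms))
  }
  if (is.null(cause_labels)) {
    cause_labels <- sprintf("cause_%02d", seq_len(n_causes))
  }
  if (is.infinite(concentration)) {
    m <- matrix(0.5, n_symptoms, n_causes)
  } else {
    set.seed(as.integer(seed))
    m <- matrix(stats::rbeta(n_symptoms * n_causes, concentration,
                             concentration),
                n_symptoms, n_causes)
  }
  m <- clamp_sci(m)
  dimnames(m) <- list(symptom_labels, cause_labels)
  structure(m, class = c("va_sci", "matrix", "array"),
            scheme = sprintf("iid Beta(%g, %g), clamped to [1e-6, 1-1e-6]",
                             concentration, concentration),
            concentration = concentration, seed = as.integer(seed))
}

# keep conditional probabilities strictly inside (0, 1)
clamp_sci <- function(m, eps = 1e-6) {
  m[m < eps] <- eps
  m[m > 1 - eps] <- 1 - eps
  m
}

#' Coerce a plain probability matrix to a validated SCI matrix
#'
#' @param m numeric symptoms x causes matrix of P(symptom = yes | cause);
#'   values at 0 or 1 are clamped to `[1e-6, 1 - 1e-6]`.
#' @return a `va_sci` matrix.
#' @export
as_sci <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || any(is.na(m)) || any(m < 0) || any(m > 1)) {
    stop("SCI entries must be probabilities in [0, 1]", call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- sprintf("s_%04d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("cause_%02d", seq_len(ncol(m)))
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("SCI symptom and cause labels must be unique", call. = FALSE)
  }
  structure(clamp_sci(m), class = c("va_sci", "matrix", "array"),
            scheme = "user supplied, clamped to [1e-6, 1-1e-6]")
}

#' Generate a synthetic VA cohort
#'
#' Generative model, per stratum: true cause ~ categorical(csmf_true row);
#' symptom v | cause j ~ Bernoulli(SCI\[v, j\]); each symptom is then
#' independently set missing with probability `missingness_rate`. One shared
#' SCI matrix is used across strata; only the CSMFs differ.
#'
#' @param config a [sim_config()].
#' @param sci a `va_sci` matrix whose dimensions and cause labels match the
#'   config.
#' @param seed integer seed; defaults to `config$seed`. Fixed seed reproduces
#'   the cohort exactly.
#' @return object of class `va_cohort`: `$records` (data frame with `id`,
#'   `site`, `sex`, `age_group`, `year`, `true_cause`), `$symptoms` (integer
#'   matrix, 1 = yes, 0 = no, `NA` = missing), `$cause_labels`, `$config`.
#' @export
generate_cohort <- function(config, sci, seed = config$seed) {
  stopifnot(inherits(config, "va_sim_config"))
  if (nrow(sci) != config$n_symptoms || ncol(sci) != config$n_causes) {
    stop("SCI dimensions (", nrow(sci), " x ", ncol(sci),
         ") do not match config (", config$n_symptoms, " x ",
         config$n_causes, ")", call. = FALSE)
  }
  if (!identical(colnames(sci), config$cause_labels)) {
    stop("SCI cause labels do not match config cause labels", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n_total <- sum(config$n_deaths)
  V <- config$n_symptoms
  records <- vector("list", nrow(config$strata))
  symptoms <- matrix(NA_integer_, n_total, V,
                     dimnames = list(NULL, rownames(sci)))
  true_cause <- character(n_total)
  row0 <- 0L
  for (s in seq_len(nrow(config$strata))) {
    n <- config$n_deaths[s]
    idx <- row0 + seq_len(n)
    cause_idx <- sample.int(config$n_causes, n, replace = TRUE,
                            prob = config$csmf_true[s, ])
    true_cause[idx] <- config$cause_labels[cause_idx]
    # Bernoulli symptoms: n x V draws against SCI columns of the drawn causes
    p <- t(sci[, cause_idx, drop = FALSE])        # n x V
    y <- matrix(as.integer(stats::runif(n * V) < p), n, V)
    if (config$missingness_rate > 0) {
      y[stats::runif(n * V) < config$missingness_rate] <- NA_integer_
    }
    symptoms[idx, ] <- y
    records[[s]] <- data.frame(
      site = config$strata$site[s], sex = config$strata$sex[s],
      age_group = config$strata$age_group[s],
      year = sample(config$years, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    row0 <- row0 + n
  }
  rec <- do.call(rbind, records)
  rec <- cbind(id = sprintf("d%05d", seq_len(n_total)), rec,
               true_cause = true_cause)
  structure(list(records = rec, symptoms = symptoms,
                 cause_labels = config$cause_labels, config = config,
                 seed = as.integer(seed)),
            class = "va_cohort")
}

#' @export
print.va_cohort <- function(x, ...) {
  cat(sprintf("VA cohort: %d deaths, %d symptoms, %d causes, %d strata\n",
              nrow(x$records), ncol(x$symptoms), length(x$cause_labels),
              nrow(unique(x$records[c("site", "sex", "age_group")]))))
  invisible(x)
}

#' Simulate physician review of a VA cohort
#'
#' A noisy-oracle model of the physician committee: each death is
#' independently "undetermined" with probability `u`; otherwise the true cause
#' with probability `theta`; otherwise a draw from the confusion row of the
#' true cause with the diagonal zeroed and the row renormalized (so an error
#' is always a *wrong* cause).
#'
#' @param cohort a `va_cohort`.
#' @param theta probability of a correct review given determined.
#' @param u probability of an undetermined review.
#' @param confusion cause x cause row-stochastic matrix; default from the
#'   cohort's config (uniform over wrong causes if unset there).
#' @param seed integer seed.
#' @return character vector of physician cause labels (may be
#'   `"undetermined"`), aligned with `cohort$records`.
#' @export
simulate_physician_review <- function(cohort,
                                      theta = cohort$config$physician_accuracy,
                                      u = cohort$config$physician_undetermined_rate,
                                      confusion = cohort$config$physician_confusion,
                                      seed = cohort$seed + 1L) {
  stopifnot(inherits(cohort, "va_cohort"))
  n <- nrow(cohort$records)
  if (n == 0L) stop("cohort is empty", call. = FALSE)
  if (theta < 0 || theta > 1 || u < 0 || u > 1) {
    stop("theta and u must be probabilities", call. = FALSE)
  }
  labels <- cohort$cause_labels
  K <- length(labels)
  confusion <- as.matrix(confusion)
  stopifnot(all(dim(confusion) == K))
  # zero the diagonal and renormalize: an error never returns the true cause
  err <- confusion
  diag(err) <- 0
  rs <- rowSums(err)
  set.seed(as.integer(seed))
  out <- character(n)
  true_idx <- match(cohort$records$true_cause, labels)
  r1 <- stats::runif(n)
  r2 <- stats::runif(n)
  undet <- r1 < u
  correct <- !undet & r2 < theta
  wrong <- !undet & !correct
  out[undet] <- "undetermined"
  out[correct] <- labels[true_idx[correct]]
  if (any(wrong)) {
    if (any(rs[true_idx[wrong]] <= 0)) {
      stop("confusion row has no off-diagonal mass but an error draw is needed",
           call. = FALSE)
    }
    out[wrong] <- vapply(true_idx[wrong], function(j) {
      sample(labels, 1L, prob = err[j, ] / rs[j])
    }, character(1))
  }
  out
}

#' Write / read a cohort as delimited text
#'
#' Columns: `id,site,sex,age_group,year,true_cause,phys_cause,s_0001..s_V`
#' with symptom states encoded `y` / `n` / `.` (dot = missing). `phys_cause`
#' is written as empty when no physician labels are supplied.
#'
#' @param cohort a `va_cohort`.
#' @param path output file path.
#' @param phys_cause optional physician labels aligned with the records.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, phys_cause = NULL) {
  sym <- cohort$symptoms
  enc <- matrix(".", nrow(sym), ncol(sym), dimnames = dimnames(sym))
  enc[!is.na(sym) & sym == 1L] <- "y"
  enc[!is.na(sym) & sym == 0L] <- "n"
  df <- cbind(cohort$records,
              phys_cause = if (is.null(phys_cause)) "" else phys_cause,
              as.data.frame(enc, stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @param cause_labels cause labels to attach to the read cohort (needed
#'   because the delimited form stores only per-death labels).
#' @export
read_cohort <- function(path, cause_labels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  sym_cols <- grep("^s_", names(df), value = TRUE)
  rec <- df[setdiff(names(df), c(sym_cols, "phys_cause"))]
  rec$year <- as.integer(rec$year)
  enc <- as.matrix(df[sym_cols])
  bad <- setdiff(unique(as.vector(enc)), c("y", "n", "."))
  if (length(bad)) {
    stop("unknown symptom codes: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sym <- matrix(NA_integer_, nrow(enc), ncol(enc),
                dimnames = list(NULL, sym_cols))
  sym[enc == "y"] <- 1L
  sym[enc == "n"] <- 0L
  if (is.null(cause_labels)) cause_labels <- sort(unique(rec$true_cause))
  phys <- df$phys_cause
  structure(list(records = rec, symptoms = sym, cause_labels = cause_labels,
                 config = NULL, seed = NA_integer_,
                 phys_cause = if (all(phys == "")) NULL else phys),
            class = "va_cohort")
}

#' Write / read an SCI matrix as delimited text
#'
#' First column is the symptom id, remaining columns one per cause label.
#'
#' @param sci a `va_sci` matrix.
#' @param path file path.
#' @return `path` (write) or a `va_sci` matrix (read).
#' @export
write_sci <- function(sci, path) {
  df <- data.frame(symptom = rownames(sci), unclass(sci),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_sci
#' @export
read_sci <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  as_sci(m)
}
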