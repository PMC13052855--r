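#' Run configuration for the two study designs
#'
#' Collects everything a full run needs: the simulation scenario (or a
#' pre-built cohort), the engines and their settings, the top-cause
#' threshold, the cause map, bootstrap settings, and the global seed. All
#' stage seeds are derived from `seed` by small fixed offsets, so the
#' configuration alone reproduces every table.
#'
#' @param sim a [sim_config()]; default [default_sim_config()].
#' @param engines character vector of engines to run: `"interva_like"`
#'   (naive Bayes), `"insilico_like"` (Gibbs CSMF sampler), `"truth"`
#'   (positive-control engine assigning the true cause).
#' @param threshold top-cause cutoff in (0, 1\], or `NA` for the
#'   no-threshold variant.
#' @param no_threshold_rerun also report metrics with the threshold removed
#'   (sensitivity analysis).
#' @param nb_mode likelihood mode for the naive-Bayes engine.
#' @param gibbs list of sampler settings (`n_iter`, `burn_in`, `thin`).
#' @param cause_map a `va_cause_map`; default the shipped fixture.
#' @param physician_site site label whose deaths carry physician reviews.
#' @param bootstrap_B bootstrap replicates for metric CIs (0 disables CIs).
#' @param conf confidence level for CSMF and bootstrap intervals.
#' @param seed global integer seed.
#' @return object of class `va_run_config`.
#' @export
run_config <- function(sim = default_sim_config(),
                       engines = c("interva_like", "insilico_like"),
                       threshold = 0.4,
                       no_threshold_rerun = FALSE,
                       nb_mode = "affirmative_only",
                       gibbs = list(n_iter = 4000, burn_in = 1000, thin = 1),
                       cause_map = default_cause_map(),
                       physician_site = "A",
                       bootstrap_B = 1000,
                       conf = 0.95,
                       seed = 1L) {
  stopifnot(inherits(sim, "va_sim_config"), inherits(cause_map, "va_cause_map"))
  known <- c("interva_like", "insilico_like", "truth")
  if (!length(engines) || !all(engines %in% known)) {
    stop("engines must be drawn from: ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  if (!is.na(threshold) && (threshold <= 0 || threshold > 1)) {
    stop("`threshold` must be in (0, 1] or NA", call. = FALSE)
  }
  gibbs <- utils::modifyList(list(n_iter = 4000, burn_in = 1000, thin = 1),
                             gibbs)
  structure(list(sim = sim, engines = engines, threshold = threshold,
                 no_threshold_rerun = no_threshold_rerun,
                 nb_mode = nb_mode, gibbs = gibbs, cause_map = cause_map,
                 physician_site = physician_site,
                 bootstrap_B = as.integer(bootstrap_B), conf = conf,
                 seed = as.integer(seed)),
            class = "va_run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The file mirrors [run_config()]'s arguments; the `sim` entry holds
#' [sim_config()] arguments (with `strata` as a list of site/sex/age_group
#' records and `csmf_true` as a list of per-stratum vectors), or the string
#' `"default"` for the study-mirroring scenario. A `cause_map` entry is a
#' path to a map file.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `va_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cm <- if (!is.null(raw$cause_map)) load_cause_map(raw$cause_map)
        else default_cause_map()
  sim <- raw$sim
  if (is.null(sim) || identical(sim, "default")) {
    sim <- default_sim_config(cause_map = cm)
  } else {
    if (!is.null(sim$strata) && !is.data.frame(sim$strata)) {
      sim$strata <- do.call(rbind, lapply(sim$strata, function(r) {
        as.data.frame(r, stringsAsFactors = FALSE)
      }))
    }
    if (is.list(sim$csmf_true)) {
      sim$csmf_true <- do.call(rbind, lapply(sim$csmf_true, unlist))
    }
    sim <- do.call(sim_config, sim)
  }
  args <- raw[setdiff(names(raw), c("sim", "cause_map"))]
  args$sim <- sim
  args$cause_map <- cm
  do.call(run_config, args)
}

# ---- internal machinery ----------------------------------------------------

subset_cohort <- function(cohort, idx) {
  out <- cohort
  out$records <- cohort$records[idx, , drop = FALSE]
  out$symptoms <- cohort$symptoms[idx, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

run_engine <- function(name, cohort, sci, config, seed) {
  switch(name,
    interva_like = va_assignments(
      va_nb(cohort, sci, mode = config$nb_mode,
            threshold = config$threshold)),
    insilico_like = va_assignments(
      va_gibbs(cohort, sci, n_iter = config$gibbs$n_iter,
               burn_in = config$gibbs$burn_in, thin = config$gibbs$thin,
               seed = seed, threshold = config$threshold)),
    truth = {
      K <- length(cohort$cause_labels)
      probs <- matrix(0, nrow(cohort$records), K,
                      dimnames = list(NULL, cohort$cause_labels))
      probs[cbind(seq_len(nrow(probs)),
                  match(cohort$records$true_cause, cohort$cause_labels))] <- 1
      out <- data.frame(id = cohort$records$id, method = "truth",
                        top_cause = cohort$records$true_cause,
                        top_probability = 1, undetermined = FALSE,
                        stringsAsFactors = FALSE)
      attr(out, "probs") <- probs
      attr(out, "threshold") <- config$threshold
      out
    },
    stop("unknown engine: ", name, call. = FALSE)
  )
}

# metric strata used in the physician-reference analysis
analysis1_strata <- function(records) {
  list(overall = rep(TRUE, nrow(records)),
       male = records$sex == "male",
       female = records$sex == "female",
       "15-49" = records$age_group %in% c("15-29", "30-49"),
       "50+" = records$age_group == "50+")
}

# agreement / accuracy / spearman / sensitivity (with bootstrap) for one
# reference-vs-predicted label pairing at the configured levels
comparison_metrics <- function(reference, predicted, ref_method, pred_method,
                               stratum, map, config, boot_seed,
                               sensitivity = TRUE) {
  lab35 <- collapse_assignments(reference, map, "harmonized35")
  prd35 <- collapse_assignments(predicted, map, "harmonized35")
  lab15 <- collapse_assignments(reference, map, "who15")
  prd15 <- collapse_assignments(predicted, map, "who15")
  lab6 <- collapse_assignments(reference, map, "broad6")
  prd6 <- collapse_assignments(predicted, map, "broad6")
  B <- config$bootstrap_B
  seed <- boot_seed
  boot <- function(stat, d) {
    if (B < 1) return(NULL)
    bootstrap_ci(stat, d, B = B, level = config$conf, seed = seed)
  }
  csmf_vec <- function(x, labels) {
    as.vector(table(factor(x, levels = labels))) / length(x)
  }
  b6 <- map$levels$broad6
  d35 <- data.frame(reference = lab35, predicted = prd35,
                    stringsAsFactors = FALSE)
  d15 <- data.frame(reference = lab15, predicted = prd15,
                    stringsAsFactors = FALSE)
  d6 <- data.frame(reference = lab6, predicted = prd6,
                   stringsAsFactors = FALSE)
  agree_stat <- function(d) percent_agreement(d$reference, d$predicted)
  acc_stat <- function(d) csmf_accuracy(csmf_vec(d$reference, b6),
                                        csmf_vec(d$predicted, b6))
  rho_stat <- function(d) spearman_rho(csmf_vec(d$reference, b6),
                                       csmf_vec(d$predicted, b6))
  rows <- list(
    metric_result("percent_agreement", ref_method, pred_method, stratum,
                  "harmonized35", agree_stat(d35), boot(agree_stat, d35),
                  B, seed),
    metric_result("percent_agreement", ref_method, pred_method, stratum,
                  "who15", agree_stat(d15), boot(agree_stat, d15), B, seed),
    metric_result("csmf_accuracy", ref_method, pred_method, stratum,
                  "broad6", acc_stat(d6), boot(acc_stat, d6), B, seed),
    metric_result("spearman_rho", ref_method, pred_method, stratum,
                  "broad6", rho_stat(d6), boot(rho_stat, d6), B, seed)
  )
  out <- do.call(rbind, rows)
  out$cause <- NA_character_
  if (sensitivity) {
    causes <- setdiff(map$levels$who15, "undetermined")
    sens <- sensitivity_by_cause(lab15, prd15, causes)
    sens_rows <- lapply(causes, function(j) {
      ci <- NULL
      if (B >= 1 && !is.na(sens[[j]])) {
        stat_j <- function(d) {
          ref_j <- d$reference == j
          if (!any(ref_j)) return(NA_real_)
          sum(ref_j & d$predicted == j) / sum(ref_j)
        }
        ci <- tryCatch(suppressMessages(boot(stat_j, d15)),
                       error = function(e) NULL)
      }
      r <- metric_result("sensitivity", ref_method, pred_method, stratum,
                         "who15", sens[[j]], ci, B, seed)
      r$cause <- j
      r
    })
    out <- rbind(out, do.call(rbind, sens_rows))
  }
  out
}

# CSMF tables for one method at the three cause levels, stratified by sex
csmf_all_levels <- function(assignments, records, map, conf,
                            by = "sex") {
  merged <- merge(assignments, records[c("id", "site", "sex", "age_group")],
                  by = "id", sort = FALSE)
  do.call(rbind, lapply(c("harmonized35", "who15", "broad6"), function(lvl) {
    coll <- merged
    coll$top_cause <- collapse_assignments(merged$top_cause, map, lvl)
    compute_csmf(coll, causes = map$levels[[lvl]], by = by,
                 level_label = lvl, conf = conf)
  }))
}

run_manifest <- function(config, stage_seeds) {
  cfg <- list(
    engines = config$engines, threshold = config$threshold,
    no_threshold_rerun = config$no_threshold_rerun,
    nb_mode = config$nb_mode, gibbs = config$gibbs,
    physician_site = config$physician_site,
    bootstrap_B = config$bootstrap_B, conf = config$conf,
    seed = config$seed,
    sim = list(n_causes = config$sim$n_causes,
               n_symptoms = config$sim$n_symptoms,
               strata = config$sim$strata,
               csmf_true = unname(apply(config$sim$csmf_true, 1, as.list)),
               n_deaths = config$sim$n_deaths,
               sci_concentration = config$sim$sci_concentration,
               physician_accuracy = config$sim$physician_accuracy,
               physician_undetermined_rate = config$sim$physician_undetermined_rate,
               missingness_rate = config$sim$missingness_rate,
               cause_labels = config$sim$cause_labels,
               seed = config$sim$seed),
    cause_map_levels = lapply(config$cause_map$levels, length)
  )
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  writeLines(json, tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  list(package = "vaconcord",
       version = as.character(utils::packageVersion("vaconcord")),
       config = cfg, config_hash = hash, stage_seeds = stage_seeds)
}

log_stage <- function(stage, n_in, n_out, note = "") {
  message(sprintf("[%s] in=%d out=%d%s", stage, n_in, n_out,
                  if (nzchar(note)) paste0(" (", note, ")") else ""))
}

# ---- the two study designs -------------------------------------------------

#' Analysis 1: algorithms versus the physician reference
#'
#' Simulates the scenario, restricts to the physician-review site, runs the
#' configured engines, excludes physician-undetermined deaths from the paired
#' comparison, and produces: CSMF tables at the three cause levels for every
#' method (physician included), agreement / CSMF accuracy / Spearman /
#' per-cause sensitivity with bootstrap CIs by stratum, the cross-tab of
#' algorithm causes among physician-undetermined deaths, and (when
#' configured) the same metrics with the top-cause threshold removed.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, all tables are written as
#'   delimited text plus a JSON manifest.
#' @return a list of class `va_report1`: `csmf_tables`, `metrics`,
#'   `crosstab_undetermined`, `no_threshold_metrics` (or NULL), `cohort`,
#'   `physician`, `assignments`, `manifest`.
#' @export
run_analysis1 <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "va_run_config"))
  seeds <- list(sci = config$seed, cohort = config$seed + 1L,
                physician = config$seed + 2L, gibbs = config$seed + 3L,
                bootstrap = config$seed + 4L)
  sim <- config$sim
  map <- config$cause_map
  sci <- generate_sci_matrix(sim$n_symptoms, sim$n_causes,
                             sim$sci_concentration, seed = seeds$sci,
                             cause_labels = sim$cause_labels)
  cohort <- generate_cohort(sim, sci, seed = seeds$cohort)
  phys <- simulate_physician_review(cohort, seed = seeds$physician)
  log_stage("simulate", sum(sim$n_deaths), nrow(cohort$records))

  at_site <- cohort$records$site == config$physician_site
  if (!any(at_site)) stop("no deaths at the physician site", call. = FALSE)
  site_cohort <- subset_cohort(cohort, at_site)
  site_phys <- phys[at_site]
  log_stage("physician-site filter", nrow(cohort$records),
            nrow(site_cohort$records))

  assignments <- lapply(config$engines, function(e) {
    run_engine(e, site_cohort, sci, config, seed = seeds$gibbs)
  })
  names(assignments) <- config$engines

  phys_assign <- va_assignments(site_phys, ids = site_cohort$records$id)
  all_assign <- c(list(physician = phys_assign), assignments)
  csmf_tables <- do.call(rbind, lapply(all_assign, function(a) {
    csmf_all_levels(a, site_cohort$records, map, config$conf)
  }))
  rownames(csmf_tables) <- NULL

  strata <- analysis1_strata(site_cohort$records)
  metric_rows <- list()
  crosstabs <- list()
  nothr_rows <- list()
  for (e in config$engines) {
    alg <- assignments[[e]]$top_cause
    for (s in names(strata)) {
      keep <- strata[[s]]
      pairs <- filter_for_reference_comparison(site_phys[keep], alg[keep])
      log_stage(paste("exclude physician-undetermined", e, s),
                sum(keep), nrow(pairs))
      metric_rows[[paste(e, s)]] <- comparison_metrics(
        pairs$reference, pairs$predicted, "physician", e, s, map, config,
        boot_seed = seeds$bootstrap)
    }
    crosstabs[[e]] <- crosstab_undetermined(site_phys, assignments[[e]],
                                            map, "who15")
    if (config$no_threshold_rerun) {
      probs <- attr(assignments[[e]], "probs")
      retop <- assign_top_cause(probs, threshold = NA)
      pairs <- filter_for_reference_comparison(site_phys, retop$top_cause)
      nothr_rows[[e]] <- comparison_metrics(
        pairs$reference, pairs$predicted, "physician",
        paste0(e, "_no_threshold"), "overall", map, config,
        boot_seed = seeds$bootstrap)
    }
  }
  metrics <- do.call(rbind, metric_rows)
  rownames(metrics) <- NULL
  no_threshold_metrics <- if (config$no_threshold_rerun) {
    m <- do.call(rbind, nothr_rows); rownames(m) <- NULL; m
  }

  report <- structure(list(
    csmf_tables = csmf_tables, metrics = metrics,
    crosstab_undetermined = crosstabs,
    no_threshold_metrics = no_threshold_metrics,
    cohort = site_cohort, physician = site_phys,
    assignments = assignments,
    manifest = run_manifest(config, seeds)
  ), class = "va_report1")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Analysis 2: algorithm versus algorithm across sites
#'
#' Runs at least two engines on every site (no physician filter; all deaths
#' included) and produces per-site CSMF tables per engine and the
#' between-engine percent agreement by age and sex at the individual
#' (harmonized) and broad levels.
#'
#' @inheritParams run_analysis1
#' @return a list of class `va_report2`: `csmf_tables`, `agreement`,
#'   `cohort`, `assignments`, `manifest`.
#' @export
run_analysis2 <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "va_run_config"))
  engines <- setdiff(config$engines, "truth")
  if (length(engines) < 2) {
    stop("analysis 2 needs at least two algorithmic engines", call. = FALSE)
  }
  seeds <- list(sci = config$seed, cohort = config$seed + 1L,
                gibbs = config$seed + 3L, bootstrap = config$seed + 4L)
  sim <- config$sim
  map <- config$cause_map
  sci <- generate_sci_matrix(sim$n_symptoms, sim$n_causes,
                             sim$sci_concentration, seed = seeds$sci,
                             cause_labels = sim$cause_labels)
  cohort <- generate_cohort(sim, sci, seed = seeds$cohort)
  log_stage("simulate", sum(sim$n_deaths), nrow(cohort$records))

  sites <- unique(cohort$records$site)
  csmf_tables <- list()
  agree_rows <- list()
  assignments <- list()
  for (site in sites) {
    sc <- subset_cohort(cohort, cohort$records$site == site)
    a <- lapply(engines, function(e) run_engine(e, sc, sci, config,
                                                seed = seeds$gibbs))
    names(a) <- engines
    assignments[[site]] <- a
    csmf_tables[[site]] <- do.call(rbind, lapply(a, function(x) {
      tab <- csmf_all_levels(x, sc$records, map, config$conf)
      cbind(site = site, tab, stringsAsFactors = FALSE)
    }))
    # pairwise agreement by age x sex, individual (harmonized) + broad level
    pairs <- utils::combn(engines, 2, simplify = FALSE)
    cells <- expand.grid(sex = unique(sc$records$sex),
                         age_group = c("overall",
                                       unique(sc$records$age_group)),
                         stringsAsFactors = FALSE)
    for (pr in pairs) {
      x <- a[[pr[1]]]$top_cause
      y <- a[[pr[2]]]$top_cause
      x6 <- collapse_assignments(x, map, "broad6")
      y6 <- collapse_assignments(y, map, "broad6")
      for (i in seq_len(nrow(cells))) {
        keep <- sc$records$sex == cells$sex[i] &
          (cells$age_group[i] == "overall" |
             sc$records$age_group == cells$age_group[i])
        if (!any(keep)) next
        n_match_ind <- sum(x[keep] == y[keep])
        n_match_broad <- sum(x6[keep] == y6[keep])
        agree_rows[[length(agree_rows) + 1L]] <- data.frame(
          site = site, sex = cells$sex[i], age_group = cells$age_group[i],
          engine_a = pr[1], engine_b = pr[2], N = sum(keep),
          n_agree_individual = n_match_ind,
          agreement_individual_pct = 100 * n_match_ind / sum(keep),
          n_agree_broad = n_match_broad,
          agreement_broad_pct = 100 * n_match_broad / sum(keep),
          stringsAsFactors = FALSE)
      }
    }
  }
  csmf_tables <- do.call(rbind, csmf_tables)
  rownames(csmf_tables) <- NULL
  agreement <- do.call(rbind, agree_rows)
  report <- structure(list(
    csmf_tables = csmf_tables, agreement = agreement,
    cohort = cohort, assignments = assignments,
    manifest = run_manifest(config, seeds)
  ), class = "va_report2")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a report bundle as delimited text plus a JSON manifest
#'
#' @param report a `va_report1` or `va_report2`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                     quote = TRUE)
  }
  wr(report$csmf_tables, "csmf_tables.csv")
  if (inherits(report, "va_report1")) {
    wr(report$metrics, "metrics.csv")
    for (e in names(report$crosstab_undetermined)) {
      wr(report$crosstab_undetermined[[e]],
         sprintf("crosstab_undetermined_%s.csv", e))
    }
    if (!is.null(report$no_threshold_metrics)) {
      wr(report$no_threshold_metrics, "metrics_no_threshold.csv")
    }
  } else {
    wr(report$agreement, "agreement.csv")
  }
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.va_report1 <- function(x, ...) {
  cat("Analysis 1 report: algorithms vs physician reference\n")
  cat(sprintf("  %d deaths at the physician site; %d physician-undetermined\n",
              nrow(x$cohort$records), sum(x$physician == "undetermined")))
  cat(sprintf("  engines: %s\n", paste(names(x$assignments), collapse = ", ")))
  ov <- x$metrics[x$metrics$stratum == "overall" &
                    x$metrics$metric != "sensitivity", ]
  print(ov[c("predicted", "level", "metric", "point", "ci_low", "ci_high")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
print.va_report2 <- function(x, ...) {
  cat("Analysis 2 report: algorithm vs algorithm\n")
  ov <- x$agreement[x$agreement$age_group == "overall", ]
  print(ov[c("site", "sex", "N", "agreement_individual_pct",
             "agreement_broad_pct")], row.names = FALSE, digits = 4)
  invisible(x)
}
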