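#' Naive-Bayes posterior over causes for one VA record
#'
#' Computes `posterior_j` proportional to `prior_j * prod_v f(s_v, SCI[v, j])`
#' over observed symptoms, where `f = SCI[v, j]` for a yes and, in
#' `full_bernoulli` mode, `f = 1 - SCI[v, j]` for a no (`f = 1` for a no in
#' `affirmative_only` mode, which mirrors classifiers that use only
#' affirmative responses). Missing symptoms contribute a factor 1 in both
#' modes. Accumulation is in the log domain so long symptom vectors cannot
#' underflow.
#'
#' @param record symptom vector: integer/logical (1 = yes, 0 = no, `NA` =
#'   missing) or character (`"y"`, `"n"`, `"."`).
#' @param sci SCI matrix (symptoms x causes).
#' @param prior per-cause prior probabilities summing to 1; default uniform.
#' @param mode `"affirmative_only"` (default) or `"full_bernoulli"`.
#' @return named per-cause posterior probability vector summing to 1.
#' @export
naive_bayes_posterior <- function(record, sci,
                                  prior = NULL,
                                  mode = c("affirmative_only",
                                           "full_bernoulli")) {
  mode <- match.arg(mode)
  record <- decode_symptoms(record)
  if (length(record) != nrow(sci)) {
    stop("record has ", length(record), " symptoms but SCI has ", nrow(sci),
         call. = FALSE)
  }
  p <- nb_posterior_matrix(matrix(record, nrow = 1), sci, prior, mode)
  stats::setNames(p[1, ], colnames(sci))
}

decode_symptoms <- function(x) {
  if (is.character(x)) {
    out <- rep(NA_integer_, length(x))
    out[x == "y"] <- 1L
    out[x == "n"] <- 0L
    bad <- !(x %in% c("y", "n", "."))
    if (any(bad)) stop("unknown symptom codes: ",
                       paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    out
  } else {
    as.integer(x)
  }
}

# vectorized log-domain naive Bayes over an n x V symptom matrix
nb_posterior_matrix <- function(symptoms, sci, prior = NULL,
                                mode = "affirmative_only") {
  K <- ncol(sci)
  if (is.null(prior)) prior <- rep(1 / K, K)
  if (length(prior) != K || any(prior < 0) || abs(sum(prior) - 1) > 1e-9) {
    stop("`prior` must be a probability vector over the ", K, " causes",
         call. = FALSE)
  }
  ll <- nb_loglik_matrix(symptoms, sci, mode)
  lp <- sweep(ll, 2, log(prior), "+")
  softmax_rows(lp)
}

# n x K matrix of log P(symptoms | cause)
nb_loglik_matrix <- function(symptoms, sci, mode = "affirmative_only") {
  yes <- symptoms == 1L
  yes[is.na(yes)] <- FALSE
  ll <- (yes + 0) %*% log(unclass(sci))
  if (mode == "full_bernoulli") {
    no <- symptoms == 0L
    no[is.na(no)] <- FALSE
    ll <- ll + (no + 0) %*% log1p(-unclass(sci))
  }
  ll
}

softmax_rows <- function(lp) {
  m <- apply(lp, 1, max)
  w <- exp(lp - m)
  w / rowSums(w)
}

#' Top-cause rule with an undetermined cutoff
#'
#' The cause with the highest posterior probability is assigned; if a
#' threshold is active and the highest probability is strictly below it, the
#' death is labelled `"undetermined"`. Probabilities exactly at the threshold
#' assign (only strictly-less is undetermined). Argmax ties are broken by the
#' first cause in label order and counted in the `n_ties` attribute.
#'
#' @param probs per-cause probability vector, or an n x causes matrix.
#' @param threshold cutoff probability in (0, 1\], or `NULL`/`NA` for the
#'   no-threshold variant (always argmax).
#' @return data frame with `top_cause`, `top_probability`, `undetermined`;
#'   attribute `n_ties` counts tied argmax rows.
#' @export
assign_top_cause <- function(probs, threshold = 0.4) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1,
                                           dimnames = list(NULL, names(probs)))
  if (ncol(probs) == 0L || nrow(probs) == 0L) {
    stop("empty probability input", call. = FALSE)
  }
  labels <- colnames(probs)
  if (is.null(labels)) labels <- sprintf("cause_%02d", seq_len(ncol(probs)))
  top_idx <- apply(probs, 1, which.max)        # which.max: first of ties
  top_p <- probs[cbind(seq_len(nrow(probs)), top_idx)]
  n_ties <- sum(apply(probs, 1, function(r) sum(r == max(r)) > 1L))
  if (n_ties > 0L) {
    message(n_ties, " argmax tie(s) broken by first cause in label order")
  }
  no_thr <- is.null(threshold) || is.na(threshold)
  if (!no_thr && (threshold <= 0 || threshold > 1)) {
    stop("`threshold` must be in (0, 1] or NA for no threshold", call. = FALSE)
  }
  undet <- if (no_thr) rep(FALSE, nrow(probs)) else top_p < threshold
  out <- data.frame(
    top_cause = ifelse(undet, "undetermined", labels[top_idx]),
    top_probability = top_p,
    undetermined = undet,
    stringsAsFactors = FALSE
  )
  attr(out, "n_ties") <- n_ties
  attr(out, "threshold") <- if (no_thr) NA_real_ else threshold
  out
}

#' Fit the deterministic naive-Bayes assignment engine to a cohort
#'
#' An InterVA-style engine: for each death, a naive-Bayes posterior over
#' causes from the SCI matrix and a fixed prior, followed by the top-cause /
#' undetermined rule.
#'
#' @param cohort a `va_cohort`, or a bare symptom matrix.
#' @param sci SCI matrix matching the cohort's symptom dimension.
#' @param prior per-cause prior; default uniform.
#' @param mode likelihood mode, see [naive_bayes_posterior()].
#' @param threshold undetermined cutoff, see [assign_top_cause()].
#' @return object of class `c("va_nb", "va_fit")` with per-death posterior
#'   probabilities, assignments, and settings. Methods: `print`, `summary`,
#'   `coef` (population CSMF estimate = mean posterior), `predict`.
#' @export
va_nb <- function(cohort, sci, prior = NULL,
                  mode = c("affirmative_only", "full_bernoulli"),
                  threshold = 0.4) {
  mode <- match.arg(mode)
  symptoms <- if (inherits(cohort, "va_cohort")) cohort$symptoms else cohort
  if (ncol(symptoms) != nrow(sci)) {
    stop("cohort has ", ncol(symptoms), " symptoms but SCI has ", nrow(sci),
         call. = FALSE)
  }
  probs <- nb_posterior_matrix(symptoms, sci, prior, mode)
  colnames(probs) <- colnames(sci)
  top <- assign_top_cause(probs, threshold)
  ids <- if (inherits(cohort, "va_cohort")) cohort$records$id
         else sprintf("d%05d", seq_len(nrow(symptoms)))
  fit <- structure(list(
    method = "interva_like",
    probs = probs,
    assignments = cbind(data.frame(id = ids, method = "interva_like",
                                   stringsAsFactors = FALSE), top),
    prior = if (is.null(prior)) rep(1 / ncol(sci), ncol(sci)) else prior,
    mode = mode, threshold = attr(top, "threshold"),
    cause_labels = colnames(sci), n = nrow(symptoms),
    call = match.call()
  ), class = c("va_nb", "va_fit"))
  fit
}

#' Dirichlet-categorical Gibbs sampler for causes and the population CSMF
#'
#' An InSilicoVA-style engine. Model: `y_i ~ categorical(pi)`; symptoms given
#' `y_i` follow the SCI Bernoulli likelihood; `pi ~ Dirichlet(alpha)`. The
#' sampler alternates `y_i | pi` (per-death categorical draw from the
#' likelihood-weighted posterior) and `pi | y` (Dirichlet with updated
#' counts). Per-death probabilities are posterior frequencies of each cause
#' across retained sweeps; the population CSMF is the posterior mean of `pi`
#' with equal-tailed credible intervals. Convergence of `pi` is reported via
#' split-chain potential scale reduction (warning above 1.1).
#'
#' @inheritParams va_nb
#' @param alpha Dirichlet concentration, scalar or per-cause (default 1,
#'   flat).
#' @param n_iter,burn_in,thin sweep counts; retained draws =
#'   `(n_iter - burn_in) / thin`.
#' @param seed integer seed; fixed seed reproduces draws exactly.
#' @return object of class `c("va_gibbs", "va_fit")` with `$csmf` (posterior
#'   mean), `$csmf_ci`, `$pi_draws`, per-death `$probs`, `$assignments`,
#'   `$psrf`.
#' @export
va_gibbs <- function(cohort, sci, alpha = 1,
                     n_iter = 4000, burn_in = 1000, thin = 1,
                     seed = 1L,
                     mode = c("full_bernoulli", "affirmative_only"),
                     threshold = 0.4) {
  mode <- match.arg(mode)
  symptoms <- if (inherits(cohort, "va_cohort")) cohort$symptoms else cohort
  if (ncol(symptoms) != nrow(sci)) {
    stop("cohort has ", ncol(symptoms), " symptoms but SCI has ", nrow(sci),
         call. = FALSE)
  }
  if (n_iter <= burn_in) stop("`n_iter` must exceed `burn_in`", call. = FALSE)
  K <- ncol(sci)
  n <- nrow(symptoms)
  alpha <- rep_len(alpha, K)
  if (any(alpha <= 0)) stop("`alpha` must be positive", call. = FALSE)

  ll <- nb_loglik_matrix(symptoms, sci, mode)   # fixed across sweeps
  if (any(!is.finite(ll))) stop("non-finite likelihood", call. = FALSE)
  set.seed(as.integer(seed))
  g <- stats::rgamma(K, alpha)
  pv <- g / sum(g)
  n_keep <- (n_iter - burn_in) %/% thin
  pi_draws <- matrix(NA_real_, n_keep, K, dimnames = list(NULL, colnames(sci)))
  cause_freq <- matrix(0, n, K, dimnames = list(NULL, colnames(sci)))
  kept <- 0L
  for (it in seq_len(n_iter)) {
    p <- softmax_rows(sweep(ll, 2, log(pv), "+"))
    # vectorized categorical draw along rows
    cp <- p
    if (K > 1) for (k in 2:K) cp[, k] <- cp[, k - 1] + p[, k]
    u <- stats::runif(n)
    y <- rowSums(u > cp) + 1L
    y[y > K] <- K
    counts <- tabulate(y, K)
    g <- stats::rgamma(K, alpha + counts)
    pv <- g / sum(g)
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      pi_draws[kept, ] <- pv
      cause_freq[cbind(seq_len(n), y)] <- cause_freq[cbind(seq_len(n), y)] + 1
    }
  }
  probs <- cause_freq / kept
  top <- assign_top_cause(probs, threshold)
  ids <- if (inherits(cohort, "va_cohort")) cohort$records$id
         else sprintf("d%05d", seq_len(n))
  psrf <- split_psrf(pi_draws)
  if (any(psrf > 1.1, na.rm = TRUE)) {
    warning("split-chain PSRF above 1.1 for ",
            sum(psrf > 1.1, na.rm = TRUE),
            " CSMF component(s); consider more sweeps", call. = FALSE)
  }
  structure(list(
    method = "insilico_like",
    csmf = colMeans(pi_draws),
    csmf_ci = apply(pi_draws, 2, stats::quantile,
                    probs = c(0.025, 0.975), names = FALSE),
    pi_draws = pi_draws,
    probs = probs,
    assignments = cbind(data.frame(id = ids, method = "insilico_like",
                                   stringsAsFactors = FALSE), top),
    psrf = psrf,
    alpha = alpha, mode = mode, threshold = attr(top, "threshold"),
    n_iter = n_iter, burn_in = burn_in, thin = thin, seed = as.integer(seed),
    cause_labels = colnames(sci), n = n,
    call = match.call()
  ), class = c("va_gibbs", "va_fit"))
}

# split each retained chain in two halves; Gelman-Rubin potential scale
# reduction per CSMF component
split_psrf <- function(draws) {
  S <- nrow(draws)
  if (S < 4L) return(rep(NA_real_, ncol(draws)))
  h <- S %/% 2
  apply(draws[seq_len(2 * h), , drop = FALSE], 2, function(x) {
    ch <- matrix(x, ncol = 2)
    m <- ncol(ch); nn <- nrow(ch)
    W <- mean(apply(ch, 2, stats::var))
    B <- nn * stats::var(colMeans(ch))
    if (W <= 0) return(1)
    sqrt(((nn - 1) / nn * W + B / nn) / W)
  })
}

#' @export
print.va_fit <- function(x, ...) {
  cat(sprintf("VA assignment fit: %s engine, %d deaths, %d causes\n",
              x$method, x$n, length(x$cause_labels)))
  cat(sprintf("  mode: %s; threshold: %s\n", x$mode,
              ifelse(is.na(x$threshold), "none", format(x$threshold))))
  cat(sprintf("  undetermined: %d (%.1f%%)\n",
              sum(x$assignments$undetermined),
              100 * mean(x$assignments$undetermined)))
  invisible(x)
}

#' @export
summary.va_fit <- function(object, ...) {
  csmf <- coef(object)
  top <- sort(csmf, decreasing = TRUE)
  cat(sprintf("%s engine on %d deaths\n", object$method, object$n))
  cat("Estimated CSMF (top 5 causes):\n")
  print(round(utils::head(top, 5), 4))
  if (inherits(object, "va_gibbs")) {
    cat(sprintf("Retained draws: %d; max split-chain PSRF: %.3f\n",
                nrow(object$pi_draws), max(object$psrf, na.rm = TRUE)))
  }
  invisible(csmf)
}

#' @export
coef.va_nb <- function(object, ...) colMeans(object$probs)

#' @export
coef.va_gibbs <- function(object, ...) object$csmf

#' Predict cause probabilities for new VA records
#'
#' For the naive-Bayes engine the fitted prior is reused; for the Gibbs
#' engine the posterior-mean CSMF serves as the prior for new deaths.
#'
#' @param object a `va_fit`.
#' @param newdata a `va_cohort` or symptom matrix; default returns the fitted
#'   probabilities.
#' @param sci SCI matrix for the new records (required with `newdata`).
#' @param ... unused.
#' @return matrix of per-death cause probabilities.
#' @export
predict.va_fit <- function(object, newdata = NULL, sci = NULL, ...) {
  if (is.null(newdata)) return(object$probs)
  if (is.null(sci)) stop("supply `sci` to predict on new data", call. = FALSE)
  symptoms <- if (inherits(newdata, "va_cohort")) newdata$symptoms else newdata
  prior <- if (inherits(object, "va_gibbs")) object$csmf else object$prior
  p <- nb_posterior_matrix(symptoms, sci, prior / sum(prior), object$mode)
  colnames(p) <- object$cause_labels
  p
}

#' Extract standardized assignment results from a fit
#'
#' @param fit a `va_fit`, or a character vector of labels (e.g., physician
#'   causes) with `ids`.
#' @param ids death ids when `fit` is a label vector.
#' @param method method label when `fit` is a label vector.
#' @return data frame `id, method, top_cause, top_probability, undetermined`
#'   with the per-death probability matrix in the `"probs"` attribute (absent
#'   for label vectors).
#' @export
va_assignments <- function(fit, ids = NULL, method = "physician") {
  if (inherits(fit, "va_fit")) {
    out <- fit$assignments
    attr(out, "probs") <- fit$probs
    attr(out, "threshold") <- fit$threshold
    return(out)
  }
  stopifnot(is.character(fit))
  if (is.null(ids)) ids <- sprintf("d%05d", seq_along(fit))
  data.frame(id = ids, method = method, top_cause = fit,
             top_probability = NA_real_,
             undetermined = fit == "undetermined",
             stringsAsFactors = FALSE)
}

#' Write assignments as delimited text with a JSON metadata sidecar
#'
#' @param assignments output of [va_assignments()].
#' @param path CSV path; metadata goes to `<path>.meta.json`.
#' @param wide include per-cause probability columns `p_<cause>`.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path, wide = FALSE) {
  df <- assignments
  probs <- attr(assignments, "probs")
  if (wide && !is.null(probs)) {
    pw <- as.data.frame(probs)
    names(pw) <- paste0("p_", names(pw))
    df <- cbind(df, pw)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  meta <- list(threshold = attr(assignments, "threshold"),
               methods = unique(assignments$method),
               n = nrow(assignments))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
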