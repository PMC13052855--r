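# Shared fixtures, built in code.

tiny_sci <- function(vals, n_symptoms, n_causes) {
  as_sci(matrix(vals, n_symptoms, n_causes,
                dimnames = list(sprintf("s_%04d", seq_len(n_symptoms)),
                                sprintf("cause_%02d", seq_len(n_causes)))))
}

one_stratum_config <- function(n_causes = 3, n_symptoms = 10, n_deaths = 100,
                               csmf = NULL, ...) {
  if (is.null(csmf)) csmf <- rep(1 / n_causes, n_causes)
  sim_config(n_causes = n_causes, n_symptoms = n_symptoms,
             strata = data.frame(site = "A", sex = "male",
                                 age_group = "30-49"),
             csmf_true = csmf, n_deaths = n_deaths, ...)
}

# 4 detailed causes over 2 broad categories, plus undetermined
tiny_map <- function() {
  cause_map(data.frame(
    detailed = c("flu", "tb", "stroke", "crash"),
    harmonized35 = c("flu", "tb", "stroke", "crash"),
    who15 = c("infection", "infection", "ncd", "injury"),
    broad6 = c("communicable", "communicable", "ncd", "external"),
    stringsAsFactors = FALSE
  ))
}

# independent brute-force naive-Bayes oracle: plain prior x likelihood
# products, no log domain, no shared code with the implementation
nb_brute <- function(record, sci, prior, mode = "affirmative_only") {
  K <- ncol(sci)
  post <- numeric(K)
  for (j in seq_len(K)) {
    f <- prior[j]
    for (v in seq_along(record)) {
      s <- record[v]
      if (is.na(s)) next
      if (s == 1) {
        f <- f * sci[v, j]
      } else if (mode == "full_bernoulli") {
        f <- f * (1 - sci[v, j])
      }
    }
    post[j] <- f
  }
  post / sum(post)
}

# small, fast run configuration for pipeline tests
small_run_config <- function(seed = 7L, ...) {
  run_config(
    sim = default_sim_config(n_deaths = 25, seed = seed),
    gibbs = list(n_iter = 300, burn_in = 100, thin = 1),
    bootstrap_B = 25,
    seed = seed,
    ...
  )
}
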