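test_that("naive-Bayes posterior matches hand computations", {
  sci <- tiny_sci(c(0.8, 0.5, 0.2, 0.5), 2, 2)  # symptom1: (0.8, 0.2)
  # one affirmative symptom: posterior = (0.8, 0.2) after normalization
  p <- naive_bayes_posterior(c(1L, NA), sci, mode = "affirmative_only")
  expect_equal(unname(p), c(0.8, 0.2), tolerance = 1e-12)
  # symptom2 = no with SCI 0.5 contributes a symmetric factor that cancels
  p2 <- naive_bayes_posterior(c(1L, 0L), sci, mode = "full_bernoulli")
  expect_equal(unname(p2), c(0.8, 0.2), tolerance = 1e-12)
  # uninformative SCI: posterior uniform in either mode
  flat <- tiny_sci(0.5, 3, 4)
  for (m in c("affirmative_only", "full_bernoulli")) {
    expect_equal(unname(naive_bayes_posterior(c(1L, 0L, 1L), flat, mode = m)),
                 rep(0.25, 4), tolerance = 1e-12)
  }
  # all-missing record in affirmative mode returns the prior
  prior <- c(0.7, 0.3)
  expect_equal(unname(naive_bayes_posterior(c(NA, NA), sci, prior = prior)),
               prior, tolerance = 1e-12)
  # character encoding accepted
  expect_equal(naive_bayes_posterior(c("y", "."), sci),
               naive_bayes_posterior(c(1L, NA), sci))
  expect_error(naive_bayes_posterior(c(1L, 0L, 1L), sci), "symptoms")
})

test_that("posterior equals brute-force enumeration on random small instances", {
  set.seed(101)
  for (i in 1:200) {
    K <- sample(2:3, 1)
    V <- sample(1:4, 1)
    sci <- tiny_sci(runif(V * K, 0.05, 0.95), V, K)
    record <- sample(c(0L, 1L, NA), V, replace = TRUE)
    prior <- as.vector(stats::rgamma(K, 1)); prior <- prior / sum(prior)
    mode <- sample(c("affirmative_only", "full_bernoulli"), 1)
    expect_equal(unname(naive_bayes_posterior(record, sci, prior, mode)),
                 nb_brute(record, sci, prior, mode), tolerance = 1e-12)
  }
})

test_that("posteriors are label-invariant up to the same permutation", {
  set.seed(5)
  sci <- tiny_sci(runif(12, 0.1, 0.9), 4, 3)
  record <- c(1L, 0L, NA, 1L)
  p <- naive_bayes_posterior(record, sci, mode = "full_bernoulli")
  perm <- c(3, 1, 2)
  sci_p <- as_sci(unclass(sci)[, perm])
  p_p <- naive_bayes_posterior(record, sci_p, mode = "full_bernoulli")
  expect_equal(unname(p_p), unname(p)[perm], tolerance = 1e-12)
})

test_that("every emitted probability vector is normalized", {
  set.seed(6)
  cfg <- one_stratum_config(n_causes = 4, n_symptoms = 30, n_deaths = 80,
                            missingness_rate = 0.2)
  sci <- generate_sci_matrix(30, 4, 0.4, seed = 1,
                             cause_labels = cfg$cause_labels)
  coh <- generate_cohort(cfg, sci, seed = 2)
  nb <- va_nb(coh, sci)
  expect_true(all(abs(rowSums(nb$probs) - 1) < 1e-9))
  g <- va_gibbs(coh, sci, n_iter = 200, burn_in = 50, seed = 3)
  expect_true(all(abs(rowSums(g$probs) - 1) < 1e-9))
  expect_true(all(abs(rowSums(g$pi_draws) - 1) < 1e-9))
})

test_that("long symptom vectors do not underflow", {
  V <- 800
  sci <- tiny_sci(rep(c(0.05, 0.9), each = V), V, 2)
  record <- rep(1L, V)
  p <- naive_bayes_posterior(record, sci, mode = "full_bernoulli")
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_gt(p[[2]], 0.999)
})

test_that("top-cause rule applies the cutoff with strict inequality", {
  p <- c(a = 0.8, b = 0.2)
  expect_equal(assign_top_cause(p, 0.4)$top_cause, "a")
  p3 <- c(a = 0.35, b = 0.33, c = 0.32)
  expect_equal(assign_top_cause(p3, 0.4)$top_cause, "undetermined")
  # boundary: exactly 0.4 assigns (only strictly-less is undetermined)
  pb <- c(a = 0.40, b = 0.35, c = 0.25)
  expect_equal(assign_top_cause(pb, 0.4)$top_cause, "a")
  # no-threshold variant always assigns the argmax
  expect_equal(assign_top_cause(p3, NA)$top_cause, "a")
  expect_error(assign_top_cause(numeric(0)), "empty")
  expect_error(assign_top_cause(p, 1.5), "threshold")
})

test_that("argmax ties break to the first cause in label order, with a note", {
  p <- c(x = 0.4, y = 0.4, z = 0.2)
  expect_message(res <- assign_top_cause(p, 0.1), "tie")
  expect_equal(res$top_cause, "x")
  expect_equal(attr(res, "n_ties"), 1L)
})

test_that("raising the threshold never decreases undetermined counts", {
  set.seed(17)
  probs <- matrix(stats::rgamma(50 * 4, 1), 50, 4)
  probs <- probs / rowSums(probs)
  colnames(probs) <- letters[1:4]
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8, 0.99),
                   function(t) sum(assign_top_cause(probs, t)$undetermined),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("Gibbs sampler recovers the prior under an uninformative SCI", {
  cfg <- one_stratum_config(n_causes = 3, n_symptoms = 8, n_deaths = 50)
  sci <- generate_sci_matrix(8, 3, Inf, cause_labels = cfg$cause_labels)
  coh <- generate_cohort(cfg, sci, seed = 2)
  g <- suppressWarnings(
    va_gibbs(coh, sci, alpha = 1, n_iter = 2000, burn_in = 500, seed = 3))
  # likelihood carries no information: posterior mean of pi near prior mean 1/3
  expect_true(all(abs(g$csmf - 1 / 3) < 0.06))
})

test_that("Gibbs sampler concentrates on a single-cause cohort", {
  cfg <- one_stratum_config(n_causes = 3, n_symptoms = 20, n_deaths = 500,
                            csmf = c(1, 0, 0), sci_concentration = 0.2)
  sci <- generate_sci_matrix(20, 3, 0.2, seed = 4,
                             cause_labels = cfg$cause_labels)
  coh <- generate_cohort(cfg, sci, seed = 5)
  g <- va_gibbs(coh, sci, n_iter = 1000, burn_in = 300, seed = 6)
  expect_gte(g$csmf[["cause_01"]], 0.95)
})

test_that("Gibbs draws are reproducible and sweep accounting is exact", {
  cfg <- one_stratum_config(n_deaths = 40)
  sci <- generate_sci_matrix(10, 3, 0.5, seed = 1,
                             cause_labels = cfg$cause_labels)
  coh <- generate_cohort(cfg, sci, seed = 2)
  a <- va_gibbs(coh, sci, n_iter = 300, burn_in = 100, thin = 2, seed = 9)
  b <- va_gibbs(coh, sci, n_iter = 300, burn_in = 100, thin = 2, seed = 9)
  expect_identical(a$pi_draws, b$pi_draws)
  expect_identical(a$probs, b$probs)
  expect_equal(nrow(a$pi_draws), (300 - 100) %/% 2)
  expect_error(va_gibbs(coh, sci, n_iter = 100, burn_in = 100), "exceed")
  expect_error(va_gibbs(coh, sci, alpha = 0), "positive")
})

test_that("strong SCI signal aligns the two engines' modal causes", {
  cfg <- one_stratum_config(n_causes = 3, n_symptoms = 40, n_deaths = 300,
                            csmf = c(0.5, 0.3, 0.2), sci_concentration = 0.1,
                            missingness_rate = 0)
  sci <- generate_sci_matrix(40, 3, 0.1, seed = 21,
                             cause_labels = cfg$cause_labels)
  coh <- generate_cohort(cfg, sci, seed = 22)
  nb <- va_nb(coh, sci, mode = "full_bernoulli", threshold = NA)
  g <- va_gibbs(coh, sci, n_iter = 800, burn_in = 200, seed = 23,
                threshold = NA)
  agree <- mean(nb$assignments$top_cause == g$assignments$top_cause)
  expect_gte(agree, 0.99)
})

test_that("fit methods expose CSMF estimates and predictions", {
  cfg <- one_stratum_config(n_deaths = 50, csmf = c(0.6, 0.3, 0.1),
                            sci_concentration = 0.2)
  sci <- generate_sci_matrix(10, 3, 0.2, seed = 1,
                             cause_labels = cfg$cause_labels)
  coh <- generate_cohort(cfg, sci, seed = 2)
  nb <- va_nb(coh, sci)
  expect_equal(sum(coef(nb)), 1, tolerance = 1e-9)
  expect_identical(dim(predict(nb)), dim(nb$probs))
  g <- va_gibbs(coh, sci, n_iter = 200, burn_in = 50, seed = 3)
  expect_equal(sum(coef(g)), 1, tolerance = 1e-9)
  pnew <- predict(g, newdata = coh, sci = sci)
  expect_true(all(abs(rowSums(pnew) - 1) < 1e-9))
  expect_output(print(nb), "interva_like")
  expect_output(summary(g), "CSMF")
})
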