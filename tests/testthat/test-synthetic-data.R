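test_that("SCI generation is deterministic under a fixed seed and varies with it", {
  a <- generate_sci_matrix(10, 3, 1.0, seed = 7)
  b <- generate_sci_matrix(10, 3, 1.0, seed = 7)
  expect_identical(unclass(a), unclass(b))
  d <- generate_sci_matrix(10, 3, 1.0, seed = 8)
  expect_true(any(a != d))
  expect_true(all(a > 0 & a < 1))
})

test_that("infinite concentration gives the uninformative SCI limit", {
  m <- generate_sci_matrix(4, 2, Inf)
  expect_true(all(m == 0.5))
})

test_that("SCI generation rejects invalid arguments", {
  expect_error(generate_sci_matrix(0, 3, 1), "n_symptoms")
  expect_error(generate_sci_matrix(4, 1, 1), "n_causes")
  expect_error(generate_sci_matrix(4, 3, -1), "positive")
  expect_error(generate_sci_matrix(4, 3, 0), "positive")
})

test_that("cohort generation follows the configured cause distribution", {
  # degenerate CSMF: every death gets cause 1
  cfg <- one_stratum_config(csmf = c(1, 0, 0), n_deaths = 50)
  sci <- generate_sci_matrix(10, 3, 0.5, seed = 1,
                             cause_labels = cfg$cause_labels)
  coh <- generate_cohort(cfg, sci, seed = 2)
  expect_true(all(coh$records$true_cause == "cause_01"))

  # law of large numbers: empirical CSMF within +-0.02 of (0.5, 0.3, 0.2)
  cfg <- one_stratum_config(csmf = c(0.5, 0.3, 0.2), n_deaths = 5000,
                            missingness_rate = 0)
  coh <- generate_cohort(cfg, generate_sci_matrix(10, 3, 0.5, seed = 1,
                                                  cause_labels = cfg$cause_labels),
                         seed = 3)
  emp <- table(factor(coh$records$true_cause, cfg$cause_labels)) / 5000
  expect_true(all(abs(as.numeric(emp) - c(0.5, 0.3, 0.2)) < 0.02))
})

test_that("missingness boundaries and symptom states behave", {
  cfg <- one_stratum_config(missingness_rate = 1, n_deaths = 20)
  sci <- generate_sci_matrix(10, 3, 0.5, seed = 1,
                             cause_labels = cfg$cause_labels)
  coh <- generate_cohort(cfg, sci, seed = 2)
  expect_true(all(is.na(coh$symptoms)))

  cfg0 <- one_stratum_config(missingness_rate = 0, n_deaths = 20)
  coh0 <- generate_cohort(cfg0, sci, seed = 2)
  expect_true(all(coh0$symptoms %in% c(0L, 1L)))
})

test_that("cohort generation is reproducible and validates dimensions", {
  cfg <- one_stratum_config(n_deaths = 40)
  sci <- generate_sci_matrix(10, 3, 0.5, seed = 1,
                             cause_labels = cfg$cause_labels)
  a <- generate_cohort(cfg, sci, seed = 9)
  b <- generate_cohort(cfg, sci, seed = 9)
  expect_identical(a$records, b$records)
  expect_identical(a$symptoms, b$symptoms)
  bad_sci <- generate_sci_matrix(11, 3, 0.5, seed = 1,
                                 cause_labels = cfg$cause_labels)
  expect_error(generate_cohort(cfg, bad_sci), "dimensions")
})

test_that("physician channel boundaries: noiseless and all-undetermined", {
  cfg <- one_stratum_config(n_deaths = 60)
  sci <- generate_sci_matrix(10, 3, 0.5, seed = 1,
                             cause_labels = cfg$cause_labels)
  coh <- generate_cohort(cfg, sci, seed = 2)
  expect_identical(simulate_physician_review(coh, theta = 1, u = 0, seed = 3),
                   coh$records$true_cause)
  expect_true(all(simulate_physician_review(coh, theta = 0.5, u = 1,
                                            seed = 3) == "undetermined"))
})

test_that("physician channel is calibrated: accuracy near theta(1-u)", {
  cfg <- one_stratum_config(n_deaths = 10000)
  sci <- generate_sci_matrix(10, 3, 0.5, seed = 1,
                             cause_labels = cfg$cause_labels)
  coh <- generate_cohort(cfg, sci, seed = 2)
  phys <- simulate_physician_review(coh, theta = 0.8, u = 0.1, seed = 4)
  expect_lt(abs(mean(phys == coh$records$true_cause) - 0.72), 0.015)
  # undetermined rate within three binomial standard errors of u
  se_u <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(mean(phys == "undetermined") - 0.1), 3 * se_u)
  # errors never return the true cause
  wrong <- phys != "undetermined" & phys != coh$records$true_cause
  expect_true(all(phys[wrong] %in% cfg$cause_labels))
})

test_that("physician channel rejects a confusion row with no off-diagonal mass", {
  cfg <- one_stratum_config(n_deaths = 200,
                            physician_confusion = diag(3))
  sci <- generate_sci_matrix(10, 3, 0.5, seed = 1,
                             cause_labels = cfg$cause_labels)
  coh <- generate_cohort(cfg, sci, seed = 2)
  expect_error(simulate_physician_review(coh, theta = 0.5, u = 0, seed = 3),
               "off-diagonal")
})

test_that("cohort and SCI round-trip through their delimited forms", {
  cfg <- one_stratum_config(n_deaths = 30, missingness_rate = 0.3)
  sci <- generate_sci_matrix(10, 3, 0.5, seed = 1,
                             cause_labels = cfg$cause_labels)
  coh <- generate_cohort(cfg, sci, seed = 2)
  phys <- simulate_physician_review(coh, seed = 3)

  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f, phys_cause = phys)
  back <- read_cohort(f, cause_labels = cfg$cause_labels)
  expect_identical(back$records$true_cause, coh$records$true_cause)
  expect_identical(back$symptoms, coh$symptoms)
  expect_identical(back$phys_cause, phys)

  g <- tempfile(fileext = ".csv")
  write_sci(sci, g)
  sci2 <- read_sci(g)
  expect_equal(unclass(sci2), unclass(sci), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("simulation config validates its invariants", {
  expect_error(one_stratum_config(csmf = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(one_stratum_config(csmf = c(1.2, -0.2, 0)), "negative")
  expect_error(one_stratum_config(physician_accuracy = 1.4), "probability")
  expect_error(one_stratum_config(missingness_rate = -0.1), "probability")
  expect_error(one_stratum_config(sci_concentration = 0), "positive")
  bad_conf <- matrix(c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5), 3, 2)
  expect_error(one_stratum_config(physician_confusion = matrix(1, 3, 3)),
               "sum")
})
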