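test_that("the shipped map loads with the advertised level cardinalities", {
  map <- default_cause_map()
  card <- vapply(map$levels, length, integer(1))
  expect_equal(unname(card[c("harmonized35", "who15", "broad6")]),
               c(35L, 15L, 6L))
  expect_true("undetermined" %in% map$levels$broad6)
})

test_that("map validation rejects duplicates and inconsistent nesting", {
  df <- tiny_map()$map
  expect_error(cause_map(rbind(df, df[1, ])), "duplicated")
  dup <- rbind(df, data.frame(detailed = "flu", harmonized35 = "flu",
                              who15 = "ncd", broad6 = "ncd"))
  expect_error(cause_map(dup), "more than once")
  bad <- df
  bad$broad6[bad$detailed == "tb"] <- "ncd"   # infection -> two broad targets
  expect_error(cause_map(bad), "inconsistent nesting")
  expect_error(cause_map(df[, 1:3]), "columns")
  expect_error(load_cause_map(tempfile()), "no such file")
})

test_that("an unmapped cause is a named error, never a silent drop", {
  map <- tiny_map()
  expect_error(collapse_assignments(c("flu", "ebola"), map, "broad6"),
               "ebola")
})

test_that("collapse conserves deaths, is idempotent, and sums probabilities", {
  map <- tiny_map()
  labels <- c("flu", "tb", "stroke", "crash", "flu", "tb", "tb", "stroke",
              "crash", "flu")
  broad <- collapse_assignments(labels, map, "broad6")
  expect_length(broad, length(labels))
  expect_equal(sum(broad == "communicable"), sum(labels %in% c("flu", "tb")))
  # idempotence: collapsing an already-collapsed vector changes nothing
  expect_identical(collapse_assignments(broad, map, "broad6"), broad)
  # identity at the finest level
  expect_identical(collapse_assignments(labels, map, "detailed"), labels)
  # undetermined maps to undetermined
  expect_identical(collapse_assignments("undetermined", map, "who15"),
                   "undetermined")

  # probability mass is pooled within target categories: causes 1,2 -> A, 3 -> B
  a <- data.frame(id = "d1", method = "m", top_cause = "flu",
                  top_probability = 0.5, undetermined = FALSE)
  attr(a, "probs") <- matrix(c(0.3, 0.2, 0.5, 0.0), 1,
                             dimnames = list(NULL, c("flu", "tb", "stroke",
                                                     "crash")))
  out <- collapse_assignments(a, map, "broad6")
  probs <- attr(out, "probs")
  expect_equal(probs[1, "communicable"], 0.5, ignore_attr = TRUE)
  expect_equal(probs[1, "ncd"], 0.5, ignore_attr = TRUE)
  expect_equal(sum(probs), 1, tolerance = 1e-12)
})

test_that("physician-undetermined pairs are excluded; algorithm-undetermined kept", {
  pairs <- filter_for_reference_comparison(
    c("A", "undetermined", "B"), c("A", "A", "C"))
  expect_equal(pairs$reference, c("A", "B"))
  expect_equal(pairs$predicted, c("A", "C"))
  # algorithm-undetermined counts against agreement but stays in
  pairs2 <- filter_for_reference_comparison(c("A", "B"),
                                            c("undetermined", "B"))
  expect_equal(nrow(pairs2), 2L)
  # no physician-undetermined: identity
  pairs3 <- filter_for_reference_comparison(c("A", "B"), c("B", "B"))
  expect_equal(nrow(pairs3), 2L)
  expect_warning(
    empty <- filter_for_reference_comparison(rep("undetermined", 3),
                                             c("A", "B", "C")),
    "no pairs")
  expect_equal(nrow(empty), 0L)
  expect_error(filter_for_reference_comparison("A", c("A", "B")), "length")
})

test_that("undetermined cross-tab counts and percentages are conserved", {
  phys <- c("flu", rep("undetermined", 4), "tb")
  alg <- c("tb", "flu", "flu", "tb", "crash", "stroke")
  tab <- crosstab_undetermined(phys, alg)
  expect_equal(sum(tab$n), 4L)
  expect_equal(sum(tab$pct), 100, tolerance = 1e-9)
  expect_equal(tab$pct[tab$cause == "flu"], 50)
  expect_setequal(tab$cause, c("flu", "tb", "crash"))
  # all physician causes determined: empty table
  empty <- crosstab_undetermined(c("flu", "tb"), c("flu", "tb"))
  expect_equal(nrow(empty), 0L)
  # collapsed tabulation
  tab6 <- crosstab_undetermined(phys, alg, tiny_map(), "broad6")
  expect_equal(sum(tab6$n), 4L)
  expect_equal(tab6$n[tab6$cause == "communicable"], 3L)
})

test_that("maternal assignments on male records are flagged, not deleted", {
  map <- default_cause_map()
  a <- va_assignments(c("Obstetric haemorrhage", "Stroke",
                        "Obstetric haemorrhage"),
                      ids = c("d1", "d2", "d3"))
  expect_warning(flag <- flag_maternal_males(a, c("male", "male", "female"),
                                             map),
                 "maternal")
  expect_identical(flag, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(a), 3L)
})

test_that("agreement never decreases when coarsening the cause level", {
  map <- default_cause_map()
  set.seed(31)
  causes <- setdiff(map$levels$harmonized35, "undetermined")
  for (rep in 1:10) {
    x <- sample(causes, 200, replace = TRUE)
    y <- sample(causes, 200, replace = TRUE)
    a35 <- percent_agreement(x, y)
    a15 <- percent_agreement(collapse_assignments(x, map, "who15"),
                             collapse_assignments(y, map, "who15"))
    a6 <- percent_agreement(collapse_assignments(x, map, "broad6"),
                            collapse_assignments(y, map, "broad6"))
    expect_gte(a15, a35)
    expect_gte(a6, a15)
  }
})
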