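Package: vaconcord
Title: Concordance of Verbal Autopsy Cause-of-Death Assignment Methods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates verbal autopsy (VA) cohorts with a known cause
    structure, assigns causes of death with two engines (a deterministic
    naive-Bayes classifier over a symptom-cause-information matrix, and a
    Dirichlet-categorical Gibbs sampler that jointly estimates individual
    causes and the population cause-specific mortality fraction), harmonizes
    cause lists across three granularity levels, and computes population- and
    individual-level concordance metrics (CSMF accuracy, percent agreement,
    per-cause sensitivity, Spearman rank correlation) with non-parametric
    bootstrap confidence intervals. CSMF tables use logit-transformed
    proportion intervals with a t critical value.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
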