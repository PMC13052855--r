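---
title: "Methods: simulating and comparing verbal-autopsy cause assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and comparing verbal-autopsy cause assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaconcord)
```

# The problem

Where deaths are not medically certified, the cause of death (CoD) is
inferred from a verbal autopsy (VA): a structured interview about the signs
and symptoms preceding death. Physician panels and computer algorithms both
interpret these records, and health surveillance programmes need to know how
much the two approaches agree — at the level of individual deaths and at the
level of the population's cause-specific mortality fractions (CSMFs).
`vaconcord` implements the full comparison pipeline on synthetic cohorts
whose true cause structure is known, so every stage is testable without
access to any confidential surveillance data.

# Generative model

A cohort is stratified by site, sex, and age group. Within stratum $s$ each
death $i$ receives a true cause $y_i \sim \mathrm{Categorical}(\pi^{(s)})$,
where $\pi^{(s)}$ is the stratum's true CSMF. Given $y_i = j$, each binary
symptom $v$ is drawn independently as
$s_{iv} \sim \mathrm{Bernoulli}(\mathrm{SCI}_{vj})$, where the
symptom-cause-information (SCI) matrix holds
$P(\text{symptom } v = \text{yes} \mid \text{cause } j)$. Each symptom is
then independently masked (set missing) with probability $m$. One SCI matrix
is shared across strata — the same instrument and algorithms applied to
different populations — while the CSMFs differ by stratum.

Synthetic SCI entries are i.i.d. $\mathrm{Beta}(c, c)$ draws indexed by a
single concentration $c$: small $c$ gives near-0/1 entries (informative,
well-separated cause profiles), large $c$ pushes entries toward 0.5;
$c = \infty$ is the exact uninformative limit. This one-knob family was
chosen because published VA tools do not disclose a reusable SCI matrix, so
informativeness must be a controllable simulation parameter rather than a
fixed fixture. Entries are clamped to $[10^{-6}, 1 - 10^{-6}]$ so that no
single contradictory symptom can analytically exclude a cause.

The physician review is modelled as a noisy oracle, not as a committee
process: independently per death, the label is "undetermined" with
probability $u$; otherwise it is the true cause with probability $\theta$;
otherwise it is a draw from the confusion row of the true cause with the
diagonal zeroed and renormalized, so an error is always a wrong cause. The
confusion matrix defaults to uniform over wrong causes (no published
confusion structure exists to copy) but is configurable, e.g. to study
structured HIV-versus-TB misclassification.

## Default scenario

`default_sim_config()` mirrors the motivating two-site study: sites A
(physician reviews available) and B; sexes male/female; age groups 15–29,
30–49, 50+; per-stratum sample sizes equal to the published
deaths-with-VA counts (1,564 deaths in total, 1,037 at site A); interview
years 2013–2021. Per-stratum true CSMFs are built by spreading the published
sex-specific broad-category fractions uniformly over the member causes of
the shipped 35-cause list (maternal mass is zero for males, and site B is
tilted toward non-communicable causes as its published tables are). Defaults
chosen once where the source material is silent: 50 symptom items (far fewer
than the ~300-item instrument, but enough that posteriors are driven by the
likelihood), SCI concentration 0.5 (moderately informative), missingness
0.05, physician accuracy $\theta = 0.8$ (a realistic panel), and
undetermined rate $u = 0.27$ (matching the published share of
physician-undetermined deaths, 236/876).

# The two assignment engines

Both engines are simplified, documented implementations of the *mechanisms*
the published tools describe — an SCI-based naive-Bayes classifier and a
fully Bayesian CSMF estimator. They are stand-ins for methodological study,
not bit-compatible re-implementations of InterVA-5 or InSilicoVA (whose
internal arithmetic and hierarchy are not fully specified in public
descriptions).

**Naive Bayes (`va_nb`).** For death $i$,
$P(y_i = j \mid s_i) \propto p_j \prod_{v \text{ observed}} f(s_{iv},
\mathrm{SCI}_{vj})$ with $f = \mathrm{SCI}_{vj}$ for a yes. Two likelihood
modes: `affirmative_only` (a no contributes factor 1; mirrors descriptions
of classifiers that use only affirmative responses; the engine default) and
`full_bernoulli` ($f = 1 - \mathrm{SCI}_{vj}$ for a no). Missing symptoms
contribute factor 1 in both modes. The prior $p$ defaults to uniform — no
prior is published for the reference tools. Accumulation is in the log
domain, so instruments with hundreds of items cannot underflow.

**Dirichlet–categorical Gibbs sampler (`va_gibbs`).** Model:
$\pi \sim \mathrm{Dirichlet}(\alpha)$, $y_i \sim
\mathrm{Categorical}(\pi)$, symptoms from the SCI Bernoulli likelihood
(`full_bernoulli` by default, since the sampler models the whole record).
The sampler alternates $y_i \mid \pi$ (categorical draw proportional to
$\pi_j \, L_{ij}$, with the per-death log-likelihood matrix $L$ precomputed
once) and $\pi \mid y \sim \mathrm{Dirichlet}(\alpha + \text{counts})$.
Defaults: $\alpha = 1$ per cause (flat), 4,000 sweeps, 1,000 burn-in, no
thinning. Per-death probabilities are posterior frequencies over retained
sweeps; the population CSMF is the posterior mean of $\pi$ with equal-tailed
credible intervals. Convergence is monitored by split-chain potential scale
reduction on each component of $\pi$, warning above 1.1. Under an
uninformative SCI the $\pi$ chain is only weakly identified and mixes
slowly; the warning is expected there and signals exactly that.

**Top-cause rule.** The assigned cause is the argmax of the posterior;
if a threshold $t$ is active and the maximum is *strictly below* $t$, the
death is "undetermined". The default $t = 0.4$ follows the moderate-
confidence convention of the motivating study; a probability exactly at the
threshold assigns. The boundary direction matters for reproducibility and is
pinned by a test. Argmax ties are broken by the first cause in label order
and counted. `threshold = NA` gives the no-threshold variant used in
sensitivity analyses.

# Harmonization

Methods emit causes on a 35-cause harmonized list; analyses run at three
nested levels: harmonized-35 → WHO-15 → broad-6. The shipped map
(`default_cause_map()`) is *fixture data*, user-replaceable by a CSV with
header `detailed,harmonized35,who15,broad6`; it is modelled on the published
tables, not on any ICD-10 mapping. Two open choices were resolved as
follows: HIV and TB are carried as a single combined WHO-level category
(15 categories including undetermined), and "undetermined" is itself a
category at every level, mapping only to itself. Validation enforces
totality, uniqueness, and nesting consistency; collapsing conserves death
counts, pools probability mass within target categories, and is idempotent.
A consequence tested as an invariant: percent agreement can only increase
when moving to a coarser level, because label matches are preserved under
any common relabelling.

When the physician review is the reference, physician-undetermined deaths
are excluded from paired comparisons (they carry no reference diagnosis) and
instead summarized in a cross-tab of the algorithm's causes among those
deaths. Algorithm-undetermined assignments are retained and count against
agreement. Maternal causes on male records are flagged by a validation pass
but never deleted — the published tables imply, but do not state, an
enforcement rule.

# CSMF tables and the proportion interval

CSMF = deaths assigned to a cause / deaths in the stratum, reported as a
percent; undetermined stays in the denominator and appears as its own row;
zero-count causes are kept. The confidence interval is the logit-transformed
interval with a t critical value on $N - 1$ degrees of freedom. This method
was selected by reconstruction: it reproduces the published worked cell
(70 of 551 → 12.70%, CI 10.17–15.76) to two decimals, where the plain Wald
interval (9.92–15.48) does not; a Wald option is retained behind a flag for
comparison. A few published intervals differ from any standard formula in
the last digit; the logit-t rule is the closest overall and the residual
discrepancy is documented rather than chased. Zero and full cells get no
interval (rendered `(-)`), matching the published convention. Simulation
places the interval's coverage at $p = 0.13$, $N = 551$ within 93–97% over
2,000 replicates (an acceptance test).

# Concordance metrics

- **Percent agreement**: 100 × exact label matches / pairs; "undetermined"
  matches only itself.
- **Sensitivity per cause** $j$: $TP_j / (TP_j + FN_j)$ against the
  reference, evaluated on the WHO-15 list; undefined (flagged NA, never
  coerced to zero) when the reference contains no death of cause $j$.
- **CSMF accuracy**: $1 - \sum_j |CSMF_j^{true} - CSMF_j^{pred}| \,/\,
  2(1 - \min_j CSMF_j^{true})$, computed over the broad-6 list by default.
  It equals 1 iff the distributions coincide and is deliberately asymmetric
  (the denominator depends on the reference); both properties are pinned by
  tests. The degenerate reference with all mass on one cause (denominator
  zero) is defined as 1 for an identical prediction and an error otherwise.
- **Spearman's rho**: Pearson correlation of average ranks of the two CSMF
  vectors. The published convention gives the largest CSMF rank 1; rho is
  invariant to applying that flip to both vectors, so plain ascending ranks
  are used. Constant vectors give NA (all ranks tied).

**Bootstrap.** Confidence intervals are non-parametric: the resampling unit
is the individual death with its full set of method labels (preserving the
pairing), B = 1,000 replicates by default, equal-tailed percentile
interval. Replicates on which a statistic is undefined (e.g., a cause
vanishing from a resample) are dropped from the percentile pool with a
logged count; more than 50% undefined is an error advising more data. An
acceptance test checks the machinery against a closed form: for percent
agreement, the bootstrap distribution of matches is Binomial(n, p̂), and the
percentile interval must land within ±0.01 of the binomial quantile
interval.

# Orchestration

`run_analysis1()` (algorithms vs physician reference at the physician site)
and `run_analysis2()` (algorithm vs algorithm on all sites, no physician
filter) reproduce the two study designs end-to-end, returning CSMF tables at
all three levels, metric tables by stratum (overall, by sex, 15–49 and 50+ —
both age conventions of the source tables are reported, labelled
explicitly), the undetermined cross-tab, and optionally a no-threshold
rerun. Every stage seed is derived from the single configured seed by fixed
offsets, and the JSON manifest (config, seeds, md5 hash of the serialized
config) suffices to reproduce every table byte-identically — pinned by a
test on written files. A `truth` engine (assigns the true cause with
probability 1) is available as a positive control: with a noiseless
physician channel it must produce 100% agreement, CSMF accuracy 1, and unit
sensitivities, which is tested.

The `pipeline_cli` surface is the exported function set (`run_config`,
`read_run_config`, `run_analysis1`, `run_analysis2`, plus the `write_*`
helpers); configurations can be supplied as YAML or JSON files. No shell
wrapper is shipped: the intended users drive the analysis from R.

# Numerical choices and degenerate inputs

- SCI clamping at $\varepsilon = 10^{-6}$; all likelihood accumulation in
  logs.
- Argmax ties: first label in order, counted and reported.
- An all-missing record under the affirmative-only mode returns the prior —
  by design, not an error.
- Proportion CIs undefined at $n_j \in \{0, N\}$; no exact fallback, to
  match the published rendering.
- CSMF fractions print to two decimals; full precision is kept internally.

# What the simulations do and do not show

The generator matches the analysis's statistical assumptions exactly: the
engines classify with the same SCI matrix that generated the symptoms. This
is deliberate — it makes parameter recovery and invariants sharply testable —
but it means simulated agreement levels are *optimistic*. Observed agreement
in the shipped example (around 80% at the harmonized level) is far above
what real studies report (around 40%), because real physicians use narrative
information the algorithms never see, real SCI matrices are misspecified for
the local population, and real symptom reporting is noisy in structured ways
(recall bias, interviewer effects, skip logic) that the independent-
Bernoulli model does not emulate. Conclusions about *relative* method
behaviour and about the correctness of the metric machinery transfer;
absolute concordance levels do not.

Problem sizes in the test suite are chosen for sharp statistical power at
modest cost: parameter recovery uses 2,000 deaths, 3 causes, 25 symptoms and
3,000 sweeps; calibration checks use 10,000-death channels and 2,000
interval replicates; the pipeline tests run the full two-site design at 25
deaths per stratum with shortened chains.

# Known limitations

- The engines are mechanism-level models, not reproductions of published
  tools; no published probbase or letter-grade probability encoding is used.
- Physician review is a parametric noisy oracle; committee dynamics,
  inter-reviewer variability, and narrative information are out of scope.
- Missingness is independent and uniform; real VA missingness is
  structured.
- VA non-response is not modelled: the generator produces deaths *with* a
  VA only.
- The shipped cause map is synthetic fixture data; substantive analyses
  should supply their own mapping.
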