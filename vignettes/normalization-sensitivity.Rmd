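---
title: "Normalization sensitivity in relative qPCR: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalization sensitivity in relative qPCR: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normsense)
```

# The problem

Relative qPCR reports a target gene as a ratio against a reference gene.
The ratio is only interpretable if the reference is unaffected by the
condition under study; when it is not, the reference's own response enters
the ratio with the opposite sign. This vignette documents the models the
package implements, the tunable parameters and their defaults, the
numerical and design choices that were genuinely open, and what the
simulation-based tests do — and do not — establish about real data.

# Efficiency-corrected quantification

A dilution series fits `Cq = intercept + slope * log10(input)` by ordinary
least squares; the amplification efficiency is `E = 10^(-1/slope)` (cycles
halve the remaining distance to threshold at `E = 2`). Fits with
`r^2 <= 0.99` warn rather than fail: a marginal curve is still a curve,
and the analyst should see it. Efficiencies outside `(1, 2.2]` also warn
(values above perfect doubling plus a tolerance are physically
implausible and usually indicate curve artifacts).

Relative expression uses the efficiency-corrected ratio
`R = E_t^(dCq_t) / E_r^(dCq_r)` with `dCq = Cq(calibrator) - Cq(sample)`,
computed in log2 space throughout to avoid overflow at extreme `dCq`, and
exported on the linear scale.

Choices worth stating explicitly:

* **Calibrator.** qPCR instruments rarely document the calibrator they
  used. The default here is the per-gene mean of QC-passing control-group
  mean Cq values, which centres control-group ratios near 1 and makes the
  two groups' medians directly readable as fold changes; a named
  calibrator sample and the grand mean are available alternatives.
* **Replicate QC.** Technical duplicates collapse to their mean; entries
  pass only if the sample SD (n−1 denominator, the convention of common
  qPCR software) of the replicates is *strictly below* 0.05 cycles. A
  single replicate has SD 0 and passes, with a note. The threshold is on
  the Cq scale — it is applied to raw cycles before any normalization.
* **Missing efficiencies** default to perfect doubling (`E = 2`) with a
  message; supplying standard-curve fits or a config map is preferred.
* **Outlier removal** is a single pass: mean and SD are computed with the
  candidates included, and values beyond `z = 1.96` SD are removed, with
  no re-iteration. With small n this rule can *mask* gross outliers
  (one extreme value inflates the SD it is judged against; with
  `(1,1,1,1,10)` nothing is removed). That behaviour is intentional and
  tested: it is the minimal reading of the rule as commonly stated, and a
  re-iterated variant would remove different samples without the analyst
  noticing. Whether screening pools groups or runs per group is a config
  choice; the default pools, because the rule's purpose is to catch
  technical failures, not biological extremes.

# Two-group inference

Group comparisons use the Wilcoxon rank-sum test and the Hodges–Lehmann
location shift, reported as
`median (IQR) vs median (IQR), location shift (95%CI), p`.

* **Exact path.** For tie-free samples with `min(n) <= 10` and
  `max(n) <= 20`, p-values come from the exact null distribution of the
  Mann–Whitney U statistic, computed by a subset-sum dynamic program over
  rank sums (equivalent to full enumeration, and tested against literal
  `combn` enumeration for all sizes up to 7). Two-sided p doubles the
  smaller tail, capped at 1.
* **Ties** take midranks and fall through to a normal approximation with
  tie-corrected variance and continuity correction (the behaviour of
  mainstream implementations, matched to machine precision in the tests).
* **Confidence intervals** take the k-th smallest and (mn+1−k)-th
  smallest pairwise differences, with k from inverting the exact (or
  approximate) null distribution. The exact inversion is conservative by
  discreteness: at n = 10 per group the realized coverage of the nominal
  95% interval is ~95.9% (verified by simulation in the test suite). At
  very small n (e.g. 2 vs 2) the requested confidence is unattainable;
  the interval widens to the extreme differences and warns.
* **Quantiles** use linear interpolation between order statistics
  (type 7, the default of mainstream statistical software); the choice
  matters for reported IQRs at small n and is fixed here for
  reproducibility.

# Reference-gene stability

Across a compendium of arrays (all on the log2 scale; matrices not
declared log2 are refused rather than silently transformed), each gene
gets its median, sample SD, and the implied *expected maximal fold
change* `2^(1.96 * SD)` — the fold range spanned by the central 95% of
its expression. The package computes this on any user-supplied or
simulated compendium matrix; selection filters (platform, genotype,
tissue) are metadata the user applies upstream.

Candidate normalizers are ranked by ascending SD (ties broken by gene id
for determinism). When a treated-vs-control experiment is available, each
candidate is additionally tested for a treatment effect (rank-sum), and
selection requires both stability (`sd_log2 <= sd_max`) and treatment
independence (`p >= p_floor`). The recommended normalizer is the most
stable gene the treatment leaves alone — stability in untreated samples
alone is necessary but not sufficient.

# Moderated differential expression

The microarray stage implements the standard two-group empirical-Bayes
chain from its published closed forms: quantile normalization (each
column's sorted values replaced by cross-column means of order
statistics; within-column ties receive the mean of the reference values
their rank range spans), per-gene pooled-variance fits, moment estimation
of the variance prior `(d0, s0^2)` on `log(s^2)` via digamma/trigamma
inversion, posterior variance shrinkage
`s~^2 = (d0*s0^2 + df*s^2) / (d0 + df)`, a t reference distribution on
`d0 + df` degrees of freedom, a B statistic (log posterior odds of
differential expression, prior DE proportion 0.01 by default, with the
coefficient-variance prior estimated from the top-ranked statistics), and
Benjamini–Hochberg step-up adjustment. The test suite pins the whole
chain against the reference Bioconductor implementation to near machine
precision on simulated data, and verifies calibration on nulls
(type-I error at nominal 5% within 3.5–6.5%, uniform p-values) and
recovery of a known `(d0, s0^2)` within 25% at 2000 genes.

Numerical edge cases: when the spread of log variances does not exceed
its pure-sampling expectation the moment estimate of `d0` is infinite and
every variance shrinks to the point-mass prior `exp(mean(log s^2))`
(matching the reference implementation's degenerate branch); quantile
normalization of a single sample is the identity with a warning.
Quantile normalization is exactly idempotent on tie-free data; with ties
the tie-averaging step can shift values slightly between passes, which is
why the idempotence test uses continuous data.

# The simulators and what they establish

`simulate_qpcr()` draws log2 expression
`x_ij = mu_j + beta_j * treated_i + a_i + eps_ij` and converts to cycles
via `Cq = c_j - x_ij / log2(E_j) + tau`. The per-animal effect `a_i`
enters every gene of a sample identically — exactly the nuisance
normalization exists to cancel — so the model makes "correct normalizer
implies unbiased effect estimate" provable: under shared efficiencies the
expected log2 ratio is `beta_target - beta_reference`, verified exactly on
noiseless data and to Monte-Carlo tolerance otherwise. Defaults: 13
animals per group (a typical rodent qPCR design), duplicate technical
replicates, animal-effect SD 0.3 and biological SD 0.2 in log2 units
(moderate inter-animal variability of the kind brain expression studies
show), technical SD 0.02 cycles (well inside the 0.05-cycle QC gate, so
QC exclusions are rare events rather than the norm), Cq intercept 28.
The default gene panel encodes the motivating scenario: a target with a
modest true downregulation (−0.2), one normalizer that responds more
strongly than the target (−0.5), and two clean normalizers — so the
default dataset reproduces the discordance pattern (apparent upregulation
against the responsive normalizer, downregulation or NS against clean
ones) out of the box.

`simulate_compendium()` draws each gene independently as
`N(median, sd^2)` across 80 arrays by default (a realistic size for a
tissue-restricted compendium query); its default panel pairs one very
stable candidate (SD 0.12) with common normalizers and a target in the
0.4–0.5 SD range. `simulate_de_matrix()` draws per-gene variances from a
scaled inverse chi-square `(d0_true, s0_sq_true)` — the same family the
moderation stage assumes — and plants symmetric ±logFC effects.

What passing tests show: the algebra and inference machinery are correct,
calibrated, and recover known parameters at the stated sizes. What they
do not show: real Cq data have heavier-than-Gaussian tails, plate and
batch effects beyond a balanced design, efficiency drift between runs,
and correlated biological noise across genes; none of these are in the
generative model, so simulation results bound optimism, not real-world
performance. Likewise, compendium genes are simulated independently,
while real arrays share global artifacts.

# Evidence curation choices

The packaged evidence table codes one experimental set-up per tissue ×
dose × duration × assay line within each study; this is the granularity
at which the outcome categories (31 non-significant, 15 significant
upregulation, 1 significant downregulation, 2 direction-without-statistics
of 49) are reproducible. Rows reporting an "increase" with no statistics
or n = 1 are coded `direction_only`. Entries reporting two starred values
for one dose range record both on one entry and count once. For the
affected-normalizer tally, tissue sub-lines of one experiment that share
study, assay, dose, regimen and normalizer reflect a *single
normalization decision* and are counted once — counting raw lines would
double-count one study that reports two brain regions from the same
cohort, blot and loading control. Normalizer matching is
case-insensitive through an explicit packaged alias table
(beta-actin → Actb, beta-tubulin → Tubb, ...), never fuzzy matching. A
checksum test pins the packaged transcription so the tallies cannot
drift silently.

# Problem sizes and runtime

The test suite runs entirely from generated data at deliberate desk
scale: exact-vs-brute-force enumeration up to 7 + 7 samples,
coverage simulation with 2000 replicates at 10 per group, sign-flip
recovery over 50 seeds at 13 per group, and moderated-t calibration on a
2000-gene null — sizes chosen to keep each stochastic check's Monte-Carlo
error far below the tolerance it asserts while the full suite stays in
the tens of seconds.

# Known limitations

* Absolute quantification (copy numbers), multi-plate batch correction
  beyond the balanced-design check, and melt-curve analysis are out of
  scope.
* The DE stage consumes pre-summarized log2 matrices; probe-level
  preprocessing (background correction, probe summarization) belongs
  upstream.
* The evidence module is a frozen transcription with tally operations,
  not a meta-analysis; it pools no effect sizes.
* Pairwise-stability algorithms of the geNorm/NormFinder family are
  intentionally not implemented; the stability module scores marginal
  variability and treatment independence only.
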