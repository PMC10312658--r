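---
title: "Detecting coupling between gene expression and alternative splicing"
author: "psicoupler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting coupling between gene expression and alternative splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psicoupler)
library(data.table)
```

## The model

Most human multi-exon genes are alternatively spliced, and a substantial
part of splicing happens co-transcriptionally: the elongating RNA
polymerase II complex both produces the transcript and shapes which exons
end up in it. `psicoupler` asks, for every cassette exon of a gene, whether
the exon's inclusion level is statistically coupled to how strongly the
gene is expressed.

The unit of analysis is a *cassette event*: an exon (identified by its
exact genomic coordinates) present in some transcripts of a gene and absent
from others. For event $e_i$ with inclusion-transcript set $I$ and
exclusion set $E$, and a transcripts-by-samples expression matrix, each
sample $s$ yields

$$\psi_s(e_i) = \frac{IT_{inc}}{IT_{inc} + IT_{excl}}, \qquad
  IT_{inc} = \sum_{t \in I} x_{ts},\; IT_{excl} = \sum_{t \in E} x_{ts},$$

the percent spliced in, undefined where the denominator is zero (such
samples are dropped pairwise, never imputed). Total gene expression is
$Y_s(g) = IT_{inc} + IT_{excl}$, the sum over all transcripts assigned to
the gene. Within each sample group (a tissue, donor, or dataset) we fit,
per event,

$$Y(g) \sim \beta_0 + \beta_1\, \psi(e_i)$$

by ordinary least squares on the linear expression scale, and correct the
two-sided slope p-values with Benjamini–Hochberg within the group. The
linear scale is deliberate: the package's slope-versus-mean diagnostic
(below) relies on the slope being commensurate with expression units.

Events are then labeled:

* **UHP** ("upregulated – high $\psi$"): adjusted $p \le 0.05$,
  $R^2 \ge 0.5$, 95th/5th expression percentile ratio $\ge 2$, and
  $\beta_1 > 0$ — higher inclusion predicts higher expression.
* **DHP**: the same with $\beta_1 < 0$.
* **TYPE0**: adjusted $p \ge 0.5$ with the percentile ratio $\ge 2$ and the
  variability filter passed — substantially variable expression with strong
  evidence of *no* coupling. This is a deliberately stringent null label:
  events with $0.05 < p_{adj} < 0.5$ remain INDETERMINATE.

Before any fitting, events must pass a variability filter: exon expression
of at least 1 unit in at least half the samples, mean exon expression of at
least 20 units, and a 95th/5th percentile ratio of at least 2. Weakly or
flatly expressed exons have little power to reveal coupling and are not
analyzed (they stay in the output, flagged `analyzed = FALSE`).

### Which 95/5 ratio the significance criteria use

The percentile-ratio criterion appears twice: in the variability filter
(exon-level expression) and again among the significance criteria, where
the phrase "the expression values" is ambiguous between exon-level and
gene-level expression. `psicoupler` computes **both** ratios and reports
them in every fit, and classification uses the **exon-level** ratio by
default (`ratio_scope = "exon"` in `default_thresholds()`). The reasons:

1. Read as a restatement of the filter criterion, the classification
   sentence refers to the same exon-level quantity.
2. The gene-level ratio conflates the coupling effect with baseline
   variability: under a multiplicative coupling model
   $Y = \mu_g (1 + b\psi)$ with $b = 1$ and $\psi$ spanning most of
   $(0, 1)$, the gene-level 95/5 ratio stays below 2 even for perfectly
   coupled events, so a gene-level criterion would reject exactly the
   events the method exists to find. The exon-level ratio
   ($IT_{inc} = Y\psi$ varies with $\psi$ itself) does not have this
   degeneracy.

Users who prefer the gene-level reading can set `ratio_scope = "gene"`;
both numbers are always in the output, so the choice is auditable after
the fact.

### Percentiles, ties, and degenerate inputs

Percentiles use linear interpolation between order statistics
(`quantile` type 7), recorded so results reproduce bit for bit. A 5th
percentile of zero makes the ratio undefined, which counts as a filter
fail. Fits with fewer than 3 usable samples, constant $\psi$, or constant
expression are flagged degenerate and become INDETERMINATE — they never
abort a run. Reported percentages are rounded to one decimal, half away
from zero.

## Downstream analyses

**Gene labels and consistency.** A gene is a UHP gene if it contains at
least one UHP exon and no DHP or type-0 exon (symmetrically for the other
classes); mixtures are MIXED. `consistency_report()` counts events labeled
UHP/DHP in two or more groups and how many conflict (UHP in one group, DHP
in another) — under a shared regulatory mechanism conflicts should be
absent, and on synthetic data with shared planted classes the package
requires exactly zero.

**Occupancy ratios.** `count_overlaps()` counts features sharing at least
one base pair with each target (half-open coordinates; abutting intervals
do not overlap — the same semantics as `bedtools intersect` defaults).
`chip_ratio_per_gene()` sums peak overlaps over experiments on each class's
exons within a gene, divides by the summed exon length of the class
("bindings per base pair"), and forms the focus/type-0 ratio; genes with
zero type-0 density are excluded and logged. Collapsed events contribute
the representative exon's coordinates. `proseq_intron_density()` computes
reads per base pair in each event's downstream intron and renormalizes
within gene so densities sum to 1. Where inclusion transcripts disagree
about the downstream intron, the first inclusion transcript in
lexicographic order defines it — a deterministic tie-break.

**Rank tests.** `rank_sum_test()` (Mann–Whitney) is exact — by
dynamic-programming enumeration over midranks, so ties are handled exactly
— when both groups have at most 20 observations, and uses the
tie-corrected normal approximation with continuity correction otherwise.
`ratio_vs_one_test()` applies the signed-rank test to log ratios (exact
midrank convolution for n ≤ 25); the log transform makes "ratio above 1"
and "ratio below 1" symmetric.

**Label-permutation enrichment.** For a binary hit matrix (one row per
gene, one column per binding-factor model) the statistic is
$\Delta = 100\,(\text{hit fraction in focus class}) -
100\,(\text{hit fraction in type-0 class})$ percentage points. Labels are
shuffled preserving class sizes; the empirical p-value is the fraction of
replicates with $\Delta' > \Delta$ (strict: ties count against
significance). Because $\Delta$ is discrete, the strict convention
undershoots by the tie mass; the returned `p_emp_inclusive`
($\Delta' \ge \Delta$) carries the distribution-free super-uniformity
guarantee and is what the calibration test checks. With at most 12 units
the full assignment space is enumerated instead. `motif_screen()` runs
every factor against UHP-vs-type0, DHP-vs-type0 and UHP-vs-DHP, applies
Bonferroni over the tests actually performed, and flags (rather than
drops) tests whose observed effect is below a reporting floor — absolute
$\Delta$ under 0.5 percentage points or under 5% of the larger proportion.
The floor is an observed-effect-size criterion: a per-replicate reading of
the exclusion rule would not define a scalar test, so the package applies
it to the observed $\Delta$ and keeps the flagged rows auditable.

**Isoform-level GO enrichment.** With isoforms classed UHP/DHP/TYPE0 (an
isoform is UHP if it is in the inclusion set of a UHP event),
`go_hypergeometric()` computes, per GO term, the upper-tail hypergeometric
probability of drawing at least the observed number of UHP isoforms among
the term's classed isoforms, skips terms with fewer than 5 UHP isoforms,
and Bonferroni-corrects over tested terms. Coverage is the UHP fraction of
the term's classed isoforms.

## The synthetic-data generator

Real multi-tissue expression compendia cannot ship with a package, so
every stage is exercised on generated data with known planted structure.
`sim_config()` fixes the study conditions; the generators are pure
functions of the seed, so all emitted files are byte-identical across
runs.

* Each gene carries one full transcript structure, one skip transcript
  lacking a random internal exon (the planted cassette event), and
  optionally extra copies of the full structure. Duplicating the full
  structure — rather than varying terminal exons — keeps the planted event
  set exactly equal to the discoverable event set under exact-coordinate
  cassette semantics.
* Per sample, $\psi \sim \mathrm{Uniform}(0.1, 0.9)$ and
  $Y = \mu_g (1 + b\psi)(1 + \varepsilon)$ for UHP events,
  $\mu_g (1 + b(1-\psi))(1 + \varepsilon)$ for DHP, and
  $\mu_g (1 + \varepsilon)$ for TYPE0, with
  $\varepsilon \sim N(0, \sigma)$ truncated at $-0.9$. Multiplicative,
  truncated noise keeps TPM-like values non-negative and gives the roughly
  constant coefficient of variation seen in expression data. $\psi$ is
  drawn first and $Y$ derived from it, matching the regression direction
  and making the planted slope interpretable as $\pm\mu_g b$.
* Defaults: $b = 1$, $\sigma = 0.1$, 200 genes, 400 samples per group,
  class proportions 0.3/0.3/0.4 (UHP/DHP/TYPE0; balanced power for every
  downstream analysis), $\mu_g \sim \mathrm{LogNormal}(\log 200,\, 0.6)$.
  The log-normal location keeps ~99.6% of genes above the mean-20
  variability filter while giving a several-fold spread of baseline means,
  which the slope-versus-mean diagnostic needs for leverage. Exon lengths
  are drawn from 80–300 bp and intron lengths around a few hundred bp,
  the order of magnitude of typical internal exons and short introns.
* Occupancy tracks are Poisson: peak counts per exon at a per-bp rate
  scaled by class (default multipliers 0.86 for UHP and 0.31 for DHP
  relative to type-0 — the occupancy contrast the method is designed to
  detect), read counts per downstream intron likewise (defaults 2.0/1.5).
  Hit matrices are Bernoulli with planted percentage-point differences;
  GO annotations plant focus-class over-representation at a set coverage.

What the generator does **not** emulate: read-level noise and mapping
bias, isoform-quantification uncertainty (RSEM posterior spread),
correlated samples (donors), batch effects, overlapping genes, alternative
5'/3' splice sites and intron retention, and non-uniform $\psi$
distributions. Passing tests therefore demonstrate that the statistical
machinery recovers planted effects under a clean generative model obeying
the method's assumptions — not that those assumptions hold in any given
real dataset.

## A worked run

```{r run, eval = FALSE}
cfg <- sim_config(n_genes = 200, n_samples = 400, seed = 1)
ann <- simulate_annotation(cfg)
expr <- simulate_expression(cfg, ann)
run <- run_group_analysis(parse_gtf(ann$gtf), expr$mat)
run$summary
#  n_events  n_quantified  n_analyzed  n_uhp  n_dhp  n_type0  n_indeterminate
#       200           200         200     55     58       53               34
```

Merging with the generator's truth table shows every planted UHP/DHP event
recovered with the correct sign and none flipped; regressing the fitted
slopes (sign-corrected for DHP) on the planted baseline means $\mu_g$
returns a coefficient statistically indistinguishable from the generative
value 1 — under the multiplicative model the slope *is* the baseline mean
times $b$.

## Problem sizes and numerical conventions

The reference synthetic study is 200 genes by 400 samples, which gives the
regression ~400 points per event and the recovery and calibration checks
~200 events; permutation tests in the test suite use 2,000–10,000
replicates, and production screens accept any `n_perm` (runs are
bit-reproducible given the seed). Exhaustive permutation is limited to 12
units (multinomial enumeration); exact rank tests switch to the normal
approximation above 20 (rank-sum) and 25 (signed-rank) observations.
Hypergeometric p-values come from `phyper`; BH adjustment from
`p.adjust` — both cross-checked in the test suite against independent
brute-force implementations.

## Known limitations

* Cassette membership is exact-coordinate: an exon truncated by an
  alternative splice site counts as a different unit, and the exclusion
  set includes transcripts that do not span the locus at all. This makes
  membership unambiguous at the cost of conflating "skipped" with "not
  covered".
* Only cassette events are modeled; alternative 5'/3' sites, intron
  retention and mutually exclusive exons are not distinct categories.
* The regression is a single-covariate OLS per event; no covariate
  adjustment, mixed effects, or donor-by-tissue structure.
* TYPE0 is an evidence-of-absence label driven by an adjusted-p floor; its
  yield depends on the surrounding p-value distribution through the BH
  adjustment, so the same event can be TYPE0 in one group and
  INDETERMINATE in another without any biological change.
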