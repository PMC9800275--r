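---
title: "Models and methods behind icbtox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind icbtox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icbtox)
```

`icbtox` implements the quantitative core of a melanoma immune
checkpoint blockade (ICB) toxicity analysis: clonality statistics on
adaptive immune receptor repertoires, B cell receptor (BCR) maturation
metrics, expression signature scoring, the lymphocyte-stability (LS)
clinical metric, and genotype/expression association with severe
immune-related adverse events (irAEs). This vignette documents the
models, the tunable parameters and their defaults, the numerical
conventions, and the design decisions that were genuinely open.

## Clonality metrics and depth-matched rarefaction

A repertoire sample is a set of clones — reads grouped under an identity
key. Two keys are supported because both conventions are in active use:
CDR3 nucleotide sequence alone (`cdr3_only`), and CDR3 plus V and J
gene (`cdr3_vj`, the default). Gini-style unevenness analyses typically
use the CDR3-only definition, occupancy analyses the V/J-qualified one;
`aggregate_clones()` exposes both rather than assuming either.

The **Gini index** of clone sizes is

$$G = \frac{\sum_{i}\sum_{j} |x_i - x_j|}{2 n^2 \bar{x}},$$

computed via the equivalent sorted form
$G = \sum_i (2i - n - 1)\,x_{(i)} / (n \sum_i x_i)$ in
$O(n \log n)$. Conventions: a single clone returns 0 (a one-clone
repertoire is trivially even in this formulation), an all-zero vector is
an undefined-metric error, and the statistic is scale invariant, so
counts and frequencies agree. The test suite holds the sorted form to
the brute-force pairwise definition at $10^{-12}$.

**Occupancy bands** partition clones by repertoire frequency: small
(<0.05%), large (>0.5%), mid otherwise. Both edges are strict
inequalities — a clone at exactly 0.5% of the repertoire is mid, not
large — because the band definitions are phrased as strict inequalities
and a deterministic rule for boundary mass avoids platform-dependent
behaviour. Band fractions are read-weighted and sum to 1 whenever the
sample has reads.

**Rarefaction.** Diversity statistics are depth-biased: deeper
sequencing finds more rare clones and depresses Gini. `rarefied_metric()`
therefore takes the minimum total read count across the input samples
as the common depth, draws that many reads with replacement from each
sample's empirical clone distribution (a multinomial draw), recomputes
the metric with zero-count clones dropped, and repeats `n_iter = 1000`
times, reporting the mean, SD and 2.5/97.5 percentile interval.
Percentile rather than normal-approximation intervals are used because
bootstrap Gini distributions are visibly skewed at low depth. Two
deliberate choices:

* **Every sample is resampled, including the minimum-depth one.** An
  alternative convention resamples only the deeper samples and leaves
  the anchor sample fixed. Uniform resampling was chosen so every
  estimate carries comparable bootstrap variance; for the anchor sample
  the point estimate is unchanged in expectation.
* **Per-sample RNG streams** are derived from the global seed and a hash
  of the sample id, so results are independent of sample ordering and
  stable under parallel or incremental execution.

## BCR maturation metrics

The mutation percentage per chain is
$100 \cdot \sum(\text{subs} + \text{ins} + \text{del}) / \sum(\text{aligned length})$,
with mutation counts taken once per unique clone (not read-weighted).
The denominator is the *sum of per-clone aligned lengths* — "total BCR
length" read as a per-base divergence rate whose denominator grows with
the clone count. The alternative reading (a fixed receptor length per
clone) is exposed as `denominator = "mean_length"` for sensitivity
analysis; at realistic length spreads the two differ by well under the
between-sample variation.

IGHC usage is the percentage of IGH clones (or reads) carrying each
constant-gene segment, with the denominator restricted to clones that
have a constant-region call; clones without one are excluded and their
count reported, never silently dropped. The IGHD-expressing clone
percentage is by construction identical to the IGHD entry of clone-unit
usage, and the test suite asserts that identity on arbitrary tables.

## Expression normalization and scoring

Size factors use the median-of-ratios estimator: with $m$ samples and
reference genes $g$ (genes with nonzero counts in all samples),

$$s_j = \operatorname{median}_g \frac{c_{gj}}{(\prod_{k=1}^m c_{gk})^{1/m}}.$$

For exactly proportional columns $c_j \cdot b_g$ this reduces to
$c_j / \text{geomean}(c)$, which the tests verify to $10^{-12}$, and on
random matrices the estimate matches the reference implementation in
DESeq2 (used in the tests as an independent cross-check only).

Signature scores are geometric means over the gene set on the
normalized layer, $\exp(\text{mean}_g \ln(v_{gj} + \epsilon))$. The
pseudocount $\epsilon$ defaults to 1 on the normalized scale for log
and geometric operations (and 0 raises a domain error on zeros): zero
handling is not standardized for this statistic, so it is an explicit,
documented parameter rather than a hidden constant. The canonical
50-gene mitotic signature comes from external single-cell work and is
not hard-coded; gene sets load from GMT files (`read_gmt()`), and
synthetic runs use generator-designated signature genes.

`group_effect()` deliberately covers only targeted two-group
comparisons (difference of group means of $\log_2(v + \epsilon)$, with
optional linear covariate adjustment); it is not a differential
expression engine, and no genome-wide Wald testing is reimplemented.
Enrichment uses the one-tailed hypergeometric upper tail
$P(X \ge k)$ with fold change
$(k/|\text{hits}|) / (|\text{annotation}|/N)$.

## Lymphocyte stability

The pre-treatment count is the observation *closest to* treatment start
within $[-30, 0]$ days; day 0 qualifies, since bloods drawn immediately
before the first infusion are clinically pre-treatment. The
post-treatment count is the *first* observation in $[21, 49]$ days.
Patients missing either window are excluded with machine-readable
reason codes (`no_pre`, `no_post`) — missingness is an analysis outcome,
not an error. Stability is `pct_change > -20`: a fall of exactly 20% is
unstable, because stability is defined as an increase or a fall
strictly below 20%. When two records share a day, the later-entered one
wins and the rule is deterministic under row shuffling.

## Association models

`odds_ratio_2x2()` reports the sample odds ratio $ad/bc$ with a Woolf
(log-normal) 95% CI and the two-sided Fisher exact p-value
(`stats::fisher.test`; the tests pin it against an explicit
`choose()`-based enumeration of the conditional hypergeometric
distribution for all small-margin tables). Under the Haldane rule
(default) 0.5 is added to every cell when any cell is zero; `none`
makes zero cells an error. Woolf CIs for raw 2×2 tables and Wald CIs
for adjusted models are both reported because published cohort analyses
often present a GLM-derived OR next to a Fisher p-value; emitting both
removes the ambiguity.

`logistic_association()` is a maximum-likelihood `glm(binomial)` fit
with the exposure coefficient exponentiated. Perfect or quasi-perfect
separation is detected (fitted probabilities pinned at 0/1, or
exploding coefficient/SE) and raised as an explicit diagnostic. With a
binary exposure and no covariates the estimate equals the 2×2 sample
odds ratio to $10^{-6}$, which the tests assert — the saturated logistic
model's MLE is the sample OR.

The mediation-style contrast follows the fixed-effect approximation:
the genotype coefficient is estimated with and without B cell *IL7*
expression as a covariate (always adjusting for ICB type), and
mediation manifests as shrinkage of the genotype term. A random-effects
mixed-model formulation exists for this analysis in the literature; the
fixed-effect logistic adjustment was chosen because the cohort design
here has one observation per patient, making random effects
unidentifiable and the fixed-effect model the exact analogue.

## The synthetic cohort generator

The generator exists so that every downstream stage can be exercised,
calibrated and regression-tested without the access-controlled patient
data it emulates. Its defaults are the study conditions of the
motivating cohort; where the literature prints no value, a default was
chosen once on domain grounds and documented here.

| Parameter | Default | Basis |
|---|---|---|
| `n_patients` | 214 | cohort size (98 sICB / 116 cICB) |
| `maf` | 0.074 | risk-allele minor allele frequency |
| `carrier_irae_or` | 2.24 | published carrier irAE odds ratio |
| `base_irae_rate` | 0.20 | plausible severe-irAE rate for a non-carrier on sICB; yields non-degenerate 2×2 tables at n = 214 |
| `cicb_irae_or` | 4 | combination therapy carries several-fold the toxicity odds of single-agent therapy |
| `eqtl_log2_shift` | 0.57 | patient-vs-healthy B cell *IL7* shift (8.87 − 8.30 log2) |
| `carrier_il7_shift`, `il7_sd` | 0.6, 0.4 | within-patient carrier eQTL effect of the same order as the patient-state shift, with dispersion making it clearly resolvable at cohort scale |
| `powerlaw_alpha` | 1.5 | bounded Pareto clone-size shape on [1, 10⁴]; reproduces heavy-tailed occupancy with a realistic large-clone fraction |
| `lymph_meanlog`, `lymph_sdlog` | log(1.82), 0.456 | log-normal matching the printed pre-treatment median 1.82 and IQR 1.26–2.33 (sdlog = log(2.33/1.26)/(2·0.6745)) |
| `ls_ratio_noncarrier`, `ls_ratio_carrier` | 0.85, 1.0 | non-carriers fall post-treatment (1.82 → ≈1.52 at the median), carriers hold steady |
| `bcr_mut_rate`, `bcr_mut_carrier_mult` | 0.02/nt, 1.5 | few-percent germline divergence typical of mutated BCR repertoires; carriers elevated |
| `ighd_carrier_mult` | 0.5 | halved IGHD isotype probability in carriers (reduced naive fraction) |

Genotype doses are Hardy–Weinberg at the configured MAF. irAE outcomes
follow $\operatorname{logit}(p) = \operatorname{logit}(\text{base}) +
\log(\text{OR}_\text{carrier})\cdot\text{carrier} +
\log(\text{OR}_\text{cICB})\cdot\text{cICB}$. In `via_il7` mode the
carrier term is replaced by
$\frac{\log \text{OR}_\text{carrier}}{\Delta_\text{IL7}}\,(\text{IL7} - \mu_0)$,
so the genotype effect flows entirely through measured IL7 — genotype
and outcome are conditionally independent given IL7, which is the
structure the adjusted regression is meant to detect — while the
linear-predictor contrast between a mean carrier and a mean non-carrier
is unchanged. Repertoires draw clone weights from a bounded Pareto law
(inverse-CDF sampling) and allocate reads multinomially, so read totals
are conserved exactly. Counts are negative binomial
($\text{var} = \mu + \phi\mu^2$, $\phi = 0.15$) with log-normal library
size factors so normalization has real work to do. All generators
derive independent RNG streams from one global seed via a polynomial
string hash of a stage/sample tag, giving byte-identical outputs per
configuration and order-independence across samples.

**What the generator does not emulate:** VDJ recombination biology and
hypermutation hotspots (CDR3 strings are random nucleotides over fixed
V/J vocabularies), shared clones between patients, batch structure and
GC bias in expression, informative missingness in blood-count
scheduling, and any survival structure. Passing tests therefore
demonstrate that the estimators recover the statistical structure they
target — not that they are robust to every artefact of real repertoire
or expression data.

## Numerical conventions and degenerate inputs

* Band edges and the large-clone threshold are strict inequalities;
  boundary mass goes mid.
* A fall of exactly 20% in LS is unstable; day 0 is pre-treatment.
* Empty repertoires, empty chains, missing constant-region calls and
  missing LS windows are reported outcomes (flags, reason codes,
  excluded counts), not errors; truly undefined statistics (all-zero
  Gini input, zero-margin 2×2 tables, aligned length 0) are typed
  errors.
* c_call majority within a clone is read-weighted with a lexicographic
  tie-break, making aggregation deterministic.
* MiXCR-style multi-hit gene strings take the first (top-score) hit
  with allele and score stripped; records whose V and J calls imply
  different chains are quarantined to a rejects table with line
  numbers rather than repaired.

## Interfaces

All stages are plain R functions over tibbles and matrices;
`run_config()`/`run_pipeline()` orchestrate them end to end from a
single configuration (synthetic or file inputs) and write a TSV/JSON
bundle plus a manifest carrying the seed and a configuration hash —
that manifest is sufficient to reproduce a run byte-for-byte. The
package intentionally ships no shell subcommand wrapper: for an
analysis library the functions, the pipeline entry point and
`scripts/acceptance.R` are the interface.

## Problem sizes and limitations

The simulation-backed checks in the test suite use cohorts of 40–214
patients, repertoires of 100–2,000 clones at 2,000–50,000 reads, and
100–500 replicate cohorts per property; these sizes were chosen so each
statistical check has clear resolving power while the whole suite stays
fast enough to run routinely.

One limitation deserves emphasis. At the default cohort conditions
(n = 214, MAF 7.4% — about 30 carriers — and a true carrier OR of
2.24), the unadjusted carrier log-odds-ratio is estimated with a
standard error near 0.45. In a meaningful minority of simulated
cohorts the unadjusted estimate is therefore close to zero by sampling
noise alone, and per-cohort attenuation (|adjusted| < |unadjusted|
under IL7 adjustment) cannot occur even though the generating model is
fully mediated; the per-cohort attenuation rate plateaus around 85%
regardless of how strongly the mediator is coupled. The aggregate
signature of mediation — the adjusted coefficient distribution
collapsing toward zero while the unadjusted one centres near
log(2.24) — is robust and is what the unit tests assert. Detecting
mediation reliably per cohort at this effect size simply needs more
carriers than the emulated cohort contains.
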