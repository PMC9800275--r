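# icbtox

Repertoire, expression and toxicity association analysis for immune
checkpoint blockade (ICB) cohorts.

Severe immune-related adverse events (irAEs) limit ICB therapy in
metastatic melanoma. Genetic risk at an *IL7*-locus SNP, B cell *IL7*
expression, peripheral lymphocyte dynamics and CD8⁺ T cell clonality all
inform who develops toxicity and who benefits. `icbtox` packages the
quantitative machinery needed to run that style of analysis end to end,
for analysts working with MiXCR-exported or AIRR-standard clonotype
tables, bulk RNA-seq count matrices and routine clinical blood counts:

* **Depth-matched clonality metrics** — Gini index
  `G = Σᵢⱼ|xᵢ − xⱼ| / (2n²x̄)` of clone sizes, clone-size occupancy bands
  (small <0.05%, large >0.5% of the repertoire) and large-clone counts,
  each computed under bootstrap rarefaction: every sample is resampled
  (multinomially, 1,000 iterations by default) down to the minimum read
  depth across samples so the statistics are comparable between samples
  of different sequencing depth.
* **BCR maturation metrics** — germline-divergent mutation percentage per
  chain, `100 · Σ(subs + ins + del) / Σ(aligned length)`, IGHC isotype
  usage per clones or per reads, and the percentage of IGHD-expressing
  (unswitched, naive-like) clones.
* **Expression scoring** — median-of-ratios size factors
  `sⱼ = medianᵍ count(g,j)/(Πⱼ count(g,j))^(1/m)`, geometric-mean
  signature scores (e.g. a 50-gene mitotic signature), targeted log2
  group-effect estimates, and one-tailed hypergeometric enrichment.
* **Lymphocyte stability (LS)** — pre-treatment count (closest to
  treatment start within −30…0 days) versus the first count 21–49 days
  after start; a fall ≥20% is "unstable".
* **Toxicity association** — 2×2 odds ratios (`ad/bc`, Woolf CI, Fisher
  exact p) and covariate-adjusted logistic regression, including the
  mediation-style contrast of a genotype coefficient with and without
  B cell *IL7* as covariate.
* **A synthetic cohort generator** — Hardy–Weinberg genotypes at
  configurable MAF, logistic irAE outcomes with a configurable carrier
  odds ratio, power-law TCR/BCR repertoires, negative-binomial count
  matrices with an *IL7* eQTL, and log-normal lymphocyte series — so the
  whole pipeline is testable without access-controlled patient data.

## Worked example

```r
library(icbtox)

cfg    <- sim_config(n_patients = 214, seed = 20)  # 98 sICB / 116 cICB, MAF 7.4%
cohort <- gen_cohort(cfg)

# Genotype ~ irAE association, unadjusted and ICB-type adjusted
tab <- table(carrier = cohort$carrier, irae = cohort$irae)[2:1, 2:1]
odds_ratio_2x2(unclass(tab))
#>   estimate ci_lo ci_hi p_value method     n
#> 1     2.98  1.29  6.88  0.0141 fisher   214
logistic_association(cohort$irae, cohort$carrier,
                     data.frame(cicb = cohort$icb_type == "cICB"))
#>   estimate ci_lo ci_hi p_value method           n log_or    se
#> 1     2.18 0.868  5.45  0.0975 glm_binomial   214  0.777 0.469

# Paired pre/post repertoires, rarefied to a common depth
pre  <- aggregate_clones(gen_repertoire(cfg, skew = 0,   sample_id = "C1"),
                         "cdr3_only")
post <- aggregate_clones(gen_repertoire(cfg, skew = 0.6, sample_id = "C2"),
                         "cdr3_only")
res <- rarefied_metric(list(C1 = pre, C2 = post), "gini",
                       n_iter = 1000, seed = 20)
res
#>   sample_id metric point      sd ci_lo ci_hi rarefied_depth n_iter
#> 1 C1        gini   0.508 0.00360 0.502 0.516          20000   1000
#> 2 C2        gini   0.856 0.00214 0.851 0.860          20000   1000
gini_delta(res[1, ], res[2, ])
#> [1] 0.3473182
```

The 2×2 odds ratio (2.98) is the raw carrier-versus-non-carrier irAE
odds ratio in this simulated cohort; the logistic estimate (2.18)
adjusts it for combination-versus-single-agent treatment and comes with
a Wald confidence interval. The rarefied Gini values say the
post-treatment repertoire is far more clonally uneven (0.856 vs 0.508
at a common depth of 20,000 reads), a ΔGini of +0.347 with bootstrap
uncertainty small enough to make the contrast unambiguous.

The same stages run end to end, from either synthetic or file inputs,
via:

```r
run_pipeline(run_config(mode = "synthetic", sim = cfg,
                        out_dir = "runs/demo"))
```

which writes per-sample metric TSVs, an association table and a
manifest (seed, config hash) sufficient to reproduce the run exactly.

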