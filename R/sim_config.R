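#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the synthetic-data module into one validated
#' object. Defaults reproduce the study conditions of the melanoma ICB
#' cohort the package emulates: 214 patients (98 single-agent, 116
#' combination ICB), risk-allele minor allele frequency 7.4%, a carrier
#' odds ratio of 2.24 for severe immune-related adverse events (irAEs),
#' and a patient B cell *IL7* log2-expression shift of 0.57 over healthy
#' donors (8.30 to 8.87).
#'
#' @param n_patients Number of patients in the cohort.
#' @param maf Minor (risk) allele frequency; genotype doses are drawn under
#'   Hardy-Weinberg equilibrium at this frequency.
#' @param carrier_irae_or True odds ratio for severe irAE in risk-allele
#'   carriers (dose >= 1) versus non-carriers.
#' @param base_irae_rate irAE probability for a non-carrier on single-agent
#'   ICB (the logistic model's baseline).
#' @param cicb_irae_or Odds ratio for combination versus single-agent ICB,
#'   reflecting the substantially higher toxicity of combination therapy.
#' @param sicb_fraction Fraction of patients on single-agent ICB.
#' @param clone_count Number of distinct clones in a simulated repertoire.
#' @param depth Sequencing reads per repertoire sample.
#' @param powerlaw_alpha Shape of the bounded Pareto clone-size law; larger
#'   values give flatter (more even) repertoires.
#' @param eqtl_log2_shift Patient-versus-healthy shift in B cell *IL7*
#'   log2 expression (default 0.57 = 8.87 - 8.30).
#' @param carrier_il7_shift Additional *IL7* log2 shift in risk-allele
#'   carriers relative to non-carrier patients.
#' @param il7_sd Between-patient standard deviation of *IL7* log2 expression.
#' @param healthy_il7_log2 Mean healthy-donor B cell *IL7* log2 expression.
#' @param nb_dispersion Negative-binomial dispersion for simulated counts
#'   (variance = mu + dispersion * mu^2).
#' @param mediation_mode `"direct"`: genotype acts on irAE risk directly.
#'   `"via_il7"`: the carrier effect is carried entirely by `il7_expr`
#'   (genotype -> IL7 -> irAE), so genotype and irAE are conditionally
#'   independent given IL7.
#' @param ls_ratio_noncarrier,ls_ratio_carrier Central post/pre lymphocyte
#'   count ratio for non-carriers and carriers (non-carriers fall after
#'   single-agent ICB, carriers hold steady).
#' @param lymph_meanlog,lymph_sdlog Log-normal parameters of the
#'   pre-treatment lymphocyte count (10^9 cells/L); defaults reproduce a
#'   median of 1.82 with interquartile range 1.26-2.33.
#' @param bcr_mut_rate Baseline per-nucleotide BCR mutation rate.
#' @param bcr_mut_carrier_mult Multiplier on the mutation rate in carriers.
#' @param ighd_carrier_mult Multiplier (<1) on the IGHD isotype probability
#'   in carriers (reduced naive, unswitched B cells).
#' @param seed Global integer seed; all generators derive independent
#'   streams from it, so one config is fully reproducible.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(n_patients = 50, seed = 1)
#' cohort <- gen_cohort(cfg)
#' @export
sim_config <- function(n_patients = 214L,
                       maf = 0.074,
                       carrier_irae_or = 2.24,
                       base_irae_rate = 0.20,
                       cicb_irae_or = 4,
                       sicb_fraction = 98 / 214,
                       clone_count = 1000L,
                       depth = 20000L,
                       powerlaw_alpha = 1.5,
                       eqtl_log2_shift = 0.57,
                       carrier_il7_shift = 0.6,
                       il7_sd = 0.4,
                       healthy_il7_log2 = 8.30,
                       nb_dispersion = 0.15,
                       mediation_mode = c("direct", "via_il7"),
                       ls_ratio_noncarrier = 0.85,
                       ls_ratio_carrier = 1.0,
                       lymph_meanlog = log(1.82),
                       lymph_sdlog = 0.456,
                       bcr_mut_rate = 0.02,
                       bcr_mut_carrier_mult = 1.5,
                       ighd_carrier_mult = 0.5,
                       seed = 1L) {
  mediation_mode <- match.arg(mediation_mode)
  assert_count(n_patients, "n_patients")
  assert_fraction(maf, "maf")
  assert_fraction(base_irae_rate, "base_irae_rate")
  assert_fraction(sicb_fraction, "sicb_fraction")
  assert_positive(carrier_irae_or, "carrier_irae_or")
  assert_positive(cicb_irae_or, "cicb_irae_or")
  assert_count(clone_count, "clone_count")
  assert_count(depth, "depth")
  assert_positive(powerlaw_alpha, "powerlaw_alpha")
  assert_positive(nb_dispersion, "nb_dispersion")
  assert_positive(il7_sd, "il7_sd")
  assert_positive(ls_ratio_noncarrier, "ls_ratio_noncarrier")
  assert_positive(ls_ratio_carrier, "ls_ratio_carrier")
  assert_positive(bcr_mut_rate, "bcr_mut_rate", strict = FALSE)
  assert_positive(bcr_mut_carrier_mult, "bcr_mut_carrier_mult")
  assert_positive(ighd_carrier_mult, "ighd_carrier_mult", strict = FALSE)
  seed <- assert_count(seed, "seed", min = 0L)

  cfg <- list(
    n_patients = as.integer(n_patients), maf = maf,
    carrier_irae_or = carrier_irae_or, base_irae_rate = base_irae_rate,
    cicb_irae_or = cicb_irae_or, sicb_fraction = sicb_fraction,
    clone_count = as.integer(clone_count), depth = as.integer(depth),
    powerlaw_alpha = powerlaw_alpha, eqtl_log2_shift = eqtl_log2_shift,
    carrier_il7_shift = carrier_il7_shift, il7_sd = il7_sd,
    healthy_il7_log2 = healthy_il7_log2, nb_dispersion = nb_dispersion,
    mediation_mode = mediation_mode,
    ls_ratio_noncarrier = ls_ratio_noncarrier,
    ls_ratio_carrier = ls_ratio_carrier,
    lymph_meanlog = lymph_meanlog, lymph_sdlog = lymph_sdlog,
    bcr_mut_rate = bcr_mut_rate,
    bcr_mut_carrier_mult = bcr_mut_carrier_mult,
    ighd_carrier_mult = ighd_carrier_mult,
    seed = seed
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}

#' Read or write a simulation configuration as YAML or JSON
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `read_sim_config()` returns a validated [sim_config()];
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param cfg A [sim_config()] object.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  vals <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path, precision = 15L)
  }
  invisible(path)
}
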