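#' Simulate a genotyped ICB cohort
#'
#' Draws a patient cohort with risk-locus genotype doses under
#' Hardy-Weinberg equilibrium, ICB treatment type, per-patient B cell
#' *IL7* log2 expression, and a severe-irAE outcome from a logistic model.
#'
#' In `direct` mode the carrier effect enters the irAE model as a genotype
#' term: `logit(p) = logit(base) + log(carrier_irae_or) * carrier +
#' log(cicb_irae_or) * cICB`. In `via_il7` mode the genotype term is
#' replaced by an IL7 term scaled so that the *marginal* carrier odds
#' ratio is unchanged, making genotype and irAE conditionally independent
#' given IL7 — the mediation structure the downstream adjusted regression
#' is designed to detect.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `patient_id`, `genotype_dose` (0/1/2),
#'   `carrier`, `icb_type` (`"sICB"`/`"cICB"`), `irae`, `start_date`,
#'   `il7_expr` (log2 normalized B cell *IL7*).
#' @examples
#' cohort <- gen_cohort(sim_config(n_patients = 100, seed = 7))
#' table(cohort$carrier, cohort$irae)
#' @export
gen_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_patients
  with_seed(derive_seed(cfg$seed, "cohort"), {
    q <- cfg$maf
    dose_probs <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    genotype_dose <- sample(0:2, n, replace = TRUE, prob = dose_probs)
    carrier <- genotype_dose > 0

    icb_type <- ifelse(runif(n) < cfg$sicb_fraction, "sICB", "cICB")

    il7_mu <- cfg$healthy_il7_log2 + cfg$eqtl_log2_shift +
      cfg$carrier_il7_shift * carrier
    il7_expr <- rnorm(n, mean = il7_mu, sd = cfg$il7_sd)

    eta0 <- qlogis(cfg$base_irae_rate) +
      log(cfg$cicb_irae_or) * (icb_type == "cICB")
    noncarrier_level <- cfg$healthy_il7_log2 + cfg$eqtl_log2_shift
    eta <- if (cfg$mediation_mode == "via_il7") {
      # carrier effect flows entirely through measured IL7
      beta_il7 <- log(cfg$carrier_irae_or) / cfg$carrier_il7_shift
      eta0 + beta_il7 * (il7_expr - noncarrier_level)
    } else {
      eta0 + log(cfg$carrier_irae_or) * carrier
    }
    irae <- runif(n) < plogis(eta)

    start_date <- as.Date("2019-01-01") + sample(0:730, n, replace = TRUE)

    tibble::tibble(
      patient_id = sprintf("PT%04d", seq_len(n)),
      genotype_dose = as.integer(genotype_dose),
      carrier = carrier,
      icb_type = icb_type,
      irae = irae,
      start_date = start_date,
      il7_expr = il7_expr
    )
  })
}

#' Simulate longitudinal lymphocyte counts around treatment start
#'
#' Generates, for each patient, a short series of blood lymphocyte counts
#' (10^9 cells/L) at integer day offsets spanning roughly [-60, +60]
#' relative to treatment start. Pre-treatment counts are log-normal and
#' calibrated so their median and interquartile range match routine
#' clinical values (median 1.82, IQR 1.26-2.33 at the defaults).
#' Post-treatment counts are the patient's pre-treatment level times a
#' post/pre ratio centred at `ls_ratio_carrier` for risk-allele carriers
#' and `ls_ratio_noncarrier` for non-carriers, so the cohort reproduces
#' the genotype-dependent lymphocyte-stability contrast.
#'
#' Not every patient is guaranteed observations inside the clinical
#' selection windows; missingness is a legitimate downstream outcome.
#'
#' @param cfg A [sim_config()].
#' @param cohort A cohort from [gen_cohort()].
#' @return A tibble with `patient_id`, `day_offset` (integer, strictly
#'   increasing within patient), `lymphocyte_count`.
#' @export
gen_lymphocyte_series <- function(cfg, cohort) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(cohort) == 0L) {
    abort("`cohort` must be non-empty", class = "icbtox_parameter_error")
  }
  with_seed(derive_seed(cfg$seed, "lymphocytes"), {
    out <- lapply(seq_len(nrow(cohort)), function(i) {
      pid <- cohort$patient_id[i]
      ratio0 <- if (cohort$carrier[i]) cfg$ls_ratio_carrier else cfg$ls_ratio_noncarrier
      # patient-level baseline and realised post/pre ratio
      base <- rlnorm(1, meanlog = cfg$lymph_meanlog, sdlog = cfg$lymph_sdlog)
      ratio <- ratio0 * rlnorm(1, 0, 0.15)
      n_pre <- sample(1:3, 1)
      n_post <- sample(2:4, 1)
      pre_days <- sort(sample(-60:0, n_pre))
      post_days <- sort(sample(10:60, n_post))
      days <- c(pre_days, post_days)
      level <- ifelse(days <= 0, base, base * ratio)
      counts <- level * rlnorm(length(days), 0, 0.08)
      tibble::tibble(patient_id = pid, day_offset = as.integer(days),
                     lymphocyte_count = counts)
    })
    dplyr::bind_rows(out)
  })
}
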