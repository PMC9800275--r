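# Clinical association: lymphocyte-stability (LS) windows and dichotomy,
# 2x2 odds ratios with Fisher exact tests, covariate-adjusted logistic
# regression for the genotype/IL7/irAE mediation logic.

#' Select the pre/post lymphocyte observation pair per patient
#'
#' Applies the clinical time windows: the pre-treatment count is the
#' observation closest to treatment start within `[-30, 0]` days (day 0
#' qualifies — bloods drawn immediately before the first infusion are
#' clinically pre-treatment); the post-treatment count is the *first*
#' observation at least 21 and at most 49 days after start. Patients
#' missing either window are excluded with a reason code rather than an
#' error. When two records share a day, the later-entered record wins.
#'
#' @param series Tibble with `patient_id`, `day_offset`,
#'   `lymphocyte_count` (any row order; selection is order-independent
#'   apart from the same-day tie rule).
#' @param pre_window,post_window Integer day windows (inclusive).
#' @return Tibble, one row per patient: `patient_id`, `pre_day`,
#'   `pre_count`, `post_day`, `post_count`, `missing_reason` (`NA` when
#'   both found, else `"no_pre"`, `"no_post"` or `"no_pre;no_post"`).
#' @export
select_lymphocyte_pair <- function(series, pre_window = c(-30L, 0L),
                                   post_window = c(21L, 49L)) {
  needed <- c("patient_id", "day_offset", "lymphocyte_count")
  missing_cols <- setdiff(needed, names(series))
  if (length(missing_cols) > 0) {
    abort(sprintf("series missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "icbtox_parameter_error")
  }
  out <- lapply(split(series, series$patient_id), function(s) {
    # same-day duplicates: keep the later-entered (last) record
    s <- s[!duplicated(s$day_offset, fromLast = TRUE), , drop = FALSE]
    s <- s[order(s$day_offset), , drop = FALSE]
    pre_ok <- s$day_offset >= pre_window[1] & s$day_offset <= pre_window[2]
    post_ok <- s$day_offset >= post_window[1] & s$day_offset <= post_window[2]
    pre_i <- if (any(pre_ok)) max(which(pre_ok)) else NA_integer_
    post_i <- if (any(post_ok)) min(which(post_ok)) else NA_integer_
    reason <- paste(c(if (is.na(pre_i)) "no_pre",
                      if (is.na(post_i)) "no_post"), collapse = ";")
    tibble::tibble(
      patient_id = s$patient_id[1],
      pre_day = if (is.na(pre_i)) NA_integer_ else s$day_offset[pre_i],
      pre_count = if (is.na(pre_i)) NA_real_ else s$lymphocyte_count[pre_i],
      post_day = if (is.na(post_i)) NA_integer_ else s$day_offset[post_i],
      post_count = if (is.na(post_i)) NA_real_ else s$lymphocyte_count[post_i],
      missing_reason = if (nzchar(reason)) reason else NA_character_
    )
  })
  dplyr::bind_rows(out)
}

#' Lymphocyte stability (LS)
#'
#' Compares the pre-treatment lymphocyte count with the first count in
#' the post-treatment window. A patient is *stable* if the count
#' increased or fell by less than 20%; a fall of 20% or more (including
#' exactly 20%) is unstable, since stability requires a fall strictly
#' below 20%.
#'
#' @param pairs Output of [select_lymphocyte_pair()] (rows with a
#'   `missing_reason` are passed through with `NA` metrics), or any
#'   tibble with `pre_count`/`post_count`.
#' @return The input with added `delta` (post - pre), `pct_change`
#'   (100 * delta / pre) and `stable` (logical).
#' @examples
#' p <- tibble::tibble(patient_id = "x", pre_count = 1.82, post_count = 1.52)
#' lymphocyte_stability(p)[, c("pct_change", "stable")]  # -16.5%, stable
#' @export
lymphocyte_stability <- function(pairs) {
  complete <- !is.na(pairs$pre_count) & !is.na(pairs$post_count)
  if (any(pairs$pre_count[complete] <= 0)) {
    abort("pre-treatment lymphocyte count must be positive",
          class = "icbtox_parameter_error")
  }
  pairs$delta <- pairs$post_count - pairs$pre_count
  pairs$pct_change <- 100 * pairs$delta / pairs$pre_count
  pairs$stable <- pairs$pct_change > -20
  pairs
}

#' Odds ratio and Fisher exact test for a 2x2 table
#'
#' Sample odds ratio `ad / bc` with a Woolf (log-normal) 95% confidence
#' interval and the two-sided Fisher exact p-value. Under the Haldane
#' rule (default) 0.5 is added to every cell whenever any cell is zero;
#' with `zero_rule = "none"` a zero cell is an error.
#'
#' @param table 2x2 matrix of non-negative integer counts; rows index
#'   exposure (exposed first), columns outcome (event first).
#' @param zero_rule `"haldane"` or `"none"`.
#' @param conf_level Confidence level for the Woolf interval.
#' @return Tibble: `estimate` (OR), `ci_lo`, `ci_hi`, `p_value`,
#'   `method` (`"fisher"`), `n`.
#' @examples
#' odds_ratio_2x2(matrix(c(6, 20, 24, 164), 2))  # OR 2.05
#' @export
odds_ratio_2x2 <- function(table, zero_rule = c("haldane", "none"),
                           conf_level = 0.95) {
  zero_rule <- match.arg(zero_rule)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0) ||
      any(table != round(table))) {
    abort("`table` must be a 2x2 matrix of non-negative integer counts",
          class = "icbtox_parameter_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("2x2 table has a zero margin; odds ratio undefined",
          class = "icbtox_parameter_error")
  }
  cells <- table
  if (any(cells == 0)) {
    if (zero_rule == "none") {
      abort("zero cell with zero_rule = 'none'",
            class = "icbtox_parameter_error")
    }
    cells <- cells + 0.5
  }
  or <- (cells[1, 1] * cells[2, 2]) / (cells[1, 2] * cells[2, 1])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- fisher.test(table)$p.value
  tibble::tibble(
    estimate = or,
    ci_lo = exp(log(or) - z * se),
    ci_hi = exp(log(or) + z * se),
    p_value = p,
    method = "fisher",
    n = sum(table)
  )
}

#' Covariate-adjusted logistic association
#'
#' Maximum-likelihood logistic regression (`glm`, binomial family) of a
#' binary outcome on an exposure, with optional covariates, reporting
#' the exponentiated exposure coefficient with its Wald 95% confidence
#' interval. With a binary exposure and no covariates this equals the
#' sample 2x2 odds ratio. Complete or quasi-complete separation is
#' detected (fitted probabilities pinned at 0/1 or an exploding standard
#' error) and raised as an explicit diagnostic, never a silent fit.
#'
#' @param outcome Logical (or 0/1) vector.
#' @param exposure Numeric or logical vector (the coefficient of
#'   interest).
#' @param covariates Optional data frame of adjustment covariates.
#' @param conf_level Wald confidence level.
#' @return Tibble: `estimate` (OR per unit exposure), `ci_lo`, `ci_hi`,
#'   `p_value`, `method` (`"glm_binomial"`), `n`, `log_or`, `se`.
#' @export
logistic_association <- function(outcome, exposure, covariates = NULL,
                                 conf_level = 0.95) {
  outcome <- as.logical(outcome)
  n <- length(outcome)
  if (n < 20L) {
    abort("logistic association requires n >= 20",
          class = "icbtox_parameter_error")
  }
  dat <- data.frame(.y = outcome, .x = as.numeric(exposure))
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  if (any(!complete.cases(dat))) {
    abort("missing values in outcome/exposure/covariates",
          class = "icbtox_parameter_error")
  }
  fit <- suppressWarnings(
    glm(.y ~ ., data = dat, family = binomial(),
        control = list(epsilon = 1e-10, maxit = 100))
  )
  probs <- fit$fitted.values
  cf <- summary(fit)$coefficients
  est <- cf[".x", "Estimate"]
  se <- cf[".x", "Std. Error"]
  if (any(probs < 1e-8) || any(probs > 1 - 1e-8) || abs(est) > 15 || se > 10) {
    abort("separation detected: exposure (plus covariates) perfectly predicts the outcome; odds ratio not estimable",
          class = "icbtox_separation_error")
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    estimate = exp(est),
    ci_lo = exp(est - z * se),
    ci_hi = exp(est + z * se),
    p_value = cf[".x", "Pr(>|z|)"],
    method = "glm_binomial",
    n = n, log_or = est, se = se
  )
}
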