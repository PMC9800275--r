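series_of <- function(days, counts = NULL, pid = "p1") {
  tibble::tibble(patient_id = pid, day_offset = as.integer(days),
                 lymphocyte_count = counts %||% rep(1.5, length(days)))
}

test_that("window selection picks the closest pre and first post count", {
  s <- series_of(c(-40, -10, -2, 15, 25, 40))
  sel <- select_lymphocyte_pair(s)
  expect_identical(sel$pre_day, -2L)
  expect_identical(sel$post_day, 25L)
  expect_true(is.na(sel$missing_reason))
})

test_that("empty windows yield reason codes, never errors", {
  sel <- select_lymphocyte_pair(series_of(c(-35, 20)))
  expect_identical(sel$missing_reason, "no_pre;no_post")
  expect_identical(select_lymphocyte_pair(series_of(c(-35, 30)))$missing_reason,
                   "no_pre")
  expect_identical(select_lymphocyte_pair(series_of(c(-5, 55)))$missing_reason,
                   "no_post")
  # boundaries: day 0 is pre; days 21 and 49 are both post-eligible
  sel0 <- select_lymphocyte_pair(series_of(c(0, 21)))
  expect_identical(sel0$pre_day, 0L)
  expect_identical(sel0$post_day, 21L)
  expect_identical(select_lymphocyte_pair(series_of(c(-1, 49)))$post_day, 49L)
  expect_identical(select_lymphocyte_pair(series_of(c(-1, 50)))$missing_reason,
                   "no_post")
})

test_that("selection is independent of row order; same-day ties keep the later record", {
  s <- series_of(c(-10, -3, 25, 30), c(1.0, 1.2, 1.4, 1.6))
  shuffled <- s[c(3, 1, 4, 2), ]
  expect_equal(select_lymphocyte_pair(s), select_lymphocyte_pair(shuffled))
  dup <- series_of(c(-3, -3, 25), c(1.0, 2.0, 1.4))
  sel <- select_lymphocyte_pair(dup)
  expect_identical(sel$pre_count, 2.0)
  expect_error(select_lymphocyte_pair(tibble::tibble(patient_id = "x")),
               class = "icbtox_parameter_error")
})

test_that("LS dichotomy follows the strict fall-below-20% rule", {
  mk <- function(pre, post) {
    lymphocyte_stability(tibble::tibble(patient_id = "x", pre_count = pre,
                                        post_count = post))
  }
  worked <- mk(1.82, 1.52)
  expect_equal(worked$delta, -0.30)
  expect_equal(worked$pct_change, -16.48352, tolerance = 1e-5)
  expect_true(worked$stable)
  expect_false(mk(2.0, 1.5)$stable)       # -25%
  expect_false(mk(5.0, 4.0)$stable)       # exactly -20% is unstable
  expect_true(mk(1.0, 1.0)$stable)
  expect_true(mk(1.0, 2.5)$stable)        # any increase is stable
  expect_error(mk(0, 1), class = "icbtox_parameter_error")
})

test_that("LS partition is exhaustive and exclusive on random series", {
  set.seed(27)
  pairs <- tibble::tibble(patient_id = paste0("p", 1:500),
                          pre_count = rlnorm(500, log(1.8), 0.5),
                          post_count = rlnorm(500, log(1.6), 0.5))
  ls <- lymphocyte_stability(pairs)
  expect_true(all(ls$stable == (ls$pct_change > -20)))
  expect_false(any(is.na(ls$stable)))
})

test_that("2x2 odds ratios match hand arithmetic and the enumeration oracle", {
  even <- matrix(c(10, 10, 10, 10), 2)
  res <- odds_ratio_2x2(even)
  expect_equal(res$estimate, 1)
  expect_equal(res$p_value, 1)
  tab <- matrix(c(6, 20, 24, 164), 2)
  res2 <- odds_ratio_2x2(tab)
  expect_equal(res2$estimate, 2.05, tolerance = 1e-12)
  expect_equal(res2$p_value, fisher_enum_two_sided(tab), tolerance = 1e-12)
  expect_true(res2$ci_lo <= res2$estimate && res2$estimate <= res2$ci_hi)
})

test_that("Fisher p equals the enumeration oracle for all margins <= 30", {
  set.seed(33)
  for (i in 1:400) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(odds_ratio_2x2(tab)$p_value, fisher_enum_two_sided(tab),
                 tolerance = 1e-12)
  }
})

test_that("zero cells follow the Haldane rule or error explicitly", {
  tab <- matrix(c(0, 5, 10, 10), 2)
  res <- odds_ratio_2x2(tab, zero_rule = "haldane")
  expect_equal(res$estimate, (0.5 * 10.5) / (10.5 * 5.5), tolerance = 1e-12)
  expect_error(odds_ratio_2x2(tab, zero_rule = "none"),
               class = "icbtox_parameter_error")
  expect_error(odds_ratio_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               class = "icbtox_parameter_error")
  expect_error(odds_ratio_2x2(matrix(c(1.5, 2, 3, 4), 2)),
               class = "icbtox_parameter_error")
})

test_that("binary-exposure logistic regression equals the 2x2 odds ratio", {
  set.seed(41)
  for (i in 1:10) {
    n <- 120
    x <- runif(n) < 0.3
    y <- runif(n) < plogis(-1 + 0.9 * x)
    tab <- matrix(c(sum(x & y), sum(!x & y), sum(x & !y), sum(!x & !y)), 2)
    if (any(tab == 0)) next
    glm_or <- logistic_association(y, x)$estimate
    expect_equal(glm_or, odds_ratio_2x2(tab)$estimate, tolerance = 1e-6)
  }
})

test_that("null exposures are recovered as null", {
  set.seed(55)
  y <- runif(300) < 0.25
  x <- rnorm(300)
  res <- logistic_association(y, x)
  expect_lt(abs(res$log_or), 3 * res$se)
})

test_that("separation and degenerate inputs raise explicit diagnostics", {
  y <- c(rep(TRUE, 30), rep(FALSE, 30))
  x <- as.numeric(y)  # perfect separation
  expect_error(logistic_association(y, x),
               class = "icbtox_separation_error")
  expect_error(logistic_association(y[1:10], x[1:10]),
               class = "icbtox_parameter_error")
  expect_error(logistic_association(y, replace(x, 3, NA)),
               class = "icbtox_parameter_error")
})

test_that("simulated cohorts recover the configured carrier odds ratio", {
  res <- t(vapply(1:120, function(s) {
    cfg <- sim_config(seed = s)
    co <- gen_cohort(cfg)
    a <- logistic_association(co$irae, co$carrier,
                              data.frame(icb = co$icb_type == "cICB"))
    c(a$estimate, a$ci_lo <= 2.24 && a$ci_hi >= 2.24)
  }, numeric(2)))
  expect_lt(abs(median(res[, 1]) - 2.24), 0.15 * 2.24)
  expect_gt(mean(res[, 2]), 0.88)
})

test_that("IL7 mediation shows up as adjusted-regression shrinkage", {
  fits <- t(vapply(1:60, function(s) {
    cfg <- sim_config(seed = s, mediation_mode = "via_il7")
    co <- gen_cohort(cfg)
    icb <- data.frame(icb = co$icb_type == "cICB")
    c(un = logistic_association(co$irae, co$carrier, icb)$log_or,
      ad = logistic_association(co$irae, co$carrier,
                                cbind(icb, il7 = co$il7_expr))$log_or)
  }, numeric(2)))
  # the genotype coefficient collapses toward 0 once IL7 is conditioned on
  expect_lt(median(abs(fits[, "ad"])), 0.5 * median(abs(fits[, "un"])))
  # and IL7 itself stays independently associated with the outcome
  cfg <- sim_config(seed = 7, mediation_mode = "via_il7")
  co <- gen_cohort(cfg)
  il7 <- logistic_association(co$irae, co$il7_expr,
                              data.frame(icb = co$icb_type == "cICB",
                                         carrier = co$carrier))
  expect_gt(il7$log_or, 0)
})
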