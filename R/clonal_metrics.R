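# Clonality statistics: Gini index, clone-size occupancy bands,
# large-clone counts, and the minimum-depth bootstrap-rarefaction wrapper
# that makes them comparable across samples sequenced to different depths.

#' Gini index of clone sizes
#'
#' Inequality of a repertoire's clone-size distribution:
#' `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`, computed via the
#' O(n log n) sorted form. `G = 0` is a perfectly even repertoire; values
#' approach 1 as a single clone dominates. A single clone returns 0 by
#' convention. Scale-invariant, so counts and frequencies give the same
#' value.
#'
#' @param counts Non-negative clone sizes (reads or frequencies); at least
#'   one must be positive.
#' @return Gini index in `[0, 1)`.
#' @examples
#' gini_index(c(5, 5, 5, 5))   # 0
#' gini_index(c(1, 1, 1, 97))  # 0.72
#' @export
gini_index <- function(counts) {
  if (length(counts) == 0L || any(is.na(counts)) || any(counts < 0)) {
    abort("`counts` must be non-negative and non-missing",
          class = "icbtox_parameter_error")
  }
  tot <- sum(counts)
  if (tot <= 0) {
    abort("Gini index undefined for all-zero clone sizes",
          class = "icbtox_undefined_metric")
  }
  n <- length(counts)
  if (n == 1L) return(0)
  x <- sort(counts)
  # sorted form: sum_ij |x_i - x_j| = 2 * sum_i (2i - n - 1) x_(i)
  sum((2 * seq_len(n) - n - 1) * x) / (n * tot)
}

#' Band thresholds for clone-size occupancy
#'
#' Small clones occupy `< small_lt` of the chain's repertoire, large
#' clones `> large_gt`; both inequalities are strict, so a clone sitting
#' exactly on a boundary is counted in the middle band. Defaults follow
#' the conventional <0.05% (small) and >0.5% (large) repertoire-fraction
#' cutoffs.
#'
#' @param small_lt Upper (exclusive) frequency bound of the small band.
#' @param large_gt Lower (exclusive) frequency bound of the large band.
#' @return A `band_thresholds` list.
#' @export
band_thresholds <- function(small_lt = 0.0005, large_gt = 0.005) {
  if (!(small_lt > 0 && small_lt < large_gt && large_gt < 1)) {
    abort("need 0 < small_lt < large_gt < 1",
          class = "icbtox_parameter_error")
  }
  structure(list(small_lt = small_lt, large_gt = large_gt),
            class = "band_thresholds")
}

#' Clone-size occupancy bands
#'
#' Partitions a single sample/chain's clones into small, mid and large
#' bands by repertoire frequency and reports the read-weighted fraction
#' of the repertoire each band occupies plus the clone count per band.
#' Fractions sum to 1 whenever reads are present.
#'
#' @param clones Clone table for one sample and one chain (needs
#'   `frequency` and `total_reads`).
#' @param thr A [band_thresholds()].
#' @return A one-row tibble: `small_frac`, `mid_frac`, `large_frac`,
#'   `small_n`, `mid_n`, `large_n`, `empty`.
#' @export
occupancy_bands <- function(clones, thr = band_thresholds()) {
  stopifnot(inherits(thr, "band_thresholds"))
  if (nrow(clones) == 0L || sum(clones$total_reads) == 0) {
    return(tibble::tibble(small_frac = 0, mid_frac = 0, large_frac = 0,
                          small_n = 0L, mid_n = 0L, large_n = 0L,
                          empty = TRUE))
  }
  check_single_sample_chain(clones)
  f <- clones$total_reads / sum(clones$total_reads)
  band <- ifelse(f < thr$small_lt, "small",
                 ifelse(f > thr$large_gt, "large", "mid"))
  frac <- function(b) sum(f[band == b])
  n_of <- function(b) sum(band == b)
  tibble::tibble(
    small_frac = frac("small"), mid_frac = frac("mid"),
    large_frac = frac("large"),
    small_n = n_of("small"), mid_n = n_of("mid"), large_n = n_of("large"),
    empty = FALSE
  )
}

#' Count large clones
#'
#' Number of clones whose repertoire frequency strictly exceeds
#' `large_gt` (default: >0.5% of the chain's repertoire).
#'
#' @inheritParams occupancy_bands
#' @param large_gt Frequency threshold (exclusive).
#' @return Integer clone count.
#' @export
count_large_clones <- function(clones, large_gt = 0.005) {
  assert_positive(large_gt, "large_gt", strict = FALSE)
  if (nrow(clones) == 0L || sum(clones$total_reads) == 0) return(0L)
  check_single_sample_chain(clones)
  f <- clones$total_reads / sum(clones$total_reads)
  sum(f > large_gt)
}

check_single_sample_chain <- function(clones) {
  if (length(unique(clones$sample_id)) > 1L ||
      length(unique(clones$chain)) > 1L) {
    abort("expected clones from a single sample and chain; filter first",
          class = "icbtox_parameter_error")
  }
  invisible(clones)
}

#' Depth-matched bootstrap rarefaction of clonality metrics
#'
#' Diversity statistics are depth-biased: deeper sequencing observes more
#' rare clones. To compare samples, every sample is resampled down to the
#' minimum total read count observed across samples — `rarefied_depth` —
#' by drawing that many reads with replacement from the sample's
#' empirical clone distribution (multinomial), recomputing the metric on
#' the resampled counts (clones drawn zero times are dropped), and
#' repeating `n_iter` times (default 1000). Every sample, including the
#' minimum-depth one, is resampled so all estimates carry comparable
#' bootstrap variance.
#'
#' @param samples Named list of clone tables (one per sample, single
#'   chain each), or a single clone table with multiple `sample_id`s.
#' @param metric `"gini"`, `"large_clones"`, or `"occupancy"` (the last
#'   reports one row per band fraction).
#' @param n_iter Bootstrap iterations.
#' @param seed Integer seed; each sample gets an independent stream
#'   derived from `(seed, sample_id)`, so results do not depend on
#'   sample order.
#' @param thr [band_thresholds()] used by the occupancy/large-clone
#'   metrics.
#' @return A tibble with one row per sample (and band, for occupancy):
#'   `sample_id`, `metric`, `point` (mean over iterations), `sd`,
#'   `ci_lo`/`ci_hi` (2.5/97.5 bootstrap percentiles), `rarefied_depth`,
#'   `n_iter`.
#' @export
rarefied_metric <- function(samples, metric = c("gini", "large_clones",
                                                "occupancy"),
                            n_iter = 1000L, seed = 1L,
                            thr = band_thresholds()) {
  metric <- match.arg(metric)
  n_iter <- assert_count(n_iter, "n_iter")
  if (is.data.frame(samples)) {
    samples <- split(samples, samples$sample_id)
  }
  if (length(samples) == 0L) {
    abort("need at least one sample", class = "icbtox_parameter_error")
  }
  depths <- vapply(samples, function(s) sum(s$total_reads), numeric(1))
  depth <- min(depths)
  if (depth < 1) {
    abort("rarefied depth < 1: a sample has no reads",
          class = "icbtox_parameter_error")
  }

  metric_fun <- switch(
    metric,
    gini = function(cts) c(gini = gini_index(cts)),
    large_clones = function(cts) {
      c(large_clones = sum(cts / sum(cts) > thr$large_gt))
    },
    occupancy = function(cts) {
      f <- cts / sum(cts)
      c(occupancy_small = sum(f[f < thr$small_lt]),
        occupancy_mid = sum(f[f >= thr$small_lt & f <= thr$large_gt]),
        occupancy_large = sum(f[f > thr$large_gt]))
    }
  )

  res <- lapply(names(samples), function(sid) {
    cl <- samples[[sid]]
    prob <- cl$total_reads / sum(cl$total_reads)
    draws <- with_seed(derive_seed(seed, paste0("rarefy:", sid)), {
      rmultinom(n_iter, size = depth, prob = prob)
    })
    vals <- apply(draws, 2, function(cts) metric_fun(cts[cts > 0]))
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1,
                                           dimnames = list(names(vals)[1] %||%
                                                             metric, NULL))
    tibble::tibble(
      sample_id = sid,
      metric = rownames(vals),
      point = unname(apply(vals, 1, mean)),
      sd = unname(apply(vals, 1, sd)),
      ci_lo = unname(apply(vals, 1, quantile, probs = 0.025, names = FALSE)),
      ci_hi = unname(apply(vals, 1, quantile, probs = 0.975, names = FALSE)),
      rarefied_depth = as.integer(depth),
      n_iter = n_iter
    )
  })
  dplyr::bind_rows(res)
}

#' Change in a rarefied metric between paired samples
#'
#' Post-treatment minus pre-treatment point estimate; both results must
#' come from the same metric and the same rarefaction settings.
#'
#' @param pre,post One-row results from [rarefied_metric()].
#' @return `post$point - pre$point`.
#' @export
gini_delta <- function(pre, post) {
  if (!identical(pre$metric, post$metric)) {
    abort("metric mismatch between pre and post results",
          class = "icbtox_parameter_error")
  }
  post$point - pre$point
}
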