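# B cell receptor maturation metrics: germline-divergent mutation
# percentage per chain, IGHC isotype usage, IGHD-expressing clone fraction.

#' Germline-divergent mutation percentage per chain
#'
#' For each chain present in the sample: the total number of mutations
#' over all clones (substitutions + insertions + deletions, counted once
#' per unique clone, not read-weighted) divided by the total aligned BCR
#' length of those clones, times 100 — a per-nucleotide divergence rate
#' that proxies somatic hypermutation load.
#'
#' @param clones Clone table carrying `n_subs`, `n_ins`, `n_del` and
#'   `aligned_length`.
#' @param denominator `"summed_lengths"` (default): denominator is the
#'   sum of per-clone aligned lengths; `"mean_length"`: a fixed
#'   per-clone receptor length (the mean aligned length) times the clone
#'   count — numerically identical here, exposed for sensitivity checks.
#' @return Tibble with one row per chain: `chain`, `total_mutations`,
#'   `total_length`, `mutation_pct`.
#' @examples
#' tb <- tibble::tibble(sample_id = "s", chain = "IGH",
#'   cdr3_nt = c("AAA", "CCC"), v_call = NA, j_call = NA, c_call = NA,
#'   total_reads = c(1L, 1L), frequency = c(0.5, 0.5),
#'   n_subs = c(7L, 14L), n_ins = 0L, n_del = 0L,
#'   aligned_length = c(350L, 360L))
#' mutation_percentage(tb)$mutation_pct  # 21/710*100
#' @export
mutation_percentage <- function(clones,
                                denominator = c("summed_lengths",
                                                "mean_length")) {
  denominator <- match.arg(denominator)
  if (nrow(clones) == 0L) {
    return(tibble::tibble(chain = character(), total_mutations = integer(),
                          total_length = integer(), mutation_pct = numeric()))
  }
  bad <- which(is.na(clones$aligned_length) | clones$aligned_length <= 0)
  if (length(bad) > 0) {
    abort(sprintf("clone(s) with non-positive aligned_length at row(s): %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "icbtox_validation_error")
  }
  clones |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(
      total_mutations = sum(.data$n_subs + .data$n_ins + .data$n_del),
      total_length = if (denominator == "summed_lengths") {
        sum(.data$aligned_length)
      } else {
        round(mean(.data$aligned_length)) * dplyr::n()
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(mutation_pct = 100 * .data$total_mutations /
                    .data$total_length)
}

#' IGHC isotype usage
#'
#' Percentage of IGH clones (or of their reads) assigned to each IGHC
#' gene segment (IGHM, IGHD, IGHG1-4, IGHA1-2, IGHE). The denominator is
#' restricted to IGH clones with a non-missing constant-region call;
#' clones lacking one are excluded and their number reported.
#'
#' @param clones Clone table (any chains; only IGH rows are used).
#' @param unit `"clones"` or `"reads"`.
#' @return List with `usage` (tibble: `segment`, `pct`, summing to 100
#'   when any call is present), `unit`, `n_excluded` (IGH clones without
#'   a c_call), and `empty` (no IGH clones with a call at all).
#' @export
ighc_usage <- function(clones, unit = c("clones", "reads")) {
  unit <- match.arg(unit)
  igh <- clones[clones$chain == "IGH", , drop = FALSE]
  with_call <- igh[!is.na(igh$c_call), , drop = FALSE]
  n_excluded <- nrow(igh) - nrow(with_call)
  if (nrow(with_call) == 0L) {
    return(list(usage = tibble::tibble(segment = character(),
                                       pct = numeric()),
                unit = unit, n_excluded = n_excluded, empty = TRUE))
  }
  w <- if (unit == "clones") rep(1, nrow(with_call)) else with_call$total_reads
  tab <- tapply(w, with_call$c_call, sum)
  usage <- tibble::tibble(segment = names(tab),
                          pct = 100 * as.numeric(tab) / sum(tab)) |>
    dplyr::arrange(dplyr::desc(.data$pct), .data$segment)
  list(usage = usage, unit = unit, n_excluded = n_excluded, empty = FALSE)
}

#' Percentage of B cell clones expressing unswitched IGHD
#'
#' Fraction (as a percentage) of IGH clones with a constant-region call
#' that express IGHD — a marker of naive, class-switch-unexperienced
#' B cells. Identical to `ighc_usage(clones, "clones")` evaluated at
#' IGHD.
#'
#' @inheritParams ighc_usage
#' @return Percentage in `[0, 100]`; `NA` if no IGH clone carries a call.
#' @export
ighd_clone_percentage <- function(clones) {
  res <- ighc_usage(clones, unit = "clones")
  if (res$empty) return(NA_real_)
  pct <- res$usage$pct[res$usage$segment == "IGHD"]
  if (length(pct) == 0L) 0 else pct
}
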