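# Count normalization and signature scoring: median-of-ratios size
# factors, geometric-mean gene-set scores, targeted group-effect
# estimates, and one-tailed hypergeometric enrichment.

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over reference genes
#' g of `count(g, j) / geomean_j(count(g, .))`, where the reference set
#' is every gene with a nonzero count in all samples. This is the
#' standard median-of-ratios normalization for RNA-seq count matrices:
#' it is robust to a minority of differentially expressed genes and, for
#' exactly proportional columns `c_j * base`, reduces to
#' `c_j / geomean(c)`.
#'
#' @param counts Numeric matrix, genes x samples, raw counts.
#' @return Positive numeric vector of per-sample size factors, named by
#'   sample.
#' @examples
#' m <- matrix(c(1, 10, 100, 2, 20, 200), ncol = 2,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' size_factors(m)  # c(1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) {
    abort("counts must be non-negative", class = "icbtox_parameter_error")
  }
  ref <- rowSums(counts == 0 | is.na(counts)) == 0
  if (!any(ref)) {
    abort("no reference genes: every gene has a zero in some sample",
          class = "icbtox_normalization_error")
  }
  logc <- log(counts[ref, , drop = FALSE])
  log_geo <- rowMeans(logc)
  sf <- apply(logc - log_geo, 2, function(lr) exp(median(lr)))
  stats::setNames(sf, colnames(counts))
}

#' Apply size factors to a count matrix
#'
#' @param counts Genes x samples raw count matrix.
#' @param factors Positive per-sample size factors (defaults to
#'   [size_factors()] of `counts`).
#' @return Normalized matrix: `counts[, j] / factors[j]`.
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  counts <- as.matrix(counts)
  if (length(factors) != ncol(counts) || any(factors <= 0)) {
    abort("`factors` must be positive, one per sample",
          class = "icbtox_parameter_error")
  }
  sweep(counts, 2, factors, `/`)
}

#' Geometric-mean signature score
#'
#' Per-sample score of a gene set on normalized expression:
#' `exp(mean(log(value + pseudocount)))` over the set members present in
#' the matrix. Used for mitotic/proliferation signature scoring of the
#' top signature genes.
#'
#' @param norm Normalized genes x samples matrix.
#' @param genes Character vector of gene-set members.
#' @param pseudocount Added inside the log; with the default 0 any zero
#'   value is a domain error.
#' @param min_present Minimum fraction of `genes` that must be present in
#'   the matrix (default 0.8); below this an error lists the missing
#'   genes.
#' @return Named per-sample numeric vector of scores.
#' @examples
#' m <- matrix(c(1, 4, 16), ncol = 1, dimnames = list(paste0("g", 1:3), "s1"))
#' signature_score(m, paste0("g", 1:3))  # 4
#' @export
signature_score <- function(norm, genes, pseudocount = 0,
                            min_present = 0.8) {
  stopifnot(length(genes) > 0)
  present <- intersect(genes, rownames(norm))
  if (length(present) < min_present * length(genes)) {
    abort(sprintf("only %d/%d signature genes present; missing: %s",
                  length(present), length(genes),
                  paste(head(setdiff(genes, present), 10), collapse = ", ")),
          class = "icbtox_parameter_error")
  }
  vals <- norm[present, , drop = FALSE] + pseudocount
  if (any(vals <= 0)) {
    abort("zero or negative value in signature genes with pseudocount 0; set a positive pseudocount",
          class = "icbtox_domain_error")
  }
  exp(colMeans(log(vals)))
}

#' Two-group expression effect for one gene
#'
#' Difference in group means of `log2(value + pseudocount)` for a single
#' gene, with optional linear covariate adjustment (fit as
#' `log2 expr ~ group + covariates`); the p-value is the two-sided t-test
#' on the group coefficient. Positive effects mean higher expression in
#' `level_hi`.
#'
#' @param norm Normalized genes x samples matrix.
#' @param gene Gene id (row of `norm`).
#' @param groups Factor-like vector (2 levels) or logical, one per
#'   sample.
#' @param level_hi Group label whose mean enters positively (defaults to
#'   the second factor level, or `TRUE` for logicals).
#' @param covariates Optional data frame of per-sample covariates.
#' @param pseudocount Added before the log2.
#' @return Tibble: `effect` (log2 scale), `se`, `statistic`, `p_value`,
#'   `n_hi`, `n_lo`.
#' @export
group_effect <- function(norm, gene, groups, level_hi = NULL,
                         covariates = NULL, pseudocount = 1) {
  if (!gene %in% rownames(norm)) {
    abort(sprintf("gene '%s' not in matrix", gene),
          class = "icbtox_parameter_error")
  }
  y <- log2(norm[gene, ] + pseudocount)
  g <- if (is.logical(groups)) factor(groups, levels = c(FALSE, TRUE)) else factor(groups)
  if (nlevels(g) != 2L) {
    abort("`groups` must have exactly two levels",
          class = "icbtox_parameter_error")
  }
  if (!is.null(level_hi)) g <- stats::relevel(g, ref = setdiff(levels(g), as.character(level_hi)))
  if (min(table(g)) < 2L) {
    abort("each group needs at least 2 samples",
          class = "icbtox_parameter_error")
  }
  dat <- data.frame(y = y, g = g)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  fit <- lm(y ~ ., data = dat)
  cf <- summary(fit)$coefficients
  row <- grep("^g", rownames(cf))[1]
  tibble::tibble(
    effect = cf[row, "Estimate"], se = cf[row, "Std. Error"],
    statistic = cf[row, "t value"], p_value = cf[row, "Pr(>|t|)"],
    n_hi = sum(g == levels(g)[2]), n_lo = sum(g == levels(g)[1])
  )
}

#' One-tailed hypergeometric enrichment
#'
#' Upper-tail probability of observing at least the realised overlap
#' between a hit set and an annotation set drawn from a background
#' universe of `background` genes, plus the fold change of the overlap
#' over its background expectation:
#' `fold = (overlap / |hits|) / (|annotation| / background)`.
#'
#' @param hits Character vector of selected genes.
#' @param annotation Character vector of pathway/annotation genes.
#' @param background Universe size (count) or character vector of
#'   universe genes (both sets must be subsets of it).
#' @return Tibble: `overlap`, `n_hits`, `n_annotation`, `background`,
#'   `fold`, `p_value`.
#' @export
hypergeometric_enrichment <- function(hits, annotation, background) {
  hits <- unique(hits)
  annotation <- unique(annotation)
  if (is.character(background)) {
    universe <- unique(background)
    stray <- setdiff(c(hits, annotation), universe)
    if (length(stray) > 0) {
      abort(sprintf("genes outside the background universe: %s",
                    paste(head(stray, 5), collapse = ", ")),
            class = "icbtox_parameter_error")
    }
    background <- length(universe)
  }
  background <- assert_count(background, "background")
  if (length(hits) > background || length(annotation) > background) {
    abort("set larger than the background universe",
          class = "icbtox_parameter_error")
  }
  k <- length(intersect(hits, annotation))
  # P(X >= k), X ~ Hypergeom(annotation in universe, draws = |hits|)
  p <- phyper(k - 1, length(annotation), background - length(annotation),
              length(hits), lower.tail = FALSE)
  fold <- if (length(hits) == 0 || length(annotation) == 0) {
    NA_real_
  } else {
    (k / length(hits)) / (length(annotation) / background)
  }
  tibble::tibble(overlap = k, n_hits = length(hits),
                 n_annotation = length(annotation),
                 background = background, fold = fold, p_value = p)
}

#' Read a GMT gene-set file
#'
#' @param path GMT path (tab-separated: name, description, members...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  sets
}
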