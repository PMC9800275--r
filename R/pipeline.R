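# Config-driven orchestration: generate or load inputs, run every
# analysis stage, write a reproducible report bundle.

#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (inputs generated from `sim`) or `"files"`
#'   (inputs read from `paths`).
#' @param sim A [sim_config()] (synthetic mode).
#' @param paths Named list for files mode: `clinical` (TSV:
#'   `patient_id`, `genotype_dose`, `icb_type`, `irae`, `start_date`),
#'   `lymphocytes` (TSV: `patient_id`, `day_offset`,
#'   `lymphocyte_count`), `clonotypes` (character vector of clonotype
#'   TSVs), `clonotype_dialect`, optionally `counts` (genes x samples
#'   TSV with a `gene_id` first column).
#' @param key_mode Clone identity key for aggregation (see
#'   [aggregate_clones()]).
#' @param thr [band_thresholds()].
#' @param n_iter Bootstrap iterations for rarefied metrics.
#' @param n_rep_samples Number of TCR/BCR repertoires to simulate in
#'   synthetic mode.
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Output directory for the report bundle.
#' @return A `run_config` object.
#' @export
run_config <- function(mode = c("synthetic", "files"), sim = sim_config(),
                       paths = NULL, key_mode = "cdr3_vj",
                       thr = band_thresholds(), n_iter = 1000L,
                       n_rep_samples = 6L, seed = 1L,
                       out_dir = tempfile("icbtox_run_")) {
  mode <- match.arg(mode)
  if (mode == "files") {
    if (is.null(paths)) {
      abort("files mode requires `paths`", class = "icbtox_parameter_error")
    }
  }
  structure(list(mode = mode, sim = sim, paths = paths, key_mode = key_mode,
                 thr = thr, n_iter = assert_count(n_iter, "n_iter"),
                 n_rep_samples = assert_count(n_rep_samples, "n_rep_samples"),
                 seed = assert_count(seed, "seed", min = 0L),
                 out_dir = out_dir),
            class = "run_config")
}

#' Validate pipeline inputs
#'
#' Schema checks for every input file referenced by a files-mode
#' configuration (synthetic mode always validates clean). Report-only:
#' problems are returned, not raised.
#'
#' @param cfg A [run_config()].
#' @return Tibble with columns `level` (`"error"`/`"warning"`), `input`,
#'   `message`.
#' @export
validate_inputs <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  report <- tibble::tibble(level = character(), input = character(),
                           message = character())
  add <- function(level, input, message) {
    report <<- dplyr::bind_rows(report, tibble::tibble(
      level = level, input = input, message = message))
  }
  if (cfg$mode == "synthetic") return(report)

  check_tsv <- function(path, input, required) {
    if (is.null(path)) return(invisible())
    if (!file.exists(path)) {
      add("error", input, sprintf("file not found: %s", path))
      return(invisible())
    }
    tb <- tryCatch(readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                                   progress = FALSE, n_max = 1000),
                   error = function(e) NULL)
    if (is.null(tb)) {
      add("error", input, sprintf("unreadable TSV: %s", path))
      return(invisible())
    }
    miss <- setdiff(required, names(tb))
    if (length(miss) > 0) {
      add("error", input, sprintf("%s: missing column(s): %s", path,
                                  paste(miss, collapse = ", ")))
    }
    tb
  }

  clin <- check_tsv(cfg$paths$clinical, "clinical",
                    c("patient_id", "genotype_dose", "icb_type", "irae",
                      "start_date"))
  if (is.data.frame(clin) && "start_date" %in% names(clin)) {
    bad <- which(is.na(suppressWarnings(as.Date(clin$start_date))))
    if (length(bad) > 0) {
      add("error", "clinical", sprintf("unparseable start_date at row(s): %s",
                                       paste(head(bad, 5), collapse = ", ")))
    }
  }
  lym <- check_tsv(cfg$paths$lymphocytes, "lymphocytes",
                   c("patient_id", "day_offset", "lymphocyte_count"))
  if (is.data.frame(lym) && "day_offset" %in% names(lym)) {
    bad <- which(is.na(suppressWarnings(as.integer(lym$day_offset))))
    if (length(bad) > 0) {
      add("error", "lymphocytes",
          sprintf("non-integer day_offset at row(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
    }
  }
  for (p in cfg$paths$clonotypes) {
    res <- tryCatch(
      read_clonotypes(p, dialect = cfg$paths$clonotype_dialect %||% "airr"),
      error = function(e) e)
    if (inherits(res, "error")) {
      add("error", "clonotypes", conditionMessage(res))
    } else if (nrow(attr(res, "rejects")) > 0) {
      add("warning", "clonotypes",
          sprintf("%s: %d row(s) quarantined", p, nrow(attr(res, "rejects"))))
    }
  }
  report
}

#' Run the full analysis pipeline
#'
#' Executes every stage — repertoire aggregation, depth-matched bootstrap
#' clonality metrics, BCR maturation metrics, normalization and
#' signature scoring, lymphocyte stability, and genotype/expression
#' association — on synthetic or file inputs, writing a TSV/JSON report
#' bundle plus a machine-readable manifest (package version, seed,
#' configuration hash). Identical configurations produce byte-identical
#' outputs.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list of the in-memory stage results (including
#'   `manifest`); side effect: files under `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  vr <- validate_inputs(cfg)
  if (any(vr$level == "error")) {
    abort(paste0("input validation failed:\n",
                 paste(sprintf("- [%s] %s", vr$input, vr$message),
                       collapse = "\n")),
          class = "icbtox_validation_error")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "icbtox_stage_error")
    })
  }

  inputs <- stage("inputs", pipeline_inputs(cfg))
  results <- list()

  results$tcr_metrics <- stage("clonal_metrics", {
    if (is.null(inputs$tcr) || nrow(inputs$tcr) == 0L) {
      NULL
    } else {
    clones <- aggregate_clones(inputs$tcr, key_mode = cfg$key_mode)
    trb <- clones[clones$chain == "TRB", , drop = FALSE]
    dplyr::bind_rows(
      rarefied_metric(trb, "gini", n_iter = cfg$n_iter, seed = cfg$seed,
                      thr = cfg$thr),
      rarefied_metric(trb, "large_clones", n_iter = cfg$n_iter,
                      seed = cfg$seed, thr = cfg$thr),
      rarefied_metric(trb, "occupancy", n_iter = cfg$n_iter,
                      seed = cfg$seed, thr = cfg$thr)
    ) |> dplyr::arrange(.data$sample_id, .data$metric)
    }
  })

  results$bcr_metrics <- stage("bcr_metrics", {
    if (is.null(inputs$bcr) || nrow(inputs$bcr) == 0L) {
      NULL
    } else {
    clones <- aggregate_clones(inputs$bcr, key_mode = cfg$key_mode)
    by_sample <- split(clones, clones$sample_id)
    mut <- dplyr::bind_rows(lapply(names(by_sample), function(sid) {
      dplyr::mutate(mutation_percentage(by_sample[[sid]]), sample_id = sid,
                    .before = 1)
    }))
    usage <- dplyr::bind_rows(lapply(names(by_sample), function(sid) {
      dplyr::bind_rows(lapply(c("clones", "reads"), function(u) {
        res <- ighc_usage(by_sample[[sid]], unit = u)
        if (res$empty) return(NULL)
        dplyr::mutate(res$usage, sample_id = sid, unit = u, .before = 1)
      }))
    }))
    list(mutation = mut, usage = usage)
    }
  })

  results$expression <- stage("expression_scores", {
    if (is.null(inputs$expression)) {
      NULL
    } else {
    counts <- inputs$expression$counts
    sf <- size_factors(counts)
    norm <- normalize_counts(counts, sf)
    scores <- signature_score(norm, inputs$expression$signature_genes,
                              pseudocount = 1)
    meta <- inputs$expression$samples
    pat <- meta$status == "patient"
    il7 <- inputs$expression$il7_gene
    eff_status <- group_effect(norm, il7, groups = pat, level_hi = TRUE,
                               pseudocount = 1)
    eff_carrier <- if (sum(meta$carrier[pat]) >= 2 &&
                       sum(!meta$carrier[pat]) >= 2) {
      group_effect(norm[, pat, drop = FALSE], il7,
                   groups = meta$carrier[pat], level_hi = TRUE,
                   pseudocount = 1)
    } else NULL
    list(size_factors = tibble::tibble(sample_id = names(sf),
                                       size_factor = unname(sf)),
         scores = tibble::tibble(sample_id = names(scores),
                                 mitotic_score = unname(scores)),
         il7_patient_vs_healthy = eff_status,
         il7_carrier_vs_noncarrier = eff_carrier)
    }
  })

  results$ls <- stage("lymphocyte_stability", {
    pairs <- select_lymphocyte_pair(inputs$lymphocytes)
    lymphocyte_stability(pairs)
  })

  results$association <- stage("association", {
    cohort <- inputs$cohort
    tab <- table(factor(cohort$carrier, levels = c(TRUE, FALSE)),
                 factor(cohort$irae, levels = c(TRUE, FALSE)))
    icb_cov <- data.frame(icb = cohort$icb_type == "cICB")
    # separation in a small cohort is a reportable diagnostic, not a crash
    glm_row <- function(term, exposure, covariates) {
      tryCatch(
        dplyr::mutate(logistic_association(cohort$irae, exposure, covariates),
                      term = term),
        icbtox_separation_error = function(e) tibble::tibble(
          estimate = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
          p_value = NA_real_, method = "glm_binomial_separation",
          n = length(cohort$irae), log_or = NA_real_, se = NA_real_,
          term = term)
      )
    }
    assoc <- dplyr::bind_rows(
      dplyr::mutate(odds_ratio_2x2(unclass(tab)), term = "carrier_fisher"),
      glm_row("carrier_glm_icb_adjusted", cohort$carrier, icb_cov),
      if ("il7_expr" %in% names(cohort)) dplyr::bind_rows(
        glm_row("il7_glm_adjusted", cohort$il7_expr,
                cbind(icb_cov, carrier = cohort$carrier)),
        glm_row("carrier_glm_il7_adjusted", cohort$carrier,
                cbind(icb_cov, il7 = cohort$il7_expr)))
    )
    dplyr::relocate(assoc, "term")
  })

  stage("write_bundle", {
    out <- cfg$out_dir
    emit <- function(tb, name) {
      if (!is.null(tb)) readr::write_tsv(tb, file.path(out, name),
                                         progress = FALSE)
    }
    emit(results$tcr_metrics, "tcr_metrics.tsv")
    emit(results$bcr_metrics$mutation, "bcr_mutation.tsv")
    emit(results$bcr_metrics$usage, "bcr_ighc_usage.tsv")
    emit(results$expression$size_factors, "size_factors.tsv")
    emit(results$expression$scores, "signature_scores.tsv")
    emit(results$ls, "lymphocyte_stability.tsv")
    emit(results$association, "association.tsv")
    if (!is.null(results$expression)) {
      jsonlite::write_json(
        list(il7_patient_vs_healthy =
               results$expression$il7_patient_vs_healthy,
             il7_carrier_vs_noncarrier =
               results$expression$il7_carrier_vs_noncarrier),
        file.path(out, "effects.json"), auto_unbox = TRUE, digits = NA)
    }
  })

  manifest <- list(
    package = "icbtox",
    version = as.character(packageVersion("icbtox")),
    mode = cfg$mode,
    seed = cfg$seed,
    n_iter = cfg$n_iter,
    key_mode = cfg$key_mode,
    config_hash = hash(cfg[setdiff(names(cfg), "out_dir")])
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

# Assemble stage inputs for either mode.
pipeline_inputs <- function(cfg) {
  if (cfg$mode == "synthetic") {
    sim <- cfg$sim
    cohort <- gen_cohort(sim)
    k <- min(cfg$n_rep_samples, nrow(cohort))
    tcr <- dplyr::bind_rows(lapply(seq_len(k), function(i) {
      gen_repertoire(sim, skew = 0.2 * (i %% 2),
                     sample_id = sprintf("%s_TCR", cohort$patient_id[i]))
    }))
    bcr <- dplyr::bind_rows(lapply(seq_len(k), function(i) {
      gen_bcr_repertoire(sim, carrier = cohort$carrier[i],
                         sample_id = sprintf("%s_BCR", cohort$patient_id[i]))
    }))
    expr <- gen_expression(sim, cohort, n_genes = 500L, n_healthy = 40L)
    list(cohort = cohort, tcr = tcr, bcr = bcr, expression = expr,
         lymphocytes = gen_lymphocyte_series(sim, cohort))
  } else {
    clin <- readr::read_tsv(cfg$paths$clinical, progress = FALSE,
                            col_types = readr::cols())
    clin$carrier <- clin$genotype_dose > 0
    clin$irae <- as.logical(clin$irae)
    lym <- readr::read_tsv(cfg$paths$lymphocytes, progress = FALSE,
                           col_types = readr::cols())
    dialect <- cfg$paths$clonotype_dialect %||% "airr"
    clono <- dplyr::bind_rows(lapply(cfg$paths$clonotypes, read_clonotypes,
                                     dialect = dialect))
    expr <- if (!is.null(cfg$paths$counts)) {
      tb <- readr::read_tsv(cfg$paths$counts, progress = FALSE,
                            col_types = readr::cols())
      m <- as.matrix(tb[, -1])
      rownames(m) <- tb[[1]]
      sig <- cfg$paths$signature_genes %||% rownames(m)[seq_len(min(50, nrow(m)))]
      meta <- tibble::tibble(
        sample_id = colnames(m),
        status = ifelse(colnames(m) %in% clin$patient_id, "patient",
                        "healthy"),
        carrier = colnames(m) %in% clin$patient_id[clin$carrier])
      list(counts = m, samples = meta, il7_gene = cfg$paths$il7_gene %||% "IL7",
           signature_genes = sig)
    } else NULL
    list(cohort = clin,
         tcr = clono[clono$chain == "TRB", , drop = FALSE],
         bcr = clono[clono$chain %in% c("IGH", "IGK", "IGL"), , drop = FALSE],
         expression = expr, lymphocytes = lym)
  }
}
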