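#' Simulate a gene-by-sample raw count matrix with an IL7 eQTL
#'
#' Draws negative-binomial counts (variance = mu + dispersion * mu^2) for
#' healthy-donor and patient B cell samples with:
#' * per-sample library size factors (log-normal), so downstream
#'   median-of-ratios normalization has real work to do;
#' * a designated *IL7* gene whose mean is `2^healthy_il7_log2` in healthy
#'   donors, multiplied by `2^eqtl_log2_shift` in patients and by a
#'   further `2^carrier_il7_shift` in risk-allele carriers;
#' * signature genes tied to a latent per-sample mitotic factor, giving
#'   the geometric-mean signature score something coherent to recover.
#'
#' @param cfg A [sim_config()].
#' @param cohort Patient cohort from [gen_cohort()]; its `carrier` column
#'   drives the eQTL.
#' @param signature_genes Character vector naming the mitotic signature
#'   genes to embed (created in the matrix).
#' @param n_genes Number of background genes.
#' @param n_healthy Number of healthy-donor samples appended to the
#'   patient samples.
#' @return A list with `counts` (integer matrix, genes x samples),
#'   `samples` (tibble: `sample_id`, `status` = healthy/patient,
#'   `carrier`, `mitotic_factor`), `il7_gene` (`"IL7"`), and
#'   `signature_genes`.
#' @examples
#' cfg <- sim_config(n_patients = 20, seed = 3)
#' expr <- gen_expression(cfg, gen_cohort(cfg), n_genes = 200, n_healthy = 20)
#' dim(expr$counts)
#' @export
gen_expression <- function(cfg, cohort,
                           signature_genes = sprintf("SIG%03d", 1:50),
                           n_genes = 2000L, n_healthy = 92L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(cohort) == 0L) {
    abort("`cohort` must be non-empty", class = "icbtox_parameter_error")
  }
  assert_positive(cfg$nb_dispersion, "nb_dispersion")
  n_genes <- assert_count(n_genes, "n_genes")
  n_healthy <- assert_count(n_healthy, "n_healthy", min = 0L)

  samples <- tibble::tibble(
    sample_id = c(if (n_healthy > 0) sprintf("HD%03d", seq_len(n_healthy)),
                  cohort$patient_id),
    status = c(rep("healthy", n_healthy), rep("patient", nrow(cohort))),
    carrier = c(rep(FALSE, n_healthy), cohort$carrier)
  )
  n_s <- nrow(samples)

  gene_ids <- c("IL7", signature_genes, sprintf("G%05d", seq_len(n_genes)))

  with_seed(derive_seed(cfg$seed, "expression"), {
    base_mu <- rlnorm(length(gene_ids), meanlog = 4, sdlog = 1.5)
    names(base_mu) <- gene_ids
    base_mu["IL7"] <- 2^cfg$healthy_il7_log2

    size_fac <- rlnorm(n_s, 0, 0.2)
    mitotic <- rlnorm(n_s, 0, 0.3)
    samples$mitotic_factor <- mitotic

    il7_mult <- ifelse(samples$status == "patient",
                       2^cfg$eqtl_log2_shift, 1) *
      ifelse(samples$carrier, 2^cfg$carrier_il7_shift, 1)

    mu <- outer(base_mu, size_fac)
    mu["IL7", ] <- mu["IL7", ] * il7_mult
    mu[signature_genes, ] <- sweep(mu[signature_genes, , drop = FALSE], 2,
                                   mitotic, `*`)

    counts <- matrix(
      rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
      nrow = nrow(mu),
      dimnames = list(gene_ids, samples$sample_id)
    )
    list(counts = counts, samples = samples, il7_gene = "IL7",
         signature_genes = signature_genes)
  })
}
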