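# Synthetic receptor repertoires with heavy-tailed clone-size structure.

# Clone weights from a bounded Pareto law on [1, 1e4] with shape `alpha`
# (inverse-CDF sampling). Larger alpha concentrates mass near 1, giving
# near-uniform clone sizes; small alpha gives a dominant-clone tail.
bounded_pareto_weights <- function(n, alpha, hmax = 1e4) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    abort("power-law exponent `alpha` must be > 0",
          class = "icbtox_parameter_error")
  }
  u <- runif(n)
  l <- 1
  (1 - u * (1 - (l / hmax)^alpha))^(-1 / alpha) * l
}

trb_v_vocab <- sprintf("TRBV%d", c(2:7, 9:16, 18:20, 24:30))
trb_j_vocab <- c(sprintf("TRBJ1-%d", 1:6), sprintf("TRBJ2-%d", 1:7))
igh_v_vocab <- sprintf("IGHV%d-%d", rep(1:6, each = 4), rep(c(2, 3, 18, 69), 6))
igh_j_vocab <- sprintf("IGHJ%d", 1:6)
igk_v_vocab <- sprintf("IGKV%d-%d", rep(1:4, each = 3), rep(c(5, 12, 39), 4))
igk_j_vocab <- sprintf("IGKJ%d", 1:5)
igl_v_vocab <- sprintf("IGLV%d-%d", rep(1:3, each = 3), rep(c(40, 44, 51), 3))
igl_j_vocab <- sprintf("IGLJ%d", 1:3)
ighc_vocab <- c("IGHM", "IGHD", "IGHG1", "IGHG2", "IGHG3", "IGHG4",
                "IGHA1", "IGHA2", "IGHE")

# One chain's worth of clones: power-law frequencies, multinomial reads.
sample_chain_clones <- function(n_clones, depth, alpha, v_vocab, j_vocab,
                                chain, sample_id) {
  w <- bounded_pareto_weights(n_clones, alpha)
  reads <- as.vector(rmultinom(1, depth, prob = w / sum(w)))
  keep <- reads > 0
  n_obs <- sum(keep)
  if (n_obs == 0L) {
    return(empty_clonotype_table())
  }
  tibble::tibble(
    sample_id = sample_id,
    chain = chain,
    cdr3_nt = random_cdr3(n_obs),
    v_call = sample(v_vocab, n_obs, replace = TRUE),
    j_call = sample(j_vocab, n_obs, replace = TRUE),
    c_call = NA_character_,
    read_count = as.integer(reads[keep]),
    n_subs = 0L, n_ins = 0L, n_del = 0L,
    aligned_length = as.integer(3L * sample(110:130, n_obs, replace = TRUE))
  )
}

empty_clonotype_table <- function() {
  tibble::tibble(
    sample_id = character(), chain = character(), cdr3_nt = character(),
    v_call = character(), j_call = character(), c_call = character(),
    read_count = integer(), n_subs = integer(), n_ins = integer(),
    n_del = integer(), aligned_length = integer()
  )
}

#' Simulate a TCR beta-chain repertoire
#'
#' Clone frequencies follow a bounded Pareto (power-law) size distribution
#' with shape `powerlaw_alpha / (1 + skew)`; reads are then drawn
#' multinomially to the configured depth, so read counts always sum
#' exactly to `cfg$depth`. CDR3 nucleotide strings and V/J gene labels are
#' synthesised from fixed vocabularies. Clones receiving zero reads are
#' unobserved, as in real sequencing.
#'
#' @param cfg A [sim_config()].
#' @param skew Extra clonal skew: `skew > 0` lowers the effective Pareto
#'   shape (heavier tail, more unequal repertoire); must be > -1.
#' @param sample_id Sample identifier stamped on every record.
#' @return A clonotype tibble (one row per observed clone) with columns
#'   `sample_id`, `chain`, `cdr3_nt`, `v_call`, `j_call`, `c_call`,
#'   `read_count`, `n_subs`, `n_ins`, `n_del`, `aligned_length`.
#' @examples
#' rep <- gen_repertoire(sim_config(clone_count = 200, depth = 5000))
#' sum(rep$read_count)  # == 5000
#' @export
gen_repertoire <- function(cfg, skew = 0, sample_id = "S1") {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.numeric(skew) || length(skew) != 1L || is.na(skew) || skew <= -1) {
    abort("`skew` must be a single number > -1",
          class = "icbtox_parameter_error")
  }
  alpha_eff <- cfg$powerlaw_alpha / (1 + skew)
  with_seed(derive_seed(cfg$seed, paste0("repertoire:", sample_id)), {
    sample_chain_clones(cfg$clone_count, cfg$depth, alpha_eff,
                        trb_v_vocab, trb_j_vocab, "TRB", sample_id)
  })
}

#' Simulate a B cell receptor repertoire with maturation structure
#'
#' Generates IGH, IGK and IGL clonotypes with per-clone germline-divergent
#' mutation counts (substitutions, insertions, deletions) drawn from
#' Poisson models at a per-nucleotide rate, and IGHC isotype assignments
#' for heavy-chain clones. Risk-allele carriers receive an elevated
#' mutation rate (`bcr_mut_rate * bcr_mut_carrier_mult`) and a reduced
#' IGHD isotype probability (`ighd_carrier_mult`), emulating the
#' increased somatic hypermutation and reduced unswitched naive B cell
#' fraction seen in carriers.
#'
#' @param cfg A [sim_config()].
#' @param carrier Logical: simulate a risk-allele carrier?
#' @param sample_id Sample identifier.
#' @return A clonotype tibble as in [gen_repertoire()]; `c_call` is set
#'   for IGH clones only.
#' @export
gen_bcr_repertoire <- function(cfg, carrier = FALSE, sample_id = "S1") {
  stopifnot(inherits(cfg, "sim_config"), is.logical(carrier), length(carrier) == 1L)
  chain_frac <- c(IGH = 0.6, IGK = 0.25, IGL = 0.15)
  n_by_chain <- setNames(pmax(1L, round(cfg$clone_count * chain_frac)),
                         names(chain_frac))
  depth_by_chain <- setNames(round(cfg$depth * chain_frac),
                             names(chain_frac))
  mut_rate <- cfg$bcr_mut_rate * (if (carrier) cfg$bcr_mut_carrier_mult else 1)

  ighc_base <- c(IGHM = 0.35, IGHD = 0.25, IGHG1 = 0.12, IGHG2 = 0.06,
                 IGHG3 = 0.05, IGHG4 = 0.02, IGHA1 = 0.10, IGHA2 = 0.04,
                 IGHE = 0.01)
  ighc_p <- ighc_base
  if (carrier) ighc_p["IGHD"] <- ighc_p["IGHD"] * cfg$ighd_carrier_mult
  ighc_p <- ighc_p / sum(ighc_p)

  vocabs <- list(
    IGH = list(v = igh_v_vocab, j = igh_j_vocab),
    IGK = list(v = igk_v_vocab, j = igk_j_vocab),
    IGL = list(v = igl_v_vocab, j = igl_j_vocab)
  )

  with_seed(derive_seed(cfg$seed, paste0("bcr:", sample_id)), {
    parts <- lapply(names(chain_frac), function(ch) {
      tb <- sample_chain_clones(n_by_chain[[ch]], max(1L, depth_by_chain[[ch]]),
                                cfg$powerlaw_alpha, vocabs[[ch]]$v,
                                vocabs[[ch]]$j, ch, sample_id)
      n <- nrow(tb)
      if (n == 0L) return(tb)
      # mutation load split ~80% substitutions, ~10% each indel class
      tb$n_subs <- rpois(n, 0.8 * mut_rate * tb$aligned_length)
      tb$n_ins <- rpois(n, 0.1 * mut_rate * tb$aligned_length)
      tb$n_del <- rpois(n, 0.1 * mut_rate * tb$aligned_length)
      if (ch == "IGH") {
        tb$c_call <- sample(names(ighc_p), n, replace = TRUE, prob = ighc_p)
      }
      tb
    })
    dplyr::bind_rows(parts)
  })
}
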