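# Independent oracles and toy-table builders shared across tests.
# The oracles deliberately use brute-force / closed-form routes that are
# independent of the package implementation.

# O(n^2) pairwise-difference Gini definition.
gini_pairwise <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, `-`))) / (2 * n^2 * mean(x))
}

# Upper-tail hypergeometric P(X >= k) by explicit choose() enumeration:
# universe N, annotation size K, |hits| draws.
hyper_enum_upper <- function(k, K, N, n) {
  js <- seq.int(max(k, max(0, n - (N - K))), min(n, K))
  if (length(js) == 0 || k > min(n, K)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Two-sided Fisher exact p for a 2x2 table by enumerating the
# conditional (hypergeometric) distribution over the first cell.
fisher_enum_two_sided <- function(tab) {
  a <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0, c1 - m2); hi <- min(m1, c1)
  xs <- lo:hi
  probs <- choose(m1, xs) * choose(m2, c1 - xs) / choose(m1 + m2, c1)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Clone table with given read counts in one sample/chain.
make_clone_table <- function(reads, chain = "TRB", sample_id = "s1",
                             c_call = NA_character_, n_subs = 0L,
                             aligned_length = 360L) {
  n <- length(reads)
  tibble::tibble(
    sample_id = sample_id, chain = chain,
    cdr3_nt = sprintf("TGTGCC%04dTTT", seq_len(n)),
    v_call = sprintf("%sV%d", substr(chain, 1, 3), (seq_len(n) %% 7) + 1),
    j_call = sprintf("%sJ%d", substr(chain, 1, 3), (seq_len(n) %% 3) + 1),
    c_call = rep_len(c_call, n),
    total_reads = as.integer(reads),
    frequency = reads / sum(reads),
    n_subs = as.integer(rep_len(n_subs, n)), n_ins = 0L, n_del = 0L,
    aligned_length = as.integer(rep_len(aligned_length, n))
  )
}

# The hand-checkable 10,000-read occupancy fixture: one 600-read clone,
# forty 30-read clones, 8,200 singletons.
occupancy_fixture <- function() {
  make_clone_table(c(600L, rep(30L, 40), rep(1L, 8200)))
}

# Power-law clone frequencies used as a common source distribution.
powerlaw_freqs <- function(n_clones = 500, exponent = 1.2) {
  w <- seq_len(n_clones)^(-exponent)
  w / sum(w)
}
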