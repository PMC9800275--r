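write_lines_tsv <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("mixcr hit strings are normalized to the top gene-level call", {
  path <- write_lines_tsv(c(
    paste("cloneCount", "nSeqCDR3", "allVHitsWithScore", "allJHitsWithScore",
          "allCHitsWithScore", "nSubstitutions", "nInsertions", "nDeletions",
          "alignedLength", sep = "\t"),
    paste("12", "TGTGCCAGCTTT", "TRBV12-3*00(1200),TRBV12-4*00(900)",
          "TRBJ2-1*00(800)", "", "0", "0", "0", "360", sep = "\t")
  ))
  tb <- read_clonotypes(path, "mixcr", sample_id = "sampA")
  expect_identical(tb$v_call, "TRBV12-3")
  expect_identical(tb$j_call, "TRBJ2-1")
  expect_identical(tb$chain, "TRB")
  expect_identical(tb$read_count, 12L)
  expect_identical(nrow(attr(tb, "rejects")), 0L)
})

test_that("airr rows map duplicate_count/junction onto the record", {
  path <- write_lines_tsv(c(
    paste("sequence_id", "duplicate_count", "junction", "v_call", "j_call",
          "c_call", "n_subs", "n_ins", "n_del", "aligned_length", sep = "\t"),
    paste("q1", "7", "TGTGCCAGCTTT", "IGHV1-2*01", "IGHJ4*02", "IGHM",
          "3", "1", "0", "350", sep = "\t")
  ))
  tb <- read_clonotypes(path, "airr")
  expect_identical(tb$read_count, 7L)
  expect_identical(tb$cdr3_nt, "TGTGCCAGCTTT")
  expect_identical(tb$c_call, "IGHM")
  expect_identical(tb$chain, "IGH")
})

test_that("empty files, bad dialects and malformed rows behave as contracted", {
  header <- paste("cloneCount", "nSeqCDR3", "allVHitsWithScore",
                  "allJHitsWithScore", "allCHitsWithScore", "nSubstitutions",
                  "nInsertions", "nDeletions", "alignedLength", sep = "\t")
  empty <- write_lines_tsv(header)
  expect_identical(nrow(read_clonotypes(empty, "mixcr")), 0L)

  expect_error(read_clonotypes(empty, "nonsense"))
  expect_error(read_clonotypes(file.path(tempdir(), "nope.tsv"), "mixcr"),
               class = "icbtox_io_error")

  missing_col <- write_lines_tsv(c("cloneCount\tnSeqCDR3", "1\tTGT"))
  expect_error(read_clonotypes(missing_col, "mixcr"),
               class = "icbtox_parse_error", regexp = "allVHitsWithScore")

  bad_count <- write_lines_tsv(c(header, paste(
    "oops", "TGT", "TRBV1", "TRBJ1", "", "0", "0", "0", "300", sep = "\t")))
  expect_error(read_clonotypes(bad_count, "mixcr"),
               class = "icbtox_parse_error", regexp = "line")
})

test_that("invalid rows are quarantined with line numbers, not fatal", {
  header <- paste("cloneCount", "nSeqCDR3", "allVHitsWithScore",
                  "allJHitsWithScore", "allCHitsWithScore", "nSubstitutions",
                  "nInsertions", "nDeletions", "alignedLength", sep = "\t")
  path <- write_lines_tsv(c(
    header,
    paste("5", "TGTGCC", "TRBV1", "TRBJ1", "", "0", "0", "0", "300", sep = "\t"),
    paste("0", "TGTGCC", "TRBV1", "TRBJ1", "", "0", "0", "0", "300", sep = "\t"),
    paste("3", "TGTXCC", "TRBV1", "TRBJ1", "", "0", "0", "0", "300", sep = "\t"),
    paste("3", "TGTGCC", "TRBV1", "IGHJ2", "", "0", "0", "0", "300", sep = "\t")
  ))
  tb <- read_clonotypes(path, "mixcr")
  rej <- attr(tb, "rejects")
  expect_identical(nrow(tb), 1L)
  expect_identical(rej$line, c(3L, 4L, 5L))
  expect_identical(rej$reason,
                   c("read_count_lt_1", "invalid_cdr3", "vj_chain_conflict"))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_rejects(tb, out)
  expect_identical(nrow(readr::read_tsv(out, show_col_types = FALSE)), 3L)
})

test_that("round-trip through both dialects preserves shared fields", {
  cfg <- sim_config(clone_count = 120L, depth = 3000L, seed = 6)
  for (dialect in c("mixcr", "airr")) {
    for (s in 1:3) {
      tab <- if (s == 1) {
        gen_bcr_repertoire(sim_config(clone_count = 80L, depth = 2000L,
                                      seed = s), carrier = TRUE, "b")
      } else {
        gen_repertoire(sim_config(clone_count = 120L, depth = 3000L, seed = s),
                       sample_id = "r")
      }
      # CDR3s with N are preserved verbatim
      tab$cdr3_nt[1] <- sub("A", "N", tab$cdr3_nt[1])
      path <- withr::local_tempfile(fileext = ".tsv")
      write_clonotypes(tab, path, dialect)
      back <- read_clonotypes(path, dialect)
      expect_equal(as.data.frame(back), as.data.frame(tab),
                   ignore_attr = TRUE)
    }
  }
})

test_that("airr output carries the standard header fields", {
  tab <- gen_repertoire(sim_config(clone_count = 20L, depth = 500L, seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clonotypes(tab, path, "airr")
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_true(all(c("sequence_id", "duplicate_count", "junction", "v_call",
                    "j_call", "c_call") %in% header))
})

test_that("clone aggregation sums reads and respects the identity key", {
  recs <- tibble::tibble(
    sample_id = "s1", chain = "TRB",
    cdr3_nt = c("TGTAAA", "TGTAAA", "TGTAAA"),
    v_call = c("TRBV1", "TRBV1", "TRBV2"),
    j_call = "TRBJ1", c_call = NA_character_,
    read_count = c(3L, 5L, 2L), n_subs = c(1L, 2L, 4L), n_ins = 0L,
    n_del = 0L, aligned_length = 300L
  )
  vj <- aggregate_clones(recs, "cdr3_vj")
  expect_identical(nrow(vj), 2L)
  expect_identical(sort(vj$total_reads), c(2L, 8L))
  only <- aggregate_clones(recs, "cdr3_only")
  expect_identical(nrow(only), 1L)
  expect_identical(only$total_reads, 10L)
  expect_identical(only$n_subs, 7L)
})

test_that("frequencies normalize per (sample, chain) and after filters", {
  cfg <- sim_config(clone_count = 150L, depth = 4000L, seed = 9)
  recs <- dplyr::bind_rows(gen_bcr_repertoire(cfg, FALSE, "s1"),
                           gen_repertoire(cfg, sample_id = "s2"))
  cl <- aggregate_clones(recs)
  sums <- dplyr::summarise(dplyr::group_by(cl, sample_id, chain),
                           f = sum(frequency))
  expect_true(all(abs(sums$f - 1) < 1e-9))
  # re-normalization property after an arbitrary filter + re-aggregation
  sub <- cl[cl$total_reads > 1, , drop = FALSE]
  re <- aggregate_clones(sub)
  sums2 <- dplyr::summarise(dplyr::group_by(re, sample_id, chain),
                            f = sum(frequency))
  expect_true(all(abs(sums2$f - 1) < 1e-9))
})

test_that("aggregation is idempotent and toy frequencies are exact", {
  toy <- make_clone_table(c(8L, 2L))
  expect_identical(toy$frequency, c(0.8, 0.2))
  cl <- aggregate_clones(gen_repertoire(
    sim_config(clone_count = 60L, depth = 1500L, seed = 12)))
  again <- aggregate_clones(cl)
  expect_equal(dplyr::arrange(again, cdr3_nt, v_call),
               dplyr::arrange(cl, cdr3_nt, v_call))
})

test_that("c_call majority is read-weighted with a deterministic tie-break", {
  recs <- tibble::tibble(
    sample_id = "s1", chain = "IGH", cdr3_nt = "TGTAAA",
    v_call = "IGHV1-2", j_call = "IGHJ4",
    c_call = c("IGHM", "IGHG1", NA),
    read_count = c(10L, 60L, 5L), n_subs = 0L, n_ins = 0L, n_del = 0L,
    aligned_length = 300L
  )
  expect_identical(aggregate_clones(recs)$c_call, "IGHG1")
  recs$read_count <- c(10L, 10L, 5L)
  expect_identical(aggregate_clones(recs)$c_call, "IGHG1")  # lexicographic tie
})
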