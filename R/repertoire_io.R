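# Clonotype table I/O: MiXCR-export-like and AIRR Rearrangement TSV
# dialects, plus aggregation of reads into clones.

mixcr_cols <- c(
  read_count = "cloneCount", cdr3_nt = "nSeqCDR3",
  v_call = "allVHitsWithScore", j_call = "allJHitsWithScore",
  c_call = "allCHitsWithScore", n_subs = "nSubstitutions",
  n_ins = "nInsertions", n_del = "nDeletions",
  aligned_length = "alignedLength"
)
airr_cols <- c(
  read_count = "duplicate_count", cdr3_nt = "junction",
  v_call = "v_call", j_call = "j_call", c_call = "c_call",
  n_subs = "n_subs", n_ins = "n_ins", n_del = "n_del",
  aligned_length = "aligned_length"
)

# "TRBV12-3*00(1200),TRBV12-4*00(900)" -> "TRBV12-3": take the top
# (first-listed, highest-score) hit, strip the score parenthesis and the
# allele suffix. Gene-level granularity matches clonotype usage downstream.
normalize_gene_call <- function(x) {
  x <- trimws(x)
  x[!is.na(x) & x == ""] <- NA_character_
  first <- sub(",.*$", "", x)
  first <- sub("\\(.*\\)", "", first)
  sub("\\*.*$", "", first)
}

chain_from_call <- function(call) {
  pfx <- substr(call, 1, 3)
  ifelse(pfx %in% c("TRB", "TRA", "TRG", "TRD", "IGH", "IGK", "IGL"),
         pfx, "other")
}

#' Read a clonotype table from a MiXCR-like or AIRR Rearrangement TSV
#'
#' Parses and validates per-clone receptor records. Gene calls are
#' normalized to gene level (top hit, allele suffix `*xx` and score
#' parentheses stripped); the chain is inferred from the V-call prefix.
#' Rows that fail validation (non-positive read counts, CDR3 characters
#' outside `ACGTN`, conflicting V/J chain prefixes) are quarantined, not
#' fatal: they are returned in the `rejects` attribute with their file
#' line numbers and a reason code.
#'
#' @param path TSV file path (UTF-8, tab-delimited, header required).
#' @param dialect `"mixcr"` (columns `cloneCount`, `nSeqCDR3`,
#'   `allVHitsWithScore`, ...) or `"airr"` (`duplicate_count`, `junction`,
#'   `v_call`, `j_call`, `c_call`, ...).
#' @param sample_id Sample identifier to stamp on the records; defaults to
#'   a `sample_id`/`sampleId` column if present, else the file name.
#' @return A clonotype tibble (see [gen_repertoire()] for columns) with a
#'   `rejects` attribute (tibble: `line`, `reason`).
#' @export
read_clonotypes <- function(path, dialect = c("mixcr", "airr"),
                            sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("clonotype file not found: %s", path),
          class = "icbtox_io_error")
  }
  cols <- if (dialect == "mixcr") mixcr_cols else airr_cols
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- setdiff(unname(cols), cols[["c_call"]])
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing mandatory %s column(s): %s",
                  path, dialect, paste(missing, collapse = ", ")),
          class = "icbtox_parse_error")
  }

  sid_col <- intersect(c("sample_id", "sampleId"), names(raw))
  sid <- if (!is.null(sample_id)) {
    rep(sample_id, nrow(raw))
  } else if (length(sid_col) > 0) {
    raw[[sid_col[1]]]
  } else {
    rep(sub("\\.[^.]*$", "", basename(path)), nrow(raw))
  }

  pick <- function(field) {
    if (cols[[field]] %in% names(raw)) raw[[cols[[field]]]] else NA_character_
  }
  count_raw <- pick("read_count")
  bad_num <- !is.na(count_raw) & is.na(suppressWarnings(as.numeric(count_raw)))
  if (any(bad_num)) {
    abort(sprintf("%s: non-numeric %s at line(s) %s",
                  path, cols[["read_count"]],
                  paste(which(bad_num) + 1L, collapse = ", ")),
          class = "icbtox_parse_error")
  }

  to_int <- function(x) {
    out <- suppressWarnings(as.numeric(x))
    as.integer(round(out))
  }
  tb <- tibble::tibble(
    sample_id = as.character(sid),
    cdr3_nt = toupper(pick("cdr3_nt")),
    v_call = normalize_gene_call(pick("v_call")),
    j_call = normalize_gene_call(pick("j_call")),
    c_call = normalize_gene_call(pick("c_call")),
    read_count = to_int(count_raw),
    n_subs = to_int(pick("n_subs")),
    n_ins = to_int(pick("n_ins")),
    n_del = to_int(pick("n_del")),
    aligned_length = to_int(pick("aligned_length"))
  )
  tb$n_subs[is.na(tb$n_subs)] <- 0L
  tb$n_ins[is.na(tb$n_ins)] <- 0L
  tb$n_del[is.na(tb$n_del)] <- 0L
  tb$chain <- chain_from_call(tb$v_call)
  tb <- tb[, c("sample_id", "chain", "cdr3_nt", "v_call", "j_call", "c_call",
               "read_count", "n_subs", "n_ins", "n_del", "aligned_length")]

  j_chain <- chain_from_call(tb$j_call)
  reason <- rep(NA_character_, nrow(tb))
  reason[is.na(tb$read_count) | tb$read_count < 1] <- "read_count_lt_1"
  bad_cdr3 <- is.na(tb$cdr3_nt) | grepl("[^ACGTN]", tb$cdr3_nt)
  reason[is.na(reason) & bad_cdr3] <- "invalid_cdr3"
  conflict <- tb$chain != "other" & j_chain != "other" & tb$chain != j_chain
  reason[is.na(reason) & conflict] <- "vj_chain_conflict"

  ok <- is.na(reason)
  rejects <- tibble::tibble(line = which(!ok) + 1L, reason = reason[!ok])
  out <- tb[ok, , drop = FALSE]
  attr(out, "rejects") <- rejects
  out
}

#' Write a clonotype table as MiXCR-like or AIRR Rearrangement TSV
#'
#' Field-for-field round-trip partner of [read_clonotypes()]:
#' `read_clonotypes(write_clonotypes(x, p, d), d)` reproduces `x` on all
#' shared columns.
#'
#' @param table A clonotype tibble.
#' @param path Output TSV path.
#' @param dialect `"mixcr"` or `"airr"`.
#' @return `path`, invisibly.
#' @export
write_clonotypes <- function(table, path, dialect = c("mixcr", "airr")) {
  dialect <- match.arg(dialect)
  cols <- if (dialect == "mixcr") mixcr_cols else airr_cols
  out <- tibble::tibble(sample_id = table$sample_id)
  for (field in names(cols)) {
    out[[cols[[field]]]] <- table[[field]]
  }
  if (dialect == "airr") {
    out <- tibble::tibble(sequence_id = sprintf("seq%06d", seq_len(nrow(table))),
                          out)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a rejects report
#'
#' @param records A clonotype tibble returned by [read_clonotypes()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_rejects <- function(records, path) {
  rej <- attr(records, "rejects") %||%
    tibble::tibble(line = integer(), reason = character())
  readr::write_tsv(rej, path, progress = FALSE)
  invisible(path)
}

#' Aggregate clonotype reads into clones under a declared identity key
#'
#' Sums read counts within the clone key — CDR3 nucleotide sequence alone
#' (`"cdr3_only"`) or CDR3 plus V and J gene (`"cdr3_vj"`) — within each
#' (sample, chain). Mutation counts and aligned lengths are summed;
#' `c_call` is assigned by read-weighted majority (lexicographic
#' tie-break, missing calls ignored). Clone frequency is the clone's reads
#' over the total reads of its (sample, chain), so frequencies sum to 1
#' per chain. Aggregation is idempotent: re-aggregating a clone table
#' under the same key is the identity on counts.
#'
#' @param records Clonotype tibble (from [read_clonotypes()] or a
#'   generator) or an already-aggregated clone table.
#' @param key_mode `"cdr3_vj"` (default; the occupancy-analysis clone
#'   definition) or `"cdr3_only"` (the Gini-analysis definition).
#' @return A clone tibble: `sample_id`, `chain`, `cdr3_nt`, `v_call`,
#'   `j_call` (`NA` under `cdr3_only`), `c_call`, `total_reads`,
#'   `frequency`, `n_subs`, `n_ins`, `n_del`, `aligned_length`.
#' @export
aggregate_clones <- function(records, key_mode = c("cdr3_vj", "cdr3_only")) {
  key_mode <- match.arg(key_mode)
  if (!"read_count" %in% names(records) && "total_reads" %in% names(records)) {
    records <- dplyr::rename(records, read_count = "total_reads")
  }
  if (nrow(records) == 0L) {
    out <- empty_clonotype_table()
    out <- dplyr::rename(out, total_reads = "read_count")
    out$frequency <- numeric()
    return(out)
  }
  keys <- c("sample_id", "chain", "cdr3_nt",
            if (key_mode == "cdr3_vj") c("v_call", "j_call"))

  majority_c_call <- function(c_call, reads) {
    keep <- !is.na(c_call)
    if (!any(keep)) return(NA_character_)
    w <- tapply(reads[keep], c_call[keep], sum)
    names(w)[order(-w, names(w))][1]
  }

  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      c_call = majority_c_call(.data$c_call, .data$read_count),
      total_reads = sum(.data$read_count),
      n_subs = sum(.data$n_subs),
      n_ins = sum(.data$n_ins),
      n_del = sum(.data$n_del),
      aligned_length = sum(.data$aligned_length),
      .groups = "drop"
    )
  if (key_mode == "cdr3_only") {
    out$v_call <- NA_character_
    out$j_call <- NA_character_
  }
  out <- out |>
    dplyr::group_by(.data$sample_id, .data$chain) |>
    dplyr::mutate(frequency = .data$total_reads / sum(.data$total_reads)) |>
    dplyr::ungroup()
  out[, c("sample_id", "chain", "cdr3_nt", "v_call", "j_call", "c_call",
          "total_reads", "frequency", "n_subs", "n_ins", "n_del",
          "aligned_length")]
}
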