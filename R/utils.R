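# Internal helpers: seed streams, validation, small shared utilities.

# Deterministic 31-bit hash of a character tag (polynomial rolling hash).
# Used to derive independent, reproducible RNG streams per sub-module or
# sample from one global seed.
str_hash31 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (code in utf8ToInt(x)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Sub-seed for a named stream; stays below 2^31 - 1.
derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) %% 2147483647 + str_hash31(tag)) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single fraction in [0, 1], got %s",
                  name, deparse(x)), class = "icbtox_parameter_error")
  }
  invisible(x)
}

assert_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    abort(sprintf("`%s` must be a single %s number, got %s",
                  name, if (strict) "positive" else "non-negative", deparse(x)),
          class = "icbtox_parameter_error")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x >= min && x == as.integer(x)
  if (!ok) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s",
                  name, min, deparse(x)), class = "icbtox_parameter_error")
  }
  invisible(as.integer(x))
}

# Random nucleotide strings (CDR3-like), lengths a multiple of 3.
random_cdr3 <- function(n, min_codons = 12L, max_codons = 20L) {
  lens <- 3L * sample(seq.int(min_codons, max_codons), n, replace = TRUE)
  vapply(lens, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
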