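# Internal helpers shared across the package.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive per-repeat sub-seeds from a master seed; kept below 2^31 - 1.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce labels to a 0/1 integer vector, checking values.
as_binary_label <- function(y) {
  y <- as.integer(round(as.numeric(y)))
  if (anyNA(y) || !all(y %in% c(0L, 1L))) {
    stop_fmt("labels must be binary 0/1")
  }
  y
}

# md5 of an in-memory character scalar (used for config hashes and the
# published-model fingerprint); tools::md5sum works on files only.
md5_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}
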