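# Small shared helpers.

# Evaluate expr under a local RNG seed, restoring the caller's stream so
# generators are pure functions of (spec, seed).
with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, globalenv())
    } else if (exists(".Random.seed", globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}

# Derive a sub-seed for an independent stream per output kind, keeping the
# result inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% .Machine$integer.max)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
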