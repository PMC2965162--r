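# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. All stochastic operations in the package route through
# this so that no call mutates global RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
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
  set.seed(as.integer(seed))
  code
}

# Derive a child seed from a base seed; keeps results within 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 10007L * as.integer(offset)) %% 2147483647L
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1]", name), call. = FALSE)
  }
  as.numeric(x)
}

# Consistent, locale-independent ordering for gene identifiers; every ranking
# and tie-break in the package uses this so output is reproducible.
sort_ids <- function(x) sort(x, method = "radix")

order_ids <- function(x) order(x, method = "radix")

combo_label <- function(genes) paste(genes, collapse = "+")

split_combo <- function(label) strsplit(label, "+", fixed = TRUE)

write_tsv <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE, na = "NA"
  )
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE, ...)
}
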