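#' Read a GMT gene-set file
#'
#' Standard Gene Matrix Transposed format: one set per line, tab-separated
#' fields `name`, `description`, then member gene ids.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors; each element carries its
#'   description as the `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file", call. = FALSE)
  sets <- list()
  for (line in lines) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stop(sprintf("malformed GMT line (need name, description, >= 1 gene): %s",
        substr(line, 1, 60)
      ), call. = FALSE)
    }
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    sets[[parts[1L]]] <- structure(genes, description = parts[2L])
  }
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Gene-set collection with a background universe
#'
#' Couples named gene sets (pathways, a secretory gene list, ...) with the
#' background universe against which enrichment is assessed — here, all
#' genes measured on the platform. Set members outside the background are
#' dropped with a warning; sets left empty are removed with a warning.
#'
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param background Character vector: the gene universe.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, background) {
  if (!is.list(sets) || is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("`sets` must be a uniquely named list", call. = FALSE)
  }
  background <- unique(as.character(background))
  if (!length(background)) stop("`background` is empty", call. = FALSE)
  dropped <- 0L
  for (nm in names(sets)) {
    inside <- intersect(sets[[nm]], background)
    dropped <- dropped + (length(unique(sets[[nm]])) - length(inside))
    sets[[nm]] <- inside
  }
  if (dropped > 0L) {
    warning(sprintf(
      "%d gene-set member(s) outside the background universe were dropped", dropped
    ), call. = FALSE)
  }
  empty <- names(sets)[!vapply(sets, length, integer(1))]
  if (length(empty)) {
    warning(sprintf(
      "empty gene set(s) removed: %s", paste(empty, collapse = ", ")
    ), call. = FALSE)
    sets <- sets[setdiff(names(sets), empty)]
  }
  if (!length(sets)) stop("no usable gene sets remain", call. = FALSE)
  structure(list(sets = sets, background = background),
    class = "gene_set_collection"
  )
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided over-representation test of a query gene list (e.g. the DE
#' genes of one cancer) against each set of a collection: the p-value is
#' the upper tail of the hypergeometric distribution at the observed
#' overlap, i.e. the probability of drawing at least that many set members
#' when `|query|` genes are drawn from the background without replacement.
#' A set is flagged enriched when `p < alpha`. Run the test separately on
#' the up- and down-regulated sublists to distinguish activated from
#' deactivated pathways.
#'
#' @param query Character vector of gene ids; members outside the
#'   background are dropped with a warning.
#' @param collection A [gene_set_collection()].
#' @param alpha Significance level (default 0.05, on raw p-values).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame sorted by p-value: `set`, `overlap`, `set_size`,
#'   `query_size`, `background_size`, `p_value`, `enriched`.
#' @examples
#' coll <- gene_set_collection(
#'   list(s1 = paste0("g", 1:5)),
#'   paste0("g", 1:20)
#' )
#' hypergeometric_enrichment(paste0("g", 1:5), coll)
#' @export
hypergeometric_enrichment <- function(query, collection, alpha = 0.05,
                                      adjust = c("none", "BH")) {
  stopifnot(inherits(collection, "gene_set_collection"))
  adjust <- match.arg(adjust)
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$background)
  if (length(outside)) {
    warning(sprintf(
      "%d query gene(s) outside the background universe were dropped", length(outside)
    ), call. = FALSE)
    query <- intersect(query, collection$background)
  }
  if (!length(query)) stop("query is empty after background intersection", call. = FALSE)
  N <- length(collection$background)
  n <- length(query)
  res <- lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    K <- length(set)
    ov <- length(intersect(query, set))
    p <- stats::phyper(ov - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(
      set = nm, overlap = ov, set_size = K, query_size = n,
      background_size = N, p_value = p, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  if (adjust == "BH") out$p_value_adjusted <- stats::p.adjust(out$p_value, "BH")
  crit <- if (adjust == "BH") out$p_value_adjusted else out$p_value
  out$enriched <- crit < alpha
  out <- out[order(out$p_value, out$set, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter marker candidates to blood-secretory panels
#'
#' Retains candidate combinations whose genes are all annotated as
#' blood-secretory (a user-supplied gene list standing in for a secretome
#' predictor) and whose classification accuracy clears `accuracy_floor`.
#' For single-cancer candidate tables the qualifying accuracy is
#' `cv_accuracy`; for multi-cancer tables every `*_train` column is a
#' qualifying accuracy and at least `min_qualifying` of them must reach the
#' floor (missing accuracies never qualify).
#'
#' @param candidates A [rank_markers()] or [find_multi_cancer_combos()]
#'   result (any data frame with a `genes` column of `"+"`-joined ids).
#' @param secretory_genes Non-empty character vector of secretory gene ids.
#' @param accuracy_floor Minimum qualifying accuracy (default 0.70).
#' @param min_qualifying Minimum number of qualifying accuracies at or
#'   above the floor (default 1).
#' @return The filtered subset of `candidates` (same columns). The
#'   operation is idempotent.
#' @export
filter_secretory <- function(candidates, secretory_genes, accuracy_floor = 0.70,
                             min_qualifying = 1L) {
  if (!length(secretory_genes)) stop("secretory gene set is empty", call. = FALSE)
  if (!"genes" %in% names(candidates)) {
    stop("`candidates` must have a `genes` column", call. = FALSE)
  }
  acc_cols <- if ("cv_accuracy" %in% names(candidates)) {
    "cv_accuracy"
  } else {
    grep("_train$", names(candidates), value = TRUE)
  }
  if (!length(acc_cols)) {
    stop("`candidates` has no accuracy column (cv_accuracy or *_train)", call. = FALSE)
  }
  combos <- split_combo(candidates$genes)
  all_secretory <- vapply(combos, function(g) all(g %in% secretory_genes), logical(1))
  acc <- as.matrix(candidates[, acc_cols, drop = FALSE])
  qualifying <- rowSums(acc >= accuracy_floor, na.rm = TRUE)
  keep <- all_secretory & qualifying >= min_qualifying
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlate DE-gene counts with five-year survival
#'
#' Across cancer types, correlates the number of differentially expressed
#' genes with the five-year survival rate — more aggressive cancers (lower
#' survival) tend to show more expression changes.
#'
#' @param records Data frame with columns `cancer`, `de_gene_count` and
#'   `five_year_survival_rate` (percent, in `[0, 100]`); at least 3 rows.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list with `r` (coefficient), `p_value` (two-sided), `method`
#'   and `n`.
#' @examples
#' survival_correlation(data.frame(
#'   cancer = c("a", "b", "c"),
#'   de_gene_count = c(1, 2, 3),
#'   five_year_survival_rate = c(90, 80, 70)
#' ))
#' @export
survival_correlation <- function(records, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  need <- c("cancer", "de_gene_count", "five_year_survival_rate")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop(sprintf("`records` lacks column(s): %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  x <- as.numeric(records$de_gene_count)
  y <- as.numeric(records$five_year_survival_rate)
  if (length(x) < 3L) stop("need at least 3 records", call. = FALSE)
  if (any(x < 0)) stop("DE counts must be non-negative", call. = FALSE)
  if (any(y < 0 | y > 100)) stop("survival rates must lie in [0, 100]", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(
    r = unname(ct$estimate), p_value = ct$p.value,
    method = method, n = length(x)
  )
}

#' Read a five-year survival table
#'
#' TSV with columns `cancer` and `five_year_survival_rate` (percent);
#' an optional `de_gene_count` column is carried through (the pipeline
#' normally fills it from its own DE results).
#'
#' @param path Path to the TSV file.
#' @return Data frame.
#' @export
read_survival_table <- function(path) {
  df <- read_tsv(path)
  need <- c("cancer", "five_year_survival_rate")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf(
      "survival table lacks column(s): %s", paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  df
}
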