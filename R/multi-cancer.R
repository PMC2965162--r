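#' Assemble a multi-cancer panel
#'
#' A `CancerPanel` collects, per cancer type, a training cohort, zero or
#' more independent test cohorts, and (once computed) the differential
#' expression table. It is the input to the cross-cancer analyses:
#' [find_shared_de_genes()] and [find_multi_cancer_combos()].
#'
#' @param entries Named list; each element a list with `train` (an
#'   [expression_dataset()]), optional `tests` (list of datasets) and
#'   optional `de` (a [call_differential()] result on `train`).
#' @return An object of class `CancerPanel`.
#' @export
cancer_panel <- function(entries) {
  if (!is.list(entries) || !length(entries)) {
    stop("`entries` must be a non-empty named list", call. = FALSE)
  }
  nms <- names(entries)
  if (is.null(nms) || anyNA(nms) || any(nms == "") || anyDuplicated(nms)) {
    stop("cancer names must be unique and non-empty", call. = FALSE)
  }
  for (nm in nms) {
    e <- entries[[nm]]
    if (!inherits(e$train, "ExpressionDataset")) {
      stop(sprintf("entry '%s' lacks a training ExpressionDataset", nm), call. = FALSE)
    }
    if (is.null(e$tests)) entries[[nm]]$tests <- list()
    if (!is.null(e$de)) {
      if (!setequal(e$de$gene, gene_ids(e$train))) {
        stop(sprintf(
          "entry '%s': DE table does not match the training gene universe", nm
        ), call. = FALSE)
      }
    }
    entries[[nm]]$name <- nm
  }
  structure(list(cancers = entries), class = "CancerPanel")
}

#' @export
print.CancerPanel <- function(x, ...) {
  cat(sprintf("CancerPanel with %d cancer type(s):\n", length(x$cancers)))
  for (e in x$cancers) {
    cat(sprintf(
      "  %s: %d genes, %d train samples, %d test cohort(s)%s\n",
      e$name, nrow(e$train$exprs), ncol(e$train$exprs), length(e$tests),
      if (is.null(e$de)) "" else sprintf(", %d DE genes", sum(e$de$is_de))
    ))
  }
  invisible(x)
}

#' Run differential expression for every cancer in a panel
#'
#' @param panel A [cancer_panel()].
#' @param ... Passed to [call_differential()] (alpha, min_fc, design, ...).
#' @return The panel with each entry's `de` table filled in.
#' @export
panel_differential <- function(panel, ...) {
  stopifnot(inherits(panel, "CancerPanel"))
  for (nm in names(panel$cancers)) {
    panel$cancers[[nm]]$de <- call_differential(panel$cancers[[nm]]$train, ...)
  }
  panel
}

panel_de_or_stop <- function(panel) {
  missing <- names(panel$cancers)[vapply(panel$cancers, function(e) is.null(e$de), logical(1))]
  if (length(missing)) {
    stop(sprintf(
      "no DE table for cancer(s) %s; run panel_differential() first",
      paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(panel)
}

#' Genes differentially expressed across multiple cancer types
#'
#' Intersects the per-cancer differential-expression calls of a panel and
#' reports every gene DE in at least `min_types` cancers, with its
#' regulation direction in each cancer. With
#' `require_consistency = TRUE` only genes with the same direction in every
#' cancer where they are DE are kept ("consistently differentially
#' expressed").
#'
#' @param panel A [cancer_panel()] with DE tables (see
#'   [panel_differential()]).
#' @param min_types Minimum number of cancer types (>= 1; `min_types = 1`
#'   returns the union of the per-cancer DE sets).
#' @param require_consistency Drop genes whose direction differs between
#'   cancers.
#' @return Data frame sorted by count (descending) then gene id: `gene`,
#'   one direction column per cancer (`+1` up, `-1` down, `0` not DE),
#'   `count`, `consistent`.
#' @export
find_shared_de_genes <- function(panel, min_types = 2L, require_consistency = TRUE) {
  stopifnot(inherits(panel, "CancerPanel"))
  panel_de_or_stop(panel)
  min_types <- check_count(min_types, "min_types", min = 1L)
  cancers <- names(panel$cancers)
  de_sets <- lapply(panel$cancers, function(e) {
    de <- e$de[e$de$is_de, , drop = FALSE]
    stats::setNames(ifelse(de$direction == "up", 1L, -1L), de$gene)
  })
  genes <- sort_ids(unique(unlist(lapply(de_sets, names))))
  if (!length(genes)) {
    out <- data.frame(gene = character(0))
    for (nm in cancers) out[[nm]] <- integer(0)
    out$count <- integer(0)
    out$consistent <- logical(0)
    return(out)
  }
  dir <- sapply(de_sets, function(s) {
    v <- s[genes]
    v[is.na(v)] <- 0L
    v
  })
  dir <- matrix(dir, nrow = length(genes), dimnames = list(genes, cancers))
  count <- rowSums(dir != 0L)
  consistent <- apply(dir, 1L, function(v) {
    v <- v[v != 0L]
    length(unique(v)) == 1L
  })
  keep <- count >= min_types
  if (require_consistency) keep <- keep & consistent
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (nm in cancers) out[[nm]] <- unname(dir[, nm])
  out$count <- as.integer(count)
  out$consistent <- consistent
  out <- out[keep, , drop = FALSE]
  out <- out[order(-out$count, out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' k-gene combinations discriminative across multiple cancers
#'
#' Enumerates k-gene combinations from the pool of genes consistently DE in
#' at least two cancer types, scores each combination's cross-validated
#' training accuracy separately in every cancer of the panel, and retains
#' combinations whose training accuracy reaches `accuracy_cutoff` in at
#' least `min_types` cancers. Test-cohort accuracies are reported as well;
#' a combination containing a gene absent from a test platform gets `NA`
#' for that cohort (membership counts use training accuracies only, so they
#' are unaffected).
#'
#' @param panel A [cancer_panel()] with DE tables.
#' @param k Combination size.
#' @param accuracy_cutoff Training-accuracy cut-off in `(0.5, 1]`
#'   (default 0.70).
#' @param min_types Minimum number of cancers meeting the cut-off.
#' @param folds,seed,cost Cross-validation settings.
#' @param require_consistency Consistency rule for the shared gene pool.
#' @param max_pool Optional cap on the shared-pool size (top genes by
#'   count, then id) to bound the enumeration.
#' @return Data frame of class `multi_cancer_combos` sorted by `count`
#'   (descending), mean training accuracy, then gene tuple: `genes`, `k`,
#'   `count`, and per cancer `<name>_train` plus `<name>_<test>` columns.
#' @export
find_multi_cancer_combos <- function(panel, k, accuracy_cutoff = 0.70,
                                     min_types = 2L, folds = 5L, seed = 1L,
                                     cost = 1, require_consistency = TRUE,
                                     max_pool = NULL) {
  stopifnot(inherits(panel, "CancerPanel"))
  panel_de_or_stop(panel)
  if (!is.numeric(accuracy_cutoff) || accuracy_cutoff <= 0.5 || accuracy_cutoff > 1) {
    stop("`accuracy_cutoff` must lie in (0.5, 1]", call. = FALSE)
  }
  min_types <- check_count(min_types, "min_types", min = 1L)
  shared <- find_shared_de_genes(panel,
    min_types = 2L,
    require_consistency = require_consistency
  )
  if (!nrow(shared)) stop("no shared DE genes to combine", call. = FALSE)
  pool <- shared$gene
  if (!is.null(max_pool) && length(pool) > max_pool) {
    pool <- shared$gene[seq_len(max_pool)]
  }
  pool <- sort_ids(pool)
  combos <- enumerate_combinations(pool, k)
  labels_list <- lapply(panel$cancers, function(e) sample_conditions(e$train))
  fold_ids <- lapply(labels_list, make_folds, folds = folds, seed = seed)
  cancers <- names(panel$cancers)

  train_acc <- matrix(NA_real_, nrow(combos), length(cancers),
    dimnames = list(NULL, cancers)
  )
  test_acc <- list()
  for (nm in cancers) {
    e <- panel$cancers[[nm]]
    have <- apply(combos, 1L, function(g) all(g %in% gene_ids(e$train)))
    for (i in which(have)) {
      train_acc[i, nm] <- cross_validated_accuracy(
        e$train, combos[i, ],
        cost = cost, fold_ids = fold_ids[[nm]]
      )
    }
    if (length(e$tests)) {
      tn <- names(e$tests)
      if (is.null(tn) || any(tn == "")) tn <- paste0("test", seq_along(e$tests))
      full_labels <- labels_list[[nm]]
      for (j in seq_along(e$tests)) {
        col <- paste0(nm, "_", tn[j])
        ds <- e$tests[[j]]
        acc <- rep(NA_real_, nrow(combos))
        for (i in which(have)) {
          genes <- combos[i, ]
          if (!all(genes %in% gene_ids(ds))) next # platform miss
          fit <- train_linear_classifier(
            t(e$train$exprs[genes, , drop = FALSE]), full_labels,
            cost = cost
          )
          pred <- predict_labels(fit, t(ds$exprs[genes, , drop = FALSE]))
          acc[i] <- classification_accuracy(pred, sample_conditions(ds))$accuracy
        }
        test_acc[[col]] <- acc
      }
    }
  }

  count <- rowSums(train_acc >= accuracy_cutoff, na.rm = TRUE)
  mean_train <- rowMeans(train_acc, na.rm = TRUE)
  label <- apply(combos, 1L, combo_label)
  keep <- which(count >= min_types)
  ord <- keep[order(-count[keep], -mean_train[keep], label[keep], method = "radix")]
  out <- data.frame(
    genes = label[ord], k = rep.int(k, length(ord)),
    count = as.integer(count[ord]),
    stringsAsFactors = FALSE
  )
  for (nm in cancers) out[[paste0(nm, "_train")]] <- train_acc[ord, nm]
  for (col in names(test_acc)) out[[col]] <- test_acc[[col]][ord]
  rownames(out) <- NULL
  class(out) <- c("multi_cancer_combos", "data.frame")
  attr(out, "accuracy_cutoff") <- accuracy_cutoff
  attr(out, "min_types") <- min_types
  out
}
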