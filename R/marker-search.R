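#' Enumerate k-gene combinations
#'
#' Deterministic lexicographic enumeration of all k-element subsets of a
#' gene list. Each combination is sorted and duplicate-free; the stream is
#' ordered lexicographically so results are reproducible across platforms.
#'
#' @param gene_list Character vector of unique gene ids.
#' @param k Combination size (1 to `max_k`).
#' @param max_k Upper bound on `k` (default 4).
#' @return Character matrix with `choose(length(gene_list), k)` rows and `k`
#'   columns, one combination per row.
#' @examples
#' enumerate_combinations(c("b", "a", "c"), 2)
#' @export
enumerate_combinations <- function(gene_list, k, max_k = 4L) {
  if (anyDuplicated(gene_list)) stop("`gene_list` contains duplicates", call. = FALSE)
  k <- check_count(k, "k")
  if (k > max_k) {
    stop(sprintf("k = %d exceeds the configured maximum of %d", k, max_k), call. = FALSE)
  }
  if (k > length(gene_list)) {
    stop(sprintf(
      "k = %d exceeds the number of available genes (%d)",
      k, length(gene_list)
    ), call. = FALSE)
  }
  genes <- sort_ids(gene_list)
  t(utils::combn(genes, k))
}

#' Classification accuracy record
#'
#' Accuracy of predicted class labels as `(TP + TN) / N`, where `TP` and
#' `TN` count correctly classified cancer and control samples respectively
#' and `N` is the total number of samples.
#'
#' @param predicted,actual Character vectors of `"cancer"`/`"control"`
#'   labels.
#' @return A list of class `accuracy_record` with `tp`, `tn`, `n` and
#'   `accuracy`.
#' @export
classification_accuracy <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  predicted <- as.character(predicted)
  actual <- as.character(actual)
  tp <- sum(predicted == "cancer" & actual == "cancer")
  tn <- sum(predicted == "control" & actual == "control")
  n <- length(actual)
  structure(
    list(tp = tp, tn = tn, n = n, accuracy = (tp + tn) / n),
    class = "accuracy_record"
  )
}

#' Train a linear support-vector classifier
#'
#' Fits a linear-kernel SVM (via `e1071`, the LIBSVM binding) separating
#' cancer from control samples on the expression of a candidate gene
#' combination. Training is deterministic given the inputs; no feature
#' scaling is applied (log2 expression values already share a scale).
#'
#' @param features Numeric matrix, samples in rows, one column per gene.
#' @param labels Vector of `"cancer"`/`"control"` labels (both classes must
#'   be present).
#' @param cost Regularization constant C of the soft-margin objective
#'   (default 1).
#' @return A list of class `linear_marker_model`: the fitted `model`, the
#'   hyperplane `weights` and `bias`, `train_pred` and `train_accuracy`.
#' @examples
#' x <- matrix(c(rnorm(20, -5), rnorm(20, 5)), ncol = 1)
#' y <- rep(c("control", "cancer"), each = 20)
#' fit <- train_linear_classifier(x, y)
#' fit$train_accuracy
#' @export
train_linear_classifier <- function(features, labels, cost = 1) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present in the training labels", call. = FALSE)
  }
  if (!all(labels %in% c("cancer", "control"))) {
    stop("labels must be 'cancer' or 'control'", call. = FALSE)
  }
  if (!is.numeric(cost) || cost <= 0) stop("`cost` must be positive", call. = FALSE)
  y <- factor(labels, levels = c("control", "cancer"))
  fit <- e1071::svm(features, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  pred <- as.character(predict(fit, features))
  structure(
    list(
      model = fit,
      weights = w,
      bias = -fit$rho,
      train_pred = pred,
      train_accuracy = classification_accuracy(pred, labels)$accuracy
    ),
    class = "linear_marker_model"
  )
}

predict_labels <- function(fit, features) {
  as.character(predict(fit$model, as.matrix(features)))
}

#' Stratified cross-validation folds
#'
#' Seeded, stratified assignment of samples to folds: within each class the
#' samples are shuffled and dealt round-robin, so class balance is
#' preserved as far as possible.
#'
#' @param labels Class labels, one per sample.
#' @param folds Number of folds.
#' @param seed Integer seed; the assignment is a pure function of
#'   `(labels, folds, seed)`.
#' @return Integer vector of fold ids in `1:folds`.
#' @export
make_folds <- function(labels, folds = 5L, seed = 1L) {
  folds <- check_count(folds, "folds", min = 2L)
  labels <- as.character(labels)
  for (cls in unique(labels)) {
    if (sum(labels == cls) < folds) {
      stop(sprintf(
        "class '%s' has fewer samples (%d) than folds (%d)",
        cls, sum(labels == cls), folds
      ), call. = FALSE)
    }
  }
  ids <- integer(length(labels))
  with_seed(seed, {
    for (cls in sort_ids(unique(labels))) {
      idx <- which(labels == cls)
      ids[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
  })
  ids
}

#' Cross-validated accuracy of a gene combination
#'
#' Accuracy of the linear classifier on a gene combination under seeded,
#' stratified k-fold cross-validation. Predictions of all held-out folds are
#' pooled and scored once as `(TP + TN) / N` over all samples (a fold-mean
#' variant is available via `pool = "fold_mean"`).
#'
#' @param dataset An [expression_dataset()].
#' @param combo Character vector of gene ids forming the combination.
#' @param folds Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param cost SVM regularization constant.
#' @param pool `"pooled"` (default) or `"fold_mean"`.
#' @param fold_ids Optional precomputed fold assignment (as from
#'   [make_folds()]); when ranking many combinations on one dataset the
#'   assignment is computed once and reused.
#' @return Accuracy in `[0, 1]`.
#' @export
cross_validated_accuracy <- function(dataset, combo, folds = 5L, seed = 1L,
                                     cost = 1, pool = c("pooled", "fold_mean"),
                                     fold_ids = NULL) {
  pool <- match.arg(pool)
  missing <- setdiff(combo, gene_ids(dataset))
  if (length(missing)) {
    stop(sprintf("gene(s) not in dataset: %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  labels <- sample_conditions(dataset)
  if (is.null(fold_ids)) fold_ids <- make_folds(labels, folds, seed)
  x <- t(dataset$exprs[combo, , drop = FALSE])
  pred <- character(length(labels))
  fold_acc <- numeric(0)
  for (f in sort(unique(fold_ids))) {
    hold <- fold_ids == f
    fit <- train_linear_classifier(x[!hold, , drop = FALSE], labels[!hold], cost = cost)
    pred[hold] <- predict_labels(fit, x[hold, , drop = FALSE])
    if (pool == "fold_mean") {
      fold_acc <- c(fold_acc, classification_accuracy(pred[hold], labels[hold])$accuracy)
    }
  }
  if (pool == "fold_mean") {
    mean(fold_acc)
  } else {
    classification_accuracy(pred, labels)$accuracy
  }
}

#' Rank k-gene marker combinations by cross-validated accuracy
#'
#' Exhaustively enumerates all k-gene combinations of a differentially
#' expressed gene pool, scores each by seeded 5-fold cross-validated
#' accuracy of the linear classifier, and returns the combinations sorted
#' by accuracy (descending), ties broken lexicographically on the gene
#' tuple.
#'
#' For `k >= 2` an optional `prefilter` restricts the pool to the top genes
#' by single-gene cross-validated accuracy before enumeration — a
#' desk-scale concession, since the fully exhaustive search over hundreds
#' of genes at k = 4 requires cluster-scale compute.
#'
#' @param train An [expression_dataset()] (the training cohort).
#' @param de_genes Character vector of candidate genes (typically the DE
#'   genes from [call_differential()]).
#' @param k Combination size (1-4).
#' @param top_n Number of top combinations to return (default 100).
#' @param folds,seed,cost Cross-validation settings, see
#'   [cross_validated_accuracy()].
#' @param prefilter Optional count: restrict the pool to this many genes by
#'   single-gene CV accuracy (only meaningful for `k >= 2`).
#' @return A data frame of class `marker_candidates`: `rank`, `genes`
#'   (ids joined by `"+"`), `k`, `cv_accuracy`.
#' @examples
#' sim <- simulate_study(simulation_config(
#'   n_genes = 30, n_patients = 12,
#'   de_fraction = 0.2, seed = 5
#' ))
#' de <- call_differential(sim$dataset)
#' rank_markers(sim$dataset, de$gene[de$is_de], k = 1, seed = 5)
#' @export
rank_markers <- function(train, de_genes, k, top_n = 100L, folds = 5L,
                         seed = 1L, cost = 1, prefilter = NULL) {
  stopifnot(inherits(train, "ExpressionDataset"))
  if (!length(de_genes)) stop("`de_genes` is empty", call. = FALSE)
  missing <- setdiff(de_genes, gene_ids(train))
  if (length(missing)) {
    stop(sprintf("gene(s) not in training dataset: %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  labels <- sample_conditions(train)
  fold_ids <- make_folds(labels, folds, seed)
  pool <- sort_ids(unique(de_genes))
  if (!is.null(prefilter)) {
    prefilter <- check_count(prefilter, "prefilter")
    if (k < 2L) stop("`prefilter` requires k >= 2", call. = FALSE)
    if (prefilter < length(pool)) {
      single <- vapply(pool, function(g) {
        cross_validated_accuracy(train, g, cost = cost, fold_ids = fold_ids)
      }, numeric(1))
      ord <- order(-single, pool, method = "radix")
      pool <- sort_ids(pool[ord[seq_len(prefilter)]])
    }
  }
  combos <- enumerate_combinations(pool, k)
  acc <- vapply(seq_len(nrow(combos)), function(i) {
    cross_validated_accuracy(train, combos[i, ], cost = cost, fold_ids = fold_ids)
  }, numeric(1))
  label <- apply(combos, 1L, combo_label)
  ord <- order(-acc, label, method = "radix")
  keep <- ord[seq_len(min(top_n, length(ord)))]
  out <- data.frame(
    rank = seq_along(keep),
    genes = label[keep],
    k = k,
    cv_accuracy = acc[keep],
    stringsAsFactors = FALSE
  )
  class(out) <- c("marker_candidates", "data.frame")
  attr(out, "folds") <- folds
  attr(out, "seed") <- seed
  attr(out, "cost") <- cost
  out
}

#' Evaluate ranked markers on independent test cohorts
#'
#' Refits the linear classifier for each candidate combination on the full
#' training cohort and scores it on each test cohort. A combination
#' containing a gene that a test cohort's platform does not measure is
#' marked missing (`NA`) for that cohort rather than scored.
#'
#' @param candidates A [rank_markers()] result.
#' @param train The training [expression_dataset()].
#' @param tests A list of test `ExpressionDataset`s (names become accuracy
#'   column names; unnamed lists get `test1`, `test2`, ...).
#' @param cost SVM regularization constant (use the training value).
#' @return `candidates` with one additional `<name>_accuracy` column per
#'   test cohort.
#' @export
evaluate_on_test <- function(candidates, train, tests, cost = 1) {
  stopifnot(inherits(candidates, "marker_candidates") || is.data.frame(candidates))
  if (inherits(tests, "ExpressionDataset")) tests <- list(tests)
  if (is.null(names(tests)) || any(names(tests) == "")) {
    names(tests) <- paste0("test", seq_along(tests))
  }
  labels <- sample_conditions(train)
  combos <- split_combo(candidates$genes)
  fits <- lapply(combos, function(genes) {
    train_linear_classifier(t(train$exprs[genes, , drop = FALSE]), labels, cost = cost)
  })
  for (nm in names(tests)) {
    ds <- tests[[nm]]
    acc <- vapply(seq_along(combos), function(i) {
      genes <- combos[[i]]
      if (!all(genes %in% gene_ids(ds))) {
        return(NA_real_) # platform does not cover the combination
      }
      pred <- predict_labels(fits[[i]], t(ds$exprs[genes, , drop = FALSE]))
      classification_accuracy(pred, sample_conditions(ds))$accuracy
    }, numeric(1))
    candidates[[paste0(nm, "_accuracy")]] <- acc
  }
  candidates
}
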