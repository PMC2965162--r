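#' Construct an expression dataset
#'
#' Bundles a log2 expression matrix (genes in rows, samples in columns) with
#' per-sample metadata. This is the container every stage of the pipeline
#' consumes: differential testing, marker search and the multi-cancer
#' analysis all operate on `ExpressionDataset` objects.
#'
#' @param exprs Numeric matrix of log2 expression values with gene ids as row
#'   names and sample ids as column names. Missing values are rejected.
#' @param samples Data frame with one row per column of `exprs`. Required
#'   columns: `sample_id`, `condition` (each sample either `"cancer"` or
#'   `"control"`). Optional: `patient_id` (enables the paired design when
#'   every patient has exactly one sample per condition) and `stage`.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `exprs` and `samples` (metadata reordered to match the matrix columns).
#'
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'   dimnames = list(paste0("g", 1:4), paste0("s", 1:5))
#' )
#' meta <- data.frame(
#'   sample_id = paste0("s", 1:5),
#'   condition = c("cancer", "cancer", "cancer", "control", "control")
#' )
#' ds <- expression_dataset(m, meta)
#' ds
#' @export
expression_dataset <- function(exprs, samples) {
  if (!is.matrix(exprs) || !is.numeric(exprs)) {
    stop("`exprs` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(exprs)) || is.null(colnames(exprs))) {
    stop("`exprs` must have gene ids as rownames and sample ids as colnames",
      call. = FALSE
    )
  }
  if (anyNA(exprs) || any(!is.finite(exprs))) {
    bad <- which(!is.finite(exprs), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-finite expression value at gene '%s', sample '%s'",
      rownames(exprs)[bad[1L]], colnames(exprs)[bad[2L]]
    ), call. = FALSE)
  }
  dup <- rownames(exprs)[duplicated(rownames(exprs))]
  if (length(dup)) {
    stop(sprintf("duplicated gene id(s): %s", paste(unique(dup), collapse = ", ")),
      call. = FALSE
    )
  }
  dup <- colnames(exprs)[duplicated(colnames(exprs))]
  if (length(dup)) {
    stop(sprintf("duplicated sample id(s): %s", paste(unique(dup), collapse = ", ")),
      call. = FALSE
    )
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  for (col in c("sample_id", "condition")) {
    if (!col %in% names(samples)) {
      stop(sprintf("metadata must contain a `%s` column", col), call. = FALSE)
    }
  }
  missing <- setdiff(colnames(exprs), samples$sample_id)
  if (length(missing)) {
    stop(sprintf(
      "metadata missing for sample(s): %s",
      paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  extra <- setdiff(samples$sample_id, colnames(exprs))
  if (length(extra)) {
    stop(sprintf(
      "metadata rows without a matrix column: %s",
      paste(extra, collapse = ", ")
    ), call. = FALSE)
  }
  bad <- setdiff(unique(samples$condition), c("cancer", "control"))
  if (length(bad)) {
    stop(sprintf(
      "condition must be 'cancer' or 'control' (found: %s)",
      paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  if (!"patient_id" %in% names(samples)) samples$patient_id <- NA_character_
  if (!"stage" %in% names(samples)) samples$stage <- NA_character_
  samples <- samples[match(colnames(exprs), samples$sample_id),
    c("sample_id", "patient_id", "condition", "stage"),
    drop = FALSE
  ]
  rownames(samples) <- NULL
  structure(list(exprs = exprs, samples = samples), class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  n_can <- sum(x$samples$condition == "cancer")
  n_con <- sum(x$samples$condition == "control")
  cat(sprintf(
    "ExpressionDataset: %d genes x %d samples (%d cancer / %d control)%s\n",
    nrow(x$exprs), ncol(x$exprs), n_can, n_con,
    if (is_paired(x)) ", paired" else ""
  ))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$exprs)

#' Gene and sample accessors
#'
#' @param dataset An [expression_dataset()].
#' @return `gene_ids()` the character vector of gene identifiers;
#'   `sample_conditions()` the per-sample condition labels in matrix column
#'   order.
#' @export
gene_ids <- function(dataset) rownames(dataset$exprs)

#' @rdname gene_ids
#' @export
sample_conditions <- function(dataset) dataset$samples$condition

#' Test whether a dataset supports the paired design
#'
#' A dataset is paired when every patient id occurs exactly once in each
#' condition, so that each patient contributes one tumor and one control
#' measurement.
#'
#' @param dataset An [expression_dataset()].
#' @return `TRUE` or `FALSE`.
#' @export
is_paired <- function(dataset) {
  s <- dataset$samples
  if (anyNA(s$patient_id)) return(FALSE)
  tab <- table(s$patient_id, s$condition)
  ncol(tab) == 2L && all(tab == 1L)
}

# Matched control/cancer matrices (genes x patients), columns aligned by
# patient, for the paired sign test.
paired_matrices <- function(dataset) {
  if (!is_paired(dataset)) {
    stop("dataset is not paired: every patient needs one cancer and one control sample",
      call. = FALSE
    )
  }
  s <- dataset$samples
  patients <- sort_ids(unique(s$patient_id))
  ctrl_cols <- s$sample_id[match(
    paste(patients, "control"),
    paste(s$patient_id, s$condition)
  )]
  canc_cols <- s$sample_id[match(
    paste(patients, "cancer"),
    paste(s$patient_id, s$condition)
  )]
  list(
    control = dataset$exprs[, ctrl_cols, drop = FALSE],
    cancer = dataset$exprs[, canc_cols, drop = FALSE],
    patients = patients
  )
}

#' Subset a dataset by genes or samples
#'
#' @param dataset An [expression_dataset()].
#' @param genes Character vector of gene ids to keep (order preserved).
#' @param sample_ids Character vector of sample ids to keep.
#' @return A new `ExpressionDataset`.
#' @export
subset_genes <- function(dataset, genes) {
  missing <- setdiff(genes, gene_ids(dataset))
  if (length(missing)) {
    stop(sprintf("gene(s) not in dataset: %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  expression_dataset(dataset$exprs[genes, , drop = FALSE], dataset$samples)
}

#' @rdname subset_genes
#' @export
subset_samples <- function(dataset, sample_ids) {
  missing <- setdiff(sample_ids, dataset$samples$sample_id)
  if (length(missing)) {
    stop(sprintf("sample(s) not in dataset: %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  expression_dataset(
    dataset$exprs[, sample_ids, drop = FALSE],
    dataset$samples[dataset$samples$sample_id %in% sample_ids, , drop = FALSE]
  )
}

#' Restrict a dataset to early-stage cancer samples and their controls
#'
#' Keeps cancer samples whose `stage` column matches `stages` plus, in a
#' paired dataset, the control samples of the same patients (all controls in
#' an unpaired dataset). Used to rank markers for early-stage disease with
#' the unchanged pipeline.
#'
#' @param dataset An [expression_dataset()].
#' @param stages Stage labels treated as early (default `"early"`).
#' @return A filtered `ExpressionDataset`.
#' @export
filter_stage <- function(dataset, stages = "early") {
  s <- dataset$samples
  keep_cancer <- s$condition == "cancer" & s$stage %in% stages
  if (!any(keep_cancer)) stop("no cancer samples in the requested stage(s)", call. = FALSE)
  if (is_paired(dataset)) {
    pats <- s$patient_id[keep_cancer]
    keep <- s$sample_id[keep_cancer | (s$condition == "control" & s$patient_id %in% pats)]
  } else {
    keep <- s$sample_id[keep_cancer | s$condition == "control"]
  }
  subset_samples(dataset, keep)
}
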