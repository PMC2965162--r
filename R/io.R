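#' Read an expression matrix and its sample metadata from TSV
#'
#' The matrix file is tab-separated with gene ids in the first column
#' (header `gene_id`) and one column per sample; the metadata file has
#' columns `sample_id`, `condition` (`cancer`/`control`) and optionally
#' `patient_id` and `stage`. Every matrix sample must be described by
#' exactly one metadata row. Non-numeric cells and duplicate ids are
#' rejected with the offending row/column named.
#'
#' @param matrix_path,metadata_path Paths to the two TSV files.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, metadata_path) {
  raw <- read_tsv(matrix_path, colClasses = "character")
  if (ncol(raw) < 2L) stop("matrix file needs a gene id column plus samples", call. = FALSE)
  genes <- raw[[1L]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop(sprintf("duplicated gene id(s) in %s: %s", matrix_path,
      paste(dup, collapse = ", ")
    ), call. = FALSE)
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-numeric value '%s' at gene '%s', sample '%s'",
      vals[bad[1L], bad[2L]], genes[bad[1L]], colnames(vals)[bad[2L]]
    ), call. = FALSE)
  }
  dimnames(num) <- list(genes, colnames(vals))
  meta <- read_tsv(metadata_path, colClasses = "character")
  expression_dataset(num, meta)
}

#' Write an expression dataset as TSV
#'
#' Inverse of [read_expression()]: writes the matrix (first column
#' `gene_id`) and the metadata as two tab-separated files.
#'
#' @param dataset An [expression_dataset()].
#' @param matrix_path,metadata_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(dataset, matrix_path, metadata_path) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  df <- data.frame(
    gene_id = gene_ids(dataset),
    dataset$exprs,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write_tsv(df, matrix_path)
  write_tsv(dataset$samples, metadata_path)
  invisible(c(matrix = matrix_path, metadata = metadata_path))
}
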