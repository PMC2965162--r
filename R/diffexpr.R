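#' Paired sign test for one gene
#'
#' Tests whether a gene is differentially expressed between paired cancer
#' and control tissues of the same patients. Under the null hypothesis the
#' probability that a patient's cancer value exceeds the control value is
#' 1/2, so the fraction `K/m` of such patients is approximately normal with
#' mean 1/2 and standard deviation `1/(2 sqrt(m))`; the standardized
#' statistic `z = (K/m - 1/2) * 2 * sqrt(m)` is approximately N(0, 1). The
#' one-sided p-value is the standard-normal upper tail at the statistic
#' computed in the direction of the observed majority; the two-sided p is
#' twice the smaller tail, capped at 1.
#'
#' Exact ties (cancer value equal to the control value) are dropped and `m`
#' reduced accordingly. With fewer than 10 usable pairs the result is
#' flagged `small_sample`, as the normal approximation is then dubious.
#'
#' @param control_values,cancer_values Numeric vectors of log2 expression,
#'   one entry per patient, aligned by patient.
#' @param correct Apply a continuity correction of 1/2 to `K` (off by
#'   default; the plain statistic above is the default behavior).
#' @return A list of class `paired_sign_test`: `m` (usable pairs), `K`
#'   (pairs with cancer > control), `z`, `p_one`, `p_two`, `direction`
#'   (`"up"`, `"down"` or `"none"`) and `small_sample`.
#' @examples
#' paired_sign_test(rnorm(20), rnorm(20, mean = 2))
#' @export
paired_sign_test <- function(control_values, cancer_values, correct = FALSE) {
  if (length(control_values) != length(cancer_values)) {
    stop("control and cancer vectors must have equal length", call. = FALSE)
  }
  if (anyNA(control_values) || anyNA(cancer_values)) {
    stop("missing values are not supported", call. = FALSE)
  }
  diff <- cancer_values - control_values
  diff <- diff[diff != 0] # drop exact ties
  m <- length(diff)
  if (m == 0L) {
    stop("no usable pairs left after dropping ties", call. = FALSE)
  }
  K <- sum(diff > 0)
  cc <- if (correct) 0.5 else 0
  z <- (K / m - 0.5) * 2 * sqrt(m)
  K_maj <- max(K, m - K)
  z_one <- ((K_maj - cc) / m - 0.5) * 2 * sqrt(m)
  p_one <- stats::pnorm(z_one, lower.tail = FALSE)
  upper <- stats::pnorm((K - cc) / m * 2 * sqrt(m) - sqrt(m), lower.tail = FALSE)
  lower <- stats::pnorm((K + cc) / m * 2 * sqrt(m) - sqrt(m))
  p_two <- min(1, 2 * min(upper, lower))
  structure(
    list(
      m = m, K = K, z = z, p_one = p_one, p_two = p_two,
      direction = if (K > m - K) "up" else if (K < m - K) "down" else "none",
      small_sample = m < 10L
    ),
    class = "paired_sign_test"
  )
}

#' @export
print.paired_sign_test <- function(x, ...) {
  cat(sprintf(
    "Paired sign test: K = %d of m = %d pairs (%s), z = %.4f, p_one = %.4g, p_two = %.4g%s\n",
    x$K, x$m, x$direction, x$z, x$p_one, x$p_two,
    if (x$small_sample) " [small sample: m < 10]" else ""
  ))
  invisible(x)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided Mann-Whitney test for unpaired cancer/control comparisons.
#' `U` counts pairs `(a, b)` with `a > b` (ties contributing 1/2). In
#' `"exact"` mode the permutation null of `U` is enumerated in full over all
#' reassignments of the pooled values, and the p-value is the probability of
#' a `|U - n1*n2/2|` at least as large as observed; ties are handled exactly.
#' In `"normal"` mode the tie-corrected normal approximation of
#' [stats::wilcox.test()] (without continuity correction) is used. `"auto"`
#' picks exact when the pooled sample size is at most `exact_limit`.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @param exact_limit Largest pooled size for which `"auto"` uses
#'   enumeration (full enumeration is combinatorial; the default 12 keeps it
#'   below C(12,6) = 924 assignments).
#' @return A list with `U` (for `group_a`), `p_two` and `mode_used`.
#' @examples
#' mann_whitney_test(c(1, 2, 3, 4, 5), c(6, 7, 8, 9, 10))
#' @export
mann_whitney_test <- function(group_a, group_b,
                              mode = c("auto", "exact", "normal"),
                              exact_limit = 12L) {
  mode <- match.arg(mode)
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  na <- length(group_a)
  nb <- length(group_b)
  n <- na + nb
  if (mode == "auto") mode <- if (n <= exact_limit) "exact" else "normal"
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (mode == "exact") {
    if (n > 24L) {
      stop("exact mode limited to pooled sizes <= 24; use mode = \"normal\"",
        call. = FALSE
      )
    }
    mu <- na * nb / 2
    sel <- utils::combn(n, na)
    base <- na * (na + 1) / 2
    u_all <- colSums(matrix(r[sel], nrow = na)) - base
    p_two <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
  } else {
    wt <- stats::wilcox.test(group_a, group_b, exact = FALSE, correct = FALSE)
    p_two <- if (is.nan(wt$p.value)) 1 else wt$p.value
  }
  list(U = U, p_two = p_two, mode_used = mode)
}

#' Fold change from log2 means
#'
#' Linear-scale fold change between cancer and control, computed as
#' `2^(mean_log2_cancer - mean_log2_control)` — the ratio of geometric means
#' of the anti-logged intensities, the natural choice for RMA-style log2
#' data.
#'
#' @param mean_log2_cancer,mean_log2_control Mean log2 expression in each
#'   condition.
#' @return Positive linear fold change (values below 1 mean down-regulation).
#' @examples
#' fold_change(8, 7) # 2-fold up
#' fold_change(5, 7) # 4-fold down -> 0.25
#' @export
fold_change <- function(mean_log2_cancer, mean_log2_control) {
  if (!all(is.finite(mean_log2_cancer)) || !all(is.finite(mean_log2_control))) {
    stop("fold_change requires finite inputs", call. = FALSE)
  }
  2^(mean_log2_cancer - mean_log2_control)
}

#' Call differentially expressed genes
#'
#' Per-gene differential-expression testing of a tumor/control dataset. For
#' a paired design the [paired_sign_test()] is applied per gene; otherwise
#' the [mann_whitney_test()]. A gene is called DE when its p-value is below
#' `alpha` and its fold change is at least `min_fc` in either direction
#' (i.e. `FC >= min_fc` or `FC <= 1/min_fc`); both conditions are required.
#'
#' @param dataset An [expression_dataset()].
#' @param alpha Significance level (default 0.05).
#' @param min_fc Minimum linear fold change (default 2).
#' @param design `"auto"` (paired when the pairing metadata allows it),
#'   `"paired"` or `"unpaired"`.
#' @param sided `"two"` (default; up- and down-regulation both reportable)
#'   or `"one"` to use the one-sided p in the direction of the observed
#'   majority.
#' @param fc_method `"geometric"` (difference of log2 means, default) or
#'   `"arithmetic"` (ratio of arithmetic means of anti-logged values).
#' @param adjust `"none"` (default: raw p-values are thresholded) or
#'   `"BH"` for Benjamini-Hochberg adjustment before thresholding.
#' @param correct Continuity correction for the paired sign test.
#'
#' @return A data frame of class `differential_result` with one row per
#'   gene: `gene`, `test_used`, `n_used`, `statistic`, `p_value`,
#'   `fold_change`, `log2_fc`, `direction`, `is_de`.
#' @examples
#' sim <- simulate_study(simulation_config(n_genes = 100, n_patients = 20, seed = 3))
#' de <- call_differential(sim$dataset)
#' table(de$is_de, de$direction)
#' @export
call_differential <- function(dataset,
                              alpha = 0.05,
                              min_fc = 2,
                              design = c("auto", "paired", "unpaired"),
                              sided = c("two", "one"),
                              fc_method = c("geometric", "arithmetic"),
                              adjust = c("none", "BH"),
                              correct = FALSE) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  design <- match.arg(design)
  sided <- match.arg(sided)
  fc_method <- match.arg(fc_method)
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(min_fc) || min_fc < 1) stop("`min_fc` must be >= 1", call. = FALSE)
  if (design == "auto") design <- if (is_paired(dataset)) "paired" else "unpaired"
  if (design == "paired" && !is_paired(dataset)) {
    stop("paired design requested but the dataset has no complete pairing metadata",
      call. = FALSE
    )
  }

  genes <- gene_ids(dataset)
  cond <- sample_conditions(dataset)
  canc_m <- dataset$exprs[, cond == "cancer", drop = FALSE]
  ctrl_m <- dataset$exprs[, cond == "control", drop = FALSE]

  if (fc_method == "geometric") {
    fc <- fold_change(rowMeans(canc_m), rowMeans(ctrl_m))
  } else {
    fc <- rowMeans(2^canc_m) / rowMeans(2^ctrl_m)
  }
  log2_fc <- log2(fc)

  if (design == "paired") {
    pm <- paired_matrices(dataset)
    res <- lapply(seq_along(genes), function(i) {
      t <- paired_sign_test(pm$control[i, ], pm$cancer[i, ], correct = correct)
      list(
        n_used = t$m, statistic = t$z,
        p_value = if (sided == "two") t$p_two else t$p_one,
        direction = t$direction, small = t$small_sample
      )
    })
    test_used <- "paired_sign"
  } else {
    res <- lapply(seq_along(genes), function(i) {
      t <- mann_whitney_test(canc_m[i, ], ctrl_m[i, ], mode = "auto")
      list(
        n_used = ncol(canc_m) + ncol(ctrl_m), statistic = t$U,
        p_value = if (sided == "two") t$p_two else t$p_two / 2,
        direction = if (fc[i] > 1) "up" else if (fc[i] < 1) "down" else "none",
        small = FALSE
      )
    })
    test_used <- "mann_whitney"
  }

  p <- vapply(res, `[[`, numeric(1), "p_value")
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  if (design == "paired" && any(vapply(res, `[[`, logical(1), "small"))) {
    warning(sprintf(
      "%d gene(s) had fewer than 10 usable pairs; normal approximation is dubious",
      sum(vapply(res, `[[`, logical(1), "small"))
    ), call. = FALSE)
  }

  out <- data.frame(
    gene = genes,
    test_used = test_used,
    n_used = vapply(res, `[[`, numeric(1), "n_used"),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    p_value = p,
    fold_change = unname(fc),
    log2_fc = unname(log2_fc),
    direction = vapply(res, `[[`, character(1), "direction"),
    stringsAsFactors = FALSE
  )
  out$is_de <- out$p_value < alpha & (out$fold_change >= min_fc | out$fold_change <= 1 / min_fc)
  class(out) <- c("differential_result", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "min_fc") <- min_fc
  attr(out, "design") <- design
  out
}

#' Summarize up/down-regulated DE gene counts
#'
#' @param de A [call_differential()] result.
#' @return Named integer vector with elements `de`, `up` and `down`.
#' @export
de_counts <- function(de) {
  stopifnot(inherits(de, "differential_result"))
  c(
    de = sum(de$is_de),
    up = sum(de$is_de & de$direction == "up"),
    down = sum(de$is_de & de$direction == "down")
  )
}
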