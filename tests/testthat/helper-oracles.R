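# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately avoid the code paths they check.

# Exact two-sided Mann-Whitney p by brute-force enumeration: U computed by
# direct pairwise comparison for every reassignment of the pooled values.
brute_force_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  n <- length(pooled)
  count_u <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  }
  mu <- na * length(b) / 2
  u_obs <- count_u(a, b)
  sel <- utils::combn(n, na)
  u_all <- apply(sel, 2L, function(idx) count_u(pooled[idx], pooled[-idx]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Upper-tail hypergeometric probability from binomial coefficients.
hyper_tail <- function(overlap, set_size, query_size, background) {
  i <- seq(overlap, min(set_size, query_size))
  sum(choose(set_size, i) * choose(background - set_size, query_size - i)) /
    choose(background, query_size)
}

# Textbook Pearson correlation coefficient and two-sided t-test p.
textbook_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Minimal paired dataset with hand-chosen values: one row per gene given as
# a named list of list(control =, cancer =) value vectors.
tiny_paired_dataset <- function(gene_values) {
  m <- length(gene_values[[1]]$control)
  patients <- sprintf("p%02d", seq_len(m))
  exprs <- do.call(rbind, lapply(gene_values, function(v) c(v$control, v$cancer)))
  rownames(exprs) <- names(gene_values)
  colnames(exprs) <- c(paste0(patients, "_control"), paste0(patients, "_cancer"))
  meta <- data.frame(
    sample_id = colnames(exprs),
    patient_id = rep(patients, 2),
    condition = rep(c("control", "cancer"), each = m),
    stringsAsFactors = FALSE
  )
  expression_dataset(exprs, meta)
}

# Unpaired two-class dataset from per-gene class means; gaussian noise.
tiny_unpaired_dataset <- function(n_genes, n_per_class, shift, seed = 1,
                                  noise_sd = 1) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  ids <- c(sprintf("con%02d", seq_len(n_per_class)), sprintf("can%02d", seq_len(n_per_class)))
  exprs <- matrix(stats::rnorm(n_genes * 2 * n_per_class, sd = noise_sd),
    n_genes, 2 * n_per_class,
    dimnames = list(genes, ids)
  )
  exprs[, seq(n_per_class + 1, 2 * n_per_class)] <-
    exprs[, seq(n_per_class + 1, 2 * n_per_class)] + shift
  meta <- data.frame(
    sample_id = ids,
    condition = rep(c("control", "cancer"), each = n_per_class),
    stringsAsFactors = FALSE
  )
  expression_dataset(exprs, meta)
}

# A small three-cancer simulated panel with DE tables, reused by the
# multi-cancer tests.
small_panel <- function(seed = 11, shared = 3, n_genes = 300, n_patients = 15,
                        test_cohorts = 1, platform_mask = NULL) {
  cfgs <- lapply(seq_len(3), function(i) {
    simulation_config(
      n_genes = n_genes, n_patients = n_patients, de_fraction = 0.05,
      log2fc_low = 2, log2fc_high = 3, seed = seed + i
    )
  })
  names(cfgs) <- c("alpha", "beta", "gamma")
  sim <- simulate_panel(cfgs,
    shared_de_genes = shared, consistency = TRUE,
    test_cohorts = test_cohorts, platform_mask = platform_mask, seed = seed
  )
  sim$panel <- panel_differential(sim$panel)
  sim
}
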