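# One small simulated three-cancer configuration reused by the pipeline
# tests; GMT/survival side inputs are generated on the fly.
pipeline_fixture <- function(dir, seed = 101, out_dir = file.path(dir, "run"), ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gmt <- file.path(dir, "sets.gmt")
  genes <- paste0("g", formatC(1:150, width = 3, flag = "0"))
  write_gmt(
    list(
      set_a = structure(genes[1:30], description = "first thirty genes"),
      set_b = structure(genes[31:45], description = "next fifteen")
    ),
    gmt
  )
  secr <- file.path(dir, "secretory.gmt")
  write_gmt(list(secreted = structure(genes[seq(1, 149, by = 2)], description = "odd genes")), secr)
  surv <- file.path(dir, "survival.tsv")
  writeLines(
    c(
      "cancer\tfive_year_survival_rate",
      "alpha\t80", "beta\t50", "gamma\t20"
    ),
    surv
  )
  pipeline_config(
    simulate = list(
      configs = list(
        alpha = list(
          n_genes = 150, n_patients = 12, de_fraction = 0.08,
          log2fc_low = 2, log2fc_high = 3, seed = seed
        ),
        beta = list(
          n_genes = 150, n_patients = 12, de_fraction = 0.08,
          log2fc_low = 2, log2fc_high = 3, seed = seed + 1
        ),
        gamma = list(
          n_genes = 150, n_patients = 12, de_fraction = 0.08,
          log2fc_low = 2, log2fc_high = 3, seed = seed + 2
        )
      ),
      shared_de_genes = 4, test_cohorts = 1, seed = seed
    ),
    k = c(1, 2), top_n = 20,
    gmt = gmt, secretory_gmt = secr, survival_table = surv,
    seed = seed, out_dir = out_dir,
    ...
  )
}
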