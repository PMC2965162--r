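#' Configuration for a synthetic expression cohort
#'
#' Describes one tumor/control cohort on the log2 scale of RMA-style
#' normalized microarray intensities. The generative model is
#' `x = baseline_gene + patient_offset + condition_effect + noise`:
#' a per-gene baseline, a per-patient (or per-sample, when unpaired) offset
#' shared by a patient's tumor and control arrays, a signed log2 fold change
#' applied to the cancer samples of differentially expressed (DE) genes, and
#' independent Gaussian measurement noise. Planted panels additionally
#' receive a joint linear signal so the panel separates the two classes at a
#' configurable margin.
#'
#' Defaults mirror the structure of the paired tumor/adjacent-tissue
#' microarray cohorts the pipeline is designed for: a 43-patient paired
#' cohort, a minority (5%) of genes truly DE with |log2 fold change| between
#' 1 and 2 (the 2-fold regime), roughly 30% of DE genes up-regulated, and
#' log2 baselines centred at 7 +/- 2.
#'
#' @param n_genes Number of genes.
#' @param n_patients Number of patients for the paired design (each
#'   contributes one cancer and one control sample). Set to `NULL` and give
#'   `n_cancer`/`n_control` instead for an unpaired cohort.
#' @param n_cancer,n_control Arm sizes of an unpaired cohort.
#' @param de_fraction Fraction of genes truly differentially expressed.
#' @param log2fc_low,log2fc_high Bounds of the |log2 fold change| magnitude
#'   of DE genes (1 means 2-fold).
#' @param up_fraction Probability that a DE gene is up-regulated in cancer.
#' @param baseline_mean,baseline_sd Mean and sd of the per-gene log2
#'   baseline expression.
#' @param patient_effect_sd Sd of the shared per-patient offset; this is
#'   what makes the paired test more powerful than the unpaired one.
#' @param noise_sd Sd of the residual per-measurement noise.
#' @param planted_panels List of character vectors of gene ids forced to be
#'   jointly discriminative. The genes of a k-panel receive alternating
#'   cancer shifts of `+/- panel_margin / sqrt(k)` plus a shared per-sample
#'   latent component (`panel_latent_sd`), so the panel is linearly
#'   separable along its sign-alternating direction at the configured
#'   margin while each member gene alone remains noisy.
#' @param panel_margin Class-mean separation along a planted panel's
#'   discriminant direction, in log2 units.
#' @param panel_latent_sd Sd of the per-sample latent component shared by
#'   the genes of a planted panel (cancels along the panel's discriminant).
#' @param early_fraction Fraction of cancer samples labelled stage
#'   `"early"` (the rest `"late"`).
#' @param seed Integer seed; together with the configuration it fully
#'   determines the simulated data.
#'
#' @return A validated list of class `simulation_config`.
#' @seealso [simulate_study()], [simulate_panel()]
#' @export
simulation_config <- function(n_genes = 2000,
                              n_patients = 43,
                              n_cancer = NULL,
                              n_control = NULL,
                              de_fraction = 0.05,
                              log2fc_low = 1,
                              log2fc_high = 2,
                              up_fraction = 0.3,
                              baseline_mean = 7,
                              baseline_sd = 2,
                              patient_effect_sd = 1,
                              noise_sd = 1,
                              planted_panels = list(),
                              panel_margin = 6,
                              panel_latent_sd = 3,
                              early_fraction = 0.75,
                              seed = 1) {
  n_genes <- check_count(n_genes, "n_genes")
  paired <- !is.null(n_patients)
  if (paired) {
    n_patients <- check_count(n_patients, "n_patients")
  } else {
    if (is.null(n_cancer) || is.null(n_control)) {
      stop("give either `n_patients` (paired) or both `n_cancer` and `n_control`",
        call. = FALSE
      )
    }
    n_cancer <- check_count(n_cancer, "n_cancer")
    n_control <- check_count(n_control, "n_control")
  }
  de_fraction <- check_fraction(de_fraction, "de_fraction")
  up_fraction <- check_fraction(up_fraction, "up_fraction")
  early_fraction <- check_fraction(early_fraction, "early_fraction")
  if (!is.numeric(log2fc_low) || !is.numeric(log2fc_high) ||
    log2fc_low <= 0 || log2fc_low > log2fc_high) {
    stop("need 0 < log2fc_low <= log2fc_high", call. = FALSE)
  }
  for (nm in c(
    "baseline_sd", "patient_effect_sd", "noise_sd", "panel_margin",
    "panel_latent_sd"
  )) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("`%s` must be a single non-negative number", nm), call. = FALSE)
    }
  }
  if (!is.list(planted_panels) ||
    !all(vapply(planted_panels, is.character, logical(1)))) {
    stop("`planted_panels` must be a list of character gene-id vectors", call. = FALSE)
  }
  seed <- check_count(seed, "seed", min = 0L)
  if (seed >= 2^31 - 1e6) stop("`seed` too large (must stay below 2^31)", call. = FALSE)
  structure(
    list(
      n_genes = n_genes, paired = paired,
      n_patients = if (paired) n_patients else NULL,
      n_cancer = if (paired) NULL else n_cancer,
      n_control = if (paired) NULL else n_control,
      de_fraction = de_fraction,
      log2fc_low = as.numeric(log2fc_low), log2fc_high = as.numeric(log2fc_high),
      up_fraction = up_fraction,
      baseline_mean = as.numeric(baseline_mean), baseline_sd = as.numeric(baseline_sd),
      patient_effect_sd = as.numeric(patient_effect_sd), noise_sd = as.numeric(noise_sd),
      planted_panels = planted_panels, panel_margin = as.numeric(panel_margin),
      panel_latent_sd = as.numeric(panel_latent_sd),
      early_fraction = early_fraction, seed = seed
    ),
    class = "simulation_config"
  )
}

sim_gene_ids <- function(n_genes) {
  paste0("g", formatC(seq_len(n_genes), width = nchar(n_genes), flag = "0"))
}

# Draw the gene-level truth for one cancer type: per-gene baselines plus a
# signed log2 fold-change vector. Baselines belong to the truth (shared by
# the training and every test cohort of the cancer), so classifiers can
# transfer across cohorts. `forced_sign` (named +/-1 vector over gene ids)
# pins designated genes as DE with the given direction (magnitudes still
# drawn from the configured range); the remaining DE budget is sampled from
# the other genes.
sim_truth <- function(config, forced_sign = NULL) {
  genes <- sim_gene_ids(config$n_genes)
  with_seed(config$seed, {
    lfc <- stats::setNames(numeric(config$n_genes), genes)
    n_de <- round(config$n_genes * config$de_fraction)
    forced <- character(0)
    if (length(forced_sign)) {
      forced <- names(forced_sign)
      if (!all(forced %in% genes)) {
        stop("forced DE gene(s) outside the gene universe", call. = FALSE)
      }
      if (length(forced) > n_de) {
        stop(sprintf(
          "shared DE budget (%d) exceeds this cohort's DE budget (%d)",
          length(forced), n_de
        ), call. = FALSE)
      }
      lfc[forced] <- forced_sign *
        stats::runif(length(forced), config$log2fc_low, config$log2fc_high)
    }
    n_free <- n_de - length(forced)
    pool <- setdiff(genes, forced)
    if (n_free > 0) {
      idx <- sample(pool, n_free)
      sign <- ifelse(stats::runif(n_free) < config$up_fraction, 1, -1)
      lfc[idx] <- sign * stats::runif(n_free, config$log2fc_low, config$log2fc_high)
    }
    # planted panels: alternating-sign shifts put the class means
    # `panel_margin` apart along the panel's sign-alternating unit
    # direction, on which patient offsets and the shared latent cancel
    for (panel in config$planted_panels) {
      if (!all(panel %in% genes)) {
        stop("planted panel gene(s) outside the gene universe", call. = FALSE)
      }
      k <- length(panel)
      s <- rep_len(c(1, -1), k)
      lfc[panel] <- lfc[panel] + s * config$panel_margin / sqrt(k)
    }
    list(
      lfc = lfc,
      baseline = stats::setNames(
        stats::rnorm(config$n_genes, config$baseline_mean, config$baseline_sd),
        genes
      )
    )
  })
}

# Draw one cohort (expression matrix + metadata) given the gene-level truth.
sim_cohort <- function(config, truth, seed, id_prefix = "") {
  lfc <- truth$lfc
  genes <- names(lfc)
  n <- length(genes)
  with_seed(seed, {
    baseline <- unname(truth$baseline)
    if (config$paired) {
      m <- config$n_patients
      patients <- paste0(id_prefix, "p", formatC(seq_len(m), width = nchar(m), flag = "0"))
      offset <- stats::rnorm(m, 0, config$patient_effect_sd)
      ctrl <- baseline +
        rep(offset, each = n) +
        stats::rnorm(n * m, 0, config$noise_sd)
      canc <- baseline + lfc +
        rep(offset, each = n) +
        stats::rnorm(n * m, 0, config$noise_sd)
      exprs <- matrix(c(ctrl, canc), nrow = n,
        dimnames = list(genes, c(
          paste0(patients, "_control"),
          paste0(patients, "_cancer")
        ))
      )
      stage <- ifelse(stats::runif(m) < config$early_fraction, "early", "late")
      samples <- data.frame(
        sample_id = colnames(exprs),
        patient_id = rep(patients, 2),
        condition = rep(c("control", "cancer"), each = m),
        stage = c(rep(NA_character_, m), stage),
        stringsAsFactors = FALSE
      )
    } else {
      nc <- config$n_cancer
      nn <- config$n_control
      ids <- c(
        paste0(id_prefix, "control_", formatC(seq_len(nn), width = nchar(max(nn, nc)), flag = "0")),
        paste0(id_prefix, "cancer_", formatC(seq_len(nc), width = nchar(max(nn, nc)), flag = "0"))
      )
      offset <- stats::rnorm(nn + nc, 0, config$patient_effect_sd)
      vals <- baseline +
        rep(offset, each = n) +
        stats::rnorm(n * (nn + nc), 0, config$noise_sd)
      vals <- matrix(vals, nrow = n, dimnames = list(genes, ids))
      vals[, seq(nn + 1L, nn + nc)] <- vals[, seq(nn + 1L, nn + nc)] + lfc
      exprs <- vals
      stage <- ifelse(stats::runif(nc) < config$early_fraction, "early", "late")
      samples <- data.frame(
        sample_id = ids,
        patient_id = NA_character_,
        condition = rep(c("control", "cancer"), c(nn, nc)),
        stage = c(rep(NA_character_, nn), stage),
        stringsAsFactors = FALSE
      )
    }
    # shared latent component across each planted panel's genes: adds
    # per-sample correlated noise that cancels along the panel discriminant
    for (panel in config$planted_panels) {
      latent <- stats::rnorm(ncol(exprs), 0, config$panel_latent_sd)
      exprs[panel, ] <- exprs[panel, ] + rep(latent, each = length(panel))
    }
    expression_dataset(exprs, samples)
  })
}

#' Simulate one tumor/control cohort with known ground truth
#'
#' Generates an [expression_dataset()] from a [simulation_config()] together
#' with the ground truth used to make it. In the paired design each patient
#' contributes one cancer and one control sample sharing a per-patient
#' offset; differentially expressed genes have a mean cancer-minus-control
#' log2 difference equal to their planted fold change, all other genes a
#' mean difference of zero. Output is fully determined by the configuration
#' (including its seed).
#'
#' @param config A [simulation_config()].
#' @return A list with elements `dataset` (the `ExpressionDataset`) and
#'   `truth`: a list with `de_lfc` (named signed log2 fold changes of the DE
#'   genes, planted-panel shifts included) and `planted_panels`.
#' @examples
#' sim <- simulate_study(simulation_config(n_genes = 50, n_patients = 10, seed = 1))
#' sim$dataset
#' head(sim$truth$de_lfc)
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- sim_truth(config)
  dataset <- sim_cohort(config, truth, seed = derive_seed(config$seed, 1L))
  list(
    dataset = dataset,
    truth = list(
      de_lfc = truth$lfc[truth$lfc != 0],
      planted_panels = config$planted_panels
    )
  )
}

#' Simulate a multi-cancer panel of train/test cohorts
#'
#' Builds a [cancer_panel()] of several cancer types, each with a training
#' cohort and independent test cohorts drawn from the same per-cancer
#' gene-level truth. A designated number of shared genes is differentially
#' expressed in every cancer, with identical direction when
#' `consistency = TRUE`; each cancer spends the rest of its DE budget on its
#' own genes. A platform mask can drop genes from individual test cohorts to
#' emulate arrays that do not cover a marker gene.
#'
#' @param configs Named list of [simulation_config()]s (>= 2 entries, one
#'   per cancer type; all with the same `n_genes`).
#' @param shared_de_genes Number of genes forced DE in every cancer.
#' @param consistency If `TRUE` shared genes have the same regulation
#'   direction in every cancer; otherwise each cancer draws its own.
#' @param test_cohorts Number of independent test cohorts per cancer.
#' @param platform_mask Optional list of entries
#'   `list(cancer =, cohort =, genes =)` removing `genes` from that cancer's
#'   `cohort`-th test dataset.
#' @param seed Seed for the shared-gene choices (which genes are shared and
#'   their directions). Defaults to the first config's seed.
#'
#' @return A list with `panel` (a [cancer_panel()]) and `truth`: per-cancer
#'   named `de_lfc` vectors, the `shared_genes` direction vector, and
#'   `planted_panels` per cancer.
#' @examples
#' cfg <- function(s) simulation_config(n_genes = 60, n_patients = 8, seed = s)
#' sim <- simulate_panel(list(A = cfg(1), B = cfg(2)),
#'   shared_de_genes = 2, test_cohorts = 1
#' )
#' sim$truth$shared_genes
#' @export
simulate_panel <- function(configs,
                           shared_de_genes = 0,
                           consistency = TRUE,
                           test_cohorts = 2,
                           platform_mask = NULL,
                           seed = NULL) {
  if (!is.list(configs) || length(configs) < 2L ||
    !all(vapply(configs, inherits, logical(1), "simulation_config"))) {
    stop("`configs` must be a named list of >= 2 simulation_config objects",
      call. = FALSE
    )
  }
  if (is.null(names(configs)) || anyNA(names(configs)) || any(names(configs) == "")) {
    stop("`configs` must be named by cancer type", call. = FALSE)
  }
  n_genes <- unique(vapply(configs, `[[`, integer(1), "n_genes"))
  if (length(n_genes) != 1L) {
    stop("all cancers must share the same gene universe (`n_genes`)", call. = FALSE)
  }
  shared_de_genes <- check_count(shared_de_genes, "shared_de_genes", min = 0L)
  test_cohorts <- check_count(test_cohorts, "test_cohorts", min = 0L)
  if (is.null(seed)) seed <- configs[[1L]]$seed
  genes <- sim_gene_ids(n_genes)

  shared <- with_seed(derive_seed(seed, 97L), {
    if (shared_de_genes > 0) {
      ids <- sample(genes, shared_de_genes)
      sign <- ifelse(stats::runif(shared_de_genes) < configs[[1L]]$up_fraction, 1, -1)
      stats::setNames(sign, ids)
    } else {
      stats::setNames(numeric(0), character(0))
    }
  })

  entries <- list()
  truth <- list(per_cancer = list(), shared_genes = shared, planted_panels = list())
  for (i in seq_along(configs)) {
    nm <- names(configs)[i]
    cfg <- configs[[i]]
    forced <- shared
    if (!consistency && length(shared)) {
      forced <- with_seed(derive_seed(cfg$seed, 131L), {
        stats::setNames(
          ifelse(stats::runif(length(shared)) < cfg$up_fraction, 1, -1),
          names(shared)
        )
      })
    }
    tr <- sim_truth(cfg, forced_sign = if (length(forced)) forced else NULL)
    train <- sim_cohort(cfg, tr, seed = derive_seed(cfg$seed, 1L))
    tests <- list()
    if (test_cohorts > 0) {
      tests <- lapply(seq_len(test_cohorts), function(j) {
        sim_cohort(cfg, tr, seed = derive_seed(cfg$seed, 1L + j))
      })
      names(tests) <- paste0("test", seq_len(test_cohorts))
    }
    entries[[nm]] <- list(name = nm, train = train, tests = tests, de = NULL)
    truth$per_cancer[[nm]] <- tr$lfc[tr$lfc != 0]
    truth$planted_panels[[nm]] <- cfg$planted_panels
  }

  if (!is.null(platform_mask)) {
    for (mask in platform_mask) {
      if (!all(c("cancer", "cohort", "genes") %in% names(mask))) {
        stop("each platform_mask entry needs `cancer`, `cohort` and `genes`",
          call. = FALSE
        )
      }
      if (!mask$cancer %in% names(entries)) {
        stop(sprintf("platform_mask cancer '%s' not in panel", mask$cancer), call. = FALSE)
      }
      ts <- entries[[mask$cancer]]$tests
      if (mask$cohort < 1 || mask$cohort > length(ts)) {
        stop("platform_mask `cohort` out of range", call. = FALSE)
      }
      ds <- ts[[mask$cohort]]
      keep <- setdiff(gene_ids(ds), mask$genes)
      entries[[mask$cancer]]$tests[[mask$cohort]] <- subset_genes(ds, keep)
    }
  }

  list(panel = cancer_panel(entries), truth = truth)
}

#' Write a simulated study to disk
#'
#' Writes the expression matrix and metadata as TSV (see
#' [write_expression()]) and the ground truth as JSON.
#'
#' @param sim Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    matrix = file.path(dir, "expression.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_expression(sim$dataset, paths[["matrix"]], paths[["metadata"]])
  jsonlite::write_json(
    list(
      de_lfc = as.list(sim$truth$de_lfc),
      planted_panels = sim$truth$planted_panels
    ),
    paths[["truth"]],
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
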