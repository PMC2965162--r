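#' Pipeline configuration
#'
#' Collects every parameter of the end-to-end analysis. Exactly one data
#' source must be given: an in-memory [cancer_panel()] (`panel`), a
#' simulation recipe (`simulate`, arguments for [simulate_panel()] with
#' per-cancer [simulation_config()] argument lists), or file inputs
#' (`cancers`: a named list with per-cancer `matrix`/`metadata` paths and
#' optional `tests`, a list of `matrix`/`metadata` pairs).
#'
#' @param panel Optional [cancer_panel()].
#' @param simulate Optional list: `configs` (named list of argument lists
#'   for [simulation_config()]) plus any other [simulate_panel()] argument.
#' @param cancers Optional named list of file inputs (see above).
#' @param alpha,min_fc,design,sided Differential-expression settings, see
#'   [call_differential()].
#' @param k Integer vector of combination sizes to search (subset of 1:4).
#' @param top_n,folds,cost,prefilter Marker-search settings, see
#'   [rank_markers()].
#' @param accuracy_cutoff,min_types Multi-cancer settings, see
#'   [find_multi_cancer_combos()].
#' @param gmt Optional path to a pathway GMT file for enrichment.
#' @param secretory_gmt Optional path to a GMT file whose sets (union) are
#'   the blood-secretory gene list.
#' @param accuracy_floor Accuracy floor of the secretory filter.
#' @param survival_table Optional path to a five-year survival TSV (see
#'   [read_survival_table()]).
#' @param seed Mandatory integer seed; every stochastic stage derives its
#'   randomness from it.
#' @param out_dir Output directory.
#' @param max_combinations Compute budget: refuse an exhaustive enumeration
#'   larger than this unless `force = TRUE` (default 4e6, about the cost of
#'   4-gene combinations over 100 genes).
#' @param force Override the compute budget guard.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(panel = NULL, simulate = NULL, cancers = NULL,
                            alpha = 0.05, min_fc = 2,
                            design = "auto", sided = "two",
                            k = c(1L, 2L), top_n = 100L, folds = 5L,
                            cost = 1, prefilter = NULL,
                            accuracy_cutoff = 0.70, min_types = 2L,
                            gmt = NULL, secretory_gmt = NULL,
                            accuracy_floor = 0.70,
                            survival_table = NULL,
                            seed = NULL, out_dir = NULL,
                            max_combinations = 4e6, force = FALSE) {
  sources <- c(!is.null(panel), !is.null(simulate), !is.null(cancers))
  if (sum(sources) != 1L) {
    stop("give exactly one of `panel`, `simulate` or `cancers`", call. = FALSE)
  }
  if (is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  seed <- check_count(seed, "seed", min = 0L)
  if (is.null(out_dir)) stop("`out_dir` is required", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(min_fc) || min_fc < 1) stop("`min_fc` must be >= 1", call. = FALSE)
  k <- vapply(k, check_count, integer(1), name = "k")
  if (any(k > 4L)) stop("`k` values must lie in 1:4", call. = FALSE)
  if (!is.numeric(accuracy_cutoff) || accuracy_cutoff <= 0.5 || accuracy_cutoff > 1) {
    stop("`accuracy_cutoff` must lie in (0.5, 1]", call. = FALSE)
  }
  structure(
    list(
      panel = panel, simulate = simulate, cancers = cancers,
      alpha = alpha, min_fc = min_fc, design = design, sided = sided,
      k = sort(unique(k)), top_n = check_count(top_n, "top_n"),
      folds = check_count(folds, "folds", min = 2L), cost = cost,
      prefilter = prefilter,
      accuracy_cutoff = accuracy_cutoff,
      min_types = check_count(min_types, "min_types", min = 1L),
      gmt = gmt, secretory_gmt = secretory_gmt,
      accuracy_floor = accuracy_floor,
      survival_table = survival_table,
      seed = seed, out_dir = out_dir,
      max_combinations = max_combinations, force = isTRUE(force)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [pipeline_config()]; the
#' `simulate` section holds [simulate_panel()] arguments with per-cancer
#' [simulation_config()] argument maps under `configs`.
#'
#' @param path Path to a YAML file.
#' @param ... Overrides passed on to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  do.call(pipeline_config, raw)
}

run_stage <- function(stage, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", stage, conditionMessage(e)), call. = FALSE)
  })
  message(sprintf(
    "[%s] done in %.2fs", stage,
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ))
  res
}

assemble_panel <- function(config) {
  if (!is.null(config$panel)) {
    return(list(panel = config$panel, truth = NULL, inputs = "in-memory panel"))
  }
  if (!is.null(config$simulate)) {
    args <- config$simulate
    args$configs <- lapply(args$configs, function(a) do.call(simulation_config, a))
    sim <- do.call(simulate_panel, args)
    return(list(panel = sim$panel, truth = sim$truth, inputs = "simulated"))
  }
  entries <- lapply(names(config$cancers), function(nm) {
    spec <- config$cancers[[nm]]
    train <- read_expression(spec$matrix, spec$metadata)
    tests <- list()
    if (!is.null(spec$tests)) {
      tests <- lapply(spec$tests, function(t) read_expression(t$matrix, t$metadata))
      names(tests) <- paste0("test", seq_along(tests))
    }
    list(train = train, tests = tests, de = NULL)
  })
  names(entries) <- names(config$cancers)
  list(
    panel = cancer_panel(entries), truth = NULL,
    inputs = unlist(config$cancers, use.names = TRUE)
  )
}

guard_budget <- function(n_genes, k, max_combinations, force) {
  n_combos <- choose(n_genes, k)
  if (n_combos > max_combinations && !force) {
    stop(sprintf(
      paste0(
        "compute budget exceeded: C(%d, %d) = %.3g combinations ",
        "(budget %.3g); use `prefilter` or `force = TRUE`"
      ),
      n_genes, k, n_combos, max_combinations
    ), call. = FALSE)
  }
  invisible(n_combos)
}

#' Run the end-to-end marker-discovery pipeline
#'
#' Orchestrates, per cancer type: differential-expression calling, the
#' exhaustive k-gene marker search with test-cohort evaluation, then the
#' cross-cancer analyses (shared DE genes, multi-cancer combinations),
#' optional pathway enrichment, secretory filtering and the DE-count /
#' survival correlation. All result tables are written to
#' `config$out_dir` as TSV together with a machine-readable `manifest.json`
#' recording inputs, parameters, seed and package versions; rerunning the
#' same configuration and seed reproduces the outputs byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the report bundle: `panel`, `de` (per-cancer tables),
#'   `markers` (per cancer, per k), `shared_genes`, `multi_combos`,
#'   `enrichment`, `secretory`, `survival`, `truth` (when simulated),
#'   `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_tsv(df, path)
    files[[length(files) + 1L]] <<- path
    path
  }

  src <- run_stage("assemble", assemble_panel(config))
  panel <- src$panel

  panel <- run_stage("differential", panel_differential(
    panel,
    alpha = config$alpha, min_fc = config$min_fc,
    design = config$design, sided = config$sided
  ))
  de_tables <- lapply(panel$cancers, `[[`, "de")
  for (nm in names(de_tables)) {
    emit(de_tables[[nm]], sprintf("de_%s.tsv", nm))
  }

  markers <- run_stage("marker_search", {
    out <- list()
    for (nm in names(panel$cancers)) {
      e <- panel$cancers[[nm]]
      genes <- e$de$gene[e$de$is_de]
      out[[nm]] <- list()
      for (kk in config$k) {
        if (length(genes) < kk) next
        pool_size <- if (!is.null(config$prefilter) && kk >= 2L) {
          min(length(genes), config$prefilter)
        } else {
          length(genes)
        }
        guard_budget(pool_size, kk, config$max_combinations, config$force)
        ranked <- rank_markers(e$train, genes,
          k = kk, top_n = config$top_n,
          folds = config$folds, seed = config$seed, cost = config$cost,
          prefilter = if (kk >= 2L) config$prefilter else NULL
        )
        if (length(e$tests)) {
          ranked <- evaluate_on_test(ranked, e$train, e$tests, cost = config$cost)
        }
        out[[nm]][[paste0("k", kk)]] <- ranked
        emit(ranked, sprintf("markers_%s_k%d.tsv", nm, kk))
      }
    }
    out
  })

  shared <- run_stage("shared_genes", find_shared_de_genes(
    panel,
    min_types = config$min_types
  ))
  emit(shared, "shared_genes.tsv")

  multi <- run_stage("multi_cancer", {
    out <- list()
    pool0 <- tryCatch(
      find_shared_de_genes(panel, min_types = 2L),
      error = function(e) NULL
    )
    for (kk in config$k[config$k >= 2L]) {
      if (is.null(pool0) || nrow(pool0) < kk) next
      guard_budget(nrow(pool0), kk, config$max_combinations, config$force)
      combos <- find_multi_cancer_combos(panel,
        k = kk,
        accuracy_cutoff = config$accuracy_cutoff,
        min_types = config$min_types,
        folds = config$folds, seed = config$seed, cost = config$cost
      )
      out[[paste0("k", kk)]] <- combos
      emit(combos, sprintf("multi_cancer_k%d.tsv", kk))
    }
    out
  })

  enrichment <- NULL
  if (!is.null(config$gmt)) {
    enrichment <- run_stage("enrichment", {
      sets <- read_gmt(config$gmt)
      rows <- list()
      for (nm in names(panel$cancers)) {
        e <- panel$cancers[[nm]]
        coll <- suppressWarnings(
          gene_set_collection(sets, background = gene_ids(e$train))
        )
        de <- e$de[e$de$is_de, , drop = FALSE]
        for (dir in c("all", "up", "down")) {
          q <- switch(dir,
            all = de$gene,
            up = de$gene[de$direction == "up"],
            down = de$gene[de$direction == "down"]
          )
          if (!length(q)) next
          res <- suppressWarnings(hypergeometric_enrichment(q, coll, alpha = config$alpha))
          res <- cbind(cancer = nm, direction = dir, res, stringsAsFactors = FALSE)
          rows[[length(rows) + 1L]] <- res
        }
      }
      do.call(rbind, rows)
    })
    if (!is.null(enrichment)) emit(enrichment, "enrichment.tsv")
  }

  secretory <- NULL
  if (!is.null(config$secretory_gmt)) {
    secretory <- run_stage("secretory", {
      secr <- unique(unlist(read_gmt(config$secretory_gmt), use.names = FALSE))
      rows <- list()
      for (nm in names(markers)) {
        for (kk in names(markers[[nm]])) {
          kept <- filter_secretory(markers[[nm]][[kk]], secr,
            accuracy_floor = config$accuracy_floor
          )
          if (nrow(kept)) {
            rows[[length(rows) + 1L]] <- cbind(
              cancer = nm, kept[, c("genes", "k", "cv_accuracy")],
              stringsAsFactors = FALSE
            )
          }
        }
      }
      for (kk in names(multi)) {
        kept <- filter_secretory(multi[[kk]], secr,
          accuracy_floor = config$accuracy_floor
        )
        if (nrow(kept)) {
          rows[[length(rows) + 1L]] <- cbind(
            cancer = "multi", kept[, c("genes", "k")],
            cv_accuracy = NA_real_, stringsAsFactors = FALSE
          )
        }
      }
      if (length(rows)) do.call(rbind, rows) else NULL
    })
    if (!is.null(secretory)) emit(secretory, "secretory_markers.tsv")
  }

  survival <- NULL
  if (!is.null(config$survival_table)) {
    survival <- run_stage("survival", {
      tab <- read_survival_table(config$survival_table)
      counts <- vapply(de_tables, function(d) sum(d$is_de), numeric(1))
      tab <- tab[tab$cancer %in% names(counts), , drop = FALSE]
      tab$de_gene_count <- unname(counts[tab$cancer])
      cor <- if (nrow(tab) >= 3L &&
        stats::sd(tab$de_gene_count) > 0 &&
        stats::sd(tab$five_year_survival_rate) > 0) {
        survival_correlation(tab)
      } else {
        NULL
      }
      list(records = tab, correlation = cor)
    })
    emit(survival$records, "survival.tsv")
  }

  manifest <- list(
    package = "markerscan",
    package_version = as.character(utils::packageVersion("markerscan")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    inputs = src$inputs,
    parameters = config[setdiff(
      names(config),
      c("panel", "simulate", "cancers", "out_dir")
    )],
    seed = config$seed,
    survival_correlation = if (!is.null(survival$correlation)) {
      survival$correlation[c("r", "p_value", "method", "n")]
    },
    outputs = basename(unlist(files))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )

  invisible(list(
    panel = panel, de = de_tables, markers = markers,
    shared_genes = shared, multi_combos = multi,
    enrichment = enrichment, secretory = secretory,
    survival = survival, truth = src$truth,
    files = c(unlist(files), manifest_path)
  ))
}
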