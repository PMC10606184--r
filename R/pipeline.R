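#' Pipeline configuration
#'
#' Bundles the stage configurations for the end-to-end run
#' (simulate -> encode -> select -> evaluate). A single global seed fans out
#' to deterministic stage-specific seeds (offset by a per-stage constant) so
#' each stage is independently reproducible.
#'
#' @param cohort a [cohort_config()] for the synthetic-cohort stage (or
#'   `NULL` when encoding existing VCFs).
#' @param encoding list of [encode_vcf_dir()] options: `mode`, `snps_only`,
#'   `pass_only`, `exclude`.
#' @param ga a [ga_config()].
#' @param k per-class panel size for the select stage.
#' @param k_grid optional grid for a sweep stage instead of a single `k`.
#' @param cv a [cv_config()].
#' @param classifiers preset names to benchmark.
#' @param whole_data_selection if `TRUE`, the panel is selected once on the full
#'   dataset before cross-validation (the protocol that concatenates
#'   selection and evaluation on the same samples; optimistic because test
#'   samples inform the selection). If `FALSE` (default) selection is
#'   re-run inside each training fold, which is leakage-safe.
#' @param seed global seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(), encoding = list(),
                            ga = ga_config(), k = 10L, k_grid = NULL,
                            cv = cv_config(), classifiers = NULL,
                            whole_data_selection = FALSE, seed = 1L) {
  enc <- utils::modifyList(list(mode = "genotype", snps_only = FALSE,
                                pass_only = FALSE, exclude = NULL), encoding)
  if (is.null(classifiers)) classifiers <- names(classifier_presets())
  seed <- as.integer(seed)
  cohort$seed <- seed
  ga$seed <- seed + 101L
  cv$seed <- seed + 202L
  structure(list(cohort = cohort, encoding = enc, ga = ga,
                 k = as.integer(k), k_grid = k_grid, cv = cv,
                 classifiers = classifiers, whole_data_selection = whole_data_selection,
                 seed = seed),
            class = "pipeline_config")
}

serialize_config <- function(x) {
  strip <- function(v) if (is.list(v)) lapply(unclass(v), strip) else v
  jsonlite::toJSON(strip(x), auto_unbox = TRUE, digits = NA, null = "null",
                   pretty = TRUE)
}

stage_done <- function(run_dir, stage, cfg_json, outputs) {
  cfg_path <- file.path(run_dir, paste0(stage, ".config.json"))
  all(file.exists(file.path(run_dir, outputs))) &&
    file.exists(cfg_path) &&
    identical(paste(readLines(cfg_path), collapse = "\n"),
              as.character(cfg_json))
}

mark_stage <- function(run_dir, stage, cfg_json) {
  writeLines(as.character(cfg_json),
             file.path(run_dir, paste0(stage, ".config.json")))
}

#' Leakage-safe nested cross-validation (selection inside each fold)
#'
#' For every outer fold, the candidate pool and GA panel search are re-run
#' on the training samples only; the held-out samples never inform the
#' selection. Returns one `cv_report` per classifier plus the per-fold
#' panels.
#'
#' @param gm labeled [genotype_matrix()].
#' @param k per-class panel size.
#' @param ga a [ga_config()].
#' @param presets named list of [classifier_spec()]s.
#' @param cv a [cv_config()].
#' @return list with `reports` (named per classifier), `table` (benchmark
#'   table as in [benchmark_classifiers()]) and `fold_panels`.
#' @export
nested_cross_validate <- function(gm, k, ga = ga_config(),
                                  presets = classifier_presets(),
                                  cv = cv_config()) {
  if (is.null(gm$labels)) stop("cohort matrix must be labeled")
  y <- factor(gm$labels)
  splits <- make_splits(y, cv)
  fold_panels <- vector("list", length(splits))
  fold_reports <- lapply(presets, function(sp) vector("list", length(splits)))
  for (i in seq_along(splits)) {
    test <- splits[[i]]
    train <- setdiff(seq_along(y), test)
    train_gm <- genotype_matrix(gm$values[train, , drop = FALSE],
                                gm$features, gm$sample_ids[train],
                                labels = gm$labels[train])
    ga_i <- ga
    ga_i$seed <- ga$seed + i
    panel <- run_ga(train_gm, k, ga_i)
    fold_panels[[i]] <- panel
    X <- subset_features(gm, panel$assembled)
    for (nm in names(presets)) {
      sp <- presets[[nm]]
      sp$seed <- sp$seed + i
      model <- fit_classifier(sp, X[train, , drop = FALSE], y[train])
      pred <- predict(model, X[test, , drop = FALSE])
      fold_reports[[nm]][[i]] <- fold_report(y[test], pred,
                                             classes = levels(y), fold = i,
                                             convention = cv$convention)
    }
  }
  reports <- lapply(names(presets), function(nm) {
    folds <- fold_reports[[nm]]
    f1 <- sapply(folds, function(f) f$per_class$f1)
    rownames(f1) <- folds[[1]]$per_class$class
    mean_f1 <- rowMeans(f1)
    structure(list(folds = folds,
                   mean_accuracy = mean(vapply(folds, `[[`, 1,
                                               "overall_accuracy")),
                   mean_f1 = mean_f1, min_f1 = min(mean_f1),
                   aggregated_cm = Reduce(`+`, lapply(folds, `[[`, "cm")),
                   cv = cv, spec = presets[[nm]], panel_size = NA_integer_),
              class = "cv_report")
  })
  names(reports) <- names(presets)
  tab <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    cbind(data.frame(classifier = nm, accuracy = r$mean_accuracy),
          as.data.frame(as.list(r$mean_f1), check.names = FALSE),
          data.frame(min_f1 = r$min_f1))
  }))
  rownames(tab) <- NULL
  list(reports = reports, table = tab, fold_panels = fold_panels)
}

#' Run the full pipeline into a run directory
#'
#' Executes simulate -> encode -> select (or sweep) -> evaluate, writing all
#' artifacts (VCFs, labels, matrix TSV, panel JSON, benchmark report JSON
#' and Table-style TSV, confusion-matrix TSVs) under `run_dir`. A stage is
#' skipped when its outputs exist and its stored stage config is unchanged.
#' The full serialized config is written into the run directory for
#' provenance.
#'
#' @param config a [pipeline_config()].
#' @param run_dir output directory.
#' @param vcf_dir optional directory of existing VCFs; when given the
#'   simulate stage is skipped and these files are encoded instead.
#' @param labels labels TSV path or named vector (required with `vcf_dir`).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the key results (`matrix`, `panel` or
#'   `sweep`, `benchmark`) and artifact paths.
#' @export
run_pipeline <- function(config, run_dir, vcf_dir = NULL, labels = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(vcf_dir)) {
    if (!dir.exists(vcf_dir)) stop("vcf_dir does not exist: ", vcf_dir)
    if (is.null(labels)) stop("labels are required when encoding ", vcf_dir)
    if (is.character(labels) && !file.exists(labels))
      stop("labels file not found: ", labels)
  }
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[aimpanel] ", ...)
  writeLines(as.character(serialize_config(config)),
             file.path(run_dir, "pipeline.config.json"))

  # simulate
  if (is.null(vcf_dir)) {
    sim_json <- serialize_config(config$cohort)
    if (!stage_done(run_dir, "simulate", sim_json,
                    c("vcf", "labels.tsv", "truth.json"))) {
      say("simulate: generating synthetic cohort")
      simulate_cohort(config$cohort, out_dir = run_dir)
      mark_stage(run_dir, "simulate", sim_json)
    } else say("simulate: up to date, skipping")
    vcf_dir <- file.path(run_dir, "vcf")
    labels <- file.path(run_dir, "labels.tsv")
  }

  # encode (cumulative config: changing the cohort invalidates the matrix)
  enc_json <- serialize_config(list(cohort = config$cohort,
                                    encoding = config$encoding))
  matrix_path <- file.path(run_dir, "matrix.tsv")
  if (!stage_done(run_dir, "encode", enc_json, "matrix.tsv")) {
    say("encode: building binary genotype matrix")
    gm <- encode_vcf_dir(vcf_dir, labels = labels,
                         mode = config$encoding$mode,
                         snps_only = config$encoding$snps_only,
                         pass_only = config$encoding$pass_only,
                         exclude = config$encoding$exclude)
    write_matrix(gm, matrix_path)
    mark_stage(run_dir, "encode", enc_json)
  } else {
    say("encode: up to date, skipping")
    gm <- read_matrix(matrix_path)
    lab <- if (is.character(labels) && length(labels) == 1)
      read_labels_tsv(labels) else labels
    if (!is.null(config$encoding$exclude) && !is.data.frame(lab))
      lab <- lab[setdiff(names(lab), config$encoding$exclude)]
    gm <- set_labels(gm, lab)
  }

  presets <- classifier_presets(config$classifiers, seed = config$cv$seed)
  result <- list(matrix = gm)

  if (!is.null(config$k_grid)) {
    say("sweep: panel sizes ", paste(config$k_grid, collapse = ","))
    sweep <- sweep_panel_size(gm, config$k_grid, config$ga)
    write_sweep(sweep, tsv_path = file.path(run_dir, "sweep.tsv"),
                json_path = file.path(run_dir, "sweep.json"))
    panel <- sweep$panels[[paste0("k", sweep$selected_k)]]
    result$sweep <- sweep
  } else if (config$whole_data_selection) {
    sel_json <- serialize_config(list(cohort = config$cohort,
                                      encoding = config$encoding,
                                      ga = config$ga, k = config$k,
                                      whole_data_selection = TRUE))
    panel_path <- file.path(run_dir, "panel.json")
    if (!stage_done(run_dir, "select", sel_json, "panel.json")) {
      say("select (whole-data selection): GA on the full dataset; ",
          "test folds inform the selection")
      panel <- run_ga(gm, config$k, config$ga)
      write_panel_json(panel, panel_path)
      mark_stage(run_dir, "select", sel_json)
    } else {
      say("select: up to date, skipping")
      panel <- read_panel_json(panel_path)
    }
  } else panel <- NULL

  say("evaluate: benchmarking ", length(presets), " classifiers")
  if (is.null(panel)) {
    nested <- nested_cross_validate(gm, config$k, config$ga, presets,
                                    config$cv)
    bench <- structure(list(table = nested$table, reports = nested$reports,
                            best = nested$table$classifier[
                              which.max(nested$table$min_f1)]),
                       class = "benchmark_report")
    result$fold_panels <- nested$fold_panels
  } else {
    bench <- benchmark_classifiers(gm, panel, presets, config$cv)
    result$panel <- panel
  }
  write_benchmark_json(bench, file.path(run_dir, "report.json"))
  utils::write.table(bench$table, file.path(run_dir, "benchmark.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(bench$reports))
    utils::write.table(as.data.frame(bench$reports[[nm]]$aggregated_cm),
                       file.path(run_dir, paste0("confusion_", nm, ".tsv")),
                       sep = "\t", quote = FALSE)
  result$benchmark <- bench
  say("done: ", run_dir)
  invisible(result)
}

#' One-command synthetic end-to-end demo
#'
#' Simulates a small cohort with planted markers, selects a panel on the
#' full data, benchmarks the classifier presets and writes all artifacts.
#' Deterministic: two runs with the same seed produce identical reports.
#'
#' @param seed global seed.
#' @param run_dir output directory (default: under `tempdir()`).
#' @param n_per_class,n_background_sites,n_aims_per_class cohort scale
#'   (reduced from the full default cohort so the demo runs in seconds).
#' @return the [run_pipeline()] result, invisibly.
#' @export
run_demo <- function(seed = 1L, run_dir = file.path(tempdir(), "aimpanel-demo"),
                     n_per_class = c(Poles = 40L, Russians = 15L,
                                     Serbs = 10L, NonSlavs = 60L),
                     n_background_sites = 300L, n_aims_per_class = 3L) {
  cfg <- pipeline_config(
    cohort = cohort_config(n_per_class = n_per_class,
                           n_background_sites = n_background_sites,
                           n_aims_per_class = n_aims_per_class),
    ga = ga_config(pool_size_per_class = 12L, population_size = 20L,
                   generations = 15L, stagnation_patience = 5L),
    k = n_aims_per_class, whole_data_selection = TRUE, seed = seed)
  run_pipeline(cfg, run_dir)
}
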