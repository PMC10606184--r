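#' Per-feature distinctiveness across populations
#'
#' For every binary feature, the carrier rate within each population (the
#' fraction of that population's individuals carrying it), the total cohort
#' carrier count, and a per-class distinctiveness score: the one-vs-rest
#' presence-rate differential
#' `score(f, c) = rate(f, c) - max over c' != c of rate(f, c')`.
#' A feature private to one population scores +1 for it and negatively
#' elsewhere; a feature everyone carries scores 0 for every class.
#'
#' @param gm labeled [genotype_matrix()] with at least two non-empty classes.
#' @return a `distinctiveness_table`: list with `classes`, `class_sizes`,
#'   `rates` (features x classes), `cohort_count` (named integer vector) and
#'   `scores` (features x classes); feature keys as rownames.
#' @export
compute_distinctiveness <- function(gm) {
  if (is.null(gm$labels)) stop("matrix must carry population labels")
  classes <- sort(unique(gm$labels))
  if (length(classes) < 2) stop("need at least two populations")
  sizes <- table(factor(gm$labels, levels = classes))
  if (any(sizes == 0))
    stop("empty class: ", paste(names(sizes)[sizes == 0], collapse = ", "))
  rates <- vapply(classes, function(cl)
    colMeans(gm$values[gm$labels == cl, , drop = FALSE]),
    numeric(ncol(gm$values)))
  if (ncol(gm$values) == 1) rates <- matrix(rates, nrow = 1)
  dimnames(rates) <- list(colnames(gm$values), classes)
  scores <- vapply(seq_along(classes), function(j) {
    other <- rates[, -j, drop = FALSE]
    rates[, j] - apply(other, 1, max)
  }, numeric(nrow(rates)))
  if (nrow(rates) == 1) scores <- matrix(scores, nrow = 1)
  dimnames(scores) <- dimnames(rates)
  structure(list(classes = classes,
                 class_sizes = stats::setNames(as.integer(sizes), classes),
                 rates = rates,
                 cohort_count = stats::setNames(
                   as.integer(colSums(gm$values)), colnames(gm$values)),
                 scores = scores),
            class = "distinctiveness_table")
}

#' Top-scoring candidate features per population
#'
#' For each class, the `pool_size_per_class` features with the highest
#' distinctiveness score for that class; ties are broken by canonical
#' feature-key order (the order of the matrix columns). Pools may overlap
#' across classes.
#'
#' @param table a [compute_distinctiveness()] result.
#' @param pool_size_per_class pool size; must not exceed the number of
#'   available features.
#' @return named list class -> character vector of feature keys, in
#'   descending score order.
#' @export
build_candidate_pool <- function(table, pool_size_per_class) {
  n <- nrow(table$scores)
  if (pool_size_per_class > n)
    stop("pool_size_per_class (", pool_size_per_class,
         ") exceeds available features (", n, ")")
  lapply(stats::setNames(table$classes, table$classes), function(cl) {
    ord <- order(-table$scores[, cl], method = "radix")  # stable: canonical tie-break
    rownames(table$scores)[ord[seq_len(pool_size_per_class)]]
  })
}

#' Genetic-algorithm configuration
#'
#' Operator and budget settings for the panel search. The search maintains a
#' population of candidate panels (one size-`k` feature subset per class,
#' drawn from that class's candidate pool) and evolves it by tournament
#' selection, uniform crossover with repair, per-gene swap mutation and
#' elitism of one.
#'
#' @param pool_size_per_class candidate pool size per class (default 50).
#' @param population_size GA population size (default 50).
#' @param generations maximum generations (default 100).
#' @param tournament_size tournament size for parent selection (default 3).
#' @param crossover_rate probability a child is produced by crossover rather
#'   than cloning (default 0.9).
#' @param mutation_rate per-gene swap probability; `NULL` (default) means
#'   `1 / (k * n_classes)`, i.e. one expected swap per candidate panel.
#'   Higher rates (e.g. `1 / k`, one expected swap per class) were observed
#'   to stall the search in a mutation-selection balance well below the
#'   optimum, because every child of a good panel is disturbed in several
#'   classes at once.
#' @param stagnation_patience stop after this many generations without
#'   improvement of the best fitness (default 20).
#' @param inner_cv_folds stratified folds for the fitness evaluation
#'   (default 3).
#' @param fitness_classifier preset name used inside the fitness function
#'   (default `"linear_svm"`).
#' @param dedupe_assembled drop duplicate features when concatenating the
#'   per-class panels into the classifier input (default `FALSE`, keeping
#'   the assembled length exactly `n_classes * k`).
#' @param seed seed controlling the GA stream and fitness CV.
#' @return a `ga_config` list.
#' @export
ga_config <- function(pool_size_per_class = 50L, population_size = 50L,
                      generations = 100L, tournament_size = 3L,
                      crossover_rate = 0.9, mutation_rate = NULL,
                      stagnation_patience = 20L, inner_cv_folds = 3L,
                      fitness_classifier = "linear_svm",
                      dedupe_assembled = FALSE, seed = 1L) {
  stopifnot(pool_size_per_class >= 1, population_size >= 2, generations >= 1,
            tournament_size >= 1, crossover_rate >= 0, crossover_rate <= 1,
            stagnation_patience >= 1, inner_cv_folds >= 2)
  if (!is.null(mutation_rate))
    stopifnot(mutation_rate >= 0, mutation_rate <= 1)
  structure(list(pool_size_per_class = as.integer(pool_size_per_class),
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 tournament_size = as.integer(tournament_size),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 stagnation_patience = as.integer(stagnation_patience),
                 inner_cv_folds = as.integer(inner_cv_folds),
                 fitness_classifier = fitness_classifier,
                 dedupe_assembled = dedupe_assembled,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Construct an SNP panel object
#'
#' @param per_class named list class -> feature keys (size `k` each).
#' @param dedupe drop duplicates in the assembled concatenation.
#' @param provenance free-form list of run metadata.
#' @return an `snp_panel`: per-class lists (canonically sorted), `k`, the
#'   `assembled` feature vector fed to classifiers, and provenance.
#' @export
snp_panel <- function(per_class, dedupe = FALSE, provenance = list()) {
  k <- unique(lengths(per_class))
  if (length(k) != 1) stop("per-class panels must share one size k")
  per_class <- lapply(per_class, function(keys)
    keys[order_features(parse_feature_key(keys))])
  assembled <- unlist(per_class, use.names = FALSE)
  if (dedupe) assembled <- unique(assembled)
  structure(list(per_class = per_class, k = k, assembled = assembled,
                 dedupe = dedupe, provenance = provenance),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("snp_panel: k =", x$k, "per class x", length(x$per_class),
      "classes ->", length(x$assembled), "assembled features\n")
  if (!is.null(x$provenance$best_fitness))
    cat("fitness (min per-class F1):",
        round(x$provenance$best_fitness, 4), "\n")
  invisible(x)
}

panel_cache_key <- function(chrom_keys) {
  paste(vapply(chrom_keys, function(g) paste(sort(g), collapse = ";"), ""),
        collapse = " || ")
}

#' Fitness of a panel: minimum per-class cross-validated F1
#'
#' Restricts the cohort matrix to the panel's assembled feature list, runs
#' the configured fitness classifier under stratified `inner_cv_folds`-fold
#' cross-validation, and returns the minimum over classes of the mean
#' per-class one-vs-all F1-score. Deterministic given `config$seed`.
#'
#' @param panel an `snp_panel` or named list class -> feature keys.
#' @param gm labeled [genotype_matrix()].
#' @param config a [ga_config()].
#' @return scalar fitness in `[0, 1]`.
#' @export
panel_fitness <- function(panel, gm, config = ga_config()) {
  keys <- if (inherits(panel, "snp_panel")) panel$assembled
          else {
            ks <- unlist(panel, use.names = FALSE)
            if (config$dedupe_assembled) unique(ks) else ks
          }
  spec <- classifier_presets(config$fitness_classifier,
                             seed = config$seed)[[1]]
  cv <- cv_config(mode = "kfold5", n_splits = config$inner_cv_folds,
                  seed = config$seed)
  cross_validate(gm, keys, spec, cv)$min_f1
}

#' Genetic-algorithm search for an ancestry-informative panel
#'
#' Evolves one size-`k` feature subset per class, drawn from per-class
#' candidate pools, to maximize the minimum per-class cross-validated
#' F1-score of the assembled panel. Operators: tournament selection,
#' uniform crossover (children repaired to size `k` by resampling from the
#' pool without replacement), per-gene swap mutation, elitism of one. Stops
#' at `config$generations` or after `config$stagnation_patience` generations
#' without improvement. Fitness values are cached by the canonical panel
#' rendering, so re-evaluations of a previously seen panel are free and the
#' search is exactly reproducible under `config$seed`.
#'
#' The initial population contains one *greedy* chromosome — the top `k`
#' features of each class's pool in score order — alongside uniformly random
#' pool subsets. Seeding with the distinctiveness-greedy panel guarantees
#' the search never returns less than the greedy solution and, when several
#' panels tie at the maximum fitness (common once the cohort is perfectly
#' separated), the tie resolves in favour of the most individually
#' distinctive markers rather than an arbitrary subset.
#'
#' @param gm labeled [genotype_matrix()].
#' @param k panel size per class; must not exceed the pool size.
#' @param config a [ga_config()].
#' @param pools optional named list class -> candidate feature keys;
#'   computed from [compute_distinctiveness()] + [build_candidate_pool()]
#'   when omitted.
#' @param fitness_fn optional replacement fitness: a function taking a named
#'   list class -> feature keys and returning a scalar (used for frozen
#'   fitness benchmarks); defaults to [panel_fitness()].
#' @return an `snp_panel` whose provenance records the seed, generations
#'   run, per-generation best fitness history, final fitness and the number
#'   of distinct panels evaluated.
#' @export
run_ga <- function(gm, k, config = ga_config(), pools = NULL,
                   fitness_fn = NULL) {
  if (is.null(pools)) {
    dt <- compute_distinctiveness(gm)
    pools <- build_candidate_pool(dt, config$pool_size_per_class)
  }
  classes <- names(pools)
  pool_sizes <- lengths(pools)
  if (any(k > pool_sizes))
    stop("k = ", k, " exceeds pool size (", min(pool_sizes), ")")
  if (is.null(fitness_fn))
    fitness_fn <- function(per_class) panel_fitness(per_class, gm, config)
  mut_rate <- if (is.null(config$mutation_rate)) 1 / (k * length(classes))
              else config$mutation_rate

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  evaluate <- function(chrom) {
    key <- panel_cache_key(chrom)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- fitness_fn(stats::setNames(chrom, classes))
    n_eval <<- n_eval + 1L
    cache[[key]] <- val
    val
  }
  random_chrom <- function()
    lapply(pools, function(p) sample(p, k))
  tournament <- function(fits) {
    cand <- sample.int(length(fits), config$tournament_size, replace = TRUE)
    cand[which.max(fits[cand])]
  }
  crossover <- function(a, b) {
    lapply(seq_along(classes), function(j) {
      pick <- stats::runif(k) < 0.5
      child <- unique(ifelse(pick, a[[j]], b[[j]]))
      if (length(child) < k)
        child <- c(child, sample(setdiff(pools[[j]], child),
                                 k - length(child)))
      child
    })
  }
  mutate <- function(chrom) {
    lapply(seq_along(classes), function(j) {
      g <- chrom[[j]]
      hit <- which(stats::runif(k) < mut_rate)
      if (length(hit) > 0) {
        repl <- sample(setdiff(pools[[j]], g),
                       min(length(hit), pool_sizes[j] - k))
        g[hit[seq_along(repl)]] <- repl
      }
      g
    })
  }

  greedy_chrom <- lapply(pools, function(p) p[seq_len(k)])
  with_seed(config$seed, {
    pop <- c(list(greedy_chrom),
             replicate(config$population_size - 1L, random_chrom(),
                       simplify = FALSE))
    best <- NULL
    best_fit <- -Inf
    history <- numeric(0)
    stagnant <- 0L
    gens_run <- 0L
    for (gen in seq_len(config$generations)) {
      gens_run <- gen
      fits <- vapply(pop, evaluate, 1)
      imp <- max(fits) > best_fit
      if (imp) {
        best_fit <- max(fits)
        best <- pop[[which.max(fits)]]
        stagnant <- 0L
      } else stagnant <- stagnant + 1L
      history <- c(history, best_fit)
      if (stagnant >= config$stagnation_patience) break
      if (gen == config$generations) break
      nxt <- list(best)  # elitism
      while (length(nxt) < config$population_size) {
        p1 <- pop[[tournament(fits)]]
        p2 <- pop[[tournament(fits)]]
        child <- if (stats::runif(1) < config$crossover_rate)
          crossover(p1, p2) else p1
        nxt[[length(nxt) + 1L]] <- mutate(child)
      }
      pop <- nxt
    }
    snp_panel(stats::setNames(best, classes),
              dedupe = config$dedupe_assembled,
              provenance = list(seed = config$seed, k = k,
                                generations_run = gens_run,
                                best_fitness = best_fit, history = history,
                                n_evaluations = n_eval,
                                fitness_classifier = config$fitness_classifier,
                                pool_sizes = as.list(pool_sizes)))
  })
}

#' Panel-size sweep: smallest panel reaching the fitness plateau
#'
#' Runs the GA at each panel size in `k_grid` and selects the smallest `k`
#' whose best fitness comes within `epsilon` of the best fitness seen
#' anywhere on the grid — the "minimum number of markers sufficient"
#' reading of the size-vs-score curve.
#'
#' @inheritParams run_ga
#' @param k_grid ascending vector of per-class panel sizes.
#' @param epsilon plateau tolerance on the minimum per-class F1
#'   (default 0.005).
#' @return a `panel_sweep`: list with `table` (data.frame `k`,
#'   `best_min_f1`), `selected_k`, `epsilon` and `panels` (the best panel
#'   per grid point).
#' @export
sweep_panel_size <- function(gm, k_grid, config = ga_config(),
                             epsilon = 0.005, pools = NULL,
                             fitness_fn = NULL) {
  if (length(k_grid) == 0) stop("k_grid must be non-empty")
  if (is.unsorted(k_grid, strictly = TRUE))
    stop("k_grid must be strictly ascending")
  if (is.null(pools)) {
    dt <- compute_distinctiveness(gm)
    pools <- build_candidate_pool(dt, config$pool_size_per_class)
  }
  panels <- vector("list", length(k_grid))
  for (i in seq_along(k_grid)) {
    cfg_k <- config
    cfg_k$seed <- config$seed + as.integer(k_grid[i])
    panels[[i]] <- run_ga(gm, k_grid[i], cfg_k, pools = pools,
                          fitness_fn = fitness_fn)
  }
  fit <- vapply(panels, function(p) p$provenance$best_fitness, 1)
  tab <- data.frame(k = as.integer(k_grid), best_min_f1 = fit)
  selected <- tab$k[which(fit >= max(fit) - epsilon)[1]]
  structure(list(table = tab, selected_k = selected, epsilon = epsilon,
                 panels = stats::setNames(panels, paste0("k", k_grid))),
            class = "panel_sweep")
}

#' @export
print.panel_sweep <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("selected k:", x$selected_k, "(plateau tolerance", x$epsilon, ")\n")
  invisible(x)
}

#' Write / read a panel as JSON
#'
#' @param panel an `snp_panel`.
#' @param path JSON file path.
#' @export
write_panel_json <- function(panel, path) {
  jsonlite::write_json(
    list(k = panel$k, dedupe = panel$dedupe, per_class = panel$per_class,
         assembled = panel$assembled, provenance = panel$provenance),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_panel_json
#' @export
read_panel_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  snp_panel(as.list(x$per_class), dedupe = isTRUE(x$dedupe),
            provenance = as.list(x$provenance))
}

#' @rdname sweep_panel_size
#' @param sweep a `panel_sweep`.
#' @param tsv_path,json_path output paths (either may be `NULL`).
#' @export
write_sweep <- function(sweep, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(sweep$table, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(table = sweep$table,
                              selected_k = sweep$selected_k,
                              epsilon = sweep$epsilon),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(sweep)
}
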