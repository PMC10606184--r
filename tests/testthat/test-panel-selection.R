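test_that("distinctiveness scores match hand-derived values on edge features", {
  # class A: rows 1-4, B: 5-7, C: 8-9, D: 10-12
  y <- rep(c("A", "B", "C", "D"), c(4, 3, 2, 3))
  X <- cbind(private_A = as.integer(y == "A"),
             universal = 1L,
             absentish = c(1L, rep(0L, 11)))
  colnames(X) <- NULL
  gm <- make_gm(X, labels = y)
  dt <- compute_distinctiveness(gm)
  k1 <- gm$features$key[1]
  expect_equal(dt$rates[k1, ], c(A = 1, B = 0, C = 0, D = 0))
  expect_equal(dt$scores[k1, ], c(A = 1, B = -1, C = -1, D = -1))
  expect_equal(unname(dt$scores[gm$features$key[2], ]), rep(0, 4))
  expect_equal(unname(dt$cohort_count), c(4L, 12L, 1L))
})

test_that("distinctiveness agrees with a brute-force recount on a random fixture", {
  set.seed(19)
  y <- rep(c("A", "B", "C", "D"), c(4, 3, 2, 3))
  gm <- make_gm(matrix(rbinom(12 * 15, 1, 0.4), 12, 15), labels = y)
  dt <- compute_distinctiveness(gm)
  for (j in seq_len(ncol(gm$values))) {
    key <- colnames(gm$values)[j]
    # independent loop-based recount
    for (cl in unique(y)) {
      carriers <- 0; total <- 0
      for (i in seq_len(nrow(gm$values))) {
        if (gm$labels[i] == cl) {
          total <- total + 1
          if (gm$values[i, j] == 1) carriers <- carriers + 1
        }
      }
      expect_equal(dt$rates[key, cl], carriers / total)
      others <- setdiff(unique(y), cl)
      other_rates <- sapply(others, function(o)
        mean(gm$values[gm$labels == o, j]))
      expect_equal(dt$scores[key, cl], dt$rates[key, cl] - max(other_rates))
    }
    expect_equal(dt$cohort_count[[key]], sum(gm$values[, j]))
  }
  # integer identity: cohort count = sum over classes of rate * class size
  sizes <- dt$class_sizes
  recon <- as.integer(round(dt$rates %*% sizes))
  expect_equal(unname(dt$cohort_count), recon)
})

test_that("candidate pools rank by score with canonical tie-break", {
  y <- rep(c("A", "B"), c(3, 3))
  # two features with identical score for A; the canonically smaller key
  # (position 1010 < 1020) must rank first
  X <- cbind(rep(c(1L, 0L), c(3, 3)), rep(c(1L, 0L), c(3, 3)),
             c(0L, 0L, 0L, 1L, 1L, 1L))
  gm <- make_gm(X, labels = y)
  dt <- compute_distinctiveness(gm)
  pool <- build_candidate_pool(dt, 2L)
  expect_equal(pool$A, c("1:1010 A/G|HET", "1:1020 A/G|HET"))
  full <- build_candidate_pool(dt, 3L)
  expect_equal(full$A[3], "1:1030 A/G|HET")
  # score-sorted full list when pool covers everything
  expect_equal(full$B[1], "1:1030 A/G|HET")
  expect_error(build_candidate_pool(dt, 10L), "exceeds")
})

test_that("planted AIMs dominate their class pools on a synthetic cohort", {
  cfg <- cohort_config(n_per_class = c(A = 60L, B = 50L, C = 40L, D = 50L),
                       n_background_sites = 400L, n_aims_per_class = 5L,
                       background_fst = 0.01, aim_delta = 0.6, seed = 37L)
  geno <- simulate_cohort(cfg)
  gm <- cohort_matrix(geno, mode = "presence")
  pools <- build_candidate_pool(compute_distinctiveness(gm), 50L)
  for (cl in names(pools)) {
    pool_sites <- unique(sub("\\|.*$", "", pools[[cl]]))
    expect_true(all(geno$truth$aim_site_ids[[cl]] %in% pool_sites),
                label = paste("class", cl))
  }
})

test_that("panel fitness is 1 on separable panels and 0 on empty columns", {
  gm <- separable_gm(c(A = 9L, B = 9L, C = 9L, D = 9L))
  cfg <- ga_config(inner_cv_folds = 3L, seed = 2L)
  expect_equal(panel_fitness(snp_panel(lapply(list(A = 1, B = 2, C = 3, D = 4),
                                              function(i) colnames(gm$values)[i])),
                             gm, cfg), 1.0)
  # constant-zero features carry no signal: minority classes get F1 = 0
  zero <- genotype_matrix(matrix(0L, 24, 4),
                          feature_key(rep("1", 4), 1:4 * 10L, rep("A", 4),
                                      rep("G", 4), rep("HET", 4)),
                          sprintf("s%02d", 1:24),
                          labels = stats::setNames(
                            rep(c("A", "B", "C", "D"), c(12, 4, 4, 4)),
                            sprintf("s%02d", 1:24)))
  expect_equal(panel_fitness(list(A = colnames(zero$values)[1:2],
                                  B = colnames(zero$values)[3:4]),
                             zero, cfg), 0)
})

test_that("panel fitness equals an independent CV + F1 re-implementation", {
  set.seed(41)
  y <- factor(rep(c("A", "B", "C", "D"), 10))
  X <- matrix(rbinom(40 * 8, 1, 0.35), 40, 8)
  X[, 1] <- X[, 1] | (y == "A")  # some signal
  X[, 2] <- X[, 2] | (y == "B")
  gm <- make_gm(X * 1L, labels = as.character(y))
  cfg <- ga_config(inner_cv_folds = 3L, seed = 77L)
  panel <- list(A = colnames(gm$values)[1:2], B = colnames(gm$values)[3:4],
                C = colnames(gm$values)[5:6], D = colnames(gm$values)[7:8])
  got <- panel_fitness(panel, gm, cfg)
  splits <- aimpanel:::make_splits(factor(gm$labels),
                                  cv_config(n_splits = 3L, seed = 77L))
  keys <- unlist(panel, use.names = FALSE)
  oracle <- oracle_min_f1_fitness(gm$values[, keys], factor(gm$labels), splits)
  expect_equal(got, oracle)
})

test_that("the GA is seed-deterministic and degenerates correctly at k = pool size", {
  fx <- frozen_fitness_fixture()
  cfg <- ga_config(pool_size_per_class = 12L, population_size = 10L,
                   generations = 5L, stagnation_patience = 3L, seed = 4L)
  p1 <- run_ga(NULL, 3L, cfg, pools = fx$pools, fitness_fn = fx$fitness)
  p2 <- run_ga(NULL, 3L, cfg, pools = fx$pools, fitness_fn = fx$fitness)
  expect_identical(p1$per_class, p2$per_class)
  expect_identical(p1$provenance$history, p2$provenance$history)

  # k equal to the pool size leaves a single possible chromosome
  pfull <- run_ga(NULL, 12L, cfg, pools = fx$pools, fitness_fn = fx$fitness)
  for (cl in names(fx$pools))
    expect_setequal(pfull$per_class[[cl]], fx$pools[[cl]])
  expect_error(run_ga(NULL, 13L, cfg, pools = fx$pools,
                      fitness_fn = fx$fitness), "exceeds pool")
})

test_that("GA best fitness never beats exhaustive search and beats random search", {
  fx <- frozen_fitness_fixture(seed = 321)
  cfg <- ga_config(pool_size_per_class = 12L, population_size = 30L,
                   generations = 40L, stagnation_patience = 40L, seed = 6L)
  p <- run_ga(NULL, 3L, cfg, pools = fx$pools, fitness_fn = fx$fitness)
  expect_lte(p$provenance$best_fitness, fx$exhaustive_best + 1e-12)
  expect_true(all(diff(p$provenance$history) >= 0))  # elitism monotonicity

  # random search with the same evaluation budget
  set.seed(6)
  n_draws <- cfg$population_size * cfg$generations
  rand_best <- max(replicate(n_draws, fx$fitness(
    lapply(fx$pools, function(pool) sample(pool, 3L)))))
  expect_gte(p$provenance$best_fitness, rand_best)
})

test_that("panel assembly keeps per-class blocks and honours deduplication", {
  keys <- sprintf("1:%d A/G|HET", seq(100, 140, by = 10))
  pan <- snp_panel(list(A = keys[1:3], B = keys[c(1, 4, 5)]))
  expect_equal(pan$k, 3L)
  expect_length(pan$assembled, 6L)           # duplicates kept by default
  pan2 <- snp_panel(list(A = keys[1:3], B = keys[c(1, 4, 5)]), dedupe = TRUE)
  expect_length(pan2$assembled, 5L)
  expect_error(snp_panel(list(A = keys[1:2], B = keys[1:3])), "share one size")
  # JSON round-trip
  path <- tempfile(fileext = ".json")
  write_panel_json(pan, path)
  back <- read_panel_json(path)
  expect_equal(back$per_class, pan$per_class)
  expect_equal(back$assembled, pan$assembled)
})

test_that("panel-size sweep selects the plateau edge", {
  fx <- frozen_fitness_fixture(seed = 99)
  cfg <- ga_config(pool_size_per_class = 12L, population_size = 8L,
                   generations = 4L, stagnation_patience = 2L, seed = 8L)
  # single-point grid
  sw1 <- sweep_panel_size(NULL, 2L, cfg, pools = fx$pools,
                          fitness_fn = fx$fitness)
  expect_equal(sw1$selected_k, 2L)
  # strictly improving synthetic fitness selects the last grid point
  size_fitness <- function(per_class) sum(lengths(per_class)) / 100
  sw2 <- sweep_panel_size(NULL, c(1L, 3L, 6L), cfg, pools = fx$pools,
                          fitness_fn = size_fitness)
  expect_equal(sw2$selected_k, 6L)
  expect_equal(sw2$table$best_min_f1, c(0.04, 0.12, 0.24))
  expect_error(sweep_panel_size(NULL, integer(0), cfg, pools = fx$pools,
                                fitness_fn = fx$fitness), "non-empty")
  expect_error(sweep_panel_size(NULL, c(3L, 1L), cfg, pools = fx$pools,
                                fitness_fn = fx$fitness), "ascending")
  # sweep artifacts write out
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_sweep(sw2, tsv, js)
  expect_equal(utils::read.table(tsv, header = TRUE)$k, c(1L, 3L, 6L))
  expect_equal(jsonlite::read_json(js)$selected_k, 6L)
})
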