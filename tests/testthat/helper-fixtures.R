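# Fixtures are built in code at test time.

write_vcf_fixture <- function(lines, path = tempfile(fileext = ".vcf"),
                              sample = "S1") {
  header <- c("##fileformat=VCFv4.2", "##contig=<ID=1>",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT",
                    sample, sep = "\t"))
  writeLines(c(header, lines), path)
  path
}

# genotype_matrix from a plain 0/1 matrix; feature keys are generated SNPs
make_gm <- function(values, labels = NULL, gstate = "HET") {
  n <- ncol(values)
  fk <- feature_key(rep("1", n), 1000L + 10L * seq_len(n),
                    rep("A", n), rep("G", n), rep(gstate, n))
  ids <- sprintf("s%02d", seq_len(nrow(values)))
  if (!is.null(labels)) labels <- stats::setNames(labels, ids)
  genotype_matrix(values, fk, ids, labels = labels)
}

# toy cohort that is perfectly separable: one private indicator per class
separable_gm <- function(n_per_class = c(A = 8L, B = 6L, C = 5L, D = 7L)) {
  y <- rep(names(n_per_class), n_per_class)
  X <- sapply(names(n_per_class), function(cl) as.integer(y == cl))
  make_gm(X, labels = y)
}

# frozen separable GA fitness fixture: 12-feature pool per class with fixed
# weights; fitness = min over classes of the mean weight of the subset.
# The global optimum is exactly enumerable per class (all C(12,3) subsets).
frozen_fitness_fixture <- function(seed = 123, pool_size = 12, k = 3) {
  set.seed(seed)
  classes <- c("A", "B", "C", "D")
  pools <- lapply(stats::setNames(classes, classes), function(cl)
    sprintf("1:%d A/G|HET", sample(1000:9999, pool_size)))
  w <- lapply(stats::setNames(classes, classes), function(cl)
    stats::setNames(stats::runif(pool_size), pools[[cl]]))
  fitness <- function(per_class)
    min(vapply(names(per_class),
               function(cl) mean(w[[cl]][per_class[[cl]]]), 1))
  # exhaustive optimum by full per-class enumeration
  exhaustive <- min(vapply(classes, function(cl) {
    subs <- utils::combn(pool_size, k)
    max(apply(subs, 2, function(ix) mean(w[[cl]][ix])))
  }, 1))
  list(pools = pools, weights = w, fitness = fitness,
       exhaustive_best = exhaustive, k = k)
}

aim_recovery <- function(panel, truth_sites) {
  sel_sites <- lapply(panel$per_class, function(k) unique(sub("\\|.*$", "", k)))
  rec <- mapply(function(tr, sel) sum(tr %in% sel),
                truth_sites, sel_sites[names(truth_sites)])
  100 * sum(rec) / sum(lengths(truth_sites))
}
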