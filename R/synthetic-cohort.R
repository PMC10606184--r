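#' Configure a synthetic ancestry cohort
#'
#' Defines a cohort of weakly differentiated populations with a small number
#' of planted ancestry-informative markers (AIMs) per population. Background
#' sites follow the Balding-Nichols model: an ancestral allele frequency `p`
#' is drawn uniformly from `ancestral_freq_range` and each population's
#' frequency is Beta-distributed with mean `p` and variance
#' `p(1-p) * background_fst` (shape parameters `p(1-F)/F` and
#' `(1-p)(1-F)/F`). Planted AIMs instead guarantee that the target
#' population's allele frequency exceeds every other population's by at least
#' `aim_delta`. Genotypes are drawn per sample as Binomial(2, p) under
#' Hardy-Weinberg equilibrium.
#'
#' The default class sizes mirror the cohort structure this pipeline is
#' designed around: 127 Poles, 28 Russians (after exclusion of one
#' low-quality sample), 20 Serbs and 503 non-Slavic European samples,
#' 678 in total.
#'
#' @param n_per_class named integer vector, population label -> sample count.
#' @param n_background_sites number of neutral biallelic sites.
#' @param n_aims_per_class number of planted AIMs per population.
#' @param background_fst differentiation parameter in (0,1) for background
#'   sites; values below 1e-12 are treated as the zero-divergence limit
#'   (per-population frequencies copied from the ancestral frequency).
#' @param aim_delta minimum allele-frequency differential of a planted AIM
#'   between its target population and every other population, in (0,1].
#' @param ancestral_freq_range bounds for ancestral allele frequencies.
#' @param seed RNG seed; all draws are deterministic given config + seed.
#' @param contig_name,position_start,position_step coordinate layout of the
#'   emitted variant records.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_per_class = c(Poles = 127L, Russians = 28L,
                                          Serbs = 20L, NonSlavs = 503L),
                          n_background_sites = 5000L,
                          n_aims_per_class = 10L,
                          background_fst = 0.005,
                          aim_delta = 0.6,
                          ancestral_freq_range = c(0.05, 0.95),
                          seed = 1L,
                          contig_name = "1",
                          position_start = 10000L,
                          position_step = 100L) {
  if (is.null(names(n_per_class)) || any(names(n_per_class) == ""))
    stop("n_per_class must be a named vector of class sizes")
  if (any(n_per_class < 1) || n_background_sites < 1 || n_aims_per_class < 1)
    stop("all counts must be >= 1")
  if (background_fst <= 0 || background_fst >= 1)
    stop("background_fst must lie in (0,1)")
  if (aim_delta <= 0 || aim_delta > 1)
    stop("aim_delta must lie in (0,1]")
  r <- ancestral_freq_range
  if (length(r) != 2 || r[1] >= r[2] || r[1] <= 0 || r[2] >= 1)
    stop("ancestral_freq_range must be ordered bounds inside (0,1)")
  structure(list(n_per_class = vapply(n_per_class, as.integer, 1L),
                 n_background_sites = as.integer(n_background_sites),
                 n_aims_per_class = as.integer(n_aims_per_class),
                 background_fst = background_fst, aim_delta = aim_delta,
                 ancestral_freq_range = as.numeric(r), seed = as.integer(seed),
                 contig_name = as.character(contig_name),
                 position_start = as.integer(position_start),
                 position_step = as.integer(position_step)),
            class = "cohort_config")
}

# run expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw per-population allele frequencies and the planted-marker truth
#'
#' Background sites get Balding-Nichols frequencies around a uniform
#' ancestral frequency; each planted AIM of population `c` gets a target
#' frequency drawn from the upper feasible range and other-population
#' frequencies at least `aim_delta` below it. Fails (naming the site) when
#' `aim_delta` exceeds the width of `ancestral_freq_range`, rather than
#' silently relaxing the differential.
#'
#' @param config a [cohort_config()].
#' @return list with `sites` (data.frame: site_id, chrom, pos, ref, alt,
#'   type = background/aim, aim_class), `freqs` (sites x populations allele
#'   frequency matrix) and `truth` (list: `aim_site_ids` per class,
#'   `per_pop_allele_freqs`).
#' @export
draw_population_frequencies <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  classes <- names(config$n_per_class)
  K <- length(classes)
  nb <- config$n_background_sites
  na <- config$n_aims_per_class
  n_sites <- nb + na * K
  lo <- config$ancestral_freq_range[1]
  hi <- config$ancestral_freq_range[2]
  F <- config$background_fst
  delta <- config$aim_delta

  with_seed(config$seed, {
    pos <- config$position_start +
      (seq_len(n_sites) - 1L) * config$position_step
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    type <- c(rep("background", nb), rep("aim", na * K))
    aim_class <- c(rep(NA_character_, nb), rep(classes, each = na))
    site_id <- paste0(config$contig_name, ":", pos, " ", ref, "/", alt)
    sites <- data.frame(site_id = site_id, chrom = config$contig_name,
                        pos = pos, ref = ref, alt = alt, type = type,
                        aim_class = aim_class, stringsAsFactors = FALSE)

    freqs <- matrix(NA_real_, n_sites, K, dimnames = list(site_id, classes))
    p_anc <- stats::runif(nb, lo, hi)
    if (F < 1e-12) {
      freqs[seq_len(nb), ] <- p_anc
    } else {
      for (j in seq_len(K))
        freqs[seq_len(nb), j] <- stats::rbeta(nb, p_anc * (1 - F) / F,
                                              (1 - p_anc) * (1 - F) / F)
    }
    for (i in which(type == "aim")) {
      cls <- aim_class[i]
      if (delta > hi - lo)
        stop("AIM site ", site_id[i], " for class ", cls,
             ": aim_delta = ", delta,
             " is infeasible within ancestral_freq_range [", lo, ", ", hi, "]")
      q <- stats::runif(1, lo + delta, hi)
      others <- stats::runif(K - 1, lo, q - delta)
      freqs[i, ] <- ifelse(classes == cls, q,
                           others[cumsum(classes != cls)])
    }
    truth <- list(
      aim_site_ids = split(site_id[type == "aim"],
                           factor(aim_class[type == "aim"], levels = classes)),
      per_pop_allele_freqs = freqs)
    list(sites = sites, freqs = freqs, truth = truth)
  })
}

#' Simulate Hardy-Weinberg genotypes for a cohort
#'
#' Each sample's alternate-allele dose at each site is Binomial(2, p) for its
#' population's allele frequency p, i.e. genotypes hom-ref / het / hom-alt in
#' HWE proportions.
#'
#' @param pop output of [draw_population_frequencies()].
#' @param config the same [cohort_config()].
#' @return list with `dose` (samples x sites integer matrix of 0/1/2,
#'   rownames = sample ids), `labels` (named population vector), `sites` and
#'   `truth` carried through.
#' @export
simulate_genotypes <- function(pop, config) {
  stopifnot(inherits(config, "cohort_config"))
  classes <- names(config$n_per_class)
  if (!identical(colnames(pop$freqs), classes))
    stop("frequency table does not cover the configured populations")
  n_sites <- nrow(pop$freqs)
  ids <- unlist(lapply(classes, function(cl)
    sprintf("%s_%03d", cl, seq_len(config$n_per_class[[cl]]))))
  labels <- stats::setNames(rep(classes, config$n_per_class), ids)
  with_seed(config$seed + 1L, {
    dose <- matrix(0L, length(ids), n_sites,
                   dimnames = list(ids, rownames(pop$freqs)))
    for (cl in classes) {
      rows <- which(labels == cl)
      n <- length(rows)
      dose[rows, ] <- matrix(
        stats::rbinom(n * n_sites, 2L, rep(pop$freqs[, cl], each = n)),
        n, n_sites)
    }
    list(dose = dose, labels = labels, sites = pop$sites, truth = pop$truth)
  })
}

#' Convert simulated genotypes directly to a binary genotype matrix
#'
#' In-memory equivalent of writing per-sample VCFs and re-encoding them:
#' every (site, genotype-state) combination carried by at least one sample
#' becomes a feature column.
#'
#' @param geno output of [simulate_genotypes()].
#' @param mode `"genotype"` or `"presence"`, as in [parse_vcf()].
#' @return a labeled [genotype_matrix()].
#' @export
cohort_matrix <- function(geno, mode = c("genotype", "presence")) {
  mode <- match.arg(mode)
  s <- geno$sites
  blocks <- if (mode == "presence")
    list(PRESENT = geno$dose >= 1L)
  else
    list(HET = geno$dose == 1L, HOM_ALT = geno$dose == 2L)
  vals <- NULL
  fk <- NULL
  for (st in names(blocks)) {
    m <- blocks[[st]]
    keep <- which(colSums(m) > 0)
    if (length(keep) == 0) next
    vals <- cbind(vals, m[, keep, drop = FALSE] * 1L)
    fk <- rbind(fk, feature_key(s$chrom[keep], s$pos[keep], s$ref[keep],
                                s$alt[keep], rep(st, length(keep))))
  }
  if (is.null(vals))
    stop("cohort has no non-reference genotypes")
  genotype_matrix(vals, fk, rownames(geno$dose), labels = geno$labels)
}

#' Write a simulated cohort as VCF files, labels TSV and truth JSON
#'
#' Default output is one VCF per sample listing ONLY that sample's
#' non-reference genotypes (matching real per-sample variant-call VCFs,
#' where an absent record implies the reference genotype); a single
#' multi-sample VCF carrying explicit `0/0` calls is available via
#' `multi_sample = TRUE`.
#'
#' @param geno output of [simulate_genotypes()].
#' @param config the [cohort_config()] used (stored alongside the truth).
#' @param out_dir output directory (created if needed).
#' @param multi_sample write one joint VCF instead of per-sample files.
#' @return invisibly, a list of written paths (`vcf_dir`/`vcf`, `labels`,
#'   `truth`).
#' @export
write_cohort_vcfs <- function(geno, config, out_dir, multi_sample = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  s <- geno$sites
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", config$contig_name, ">"),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  col_line <- "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT"
  gt_str <- c("0/0", "0/1", "1/1")
  ids <- rownames(geno$dose)

  if (multi_sample) {
    vcf_path <- file.path(out_dir, "cohort.vcf")
    any_alt <- which(colSums(geno$dose) > 0)
    gts <- apply(geno$dose[, any_alt, drop = FALSE] + 1L, 2,
                 function(d) paste(gt_str[d], collapse = "\t"))
    lines <- paste(s$chrom[any_alt], s$pos[any_alt], ".", s$ref[any_alt],
                   s$alt[any_alt], ".", ".", ".", "GT", gts, sep = "\t")
    writeLines(c(header, paste(c(col_line, ids), collapse = "\t"), lines),
               vcf_path)
    paths <- list(vcf = vcf_path)
  } else {
    vcf_dir <- file.path(out_dir, "vcf")
    dir.create(vcf_dir, showWarnings = FALSE)
    for (i in seq_along(ids)) {
      carried <- which(geno$dose[i, ] > 0)
      lines <- if (length(carried) > 0)
        paste(s$chrom[carried], s$pos[carried], ".", s$ref[carried],
              s$alt[carried], ".", ".", ".", "GT",
              gt_str[geno$dose[i, carried] + 1L], sep = "\t")
      else character(0)
      writeLines(c(header, paste(col_line, ids[i], sep = "\t"), lines),
                 file.path(vcf_dir, paste0(ids[i], ".vcf")))
    }
    paths <- list(vcf_dir = vcf_dir)
  }

  labels_path <- file.path(out_dir, "labels.tsv")
  write_labels_tsv(geno$labels, labels_path)
  truth_path <- file.path(out_dir, "truth.json")
  truth <- list(
    config = unclass(config),
    aim_site_ids = geno$truth$aim_site_ids,
    per_pop_allele_freqs = as.data.frame(geno$truth$per_pop_allele_freqs))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, list(labels = labels_path, truth = truth_path)))
}

#' Simulate a full cohort in one call
#'
#' Runs [draw_population_frequencies()] and [simulate_genotypes()]; if
#' `out_dir` is given, also writes the VCF/labels/truth artifacts.
#'
#' @inheritParams write_cohort_vcfs
#' @param config a [cohort_config()].
#' @param out_dir optional output directory.
#' @return the [simulate_genotypes()] result (with `paths` appended when
#'   files were written).
#' @export
simulate_cohort <- function(config, out_dir = NULL, multi_sample = FALSE) {
  pop <- draw_population_frequencies(config)
  geno <- simulate_genotypes(pop, config)
  if (!is.null(out_dir))
    geno$paths <- write_cohort_vcfs(geno, config, out_dir,
                                    multi_sample = multi_sample)
  geno
}

#' Estimate FST from a per-population allele-frequency table
#'
#' Variance-of-frequencies estimator: the across-site ratio of the mean
#' between-population variance of allele frequencies to the mean
#' `p_bar (1 - p_bar)`. Under the Balding-Nichols model its expectation is
#' the generating FST.
#'
#' @param freqs sites x populations allele-frequency matrix.
#' @return scalar FST estimate.
#' @export
estimate_fst <- function(freqs) {
  pbar <- rowMeans(freqs)
  v <- apply(freqs, 1, stats::var)
  mean(v) / mean(pbar * (1 - pbar))
}
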