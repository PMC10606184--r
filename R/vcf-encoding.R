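#' Parse a VCF file into per-sample feature calls
#'
#' Reads a VCF (v4.x, plain or bgzipped) and resolves every (record, alternate
#' allele, sample) combination into a binary feature call. Multiallelic
#' records are split into one feature per alternate allele, with the sample's
#' genotype resolved against that allele: one copy gives state `HET`, two
#' copies `HOM_ALT`. A genotype of `0/0` emits nothing (the reference genotype
#' is absence) and fully missing genotypes (`./.`) are skipped. In presence
#' mode any non-zero dose collapses to a single `PRESENT` state per allele.
#'
#' @param path VCF file.
#' @param mode `"genotype"` (default; HET / HOM_ALT states) or `"presence"`.
#' @param snps_only drop records whose REF or ALT allele is not a single
#'   A/C/G/T base (indels, multi-base substitutions).
#' @param pass_only keep only records whose FILTER is `PASS` or `.`
#'   (unfiltered); by default FILTER is ignored.
#' @return named list, one element per sample column in the file, each a
#'   feature data.frame (see [feature_key()]) of the features that sample
#'   carries.
#' @export
parse_vcf <- function(path, mode = c("genotype", "presence"),
                      snps_only = FALSE, pass_only = FALSE) {
  mode <- match.arg(mode)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  empty <- feature_key(character(0), integer(0), character(0), character(0),
                       character(0))
  if (ncol(gt) < 2)
    stop("no sample genotype columns in ", path)
  samples <- colnames(gt)[-1]
  if (nrow(fix) == 0)
    return(stats::setNames(rep(list(empty), length(samples)), samples))

  fmt <- gt[, "FORMAT"]
  gt_idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) match("GT", f), 1L)
  if (anyNA(gt_idx)) {
    bad <- which(is.na(gt_idx))[1]
    stop("record ", fix[bad, "CHROM"], ":", fix[bad, "POS"], " in ", path,
         " has no GT field in FORMAT")
  }
  keep <- rep(TRUE, nrow(fix))
  if (pass_only)
    keep <- keep & (is.na(fix[, "FILTER"]) | fix[, "FILTER"] %in% c("PASS", "."))
  alts_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)

  out <- lapply(samples, function(s) {
    calls <- gt[, s]
    chroms <- poss <- refs <- altv <- states <- vector("list", nrow(fix))
    for (i in which(keep)) {
      gstr <- strsplit(calls[i], ":", fixed = TRUE)[[1]][gt_idx[i]]
      if (is.na(gstr)) next
      alleles <- strsplit(gstr, "[/|]")[[1]]
      alleles <- alleles[alleles != "."]
      if (length(alleles) == 0) next
      idx <- suppressWarnings(as.integer(alleles))
      if (anyNA(idx))
        stop("malformed genotype '", gstr, "' at record ", fix[i, "CHROM"],
             ":", fix[i, "POS"], " in ", path)
      alts <- alts_list[[i]]
      ref <- fix[i, "REF"]
      for (a in seq_along(alts)) {
        if (snps_only && !(nchar(ref) == 1 && nchar(alts[a]) == 1 &&
                           ref %in% c("A", "C", "G", "T") &&
                           alts[a] %in% c("A", "C", "G", "T"))) next
        dose <- sum(idx == a)
        if (dose == 0) next
        st <- if (mode == "presence") "PRESENT"
              else if (dose >= 2) "HOM_ALT" else "HET"
        chroms[[i]] <- c(chroms[[i]], fix[i, "CHROM"])
        poss[[i]] <- c(poss[[i]], as.integer(fix[i, "POS"]))
        refs[[i]] <- c(refs[[i]], ref)
        altv[[i]] <- c(altv[[i]], alts[a])
        states[[i]] <- c(states[[i]], st)
      }
    }
    feature_key(unlist(chroms), unlist(poss), unlist(refs), unlist(altv),
                unlist(states))
  })
  stats::setNames(out, samples)
}

#' Assemble per-sample calls into a binary genotype matrix
#'
#' The feature set is the union of feature keys over all samples, in
#' canonical order; a cell is 1 iff that sample carries that feature.
#' Samples lacking a record at a feature's site get 0 (assumed homozygous
#' reference). The result is therefore invariant under the order in which
#' sample files were read.
#'
#' @param calls named list sample id -> feature data.frame, as produced by
#'   [parse_vcf()] (concatenate lists to pool files).
#' @param labels optional sample -> population labels (vector or data.frame,
#'   see [set_labels()]); when given, every sample must be labeled.
#' @return a [genotype_matrix()].
#' @export
build_matrix <- function(calls, labels = NULL) {
  if (length(calls) == 0) stop("no samples to encode")
  ids <- names(calls)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sample IDs must be present and unique")
  all_fk <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
  fk <- sort_features(all_fk[!duplicated(all_fk$key), , drop = FALSE])
  vals <- matrix(0L, nrow = length(ids), ncol = nrow(fk))
  for (i in seq_along(ids)) {
    hit <- match(unique(calls[[i]]$key), fk$key)
    vals[i, hit] <- 1L
  }
  genotype_matrix(vals, fk, ids, labels = labels)
}

#' Encode a directory of VCF files into a genotype matrix
#'
#' Convenience wrapper: parses every `*.vcf` / `*.vcf.gz` under `vcf_dir`
#' (each may hold one or several samples) and builds the binary matrix.
#'
#' @inheritParams parse_vcf
#' @param vcf_dir directory of VCF files.
#' @param labels optional labels TSV path, or a named vector / data.frame.
#' @param exclude character vector of sample IDs to drop (e.g. known
#'   low-quality samples), applied before matrix construction.
#' @return a [genotype_matrix()].
#' @export
encode_vcf_dir <- function(vcf_dir, labels = NULL,
                           mode = c("genotype", "presence"),
                           snps_only = FALSE, pass_only = FALSE,
                           exclude = NULL) {
  mode <- match.arg(mode)
  files <- list.files(vcf_dir, pattern = "\\.vcf(\\.gz)?$", full.names = TRUE)
  if (length(files) == 0) stop("no VCF files under ", vcf_dir)
  calls <- do.call(c, lapply(files, parse_vcf, mode = mode,
                             snps_only = snps_only, pass_only = pass_only))
  if (!is.null(exclude)) calls <- calls[setdiff(names(calls), exclude)]
  if (is.character(labels) && length(labels) == 1 && file.exists(labels))
    labels <- read_labels_tsv(labels)
  if (!is.null(labels) && !is.data.frame(labels) && !is.null(exclude))
    labels <- labels[setdiff(names(labels), exclude)]
  build_matrix(calls, labels = labels)
}
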