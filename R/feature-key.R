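#' Binary feature identities for (polymorphism, genotype) columns
#'
#' Each column of the binary genotype matrix is identified by a *feature key*:
#' the variant's coordinates and alleles plus a genotype-state tag. In
#' genotype mode the tag is `"HET"` or `"HOM_ALT"`, so a heterozygous and a
#' homozygous-alternate call at the same site occupy different columns; in
#' presence mode a single `"PRESENT"` tag records that the sample carries the
#' alternate allele in any dose.
#'
#' The canonical string rendering is `"chrom:pos ref/alt|gstate"`, e.g.
#' `"1:13302 C/T|HET"`. Keys are totally ordered by
#' (chrom, pos, ref, alt, gstate); this order fixes the column order of every
#' matrix the package produces, making it independent of input-file order.
#'
#' @param chrom character vector of contig names.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt character vectors of alleles (uppercase A/C/G/T/N strings;
#'   indels are multi-base strings).
#' @param gstate genotype-state tags, each one of `"HET"`, `"HOM_ALT"` or
#'   `"PRESENT"`.
#' @return `feature_key()` returns a data.frame with columns
#'   `chrom, pos, ref, alt, gstate, key` (one row per feature), rows in the
#'   order given.
#' @examples
#' feature_key("1", 13302L, "C", "T", "HET")$key
#' @export
feature_key <- function(chrom, pos, ref, alt, gstate) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  gstate <- as.character(gstate)
  n <- length(chrom)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n,
            length(gstate) == n)
  if (n > 0) {
    if (any(is.na(pos)) || any(pos < 1))
      stop("feature positions must be positive integers")
    if (any(!grepl("^[ACGTN]+$", ref)) || any(!grepl("^[ACGTN]+$", alt)))
      stop("alleles must be non-empty strings over A/C/G/T/N")
    bad <- !gstate %in% c("HET", "HOM_ALT", "PRESENT")
    if (any(bad))
      stop("unknown genotype state: ", paste(unique(gstate[bad]), collapse = ", "))
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gstate = gstate,
             key = render_feature_key(chrom, pos, ref, alt, gstate),
             stringsAsFactors = FALSE)
}

render_feature_key <- function(chrom, pos, ref, alt, gstate) {
  if (length(chrom) == 0) return(character(0))
  paste0(chrom, ":", pos, " ", ref, "/", alt, "|", gstate)
}

#' Parse canonical feature-key strings
#'
#' Inverse of the rendering used by [feature_key()]; used when reading matrix
#' TSV headers and panel files.
#'
#' @param keys character vector of canonical `"chrom:pos ref/alt|gstate"`
#'   strings.
#' @return a feature data.frame as from [feature_key()].
#' @export
parse_feature_key <- function(keys) {
  if (length(keys) == 0)
    return(feature_key(character(0), integer(0), character(0), character(0),
                       character(0)))
  m <- regmatches(keys, regexec("^(.+):([0-9]+) ([A-Z]+)/([A-Z]+)\\|([A-Z_]+)$",
                                keys))
  bad <- vapply(m, length, 1L) != 6L
  if (any(bad))
    stop("malformed feature key: ", keys[which(bad)[1]])
  feature_key(vapply(m, `[`, "", 2L), as.integer(vapply(m, `[`, "", 3L)),
              vapply(m, `[`, "", 4L), vapply(m, `[`, "", 5L),
              vapply(m, `[`, "", 6L))
}

# canonical (chrom, pos, ref, alt, gstate) order
order_features <- function(fk) {
  order(fk$chrom, fk$pos, fk$ref, fk$alt, fk$gstate, method = "radix")
}

sort_features <- function(fk) {
  fk <- fk[order_features(fk), , drop = FALSE]
  rownames(fk) <- NULL
  fk
}
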