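#' Binary samples x features genotype matrix
#'
#' The central container of the pipeline: a binary matrix with one row per
#' sample and one column per (polymorphism, genotype) feature. A cell is 1
#' when the sample carries that feature and 0 otherwise; a variant absent
#' from a sample's VCF is taken to be homozygous reference and contributes 0
#' (per-sample exome VCFs over a shared capture target list only non-reference
#' genotypes, so absence is informative).
#'
#' @param values integer/numeric matrix of 0/1, samples in rows.
#' @param features feature data.frame from [feature_key()], one row per
#'   column of `values`, already in canonical order or not (columns are
#'   re-sorted canonically).
#' @param sample_ids character vector of unique sample identifiers, length
#'   `nrow(values)`.
#' @param labels optional named character vector mapping every sample id to a
#'   population label.
#' @return an object of class `genotype_matrix`: a list with elements
#'   `values` (integer matrix, dimnames = sample ids x canonical keys),
#'   `features`, `sample_ids`, `labels`.
#' @export
genotype_matrix <- function(values, features, sample_ids, labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (nrow(features) != ncol(values))
    stop("feature table rows (", nrow(features),
         ") must match matrix columns (", ncol(values), ")")
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length must match matrix rows")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(features$key))
    stop("duplicate feature keys: ",
         paste(unique(features$key[duplicated(features$key)]), collapse = ", "))
  if (length(values) > 0 && !all(values %in% c(0L, 1L)))
    stop("genotype matrix values must be 0/1")
  ord <- order_features(features)
  features <- features[ord, , drop = FALSE]
  rownames(features) <- NULL
  values <- values[, ord, drop = FALSE]
  dimnames(values) <- list(sample_ids, features$key)
  gm <- structure(list(values = values, features = features,
                       sample_ids = as.character(sample_ids), labels = NULL),
                  class = "genotype_matrix")
  if (!is.null(labels)) gm <- set_labels(gm, labels)
  gm
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$values), " samples x ", ncol(x$values),
      " binary features\n", sep = "")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("labels: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Attach population labels to a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param labels named character vector (names = sample ids) or two-column
#'   data.frame `(sample_id, population)`. Every sample in `gm` must be
#'   labeled.
#' @return the matrix with `labels` set (ordered as `sample_ids`).
#' @export
set_labels <- function(gm, labels) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels[[2]]),
                              as.character(labels[[1]]))
  }
  missing <- setdiff(gm$sample_ids, names(labels))
  if (length(missing) > 0)
    stop("label table missing samples: ",
         paste(utils::head(missing, 5), collapse = ", "))
  gm$labels <- labels[gm$sample_ids]
  gm
}

#' Restrict a genotype matrix to a set of feature keys
#'
#' @param gm a [genotype_matrix()].
#' @param keys canonical feature-key strings; duplicates allowed (a panel may
#'   select the same feature for two classes), each occurrence becomes a
#'   column in the given order.
#' @return a plain integer matrix (samples x keys) ready for a classifier.
#' @export
subset_features <- function(gm, keys) {
  missing <- setdiff(unique(keys), colnames(gm$values))
  if (length(missing) > 0)
    stop("features not in matrix: ", paste(utils::head(missing, 5),
                                           collapse = ", "))
  gm$values[, keys, drop = FALSE]
}

#' Write / read a genotype matrix as TSV
#'
#' The dialect is a header row `sample_id` followed by canonical feature-key
#' strings, then one row per sample of 0/1 cells. Round-trips losslessly
#' (labels travel separately; see [read_labels_tsv()]).
#'
#' @param gm a [genotype_matrix()].
#' @param path output / input file path.
#' @return `read_matrix` returns a [genotype_matrix()] (unlabeled).
#' @export
write_matrix <- function(gm, path) {
  df <- as.data.frame(gm$values, check.names = FALSE)
  df <- cbind(sample_id = gm$sample_ids, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  if (colnames(df)[1] != "sample_id")
    stop("matrix TSV must start with a sample_id column: ", path)
  keys <- colnames(df)[-1]
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (length(vals) > 0 && !all(vals %in% c("0", "1")))
    stop("non-binary cell in matrix TSV: ", path)
  storage.mode(vals) <- "integer"
  genotype_matrix(vals, parse_feature_key(keys), df$sample_id)
}

#' Read a sample -> population label table
#'
#' @param path TSV with two columns `sample_id<TAB>population` and a header
#'   line.
#' @return named character vector of populations, names = sample ids.
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("labels TSV needs sample_id and population columns")
  stats::setNames(df[[2]], df[[1]])
}

#' @rdname read_labels_tsv
#' @param labels named character vector.
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), population = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
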