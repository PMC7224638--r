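#' Multimodal molecule-count matrix
#'
#' A `CountMatrix` holds UMI-corrected molecule counts for one experiment:
#' barcodes (rows) by features (columns), with every feature tagged by its
#' modality: `"rna"` (panel transcript), `"protein"` (AbSeq/ADT antibody),
#' or `"sample_tag"` (cell-hashing antibody). Counts are non-negative
#' integers. The matrix is stored sparse when fewer than half the entries
#' are non-zero; all operations are defined on the logical dense view.
#'
#' @param counts A numeric matrix (or `Matrix::Matrix`) of non-negative
#'   integers with unique row names (barcodes) and column names (features).
#' @param modality Character vector of length `ncol(counts)` giving the
#'   modality of each feature; values must be `"rna"`, `"protein"`, or
#'   `"sample_tag"`.
#' @return An object of class `CountMatrix`.
#' @examples
#' m <- matrix(c(3L, 1L, 0L, 5L), 2, 2,
#'             dimnames = list(c("AAAC", "AAAG"), c("CD3E", "CD4")))
#' cm <- count_matrix(m, c("rna", "rna"))
#' total_molecules(cm)
#' @export
count_matrix <- function(counts, modality) {
  dn <- dimnames(counts)
  counts <- as(counts, "CsparseMatrix")
  if (is.null(dimnames(counts)) && !is.null(dn)) dimnames(counts) <- dn
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must have barcode row names and feature column names")
  if (is.null(rownames(counts)))
    rownames(counts) <- character(0)
  if (is.null(colnames(counts)))
    colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate barcode identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))])[1:3],
               collapse = ", "))
  modality <- as.character(modality)
  if (length(modality) != ncol(counts))
    stop("modality must have one entry per feature")
  bad_mod <- setdiff(unique(modality), c("rna", "protein", "sample_tag"))
  if (length(bad_mod))
    stop("unknown modality: ", paste(bad_mod, collapse = ", "))
  for (m in unique(modality)) {
    f <- colnames(counts)[modality == m]
    if (anyDuplicated(f))
      stop("duplicate feature names within modality '", m, "'")
  }
  x <- counts@x
  if (any(x < 0))
    stop("negative counts are not allowed")
  if (any(x != round(x)))
    stop("counts must be integral molecule counts")
  # keep dense when density >= 0.5 (small matrices mostly)
  dens <- length(x) / max(1, prod(dim(counts)))
  stored <- if (dens >= 0.5) as.matrix(counts) else counts
  structure(list(counts = stored, modality = stats::setNames(modality, colnames(counts))),
            class = "CountMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
dimnames.CountMatrix <- function(x) dimnames(x$counts)

#' Barcodes, features and modalities of a CountMatrix
#' @param x A `CountMatrix`.
#' @return Character vector of barcode / feature names, or the named
#'   modality vector.
#' @export
barcodes <- function(x) rownames(x$counts)

#' @rdname barcodes
#' @export
features <- function(x) colnames(x$counts)

#' @rdname barcodes
#' @export
modalities <- function(x) x$modality

#' Dense count matrix view
#' @param x A `CountMatrix`.
#' @return A base integer matrix of counts (barcodes x features).
#' @export
count_values <- function(x) {
  m <- as.matrix(x$counts)
  storage.mode(m) <- "double"
  m
}

#' Total molecules in a CountMatrix
#' @param x A `CountMatrix`.
#' @return A single number, the grand total of all counts.
#' @export
total_molecules <- function(x) sum(x$counts)

#' @exportS3Method base::print
print.CountMatrix <- function(x, ...) {
  tab <- table(x$modality)
  cat(sprintf("CountMatrix: %d barcodes x %d features (%s); %.0f molecules\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "),
              sum(x$counts)))
  invisible(x)
}

#' Subset a CountMatrix by modality
#'
#' Returns a `CountMatrix` restricted to the features of one (or several)
#' modalities. Barcodes are preserved, so modality slices of the same
#' matrix always share a cell set.
#'
#' @param x A `CountMatrix`.
#' @param modality Character vector of modalities to keep.
#' @return A `CountMatrix` with the same barcodes.
#' @export
subset_modality <- function(x, modality) {
  keep <- x$modality %in% modality
  if (!any(keep))
    stop("no features with modality ", paste(modality, collapse = "/"))
  count_matrix(x$counts[, keep, drop = FALSE], x$modality[keep])
}

#' Subset a CountMatrix by barcodes and/or features
#' @param x A `CountMatrix`.
#' @param barcodes,features Character vectors (or indices) to keep; `NULL`
#'   keeps everything.
#' @return A `CountMatrix`.
#' @export
subset_counts <- function(x, barcodes = NULL, features = NULL) {
  m <- x$counts
  if (!is.null(barcodes)) {
    if (is.character(barcodes) && !all(barcodes %in% rownames(m)))
      stop("unknown barcodes requested")
    m <- m[barcodes %||% rownames(m), , drop = FALSE]
  }
  mod <- x$modality
  if (!is.null(features)) {
    if (is.character(features) && !all(features %in% colnames(m)))
      stop("unknown features requested")
    m <- m[, features, drop = FALSE]
    mod <- mod[colnames(m)]
  }
  count_matrix(m, mod[colnames(m)])
}

#' Column-bind two CountMatrix objects over the same barcodes
#' @param x,y `CountMatrix` objects with identical barcode sets (same order).
#' @return A `CountMatrix` containing the features of both.
#' @export
bind_features <- function(x, y) {
  if (!identical(rownames(x$counts), rownames(y$counts)))
    stop("barcode sets differ; cannot bind features")
  count_matrix(cbind(as(x$counts, "CsparseMatrix"), as(y$counts, "CsparseMatrix")),
               c(x$modality, y$modality))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
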