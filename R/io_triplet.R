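#' Read a sparse triplet (MatrixMarket-style) count matrix
#'
#' Whole-transcriptome matrices usually arrive as a MatrixMarket `.mtx`
#' triplet file plus two label files (one barcode / feature name per line).
#' Omitted entries are zero; triplet order is irrelevant.
#'
#' @param mtx Path to a MatrixMarket coordinate file, or a data.frame with
#'   columns row index, column index, count.
#' @param barcodes Character vector of row labels, or path to a one-per-line
#'   text file.
#' @param features Character vector of column labels, or a path.
#' @param modality_map Named character vector feature -> modality; missing
#'   features default to `"rna"`.
#' @param dims Integer vector `c(nrow, ncol)`; required when `mtx` is a
#'   data.frame, taken from the file header otherwise.
#' @return A [count_matrix()].
#' @export
read_triplet_matrix <- function(mtx, barcodes, features,
                                modality_map = NULL, dims = NULL) {
  if (is.character(barcodes) && length(barcodes) == 1L && file.exists(barcodes))
    barcodes <- readLines(barcodes)
  if (is.character(features) && length(features) == 1L && file.exists(features))
    features <- readLines(features)
  if (is.character(mtx)) {
    m <- as(Matrix::readMM(mtx), "CsparseMatrix")
  } else {
    tr <- as.data.frame(mtx)
    if (is.null(dims)) stop("dims = c(nrow, ncol) required for triplet data")
    if (nrow(tr) > 0 && (any(tr[[1L]] < 1) || any(tr[[1L]] > dims[1L]) ||
                         any(tr[[2L]] < 1) || any(tr[[2L]] > dims[2L])))
      stop("triplet index out of declared dimensions")
    m <- Matrix::sparseMatrix(i = tr[[1L]], j = tr[[2L]], x = tr[[3L]],
                              dims = dims)
  }
  if (nrow(m) != length(barcodes) || ncol(m) != length(features))
    stop(sprintf("label lengths (%d, %d) do not match matrix dims (%d, %d)",
                 length(barcodes), length(features), nrow(m), ncol(m)))
  dimnames(m) <- list(barcodes, features)
  modality <- rep("rna", length(features))
  if (!is.null(modality_map)) {
    hit <- features %in% names(modality_map)
    modality[hit] <- unname(modality_map[features[hit]])
  }
  count_matrix(m, modality)
}

#' Write a CountMatrix as MatrixMarket triplets plus label files
#'
#' @param x A `CountMatrix`.
#' @param mtx,barcodes,features Output paths for the coordinate file and
#'   the two label files.
#' @return `mtx`, invisibly.
#' @export
write_triplet_matrix <- function(x, mtx, barcodes, features) {
  Matrix::writeMM(as(as(x$counts, "CsparseMatrix"), "generalMatrix"), mtx)
  writeLines(rownames(x$counts), barcodes)
  writeLines(colnames(x$counts), features)
  invisible(mtx)
}
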