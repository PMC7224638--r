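#' Read a molecule-count table (Rhapsody-style CSV)
#'
#' Parses a comma-separated molecule-count table: one header row of feature
#' names, one row per barcode, first column the barcode identifier.
#' A leading comment block of lines starting with `#` (as written by the
#' vendor pipeline) is skipped. Cells must be non-negative integers
#' (UMI/DBEC-corrected molecule counts).
#'
#' @param path Path to the CSV file.
#' @param modality_map Named character vector mapping feature names to
#'   modalities (`"rna"`, `"protein"`, `"sample_tag"`). Features without an
#'   entry default to `"rna"` (a message is emitted).
#' @return A [count_matrix()].
#' @export
read_molecule_counts <- function(path, modality_map = NULL) {
  lines_head <- readLines(path, n = 200L)
  skip <- 0L
  while (skip < length(lines_head) && startsWith(lines_head[skip + 1L], "#"))
    skip <- skip + 1L
  dt <- data.table::fread(path, skip = skip, header = TRUE, sep = ",",
                          colClasses = list(character = 1L), data.table = FALSE,
                          encoding = "UTF-8")
  if (ncol(dt) < 2L) stop("count table needs a barcode column and >= 1 feature")
  bc <- dt[[1L]]
  if (anyDuplicated(bc))
    stop("duplicate barcode in count table: ", bc[duplicated(bc)][1L])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(dt[-1L], is.numeric, logical(1)))[1L]
    stop("non-numeric values in column '", colnames(dt)[bad + 1L], "'")
  }
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-integer or negative count at barcode '%s', feature '%s'",
                 bc[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  rownames(m) <- bc
  feats <- colnames(m)
  modality <- rep("rna", length(feats))
  if (!is.null(modality_map)) {
    hit <- feats %in% names(modality_map)
    modality[hit] <- unname(modality_map[feats[hit]])
    if (any(!hit))
      message(sum(!hit), " feature(s) missing from modality_map; defaulting to rna")
  } else {
    message("no modality_map supplied; all features treated as rna")
  }
  count_matrix(m, modality)
}

#' Write a molecule-count table as CSV
#'
#' Inverse of [read_molecule_counts()]: first column `Barcode`, one column
#' per feature. Set `modality_comment = TRUE` to prepend a `#`-comment line
#' recording each feature's modality (ignored by the reader's table parser
#' but recoverable with [read_modality_comment()]).
#'
#' @param x A `CountMatrix`.
#' @param path Output path.
#' @param modality_comment Write the modality comment line (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_molecule_counts <- function(x, path, modality_comment = TRUE) {
  df <- data.frame(Barcode = barcodes(x), count_values(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (modality_comment) {
    writeLines(paste0("#modality,", paste(modalities(x), collapse = ",")), path)
    data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
  } else {
    data.table::fwrite(df, path)
  }
  invisible(path)
}

#' Recover the modality map from a CSV written by [write_molecule_counts()]
#' @param path Path to the CSV file.
#' @return Named character vector feature -> modality, or `NULL` when the
#'   file carries no modality comment.
#' @export
read_modality_comment <- function(path) {
  first <- readLines(path, n = 50L)
  mline <- grep("^#modality,", first, value = TRUE)
  if (!length(mline)) return(NULL)
  mods <- strsplit(sub("^#modality,", "", mline[1L]), ",", fixed = TRUE)[[1L]]
  skip <- sum(startsWith(first, "#"))
  hdr <- strsplit(first[skip + 1L], ",", fixed = TRUE)[[1L]][-1L]
  hdr <- gsub('^"|"$', "", hdr)
  stats::setNames(mods, hdr)
}
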