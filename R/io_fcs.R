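#' Export antibody counts as an FCS 3.1 file
#'
#' Writes one FCS event per barcode and one channel per protein feature so
#' that sequencing-derived antibody counts can be inspected in standard
#' cytometry software. The file is FCS 3.1, list mode, little-endian
#' float32 data, with no timestamp keywords so that identical inputs
#' produce byte-identical files.
#'
#' @param x A `CountMatrix` containing only protein-modality features
#'   (use [subset_modality()]).
#' @param path Output path.
#' @param transform `"none"` writes the raw counts; `"jittered_arcsinh"`
#'   applies [jittered_arcsinh()] (uniform jitter on \[0,1\), then
#'   `asinh(x / cofactor)`) before writing.
#' @param cofactor Arcsinh cofactor (default 5, the cytometry convention
#'   for sequencing-derived antibody counts).
#' @param seed Integer seed for the jitter; required when
#'   `transform = "jittered_arcsinh"`.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(x, path, transform = c("none", "jittered_arcsinh"),
                      cofactor = 5, seed = NULL) {
  transform <- match.arg(transform)
  if (!all(modalities(x) == "protein"))
    stop("write_fcs expects a protein-only CountMatrix; use subset_modality()")
  values <- count_values(x)
  if (nrow(values) < 1L)
    stop("FCS requires at least one event; matrix has zero barcodes")
  if (transform == "jittered_arcsinh") {
    if (is.null(seed)) stop("seed is required for the jittered arcsinh transform")
    values <- jittered_arcsinh(values, cofactor = cofactor, seed = seed)$values
  }
  ch <- sanitize_channel_names(colnames(values))
  write_fcs31(values, ch, path)
  invisible(path)
}

sanitize_channel_names <- function(nm) {
  nm <- gsub("[/\\\\,]", "_", nm)
  nm <- substr(nm, 1L, 32L)  # short-name limit honoured by cytometry software
  make.unique(nm, sep = "_")
}

# Minimal FCS 3.1 writer: list mode, $DATATYPE F, $BYTEORD 1,2,3,4.
# Offsets inside TEXT are zero-padded to fixed width so the segment length
# is independent of their values.
write_fcs31 <- function(values, channels, path) {
  n <- nrow(values); p <- ncol(values)
  delim <- "/"
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F",
          "$MODE", "L", "$NEXTDATA", "0",
          "$PAR", as.character(p), "$TOT", as.character(n))
  rng <- pmax(1, ceiling(apply(values, 2, max)))
  for (j in seq_len(p)) {
    kw <- c(kw,
            sprintf("$P%dN", j), channels[j],
            sprintf("$P%dB", j), "32",
            sprintf("$P%dE", j), "0,0",
            sprintf("$P%dR", j), as.character(rng[j]))
  }
  text_of <- function(bd, ed) {
    vals <- kw
    vals[vals == "%BD%"] <- sprintf("%010d", bd)
    vals[vals == "%ED%"] <- sprintf("%010d", ed)
    paste0(delim, paste(vals, collapse = delim), delim)
  }
  header_len <- 58L
  text <- text_of(0L, 0L)
  text_start <- header_len
  text_end <- text_start + nchar(text, type = "bytes") - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n * p - 1L
  text <- text_of(data_start, data_end)

  hdr_field <- function(v) {
    # header offset fields are 8 chars; 0 signals "see TEXT" when too large
    if (v > 99999999) v <- 0
    sprintf("%8d", as.integer(v))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("FCS3.1    ", con, eos = NULL)
  writeChar(paste0(hdr_field(text_start), hdr_field(text_end),
                   hdr_field(data_start), hdr_field(data_end),
                   hdr_field(0), hdr_field(0)), con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(values)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read back an FCS file written by [write_fcs()]
#'
#' A deliberately narrow parser for round-trip verification: it understands
#' FCS 3.0/3.1 list-mode files with `$DATATYPE F` and little-endian byte
#' order, which is exactly what [write_fcs()] emits. It is not a
#' general-purpose FCS reader.
#'
#' @param path Path to the FCS file.
#' @return A list with `values` (events x channels float matrix) and
#'   `keywords` (named character vector of the TEXT segment).
#' @export
read_fcs <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  magic <- rawToChar(raw[1:6])
  if (!magic %in% c("FCS3.0", "FCS3.1"))
    stop("not an FCS 3.x file: ", magic)
  off <- function(i) as.integer(trimws(rawToChar(raw[(11 + 8 * (i - 1)):(10 + 8 * i)])))
  text_start <- off(1); text_end <- off(2)
  text <- rawToChar(raw[(text_start + 1):(text_end + 1)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(substr(text, 2, nchar(text)), delim, fixed = TRUE)[[1]]
  keys <- parts[seq(1, length(parts) - 1, by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- stats::setNames(vals, keys)
  if (kw[["$DATATYPE"]] != "F" || kw[["$MODE"]] != "L")
    stop("only list-mode float FCS files are supported")
  if (!kw[["$BYTEORD"]] %in% c("1,2,3,4"))
    stop("only little-endian FCS files are supported")
  n <- as.integer(kw[["$TOT"]]); p <- as.integer(kw[["$PAR"]])
  data_start <- as.integer(kw[["$BEGINDATA"]])
  if (is.na(data_start) || data_start == 0L) data_start <- off(3)
  vec <- readBin(raw[(data_start + 1):length(raw)], "numeric",
                 n = n * p, size = 4L, endian = "little")
  values <- matrix(vec, nrow = n, ncol = p, byrow = TRUE)
  colnames(values) <- vapply(seq_len(p),
                             function(j) kw[[sprintf("$P%dN", j)]], character(1))
  list(values = values, keywords = kw)
}
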