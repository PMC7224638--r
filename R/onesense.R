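#' One-dimensional UMAP embedding of one modality
#'
#' Reduces a modality's full feature set to a single embedding coordinate
#' per cell with UMAP, the building block of the One-SENSE view. The
#' computation is delegated to the installed Python `umap-learn` (an
#' established UMAP implementation) and is deterministic under the seed.
#'
#' @param x A `NormalizedMatrix` or numeric matrix (cells x features) with
#'   cell row names.
#' @param n_neighbors,min_dist,metric UMAP hyperparameters (defaults 15,
#'   0.1, `"euclidean"`).
#' @param seed Integer random state (default 42).
#' @param python Python executable to use (default: `targetomics.python`
#'   option, else `python` on the PATH).
#' @return An `Embedding1D`: list with `coordinate` (named numeric, one
#'   finite value per cell) and `params`.
#' @export
embed_1d <- function(x, n_neighbors = 15, min_dist = 0.1,
                     metric = "euclidean", seed = 42,
                     python = getOption("targetomics.python", "python")) {
  v <- if (inherits(x, "NormalizedMatrix")) x$values else as.matrix(x)
  if (is.null(rownames(v))) stop("cells must be named (row names)")
  if (nrow(v) < n_neighbors + 1)
    stop("fewer cells (", nrow(v), ") than n_neighbors + 1 (",
         n_neighbors + 1, "); reduce n_neighbors")
  script <- system.file("python", "embed1d.py", package = "targetomics",
                        mustWork = TRUE)
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".txt")
  on.exit(unlink(c(fin, fout)))
  data.table::fwrite(as.data.frame(v), fin, col.names = FALSE)
  status <- system2(python,
                    c(script, "--input", fin, "--output", fout,
                      "--n-neighbors", as.integer(n_neighbors),
                      "--min-dist", min_dist, "--metric", metric,
                      "--seed", as.integer(seed)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(fout))
    stop("UMAP embedding failed (python exit status ", status, ")")
  coord <- scan(fout, quiet = TRUE)
  if (length(coord) != nrow(v) || any(!is.finite(coord)))
    stop("embedding returned invalid coordinates")
  structure(list(coordinate = stats::setNames(coord, rownames(v)),
                 params = list(n_neighbors = n_neighbors,
                               min_dist = min_dist, metric = metric,
                               seed = as.integer(seed))),
            class = "Embedding1D")
}

#' @exportS3Method base::print
print.Embedding1D <- function(x, ...) {
  cat(sprintf("Embedding1D: %d cells, range [%.3f, %.3f]\n",
              length(x$coordinate), min(x$coordinate), max(x$coordinate)))
  invisible(x)
}

#' Bin a 1D embedding into equal-width bins
#'
#' Splits the coordinate range into `n_bins` half-open bins
#' `[lo, hi)` of equal width (the last bin closed), assigning every cell
#' to exactly one bin. A value sitting exactly on an interior edge belongs
#' to the bin on its right.
#'
#' @param embedding An `Embedding1D` (or named numeric coordinate vector).
#' @param n_bins Number of bins (default 500).
#' @return A list with `bin` (named integer assignment in `1..n_bins`),
#'   `edges` (length `n_bins + 1`), `counts` (cells per bin).
#' @export
bin_1d <- function(embedding, n_bins = 500) {
  stopifnot(n_bins >= 2)
  x <- if (inherits(embedding, "Embedding1D")) embedding$coordinate
       else embedding
  lo <- min(x); hi <- max(x)
  if (hi == lo) stop("degenerate range: all coordinates identical")
  edges <- seq(lo, hi, length.out = n_bins + 1)
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  list(bin = stats::setNames(as.integer(bin), names(x)),
       edges = edges,
       counts = tabulate(bin, nbins = n_bins))
}

#' Per-bin median-expression heatmap
#'
#' For each feature, the median transformed expression of the cells in
#' each bin. Bins with no cells are masked (their medians undefined) and
#' later rendered black.
#'
#' @param x A `NormalizedMatrix` or numeric matrix (cells x features).
#' @param binning Result of [bin_1d()] over the same cells.
#' @param features Features to include; default all columns. Must be
#'   non-empty.
#' @return A `BinnedHeatmap`: list with `medians` (features x bins,
#'   `NA` where masked), `empty_mask` (length `n_bins`), `edges`,
#'   `n_bins`.
#' @export
bin_medians <- function(x, binning, features = NULL) {
  v <- if (inherits(x, "NormalizedMatrix")) x$values else as.matrix(x)
  if (is.null(features)) features <- colnames(v)
  if (length(features) == 0L) stop("empty feature list")
  if (!all(features %in% colnames(v)))
    stop("features absent from the matrix: ",
         paste(setdiff(features, colnames(v))[1:3], collapse = ", "))
  bin <- binning$bin
  if (!is.null(names(bin)) && !is.null(rownames(v)))
    v <- v[names(bin), , drop = FALSE]
  n_bins <- length(binning$counts)
  f <- factor(bin, levels = seq_len(n_bins))
  med <- matrix(NA_real_, length(features), n_bins,
                dimnames = list(features, NULL))
  for (i in seq_along(features)) {
    agg <- tapply(v[, features[i]], f, stats::median)
    med[i, ] <- as.numeric(agg)
  }
  structure(list(medians = med,
                 empty_mask = binning$counts == 0L,
                 edges = binning$edges,
                 n_bins = n_bins),
            class = "BinnedHeatmap")
}

#' Heatmap colors for a BinnedHeatmap
#'
#' Applies the One-SENSE color convention: per feature, medians are
#' min-max normalized between their 1st and 99th percentiles (robust to
#' outlier bins) and mapped onto a blue (low) - green (mid) - red (high)
#' ramp; empty bins are black.
#'
#' @param heatmap A `BinnedHeatmap`.
#' @param palette_size Number of ramp colors (default 256).
#' @return Character matrix (features x bins) of hex colors; masked
#'   entries are `"#000000"`.
#' @export
heatmap_colors <- function(heatmap, palette_size = 256) {
  ramp <- grDevices::colorRampPalette(c("blue", "green", "red"))(palette_size)
  med <- heatmap$medians
  out <- matrix("#000000", nrow(med), ncol(med), dimnames = dimnames(med))
  for (i in seq_len(nrow(med))) {
    vals <- med[i, ]
    ok <- !is.na(vals)
    if (!any(ok)) next
    q <- stats::quantile(vals[ok], c(0.01, 0.99), names = FALSE)
    if (q[2] <= q[1]) q <- range(vals[ok])
    scaled <- (vals[ok] - q[1]) / max(q[2] - q[1], .Machine$double.eps)
    idx <- pmin(pmax(ceiling(scaled * palette_size), 1), palette_size)
    out[i, ok] <- ramp[idx]
  }
  out[, heatmap$empty_mask] <- "#000000"
  out
}

#' Render the combined One-SENSE figure
#'
#' Central scatter of cells at (protein 1D coordinate, transcript 1D
#' coordinate), optionally colored by cluster labels, with the protein
#' binned-median heatmap aligned under the x axis and the transcript
#' heatmap along the y axis. Low expression is blue, mid green, high red;
#' bins devoid of cells are black.
#'
#' @param protein,rna Lists `list(embedding =, heatmap =)` holding an
#'   `Embedding1D` and its `BinnedHeatmap` for each modality. Both
#'   embeddings must cover the identical cell set.
#' @param file Output path; `.png` or `.pdf` decides the device.
#' @param cluster_labels Optional named vector (factor/character/integer)
#'   of cluster labels per cell for coloring the scatter.
#' @param width,height Device size in inches (default 8 x 8).
#' @return Invisibly, a list with the color matrices actually drawn
#'   (`protein_colors`, `rna_colors`) and `file`.
#' @export
render_onesense <- function(protein, rna, file, cluster_labels = NULL,
                            width = 8, height = 8) {
  pc <- protein$embedding$coordinate
  rc <- rna$embedding$coordinate
  diff_n <- length(union(names(pc), names(rc))) -
    length(intersect(names(pc), names(rc)))
  if (diff_n > 0)
    stop("protein and rna embeddings cover different cells (symmetric difference: ",
         diff_n, ")")
  rc <- rc[names(pc)]
  pcol <- heatmap_colors(protein$heatmap)
  rcol <- heatmap_colors(rna$heatmap)

  if (grepl("\\.png$", file, ignore.case = TRUE)) {
    grDevices::png(file, width = width, height = height, units = "in",
                   res = 150, type = "cairo")
  } else {
    grDevices::pdf(file, width = width, height = height)
  }
  on.exit(grDevices::dev.off())

  dot_col <- "grey30"
  if (!is.null(cluster_labels)) {
    lab <- factor(cluster_labels[names(pc)])
    pal <- grDevices::hcl.colors(max(2L, nlevels(lab)), "Dark 3")
    dot_col <- pal[as.integer(lab)]
  }
  graphics::layout(matrix(c(2, 4, 1, 3), 2, 2, byrow = TRUE),
                   widths = c(1.2, 4), heights = c(4, 1.2))
  op <- graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  on.exit(graphics::par(op), add = TRUE)

  draw_strip <- function(colors, horizontal) {
    nf <- nrow(colors); nb <- ncol(colors)
    graphics::plot.new()
    if (horizontal) {
      graphics::plot.window(xlim = c(0, nb), ylim = c(0, nf))
      graphics::rasterImage(grDevices::as.raster(colors[rev(seq_len(nf)), ,
                                                        drop = FALSE]),
                            0, 0, nb, nf, interpolate = FALSE)
    } else {
      # transcript axis runs bottom-to-top: bin 1 at the bottom
      m <- t(colors)[rev(seq_len(nb)), , drop = FALSE]
      graphics::plot.window(xlim = c(0, nf), ylim = c(0, nb))
      graphics::rasterImage(grDevices::as.raster(m), 0, 0, nf, nb,
                            interpolate = FALSE)
    }
  }

  # 1: central scatter
  graphics::plot(pc, rc, pch = 16, cex = 0.4, col = dot_col,
                 axes = FALSE, xlab = "", ylab = "",
                 xlim = range(protein$heatmap$edges),
                 ylim = range(rna$heatmap$edges))
  graphics::box()
  # 2: transcript heatmap (left, vertical)
  draw_strip(rcol, horizontal = FALSE)
  # 3: protein heatmap (bottom, horizontal)
  draw_strip(pcol, horizontal = TRUE)
  # 4: corner
  graphics::plot.new()

  invisible(list(protein_colors = pcol, rna_colors = rcol, file = file))
}
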