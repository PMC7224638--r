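#' Mean molecules per cell, per feature
#'
#' @param x A `CountMatrix` with at least one cell.
#' @return Named numeric vector: arithmetic mean count over all cells.
#' @export
mean_molecules_per_cell <- function(x) {
  if (nrow(x$counts) < 1L) stop("matrix has no cells")
  Matrix::colMeans(x$counts)
}

#' Relative detection ratio of a targeted panel versus WTA
#'
#' For every gene shared between a targeted-panel matrix and a
#' whole-transcriptome matrix (matched after uppercasing and optional
#' aliasing), computes mean molecules/cell in each and their ratio
#' targeted/WTA, then assigns each gene to a detection group. The `< 0.3`
#' boundary flags targets detected at under 30% of their WTA level; the
#' upper boundaries default to 1 and 3 (log-symmetric) and are
#' configurable.
#'
#' @param targeted,wta `CountMatrix` objects (RNA counts over called
#'   cells).
#' @param aliases Optional named character vector mapping alternate gene
#'   symbols to the canonical ones (applied to both matrices after
#'   uppercasing).
#' @param breaks Ascending group boundaries, default `c(0.3, 1, 3)`:
#'   group 1 `ratio < 0.3`, group 2 `[0.3, 1)`, group 3 `[1, 3)`,
#'   group 4 `>= 3`.
#' @return A `RatioTable` data.frame: `gene`, `mean_targeted`, `mean_wta`,
#'   `ratio` (`NA` when the WTA mean is 0), `group` (`NA` when the ratio
#'   is undefined). Attributes `only_targeted` / `only_wta` list genes
#'   absent from the other matrix.
#' @export
detection_ratio <- function(targeted, wta, aliases = NULL,
                            breaks = c(0.3, 1, 3)) {
  stopifnot(all(diff(breaks) > 0))
  canon <- function(x) {
    nm <- toupper(features(x))
    if (!is.null(aliases)) {
      al <- stats::setNames(toupper(aliases), toupper(names(aliases)))
      hit <- nm %in% names(al)
      nm[hit] <- unname(al[nm[hit]])
    }
    nm
  }
  tn <- canon(targeted); wn <- canon(wta)
  shared <- intersect(tn, wn)
  if (!length(shared))
    stop("no shared genes between targeted and WTA matrices; ",
         "check gene-name mapping / aliases")
  tm <- mean_molecules_per_cell(targeted); names(tm) <- tn
  wm <- mean_molecules_per_cell(wta); names(wm) <- wn
  ratio <- ifelse(wm[shared] > 0, tm[shared] / wm[shared], NA_real_)
  group <- ifelse(is.na(ratio), NA_integer_,
                  findInterval(ratio, breaks) + 1L)
  out <- data.frame(gene = shared,
                    mean_targeted = unname(tm[shared]),
                    mean_wta = unname(wm[shared]),
                    ratio = unname(ratio),
                    group = unname(group),
                    stringsAsFactors = FALSE)
  class(out) <- c("RatioTable", "data.frame")
  attr(out, "only_targeted") <- setdiff(tn, wn)
  attr(out, "only_wta") <- setdiff(wn, tn)
  out
}

#' Positive-population summary for a bimodal protein
#'
#' Antibody counts for lineage markers are bimodal: a low background mode
#' and a positive mode. On the `asinh(count / cofactor)` scale, a kernel
#' density estimate locates the two highest modes and the deepest interior
#' minimum between them (the valley); cells above the valley are called
#' positive.
#'
#' @param counts Integer counts of one protein across cells (>= 50).
#' @param cofactor Arcsinh cofactor (default 5).
#' @return A list: `bimodal` (logical flag), and when bimodal:
#'   `positive_fraction`, `positive_mean` (mean raw count among
#'   positives), `valley` (transformed scale), `valley_count` (back on
#'   the count scale).
#' @export
bimodal_positive_stats <- function(counts, cofactor = 5) {
  stopifnot(all(counts >= 0))
  if (length(counts) < 50L) stop("need at least 50 cells")
  y <- asinh(counts / cofactor)
  if (max(y) == min(y))
    return(list(bimodal = FALSE))
  d <- stats::density(y)
  dy <- d$y
  # interior local maxima / minima of the KDE
  is_max <- which(diff(sign(diff(dy))) == -2) + 1L
  is_min <- which(diff(sign(diff(dy))) == 2) + 1L
  if (length(is_max) < 2L || length(is_min) < 1L)
    return(list(bimodal = FALSE))
  top2 <- is_max[order(dy[is_max], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  between <- is_min[is_min > lo & is_min < hi]
  if (!length(between))
    return(list(bimodal = FALSE))
  valley_idx <- between[which.min(dy[between])]
  valley <- d$x[valley_idx]
  pos <- y > valley
  list(bimodal = TRUE,
       positive_fraction = mean(pos),
       positive_mean = mean(counts[pos]),
       valley = valley,
       valley_count = sinh(valley) * cofactor)
}
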