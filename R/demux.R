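#' Data-driven per-tag minimum count thresholds
#'
#' The singlet rule requires each sample tag to reach a minimum read
#' count. The vendor does not publish the threshold, so it is estimated
#' from the data: for each tag, the background distribution is its counts
#' in cells where it is not the dominant (argmax) tag, and the threshold
#' is `max(floor(mean + n_sd * sd), floor_count)`. A tag that dominates
#' every cell has no background and falls back to the absolute floor
#' (with a warning).
#'
#' @param x A `CountMatrix`; only its sample-tag features are used.
#' @param floor_count Absolute floor (default 10), protecting shallow runs.
#' @param n_sd Number of background SDs above the background mean
#'   (default 3).
#' @return Named integer vector of per-tag minimum counts.
#' @export
estimate_tag_thresholds <- function(x, floor_count = 10, n_sd = 3) {
  tm <- count_values(subset_modality(x, "sample_tag"))
  if (ncol(tm) < 2L) stop("need at least 2 sample tags")
  if (nrow(tm) < 10L) stop("need at least 10 cells to estimate backgrounds")
  top <- max.col(tm, ties.method = "first")
  thr <- integer(ncol(tm))
  for (j in seq_len(ncol(tm))) {
    bg <- tm[top != j, j]
    if (length(bg) == 0L) {
      warning("tag '", colnames(tm)[j],
              "' dominates every cell; threshold falls back to the floor")
      thr[j] <- as.integer(floor_count)
    } else {
      s <- if (length(bg) > 1L) stats::sd(bg) else 0
      thr[j] <- max(as.integer(floor(mean(bg) + n_sd * s)),
                    as.integer(floor_count))
    }
  }
  stats::setNames(thr, colnames(tm))
}

#' Classify one barcode from its sample-tag counts
#'
#' Singlet: exactly one tag reaches its minimum threshold AND that tag
#' carries strictly more than 75% of all tag reads. Multiplet: two or more
#' tags reach their thresholds. Undetermined otherwise (including zero tag
#' reads, or a tag above threshold without the read majority).
#'
#' @param tag_counts Non-negative counts, one per tag (named or not).
#' @param thresholds Per-tag minimum counts, same length/order.
#' @param min_fraction Majority fraction for a singlet (default 0.75,
#'   strict inequality).
#' @return A list: `call` (`"singlet"`, `"multiplet"`, `"undetermined"`),
#'   `assigned_tag` (index, `NA` unless singlet) and `tag_fraction`
#'   (top tag reads / total tag reads; `NA` when the total is zero).
#' @examples
#' classify_cell(c(80, 5, 5), c(10, 10, 10))$call      # singlet
#' classify_cell(c(50, 40, 0), c(10, 10, 10))$call     # multiplet
#' classify_cell(c(12, 5, 0), c(10, 10, 10))$call      # undetermined
#' @export
classify_cell <- function(tag_counts, thresholds, min_fraction = 0.75) {
  stopifnot(length(tag_counts) == length(thresholds), all(tag_counts >= 0))
  total <- sum(tag_counts)
  over <- which(tag_counts >= thresholds)
  frac <- if (total > 0) max(tag_counts) / total else NA_real_
  if (length(over) >= 2L)
    return(list(call = "multiplet", assigned_tag = NA_integer_,
                tag_fraction = frac))
  if (length(over) == 1L && total > 0 &&
      tag_counts[over] / total > min_fraction)
    return(list(call = "singlet", assigned_tag = over,
                tag_fraction = tag_counts[over] / total))
  list(call = "undetermined", assigned_tag = NA_integer_, tag_fraction = frac)
}

#' Demultiplex called cells by sample tag
#'
#' Applies [classify_cell()] to every barcode (vectorized) and summarizes
#' the partition. Multiplets and undetermined cells are excluded from the
#' singlet-only export.
#'
#' @param x A `CountMatrix` containing a sample-tag modality.
#' @param thresholds Optional per-tag minimum counts; estimated with
#'   [estimate_tag_thresholds()] when `NULL`.
#' @param floor_count,n_sd Passed to the threshold estimator.
#' @param min_fraction Singlet majority fraction (default 0.75).
#' @return A list:
#'   * `calls`: data.frame `barcode`, `call`, `assigned_tag` (tag name or
#'     `NA`), `tag_fraction`;
#'   * `summary`: list `n_singlet` (named per tag), `n_multiplet`,
#'     `n_undetermined`, `n_total`;
#'   * `singlets`: `CountMatrix` restricted to singlet barcodes;
#'   * `thresholds`: the thresholds used.
#' @export
demultiplex <- function(x, thresholds = NULL, floor_count = 10, n_sd = 3,
                        min_fraction = 0.75) {
  if (!any(modalities(x) == "sample_tag"))
    stop("matrix has no sample_tag features")
  tm <- count_values(subset_modality(x, "sample_tag"))
  tags <- colnames(tm)
  if (is.null(thresholds))
    thresholds <- estimate_tag_thresholds(x, floor_count, n_sd)
  thresholds <- thresholds[tags]

  over <- sweep(tm, 2L, thresholds, ">=")
  n_over <- rowSums(over)
  total <- rowSums(tm)
  # the unique over-threshold tag, where there is exactly one
  single_idx <- pmin(pmax(as.integer(over %*% seq_along(tags)), 1L),
                     length(tags))
  single_count <- tm[cbind(seq_len(nrow(tm)), single_idx)]
  is_singlet <- n_over == 1L & total > 0 &
    single_count / pmax(total, 1) > min_fraction
  call <- ifelse(n_over >= 2L, "multiplet",
                 ifelse(is_singlet, "singlet", "undetermined"))
  assigned <- ifelse(call == "singlet", tags[single_idx], NA_character_)
  frac <- ifelse(total > 0,
                 ifelse(call == "singlet", single_count / total,
                        apply(tm, 1L, max) / pmax(total, 1)),
                 NA_real_)

  calls <- data.frame(barcode = rownames(tm), call = call,
                      assigned_tag = assigned, tag_fraction = frac,
                      stringsAsFactors = FALSE, row.names = NULL)
  n_singlet <- stats::setNames(
    vapply(tags, function(t) sum(call == "singlet" & assigned == t, na.rm = TRUE),
           integer(1)), tags)
  summary <- list(n_singlet = n_singlet,
                  n_multiplet = sum(call == "multiplet"),
                  n_undetermined = sum(call == "undetermined"),
                  n_total = nrow(tm))
  singlets <- subset_counts(x, barcodes = calls$barcode[call == "singlet"])
  list(calls = calls, summary = summary, singlets = singlets,
       thresholds = thresholds)
}
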