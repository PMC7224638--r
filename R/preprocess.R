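#' Library-size log normalization (scale factor 10,000)
#'
#' Per cell: counts are divided by the cell's total over the supplied
#' features, multiplied by `scale_factor`, and natural-log transformed via
#' `log1p`: `value = ln(1 + count / cell_total * scale_factor)`. Zero
#' counts map to exactly zero; cells with zero total are dropped with a
#' warning.
#'
#' @param x A `CountMatrix` (typically one modality slice).
#' @param scale_factor Positive scale factor (default 10000).
#' @return A `NormalizedMatrix`: list with `values` (cells x features),
#'   `transform = "lognorm10k"`, `parameters`, `seed = NULL`.
#' @export
log_normalize <- function(x, scale_factor = 1e4) {
  if (scale_factor <= 0) stop("scale_factor must be positive")
  m <- x$counts
  totals <- Matrix::rowSums(m)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " cell(s) with zero total dropped")
    m <- m[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  v <- log1p(as.matrix(m / totals * scale_factor))
  normalized_matrix(v, "lognorm10k", list(scale_factor = scale_factor))
}

normalized_matrix <- function(values, transform, parameters, seed = NULL) {
  structure(list(values = values, transform = transform,
                 parameters = parameters, seed = seed),
            class = "NormalizedMatrix")
}

#' @exportS3Method base::print
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix [%s]: %d cells x %d features\n",
              x$transform, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Jittered arcsinh transform for antibody counts
#'
#' The cytometry-style transform for sequencing-derived protein counts:
#' each integer count is de-quantized by adding a uniform draw on \[0, 1),
#' then transformed with `asinh(x / cofactor)`. The jitter consumes one
#' uniform per matrix entry in row-major order under a single seeded
#' stream, so output is reproducible and order-stable.
#'
#' @param x A `CountMatrix`, or a plain numeric matrix of counts.
#' @param cofactor Positive cofactor (default 5).
#' @param seed Integer seed for the jitter.
#' @param jitter Set `FALSE` to force the uniform draw to 0 (the closed
#'   form `asinh(count / cofactor)`), mainly for verification.
#' @return A `NormalizedMatrix` with `transform = "jittered_arcsinh"`.
#' @examples
#' asinh(5 / 5)  # 0.8814, the u = 0 value for a count of 5
#' @export
jittered_arcsinh <- function(x, cofactor = 5, seed = 1L, jitter = TRUE) {
  if (cofactor <= 0) stop("cofactor must be positive")
  m <- if (inherits(x, "CountMatrix")) count_values(x) else as.matrix(x)
  if (jitter) {
    u <- withr::with_seed(as.integer(seed),
                          stats::runif(length(m)))
    # row-major assignment of the uniform stream
    u <- matrix(u, nrow = nrow(m), byrow = TRUE)
    m <- m + u
  }
  v <- asinh(m / cofactor)
  dimnames(v) <- dimnames(m)
  normalized_matrix(v, "jittered_arcsinh",
                    list(cofactor = cofactor, jitter = jitter),
                    seed = if (jitter) as.integer(seed) else NULL)
}

#' Quality-control cell filtering
#'
#' Rulesets mirror common whole-transcriptome practice:
#' * `wta_inclusion` keeps cells with >= 200 detected genes and
#'   mitochondrial fraction <= 20%.
#' * `wta_doublet_removal` drops cells with more than 15,000 total UMIs,
#'   more than 3,000 detected genes, or mitochondrial fraction over 20%
#'   (outlier doublet/low-quality removal).
#' * `none` applies no per-cell gene cutoffs — the targeted-panel setting.
#'
#' Gene detection and mitochondrial fractions are computed on the RNA
#' modality only.
#'
#' @param x A `CountMatrix`.
#' @param ruleset One of `"wta_inclusion"`, `"wta_doublet_removal"`,
#'   `"none"`.
#' @param mito_features Character vector of mitochondrial gene names
#'   (subset of the RNA features) used for the mito fraction.
#' @param min_genes,max_genes,max_umi,max_mito_fraction Rule parameters
#'   (defaults 200, 3000, 15000, 0.2).
#' @return A list with `matrix` (filtered `CountMatrix`) and `report`:
#'   per-rule drop counts, `n_input`, `n_kept`, `n_dropped`.
#' @export
qc_filter <- function(x, ruleset = c("none", "wta_inclusion",
                                     "wta_doublet_removal"),
                      mito_features = character(0),
                      min_genes = 200, max_genes = 3000,
                      max_umi = 15000, max_mito_fraction = 0.2) {
  ruleset <- match.arg(ruleset)
  if (ruleset == "none")
    return(list(matrix = x,
                report = list(ruleset = "none", n_input = nrow(x$counts),
                              n_kept = nrow(x$counts), n_dropped = 0L,
                              rule_drops = integer(0))))
  rna <- subset_modality(x, "rna")
  if (length(mito_features) && !all(mito_features %in% features(rna)))
    stop("mito_features must be a subset of the RNA features")
  m <- rna$counts
  detected <- Matrix::rowSums(m > 0)
  total_umi <- Matrix::rowSums(m)
  mito_frac <- if (length(mito_features))
    Matrix::rowSums(m[, mito_features, drop = FALSE]) / pmax(total_umi, 1)
  else rep(0, nrow(m))

  if (ruleset == "wta_inclusion") {
    drop_genes <- detected < min_genes
    drop_mito <- mito_frac > max_mito_fraction
    drop <- drop_genes | drop_mito
    rule_drops <- c(low_genes = sum(drop_genes), high_mito = sum(drop_mito))
  } else {
    drop_umi <- total_umi > max_umi
    drop_genes <- detected > max_genes
    drop_mito <- mito_frac > max_mito_fraction
    drop <- drop_umi | drop_genes | drop_mito
    rule_drops <- c(high_umi = sum(drop_umi), high_genes = sum(drop_genes),
                    high_mito = sum(drop_mito))
  }
  kept <- rownames(m)[!drop]
  list(matrix = subset_counts(x, barcodes = kept),
       report = list(ruleset = ruleset, n_input = nrow(m),
                     n_kept = length(kept), n_dropped = sum(drop),
                     rule_drops = rule_drops))
}

#' Regress out covariates and scale features
#'
#' Per feature: ordinary least squares on the supplied per-cell covariates
#' (with intercept), residuals standardized to mean 0 / SD 1, then clipped.
#' This is the usual "regress out UMI (and mito) then scale" step before
#' embedding. Constant features (zero residual SD) scale to all zeros.
#'
#' @param x A `NormalizedMatrix` or numeric matrix (cells x features).
#' @param covariates Numeric vector or matrix, one row per cell; `NULL`
#'   for plain z-scoring.
#' @param clip Symmetric clipping bound for the scaled values (default 10).
#' @return A `NormalizedMatrix` with `transform = "scaled_residual"`.
#' @export
regress_and_scale <- function(x, covariates = NULL, clip = 10) {
  v <- if (inherits(x, "NormalizedMatrix")) x$values else as.matrix(x)
  n <- nrow(v)
  X <- if (is.null(covariates)) matrix(1, n, 1)
       else cbind(1, as.matrix(covariates))
  if (nrow(X) != n) stop("covariate length must equal the number of cells")
  fit <- stats::lm.fit(X, v)
  res <- as.matrix(fit$residuals)
  sds <- apply(res, 2L, stats::sd)
  zero_sd <- sds < 1e-12 | !is.finite(sds)
  if (any(zero_sd))
    message(sum(zero_sd), " constant feature(s) scaled to zero")
  sds[zero_sd] <- 1
  out <- sweep(res, 2L, sds, "/")
  out[, zero_sd] <- 0
  out <- pmin(pmax(out, -clip), clip)
  dimnames(out) <- dimnames(v)
  normalized_matrix(out, "scaled_residual", list(clip = clip))
}

#' Binomial down-sampling of molecule counts
#'
#' Emulates reduced sequencing depth: each molecule is kept independently
#' with probability `fraction` (binomial thinning per matrix entry). Note
#' this thins UMI-corrected molecules, not raw reads — an approximation to
#' subsampling the run's raw reads before error correction.
#'
#' @param x A `CountMatrix`.
#' @param fraction Keep probability, in (0, 1].
#' @param seed Integer seed.
#' @return A `CountMatrix` of thinned integer counts.
#' @export
downsample_counts <- function(x, fraction, seed = 1L) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  if (fraction == 1) return(x)
  m <- as(x$counts, "CsparseMatrix")
  withr::with_seed(as.integer(seed), {
    m@x <- as.double(stats::rbinom(length(m@x), size = as.integer(m@x),
                                   prob = fraction))
  })
  m <- Matrix::drop0(m)
  count_matrix(m, modalities(x))
}
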