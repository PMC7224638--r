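# the UMAP-backed tests share one small fixture and reuse embeddings to keep
# the python round-trips (the slow part) to a minimum

test_that("bin_1d partitions cells into equal-width half-open bins", {
  x <- stats::setNames(seq(0, 1, length.out = 101), sprintf("c%03d", 1:101))
  b <- bin_1d(x, n_bins = 500)
  expect_length(b$edges, 501)
  expect_equal(diff(b$edges), rep(0.002, 500), tolerance = 1e-12)
  expect_identical(sum(b$counts), 101L)
  expect_true(all(b$bin >= 1 & b$bin <= 500))
  # every cell in exactly one bin
  expect_length(b$bin, 101)

  # an interior edge value belongs to the bin on its right
  y <- c(a = 0, b = 0.5, d = 1)
  b2 <- bin_1d(y, n_bins = 2)
  expect_identical(unname(b2$bin), c(1L, 2L, 2L))

  expect_error(bin_1d(c(a = 1, b = 1, d = 1), 10), "degenerate range")
})

test_that("bin_medians matches direct medians and masks empty bins", {
  v <- matrix(c(1, 2, 9, 4, 6, 8), 3, 2,
              dimnames = list(c("c1", "c2", "c3"), c("f1", "f2")))
  bn <- list(bin = c(c1 = 1L, c2 = 1L, c3 = 1L), edges = c(0, 1),
             counts = c(3L))
  bm <- bin_medians(v, bn)
  expect_equal(unname(bm$medians[, 1]), c(2, 6))  # median of {1,2,9}, {4,6,8}

  # with one bin spanning all cells the heatmap row is the global median
  coord <- stats::setNames(rnorm(50), sprintf("c%02d", 1:50))
  vals <- matrix(rnorm(100), 50, 2,
                 dimnames = list(names(coord), c("f1", "f2")))
  whole <- bin_medians(vals, list(bin = stats::setNames(rep(1L, 50), names(coord)),
                                  edges = range(coord), counts = 50L))
  expect_equal(unname(whole$medians[, 1]),
               unname(apply(vals, 2, median)), tolerance = 1e-12)

  b <- bin_1d(stats::setNames(c(0, 0.01, 0.99, 1), paste0("c", 1:4)), 10)
  bm2 <- bin_medians(matrix(1:4, 4, 1, dimnames = list(paste0("c", 1:4), "f")),
                     b)
  expect_true(any(bm2$empty_mask))
  expect_true(all(is.na(bm2$medians[, bm2$empty_mask])))
  expect_identical(dim(bm2$medians), c(1L, 10L))  # (n_features, n_bins)

  expect_error(bin_medians(vals, b, features = character(0)), "empty feature")
  expect_error(bin_medians(vals, b, features = "nope"), "absent")
})

test_that("heatmap colors map empty bins to black and values onto the ramp", {
  med <- matrix(c(0, 5, 10, NA), 1, 4)
  hm <- structure(list(medians = med, empty_mask = c(FALSE, FALSE, FALSE, TRUE),
                       edges = 0:4, n_bins = 4L), class = "BinnedHeatmap")
  cols <- heatmap_colors(hm)
  expect_identical(dim(cols), dim(med))
  expect_identical(cols[1, 4], "#000000")
  expect_false(any(cols[1, 1:3] == "#000000"))
  # low end of the ramp is blue-ish, high end red-ish
  expect_gt(col2rgb(cols[1, 1])["blue", 1], col2rgb(cols[1, 1])["red", 1])
  expect_gt(col2rgb(cols[1, 3])["red", 1], col2rgb(cols[1, 3])["blue", 1])
})

test_that("1D embedding is deterministic, separates clusters, and survives permutation", {
  withr::local_seed(7)
  n <- 150; lab <- rep(1:2, each = 75)
  m <- matrix(rnorm(n * 8, mean = ifelse(lab == 1, 0, 4)), n, 8,
              dimnames = list(sprintf("C%03d", 1:n), sprintf("F%d", 1:8)))
  e1 <- embed_1d(m, seed = 42)
  e2 <- embed_1d(m, seed = 42)
  expect_identical(e1$coordinate, e2$coordinate)
  expect_true(all(is.finite(e1$coordinate)))
  expect_identical(names(e1$coordinate), rownames(m))

  sil <- cluster::silhouette(lab, dist(e1$coordinate))
  expect_gt(mean(sil[, "sil_width"]), 0.5)

  # permutation: UMAP's SGD layout is not exactly equivariant, but the
  # cluster structure and coarse geometry must survive a row permutation
  p <- sample(n)
  e3 <- embed_1d(m[p, ], seed = 42)
  sil_p <- cluster::silhouette(lab[p], dist(e3$coordinate))
  expect_gt(mean(sil_p[, "sil_width"]), 0.5)
  expect_gt(abs(cor(e1$coordinate[rownames(m)[p]], e3$coordinate,
                    method = "spearman")), 0.5)

  expect_error(embed_1d(m[1:10, ], n_neighbors = 15), "n_neighbors")
})

test_that("render_onesense draws aligned heatmaps with black empty bins", {
  fx <- split_cluster_fixture(n_per_group = 70, seed = 2)
  prot_vals <- jittered_arcsinh(fx$protein, seed = 1)
  rna_vals <- log_normalize(fx$rna)
  pe <- embed_1d(prot_vals, seed = 42)
  re <- embed_1d(rna_vals, seed = 42)
  pb <- bin_1d(pe, 500); rb <- bin_1d(re, 500)
  ph <- bin_medians(prot_vals, pb); rh <- bin_medians(rna_vals, rb)

  f <- withr::local_tempfile(fileext = ".png")
  out <- render_onesense(list(embedding = pe, heatmap = ph),
                         list(embedding = re, heatmap = rh),
                         file = f, cluster_labels = fx$group)
  expect_true(file.exists(f) && file.size(f) > 0)
  expect_identical(ncol(out$protein_colors), 500L)
  expect_identical(ncol(out$rna_colors), 500L)
  # with 210 cells in 500 bins, empty bins exist and are rendered black
  expect_true(any(ph$empty_mask))
  expect_true(all(out$protein_colors[, ph$empty_mask] == "#000000"))

  # the protein axis separates the protein-split subgroups; the
  # transcript axis does not
  a1 <- names(fx$group)[fx$group == "A1"]
  a2 <- names(fx$group)[fx$group == "A2"]
  expect_gt(axis_separation(pe$coordinate, a1, a2), 3)
  expect_lt(axis_separation(re$coordinate, a1, a2), 3)

  # mismatched cell sets are rejected with the symmetric difference size
  pe_bad <- pe; pe_bad$coordinate <- pe$coordinate[-(1:3)]
  expect_error(render_onesense(list(embedding = pe_bad, heatmap = ph),
                               list(embedding = re, heatmap = rh),
                               file = f),
               "symmetric difference: 3")
})
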