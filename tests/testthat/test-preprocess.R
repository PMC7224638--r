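test_that("log_normalize matches the closed form and its invariants", {
  m <- matrix(c(1, 0, 99, 10, 0, 90), 2, 3, byrow = TRUE,
              dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
  nm <- log_normalize(cm_fixture(m), scale_factor = 1e4)
  # count 1 of a 100-total cell at scale 10000: ln(1 + 100)
  expect_equal(nm$values["c1", "g1"], log(101), tolerance = 1e-12)
  expect_identical(nm$values["c1", "g2"], 0)        # count 0 -> exactly 0
  # proportional cells normalize identically (c2 = 10 x c1 pattern? use scale)
  m2 <- rbind(a = c(2, 4, 6), b = c(20, 40, 60))
  colnames(m2) <- paste0("g", 1:3)
  nm2 <- log_normalize(cm_fixture(m2))
  expect_equal(nm2$values["a", ], nm2$values["b", ], tolerance = 1e-12)
  # pre-log per-cell sums equal the scale factor exactly
  pre <- expm1(nm$values)
  expect_equal(unname(rowSums(pre)), rep(1e4, 2), tolerance = 1e-9)

  expect_error(log_normalize(cm_fixture(m), scale_factor = 0), "positive")
  m3 <- rbind(c1 = c(1, 2, 3), c2 = c(0, 0, 0)); colnames(m3) <- paste0("g", 1:3)
  expect_warning(nm3 <- log_normalize(cm_fixture(m3)), "zero total")
  expect_equal(nrow(nm3$values), 1)
})

test_that("jittered_arcsinh matches closed forms and is seed-stable", {
  m <- matrix(c(5, 0, 26, 3), 2, 2,
              dimnames = list(c("a", "b"), c("p1", "p2")))
  plain <- jittered_arcsinh(m, jitter = FALSE)
  expect_equal(plain$values["a", "p1"], asinh(1), tolerance = 1e-12)  # 0.8814
  expect_identical(plain$values["b", "p1"], 0)
  expect_equal(plain$values, asinh(m / 5), tolerance = 1e-12)

  j1 <- jittered_arcsinh(m, seed = 3)
  j2 <- jittered_arcsinh(m, seed = 3)
  expect_identical(j1$values, j2$values)
  # jitter lies in [0, 1): values bracketed by the u=0 and u=1 closed forms
  expect_true(all(j1$values >= asinh(m / 5) & j1$values < asinh((m + 1) / 5)))
  # monotone in the count for a fixed jitter
  expect_true(all(diff(asinh((0:50) / 5)) > 0))
  # row-major jitter stream: first row consumes the first uniforms
  u <- withr::with_seed(3L, stats::runif(4))
  expect_equal(j1$values["a", "p1"], asinh((5 + u[1]) / 5), tolerance = 1e-12)
  expect_equal(j1$values["a", "p2"], asinh((26 + u[2]) / 5), tolerance = 1e-12)
})

test_that("qc_filter applies the inclusion and doublet-removal rulesets", {
  set.seed(2)
  n_genes <- 400
  base <- matrix(rpois(3 * n_genes, 2), 3, n_genes)
  base[1, ] <- 0; base[1, 1:150] <- 1          # 150 detected genes
  base[3, ] <- 40                               # 16,000 UMIs, 400 genes
  rownames(base) <- c("lowgenes", "ok", "deep")
  colnames(base) <- sprintf("G%03d", 1:n_genes)
  cm <- cm_fixture(base)

  inc <- qc_filter(cm, "wta_inclusion")
  expect_false("lowgenes" %in% barcodes(inc$matrix))
  expect_true(all(c("ok", "deep") %in% barcodes(inc$matrix)))
  expect_identical(inc$report$n_input - inc$report$n_kept,
                   inc$report$n_dropped)

  dbl <- qc_filter(cm, "wta_doublet_removal")
  expect_false("deep" %in% barcodes(dbl$matrix))
  expect_true("ok" %in% barcodes(dbl$matrix))

  none <- qc_filter(cm, "none")
  expect_identical(count_values(none$matrix), count_values(cm))

  # mitochondrial fraction rule
  mito_cm <- cm_fixture({
    m <- matrix(1, 2, 300, dimnames = list(c("mhi", "mlo"),
                                           c(sprintf("MT-%d", 1:30),
                                             sprintf("G%03d", 1:270))))
    m["mhi", 1:30] <- 50  # 1500 of 1770 mito
    m
  })
  res <- qc_filter(mito_cm, "wta_inclusion",
                   mito_features = sprintf("MT-%d", 1:30))
  expect_false("mhi" %in% barcodes(res$matrix))
  expect_true("mlo" %in% barcodes(res$matrix))
  expect_error(qc_filter(mito_cm, "wta_inclusion", mito_features = "NOPE"),
               "subset")
  expect_error(qc_filter(cm, "bogus"))
})

test_that("regress_and_scale residualizes, standardizes, and clips", {
  set.seed(9)
  n <- 200
  cov <- rnorm(n)
  y_orth <- rnorm(n)                      # orthogonal-ish to cov
  y_lin <- 2 * cov + 1                    # exactly linear in cov
  y_const <- rep(3, n)
  v <- cbind(orth = y_orth, lin = y_lin, konst = y_const)
  rownames(v) <- sprintf("c%03d", 1:n)
  expect_message(sc <- regress_and_scale(v, cov), "constant feature")
  expect_equal(unname(colMeans(sc$values)), c(0, 0, 0), tolerance = 1e-8)
  expect_equal(sd(sc$values[, "orth"]), 1, tolerance = 1e-8)
  expect_equal(unname(sc$values[, "lin"]), rep(0, n), tolerance = 1e-8)
  expect_identical(unname(sc$values[, "konst"]), rep(0, n))

  # no covariate -> plain z-score
  z <- regress_and_scale(v[, "orth", drop = FALSE], NULL)
  expect_equal(unname(z$values[, 1]),
               as.numeric(scale(y_orth)), tolerance = 1e-8)

  # clipping bound respected
  spike <- v; spike[1, "orth"] <- 1e6
  cl <- regress_and_scale(spike[, "orth", drop = FALSE], NULL, clip = 2)
  expect_lte(max(abs(cl$values)), 2)

  expect_error(regress_and_scale(v, rnorm(7)), "covariate length")
})

test_that("downsample_counts thins binomially and composes", {
  cm <- cm_fixture(matrix(c(10000, 0, 25, 3), 2, 2))
  expect_identical(count_values(downsample_counts(cm, 1, seed = 1)),
                   count_values(cm))
  expect_error(downsample_counts(cm, 0), "fraction")
  expect_error(downsample_counts(cm, 1.2), "fraction")

  draws <- vapply(1:50, function(s)
    count_values(downsample_counts(cm, 0.2, seed = s))[1, 1], numeric(1))
  expect_lt(abs(mean(draws) - 2000), 3 * sqrt(10000 * 0.2 * 0.8))
  expect_true(all(vapply(1:10, function(s)
    total_molecules(downsample_counts(cm, 0.5, seed = s)), numeric(1)) <=
      total_molecules(cm)))

  # thinning at p then q matches a single thin at pq in mean and variance
  two <- vapply(1:60, function(s)
    count_values(downsample_counts(downsample_counts(cm, 0.5, seed = s),
                                   0.4, seed = s + 1000))[1, 1], numeric(1))
  one <- vapply(1:60, function(s)
    count_values(downsample_counts(cm, 0.2, seed = s + 2000))[1, 1],
    numeric(1))
  se <- sqrt(10000 * 0.2 * 0.8 / 60)
  expect_lt(abs(mean(two) - mean(one)), 4 * se)
  expect_lt(abs(var(two) / var(one) - 1), 1)  # same order of magnitude
})
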