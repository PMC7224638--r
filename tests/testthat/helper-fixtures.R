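# shared fixture builders; everything generated in code, no stored data

# CountMatrix from a plain matrix of counts, default all-RNA
cm_fixture <- function(m, modality = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("BC%04d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("F%03d", seq_len(ncol(m)))
  count_matrix(m, modality %||% rep("rna", ncol(m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-feature CountMatrix whose row sums are the given totals
totals_cm <- function(totals) {
  cm_fixture(matrix(as.numeric(totals), ncol = 1,
                    dimnames = list(names(totals), "total")))
}

# random integer count matrix with reproducible content
random_counts <- function(n, p, seed = 1, lambda = 3) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n * p, lambda), n, p,
                dimnames = list(sprintf("BC%05d", seq_len(n)),
                                sprintf("F%03d", seq_len(p))))
    m
  })
}

# two transcript clusters, the first split in half by one bimodal protein;
# used by the One-SENSE structure tests
split_cluster_fixture <- function(n_per_group = 100, seed = 1) {
  withr::with_seed(seed, {
    n <- 3 * n_per_group
    grp <- rep(c("A1", "A2", "B"), each = n_per_group)
    rna <- matrix(stats::rpois(n * 20, ifelse(grp == "B", 8, 2)), n, 20,
                  dimnames = list(sprintf("S%04d", seq_len(n)),
                                  sprintf("G%02d", 1:20)))
    prot <- matrix(stats::rpois(n * 4, 3), n, 4,
                   dimnames = list(rownames(rna), sprintf("P%d", 1:4)))
    prot[grp == "A2", 1] <- prot[grp == "A2", 1] +
      stats::rnbinom(n_per_group, mu = 200, size = 5)
    list(rna = cm_fixture(rna), protein = cm_fixture(prot, rep("protein", 4)),
         group = stats::setNames(grp, rownames(rna)))
  })
}

# separation of two groups along a 1D coordinate, in units of within-group SD
axis_separation <- function(coord, a, b) {
  abs(mean(coord[a]) - mean(coord[b])) / mean(c(sd(coord[a]), sd(coord[b])))
}
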