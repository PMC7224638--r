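#' Generate a synthetic multimodal dataset with known ground truth
#'
#' Emulates a pooled, sample-tagged targeted single-cell experiment so that
#' cell calling, demultiplexing, normalization and visualization can be
#' exercised without downloaded data. The stated world:
#'
#' * RNA: negative-binomial counts (dispersion `rna_dispersion`) with
#'   cluster-specific means and Bernoulli dropout at a per-gene rate drawn
#'   from U(0.3, 0.8) — lymphocytes carry little mRNA, so target-level
#'   dropout is heavy.
#' * Proteins: a low Poisson background in every cell plus, for marker
#'   positive cells, a strong negative-binomial positive signal
#'   (mean `protein_positive_mean`, dispersion `protein_dispersion`),
#'   giving the bimodal distributions typical of lineage antibodies.
#' * Sample tags: the cell's own tag ~ NB(mean `tag_mean` = 100), all other
#'   tags ~ Poisson(mean `tag_background_mean` = 2) ambient background.
#' * Doublets: a Binomial(`n_cells`, `doublet_rate`) subset of barcodes is
#'   the sum of two latent cells from different donors.
#' * Noise barcodes: scaled-down Poisson profiles with totals 20-100x below
#'   a typical cell, as under the knee of a barcode rank curve.
#'
#' @param n_cells Number of true cell barcodes (default 2000).
#' @param n_noise_barcodes Number of sub-knee noise barcodes (default 6000).
#' @param n_clusters,n_genes,n_proteins,n_tags Panel geometry; every
#'   cluster is guaranteed non-empty.
#' @param doublet_rate Expected fraction of true cell barcodes that are
#'   doublets, in `[0, 1)`.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the arguments and this seed.
#' @param rna_dispersion,protein_dispersion NB dispersion (1/size); defaults
#'   0.5 and 0.2, typical UMI overdispersion.
#' @param protein_background_mean,protein_positive_mean Poisson background
#'   and NB positive-signal means for proteins (defaults 3 and 200).
#' @param tag_mean,tag_background_mean Sample-tag means (defaults 100, 2).
#' @return A list with `matrix` (a [count_matrix()] over all barcodes) and
#'   `truth`, a list holding `true_cell_barcodes`, `donor_of_cell` (named;
#'   `NA` for doublets), `doublet_barcodes`, `cluster_of_cell`, and
#'   `positive_protein_cells` (data.frame `feature`, `barcode`).
#' @examples
#' d <- generate_dataset(n_cells = 200, n_noise_barcodes = 200, seed = 1)
#' d$matrix
#' @export
generate_dataset <- function(n_cells = 2000, n_noise_barcodes = 6000,
                             n_clusters = 4, n_genes = 100, n_proteins = 10,
                             n_tags = 3, doublet_rate = 0.05, seed = 1L,
                             rna_dispersion = 0.5, protein_dispersion = 0.2,
                             protein_background_mean = 3,
                             protein_positive_mean = 200,
                             tag_mean = 100, tag_background_mean = 2) {
  stopifnot(n_cells >= 1, n_clusters >= 1, n_genes >= 1, n_proteins >= 1,
            n_tags >= 1, n_noise_barcodes >= 0,
            doublet_rate >= 0, doublet_rate < 1)
  withr::with_seed(as.integer(seed), {
    genes <- sprintf("G%03d", seq_len(n_genes))
    prots <- sprintf("P%02d", seq_len(n_proteins))
    tags <- sprintf("SampleTag%02d", seq_len(n_tags))
    cell_bc <- sprintf("CELL%06d", seq_len(n_cells))
    noise_bc <- if (n_noise_barcodes > 0)
      sprintf("NOISE%06d", seq_len(n_noise_barcodes)) else character(0)

    cluster <- sample.int(n_clusters, n_cells, replace = TRUE)
    cluster[seq_len(min(n_clusters, n_cells))] <- seq_len(min(n_clusters, n_cells))
    donor <- sample.int(n_tags, n_cells, replace = TRUE)

    if (doublet_rate > 0 && doublet_rate * n_cells < 1) {
      warning("doublet_rate * n_cells < 1; generating zero doublets")
      n_doub <- 0L
    } else {
      n_doub <- stats::rbinom(1L, n_cells, doublet_rate)
    }
    doub_idx <- if (n_doub > 0) sort(sample.int(n_cells, n_doub)) else integer(0)

    # cluster-specific gene means: lognormal baseline, 5x marker blocks
    base_mu <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
    mu <- matrix(base_mu, n_genes, n_clusters)
    block <- split(seq_len(n_genes),
                   rep(seq_len(n_clusters), length.out = n_genes))
    for (k in seq_len(n_clusters)) mu[block[[k]], k] <- mu[block[[k]], k] * 5
    dropout <- stats::runif(n_genes, 0.3, 0.8)

    # marker proteins: each protein positive in a random half of clusters
    pos_clusters <- lapply(seq_len(n_proteins), function(p)
      sample.int(n_clusters, max(1L, n_clusters %/% 2L)))

    draw_cell <- function(k, dn) {
      rna <- stats::rnbinom(n_genes, mu = mu[, k], size = 1 / rna_dispersion)
      rna[stats::runif(n_genes) < dropout] <- 0L
      prot <- stats::rpois(n_proteins, protein_background_mean)
      pos <- vapply(pos_clusters, function(pc) k %in% pc, logical(1))
      prot[pos] <- prot[pos] + stats::rnbinom(sum(pos),
                                              mu = protein_positive_mean,
                                              size = 1 / protein_dispersion)
      tg <- stats::rpois(n_tags, tag_background_mean)
      tg[dn] <- stats::rnbinom(1L, mu = tag_mean, size = 30)
      list(counts = c(rna, prot, tg), pos = pos)
    }

    nf <- n_genes + n_proteins + n_tags
    counts <- matrix(0, n_cells + n_noise_barcodes, nf)
    pos_list <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      d1 <- draw_cell(cluster[i], donor[i])
      pos_list[[i]] <- d1$pos
      counts[i, ] <- d1$counts
      if (i %in% doub_idx) {
        other_donor <- if (n_tags > 1)
          sample(setdiff(seq_len(n_tags), donor[i]), 1L) else donor[i]
        d2 <- draw_cell(sample.int(n_clusters, 1L), other_donor)
        counts[i, ] <- counts[i, ] + d2$counts
        pos_list[[i]] <- pos_list[[i]] | d2$pos
      }
    }

    if (n_noise_barcodes > 0) {
      prof <- colMeans(counts[seq_len(n_cells), , drop = FALSE])
      depth <- stats::runif(n_noise_barcodes, 20, 100)
      for (j in seq_len(n_noise_barcodes))
        counts[n_cells + j, ] <- stats::rpois(nf, prof / depth[j])
    }

    rownames(counts) <- c(cell_bc, noise_bc)
    colnames(counts) <- c(genes, prots, tags)
    cm <- count_matrix(counts,
                       c(rep("rna", n_genes), rep("protein", n_proteins),
                         rep("sample_tag", n_tags)))

    donor_of_cell <- stats::setNames(donor, cell_bc)
    donor_of_cell[doub_idx] <- NA_integer_
    pos_mat <- do.call(rbind, pos_list)
    ppc <- which(pos_mat, arr.ind = TRUE)
    truth <- list(
      true_cell_barcodes = cell_bc,
      donor_of_cell = donor_of_cell,
      doublet_barcodes = cell_bc[doub_idx],
      cluster_of_cell = stats::setNames(cluster, cell_bc),
      positive_protein_cells = data.frame(
        feature = prots[ppc[, 2L]], barcode = cell_bc[ppc[, 1L]],
        stringsAsFactors = FALSE),
      tags = tags)
    list(matrix = cm, truth = truth)
  })
}

#' Generate a synthetic barcode rank curve with a known knee
#'
#' Draws per-barcode molecule totals for `n_cells` cell-containing barcodes
#' (mean `cell_mean`) and `n_noise` noise barcodes (mean `noise_mean`), the
#' two classes a rank curve's knee separates. Totals are negative binomial
#' with size 10: a barcode total is a sum over hundreds of features, which
#' damps the relative dispersion well below that of a single gene.
#'
#' @param n_cells,n_noise Barcode counts per class.
#' @param cell_mean,noise_mean Class means; a well-posed knee needs
#'   `cell_mean / noise_mean >= 10`.
#' @param seed Integer seed.
#' @return A list with `totals` (named, unordered) and `n_cells`, the
#'   ground-truth number of cell barcodes.
#' @export
generate_barcode_rank_curve <- function(n_cells = 100, n_noise = 900,
                                        cell_mean = 5000, noise_mean = 50,
                                        seed = 1L) {
  stopifnot(n_cells >= 1, n_noise >= 0, cell_mean > 0, noise_mean > 0)
  withr::with_seed(as.integer(seed), {
    cells <- stats::rnbinom(n_cells, mu = cell_mean, size = 10)
    noise <- if (n_noise > 0) stats::rnbinom(n_noise, mu = noise_mean, size = 10)
             else integer(0)
    totals <- c(cells, noise)
    names(totals) <- c(sprintf("CELL%06d", seq_len(n_cells)),
                       if (n_noise > 0) sprintf("NOISE%06d", seq_len(n_noise)))
    list(totals = totals, n_cells = n_cells)
  })
}

#' Write a synthetic dataset to plain-text files
#'
#' Convenience used by the command-line `simulate` entry point: writes the
#' counts CSV (with modality comment) plus a ground-truth CSV.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_molecule_counts(dataset$matrix, file.path(dir, "counts.csv"))
  tr <- dataset$truth
  df <- data.frame(
    barcode = tr$true_cell_barcodes,
    donor = unname(tr$donor_of_cell[tr$true_cell_barcodes]),
    cluster = unname(tr$cluster_of_cell[tr$true_cell_barcodes]),
    is_doublet = tr$true_cell_barcodes %in% tr$doublet_barcodes,
    stringsAsFactors = FALSE)
  data.table::fwrite(df, file.path(dir, "truth.csv"))
  invisible(dir)
}
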