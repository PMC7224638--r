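Package: targetomics
Title: Targeted Single-Cell Multi-Omics: Cell Calling, Sample-Tag
    Demultiplexing, and One-SENSE Visualization
Version: 0.1.0
Authors@R:
    person("Targetomics", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolchain for targeted single-cell multi-omic
    experiments that measure a gene panel together with
    oligonucleotide-barcoded antibodies (AbSeq/ADT) and sample-tag
    (cell-hashing) antibodies. Provides cell calling from barcode
    rank curves via the minimum second derivative of the cumulative
    read curve, sample-tag singlet/multiplet/undetermined
    classification, modality-specific normalization (library-size log
    normalization, jittered arcsinh), quality-control filtering,
    covariate regression and scaling, binomial read down-sampling,
    targeted-versus-whole-transcriptome detection-ratio tables, and an
    adapted One-SENSE visualization juxtaposing independent
    one-dimensional embeddings of the protein and transcript
    modalities with binned median-expression heatmaps. Includes a
    synthetic multimodal data generator with known ground truth and a
    minimal FCS 3.1 writer for export to cytometry software.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    withr
Suggests:
    testthat (>= 3.0.0),
    cluster
SystemRequirements: Python (>= 3.8) with numpy and umap-learn, used by
    embed_1d() for the one-dimensional UMAP embedding.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
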