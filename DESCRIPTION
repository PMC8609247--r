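Package: embedsep
Title: Separability of 2D Versus 3D Single-Cell Embeddings and In-Session
    Selection Statistics
Version: 0.1.0
Authors@R:
    person("Maintainer", "Embedsep", email = "embedsep@example.org",
           role = c("aut", "cre"))
Description: Quantifies how well pairs of cell populations separate in two-
    versus three-dimensional dimension-reduction embeddings (UMAP, tSNE,
    PHATE and similar). Two mixing metrics are provided: a shifted-grid
    Shannon-index entropy score and a convex-hull area-overlap percentage,
    each minimized over a deterministic set of 3D viewing directions so the
    best achievable 2D view of a 3D embedding is compared against a native
    2D embedding. Also implements a plain-text/SQLite interchange bundle for
    single-cell coordinate and expression data (.mds coordinate files,
    sparse expression database, one-hot cell-type tables), plus the
    statistics run on user-selected cell groups: Wilcoxon rank-sum
    differential expression with Benjamini-Hochberg correction and marker
    ordering, transcription-factor network edge selection, trajectory
    partitioning, and pseudotime binning and gene-correlation ranking. A
    seeded synthetic-data generator makes every analysis testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    DBI,
    RSQLite,
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
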