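#' Configuration for the Gaussian-blob embedding generator
#'
#' @param n_populations number of populations.
#' @param cells_per_population cells per population (recycled).
#' @param centers n_populations x 3 matrix of blob centers.
#' @param sigma isotropic standard deviation per population (recycled),
#'   embedding units.
#' @param seed RNG seed fixing all randomness.
#' @return an object of class `BlobConfig`.
#' @export
blob_config <- function(n_populations = 2, cells_per_population = 200,
                        centers = NULL, sigma = 1, seed = 1) {
  if (is.null(centers)) {
    centers <- cbind(10 * seq_len(n_populations), 0, 0)
  }
  centers <- as.matrix(centers)
  check_finite_matrix(centers, "centers")
  if (nrow(centers) != n_populations || ncol(centers) != 3) {
    stop_input("centers must be n_populations x 3")
  }
  sigma <- rep(as.numeric(sigma), length.out = n_populations)
  if (any(sigma <= 0)) stop_input("sigma must be > 0")
  structure(list(n_populations = as.integer(n_populations),
                 cells_per_population =
                   rep(as.integer(cells_per_population),
                       length.out = n_populations),
                 centers = centers, sigma = sigma, seed = as.integer(seed)),
            class = "BlobConfig")
}

#' Simulate 3D Gaussian blob populations
#'
#' Isotropic Gaussian blobs at the configured centers with one-hot type
#' labels; fully deterministic under the config seed. Cell IDs are
#' `cell_0001, cell_0002, ...` across populations.
#'
#' @param config a [blob_config()].
#' @return list with `embedding` (3D [embedding_table()]) and `celltypes`
#'   (a [celltype_table()] with types `pop1, pop2, ...`).
#' @export
make_blobs_3d <- function(config = blob_config()) {
  stopifnot(inherits(config, "BlobConfig"))
  n_tot <- sum(config$cells_per_population)
  coords <- with_seed(config$seed, {
    do.call(rbind, lapply(seq_len(config$n_populations), function(p) {
      n <- config$cells_per_population[p]
      matrix(rnorm(3 * n, sd = config$sigma[p]), n, 3, byrow = FALSE) +
        matrix(config$centers[p, ], n, 3, byrow = TRUE)
    }))
  })
  ids <- sprintf("cell_%04d", seq_len(n_tot))
  pop <- rep(seq_len(config$n_populations), config$cells_per_population)
  membership <- matrix(0L, n_tot, config$n_populations)
  membership[cbind(seq_len(n_tot), pop)] <- 1L
  list(embedding = embedding_table(coords, cell_ids = ids, name = "blobs3d"),
       celltypes = celltype_table(
         membership, cell_ids = ids,
         type_names = paste0("pop", seq_len(config$n_populations))))
}

#' Simulate a pair of populations separated only along the hidden axis
#'
#' Two populations with identical x-y distributions whose means differ by
#' `separation` along z. The returned 2D embedding is the (x, y) projection,
#' so the pair overlaps heavily in 2D but separates at an edge-on 3D viewing
#' angle - the situation where a 3D embedding resolves what a 2D one
#' flattens together.
#'
#' @param separation distance between population means along z (> 0, same
#'   units as `sigma`).
#' @param sigma isotropic spread of each population.
#' @param n_per_pop cells per population.
#' @param seed RNG seed.
#' @return list with `embedding3d`, `embedding2d` and `celltypes`.
#' @export
make_axis_hidden_pair <- function(separation = 10, sigma = 1, n_per_pop = 200,
                                  seed = 1) {
  if (separation < 0) stop_input("separation must be >= 0")
  cfg <- blob_config(n_populations = 2, cells_per_population = n_per_pop,
                     centers = rbind(c(0, 0, 0), c(0, 0, separation)),
                     sigma = sigma, seed = seed)
  blobs <- make_blobs_3d(cfg)
  emb2 <- embedding_table(blobs$embedding$coords[, 1:2, drop = FALSE],
                          cell_ids = blobs$embedding$cell_ids,
                          name = "flat2d")
  blobs$embedding$name <- "hidden3d"
  list(embedding3d = blobs$embedding, embedding2d = emb2,
       celltypes = blobs$celltypes)
}

#' Configuration for the synthetic expression generator
#'
#' @param n_genes total genes.
#' @param de_fraction fraction of genes that are truly differentially
#'   expressed (in `[0, 1]`).
#' @param effect log-scale mean shift applied to DE genes (>= 0; the DE
#'   population's negative-binomial mean is multiplied by `exp(effect)`).
#' @param base_mean baseline negative-binomial mean of counts.
#' @param dispersion negative-binomial size parameter (smaller = noisier).
#' @param seed RNG seed.
#' @return an object of class `ExprSimConfig`.
#' @export
expr_sim_config <- function(n_genes = 1000, de_fraction = 0.05, effect = 2,
                            base_mean = 2, dispersion = 2, seed = 1) {
  if (de_fraction < 0 || de_fraction > 1) {
    stop_input("de_fraction must lie in [0, 1]")
  }
  if (effect < 0) stop_input("effect must be >= 0")
  structure(list(n_genes = as.integer(n_genes), de_fraction = de_fraction,
                 effect = effect, base_mean = base_mean,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "ExprSimConfig")
}

#' Simulate a genes x cells expression matrix with known DE genes
#'
#' Negative-binomial counts with mildly variable per-gene baseline means,
#' `log1p`-normalized. With two populations the designated DE genes are
#' up-shifted in the second population; with more, the DE genes are split
#' evenly across populations 2..P and shifted one-vs-rest.
#'
#' @param celltypes a [celltype_table()] defining the populations.
#' @param config an [expr_sim_config()].
#' @return list with `expr` (an [expression_matrix()]) and `de_genes`
#'   (character vector of ground-truth DE gene names).
#' @export
make_expression <- function(celltypes, config = expr_sim_config()) {
  stopifnot(inherits(celltypes, "CellTypeTable"),
            inherits(config, "ExprSimConfig"))
  n_cells <- length(celltypes$cell_ids)
  n_pop <- length(celltypes$type_names)
  if (n_pop < 2) stop_input("need at least 2 populations")
  pop_of_cell <- apply(celltypes$membership, 1, function(r) which(r == 1)[1])
  genes <- sprintf("gene_%05d", seq_len(config$n_genes))
  n_de <- round(config$n_genes * config$de_fraction)
  out <- with_seed(config$seed, {
    gene_means <- rlnorm(config$n_genes, meanlog = log(config$base_mean),
                         sdlog = 0.5)
    de_idx <- if (n_de > 0) sort(sample.int(config$n_genes, n_de)) else integer(0)
    # assign each DE gene to one of populations 2..P (round-robin)
    de_pop <- if (n_de > 0) 1 + (seq_len(n_de) - 1) %% (n_pop - 1) + 1
              else integer(0)
    mu <- matrix(gene_means, config$n_genes, n_cells)
    if (n_de > 0) {
      for (k in seq_along(de_idx)) {
        cells_k <- which(pop_of_cell == de_pop[k])
        mu[de_idx[k], cells_k] <- mu[de_idx[k], cells_k] * exp(config$effect)
      }
    }
    counts <- matrix(rnbinom(length(mu), size = config$dispersion, mu = mu),
                     nrow = config$n_genes)
    list(values = log1p(counts), de_idx = de_idx)
  })
  expr <- expression_matrix(out$values, gene_names = genes,
                            cell_ids = celltypes$cell_ids)
  list(expr = expr, de_genes = genes[out$de_idx])
}

#' Write a complete synthetic bundle for a named preset
#'
#' Presets:
#' * `"fig2"`: the hidden-axis pair (z-separation 10 sigma, n = 200 per
#'   population) with its 2D projection, plus an expression matrix - the
#'   benchmark where the 3D best angle should fully separate what the 2D
#'   embedding mixes.
#' * `"minimal"`: expression plus a single 3D embedding, the smallest legal
#'   bundle.
#' * `"de"`: two blob populations with 50 true DE genes out of 1000 for
#'   testing differential-expression recovery.
#'
#' A `ground_truth.json` manifest with the generating parameters is written
#' alongside the bundle.
#'
#' @param out_dir output directory.
#' @param preset one of `"fig2"`, `"minimal"`, `"de"`.
#' @param seed RNG seed.
#' @return `out_dir`, invisibly.
#' @export
fixture_bundle <- function(out_dir, preset = c("fig2", "minimal", "de"),
                           seed = 1) {
  preset <- match.arg(preset)
  truth <- list(preset = preset, seed = seed)
  if (preset == "fig2") {
    pair <- make_axis_hidden_pair(separation = 10, sigma = 1, n_per_pop = 200,
                                  seed = seed)
    sim <- make_expression(pair$celltypes,
                           expr_sim_config(n_genes = 200, seed = seed))
    export_bundle(sim$expr, list(pair$embedding2d, pair$embedding3d),
                  celltypes = pair$celltypes, out_dir = out_dir)
    truth <- c(truth, list(separation = 10, sigma = 1, n_per_pop = 200,
                           embedding_2d = "flat2d", embedding_3d = "hidden3d",
                           de_genes = sim$de_genes))
  } else if (preset == "minimal") {
    blobs <- make_blobs_3d(blob_config(seed = seed))
    sim <- make_expression(blobs$celltypes,
                           expr_sim_config(n_genes = 100, seed = seed))
    export_bundle(sim$expr, list(blobs$embedding), out_dir = out_dir)
    truth <- c(truth, list(n_per_pop = 200, de_genes = sim$de_genes))
  } else {
    blobs <- make_blobs_3d(blob_config(cells_per_population = 100, seed = seed))
    sim <- make_expression(blobs$celltypes,
                           expr_sim_config(n_genes = 1000, de_fraction = 0.05,
                                           effect = 2, seed = seed))
    export_bundle(sim$expr, list(blobs$embedding), celltypes = blobs$celltypes,
                  out_dir = out_dir)
    truth <- c(truth, list(n_per_pop = 100, n_genes = 1000, effect = 2,
                           de_genes = sim$de_genes))
  }
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
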