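#' Parameters for the all-pairs 2D-vs-3D comparison
#'
#' @param sectors_per_axis entropy grid resolution (default 10 x 10).
#' @param n_shift_steps entropy shift lattice size per axis (default 5).
#' @param n_angles viewing directions for the 3D best-angle search
#'   (default 2048, matching the published exhaustive search).
#' @param min_pop_size populations smaller than this are dropped rather than
#'   scored (default 10): a grid or hull over a handful of cells is noise.
#' @return an object of class `ComparisonConfig`.
#' @export
comparison_config <- function(sectors_per_axis = c(10, 10), n_shift_steps = 5,
                              n_angles = 2048, min_pop_size = 10) {
  s <- rep(as.integer(sectors_per_axis), length.out = 2)
  if (any(s < 1) || n_shift_steps < 1 || n_angles < 1 || min_pop_size < 1) {
    stop_input("all ComparisonConfig counts must be positive")
  }
  structure(list(sectors_per_axis = s,
                 n_shift_steps = as.integer(n_shift_steps),
                 n_angles = as.integer(n_angles),
                 min_pop_size = as.integer(min_pop_size)),
            class = "ComparisonConfig")
}

annotation_populations <- function(annotations) {
  if (inherits(annotations, "CellTypeTable")) annotations$type_names
  else sort(unique(as.character(annotations)))
}

#' All-pairs 2D-vs-3D overlap difference matrix
#'
#' For every unordered pair of populations the mixing score is computed on
#' the native 2D embedding and at the best viewing angle of the 3D
#' embedding; the matrix entry is `score_3D_best - score_2D`, so negative
#' entries mean the third dimension helped separate the pair. Populations
#' below `min_pop_size` are dropped and recorded in the metadata, as are
#' pairs that share cells (legal when a cell carries several type labels).
#'
#' @param embedding2d a 2D (or constant-z 3D) [embedding_table()].
#' @param embedding3d a 3D [embedding_table()] over the same cells.
#' @param annotations a [celltype_table()] or named label vector.
#' @param method `"entropy"` or `"hull"`.
#' @param config a [comparison_config()].
#' @param angles optional pre-built `AngleSet` (defaults to
#'   `sample_viewing_angles(config$n_angles)`).
#' @return an object of class `PairwiseOverlapMatrix`: list with
#'   `population_names`, `values` (P x P, diagonal `NA`), `score_2d` and
#'   `score_3d` matrices, `method`, and `metadata`.
#' @export
pairwise_matrix <- function(embedding2d, embedding3d, annotations,
                            method = c("entropy", "hull"),
                            config = comparison_config(), angles = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(config, "ComparisonConfig"))
  if (embedding_dim(embedding3d) != 3) stop_input("embedding3d must be 3D")
  if (!setequal(embedding2d$cell_ids, embedding3d$cell_ids)) {
    stop_input("the two embeddings must cover the same cell set")
  }
  pts2d <- embedding_points_2d(embedding2d)
  if (is.null(angles)) angles <- sample_viewing_angles(config$n_angles)

  pops <- annotation_populations(annotations)
  sizes <- vapply(pops, function(p) length(population_cells(annotations, p)),
                  integer(1))
  dropped <- pops[sizes < config$min_pop_size]
  pops <- pops[sizes >= config$min_pop_size]
  if (length(pops) < 2) {
    stop_input("fewer than 2 populations meet the size floor (",
               config$min_pop_size, ")")
  }

  p <- length(pops)
  vals <- s2d <- s3d <- matrix(NA_real_, p, p, dimnames = list(pops, pops))
  shared <- character(0)
  members <- lapply(pops, function(x) population_cells(annotations, x))
  names(members) <- pops
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      a <- pops[i]; b <- pops[j]
      if (length(intersect(members[[a]], members[[b]])) > 0) {
        shared <- c(shared, paste(a, b, sep = "|"))
      }
      if (method == "entropy") {
        sc2 <- entropy_overlap_pair_2d(
          embedding2d, annotations, a, b,
          sectors_per_axis = config$sectors_per_axis,
          n_shift_steps = config$n_shift_steps)$total_SI
        sc3 <- entropy_overlap_pair_3d(
          embedding3d, annotations, a, b, angles = angles,
          sectors_per_axis = config$sectors_per_axis,
          n_shift_steps = config$n_shift_steps)$total_SI
      } else {
        ai2 <- match(members[[a]], embedding2d$cell_ids)
        bi2 <- match(members[[b]], embedding2d$cell_ids)
        sc2 <- hull_overlap_percent_2d(pts2d[ai2, , drop = FALSE],
                                       pts2d[bi2, , drop = FALSE])$overlap_percent
        ai3 <- match(members[[a]], embedding3d$cell_ids)
        bi3 <- match(members[[b]], embedding3d$cell_ids)
        sc3 <- min_hull_overlap_over_angles(
          embedding3d$coords[ai3, , drop = FALSE],
          embedding3d$coords[bi3, , drop = FALSE], angles)$overlap_percent
      }
      s2d[i, j] <- s2d[j, i] <- sc2
      s3d[i, j] <- s3d[j, i] <- sc3
      vals[i, j] <- vals[j, i] <- sc3 - sc2
    }
  }
  structure(list(population_names = pops, values = vals,
                 score_2d = s2d, score_3d = s3d, method = method,
                 metadata = list(
                   embedding_2d = embedding2d$name,
                   embedding_3d = embedding3d$name,
                   difference = "3D_best - 2D (negative = 3D separates better)",
                   dropped_populations = dropped,
                   pairs_sharing_cells = shared,
                   config = unclass(config))),
            class = "PairwiseOverlapMatrix")
}

#' @export
print.PairwiseOverlapMatrix <- function(x, ...) {
  cat(sprintf("PairwiseOverlapMatrix (%s): %d populations, %s vs %s\n",
              x$method, length(x$population_names),
              x$metadata$embedding_3d, x$metadata$embedding_2d))
  print(round(x$values, 4))
  invisible(x)
}

#' Summarize a pairwise difference matrix
#'
#' @param matrix a `PairwiseOverlapMatrix`.
#' @return list with counts and fractions of negative (3D better), zero and
#'   positive pairs, and the mean and median difference.
#' @export
summarize_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "PairwiseOverlapMatrix"))
  v <- matrix$values[upper.tri(matrix$values)]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop_input("matrix has no defined entries")
  list(n_pairs = length(v),
       n_negative = sum(v < 0), n_zero = sum(v == 0), n_positive = sum(v > 0),
       fraction_3D_better = mean(v < 0),
       fraction_2D_better = mean(v > 0),
       mean_difference = mean(v), median_difference = stats::median(v))
}

#' Render a difference matrix as a heatmap image
#'
#' Diverging palette centered at 0 (blue-to-red; negative = "3D better" in
#' red to match the published convention). When a second matrix with the
#' same population list is supplied its entries fill the upper triangle so
#' two methods/embeddings can share one plot.
#'
#' @param matrix a `PairwiseOverlapMatrix` (fills the lower triangle).
#' @param path output PNG path.
#' @param upper optional second `PairwiseOverlapMatrix` for the upper
#'   triangle; must have an identical population list.
#' @return `path`, invisibly.
#' @export
render_matrix <- function(matrix, path, upper = NULL) {
  stopifnot(inherits(matrix, "PairwiseOverlapMatrix"))
  v <- matrix$values
  if (!is.null(upper)) {
    stopifnot(inherits(upper, "PairwiseOverlapMatrix"))
    if (!identical(matrix$population_names, upper$population_names)) {
      stop_input("population lists of the two matrices differ")
    }
    v[upper.tri(v)] <- upper$values[upper.tri(v)]
  }
  p <- nrow(v)
  lim <- max(abs(v), na.rm = TRUE)
  if (lim == 0) lim <- 1
  pal <- grDevices::colorRampPalette(c("#b2182b", "#f7f7f7", "#2166ac"))(255)
  grDevices::png(path, width = 160 + 40 * p, height = 160 + 40 * p)
  on.exit(grDevices::dev.off(), add = TRUE)
  op <- graphics::par(mar = c(8, 8, 2, 2))
  on.exit(graphics::par(op), add = TRUE)
  graphics::image(seq_len(p), seq_len(p), t(v[p:1, , drop = FALSE]),
                  zlim = c(-lim, lim), col = pal, axes = FALSE,
                  xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(p), labels = matrix$population_names,
                 las = 2, cex.axis = 0.8)
  graphics::axis(2, at = seq_len(p), labels = rev(matrix$population_names),
                 las = 2, cex.axis = 0.8)
  graphics::box()
  invisible(path)
}
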