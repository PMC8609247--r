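#' Shannon index of a proportion vector
#'
#' `SI = -sum(p_i * log(p_i))` in nats; terms with `p = 0` contribute 0. For
#' a two-population sector this ranges from 0 (pure) to `log(2)` (perfectly
#' mixed).
#'
#' @param proportions non-negative values summing to 1 (within 1e-9).
#' @return the Shannon index (nats).
#' @examples
#' shannon_index(c(0.5, 0.5)) # log(2)
#' shannon_index(c(1, 0))     # 0
#' @export
shannon_index <- function(proportions) {
  p <- as.numeric(proportions)
  if (any(!is.finite(p)) || any(p < 0)) {
    stop_input("proportions must be finite and non-negative")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop_input("proportions must sum to 1 (got ", format(sum(p)), ")")
  }
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Sector-grid specification
#'
#' @param sectors_per_axis integer pair (columns, rows); a single value is
#'   recycled.
#' @param shift_fractions grid-origin offset per axis as a fraction of the
#'   sector size, each in `[0, 1)`.
#' @return an object of class `GridSpec`.
#' @export
grid_spec <- function(sectors_per_axis = c(10, 10), shift_fractions = c(0, 0)) {
  s <- rep(as.integer(sectors_per_axis), length.out = 2)
  f <- rep(as.numeric(shift_fractions), length.out = 2)
  if (any(s < 1)) stop_input("sectors_per_axis must be positive")
  if (any(f < 0 | f >= 1)) stop_input("shift_fractions must lie in [0, 1)")
  structure(list(sectors_per_axis = s, shift_fractions = f,
                 bounding_box = NULL),
            class = "GridSpec")
}

# Map two-population labels to 0/1 in sorted-unique order; errors if not
# exactly two populations or either is empty.
label_codes <- function(labels) {
  labels <- as.character(labels)
  u <- sort(unique(labels))
  if (length(u) != 2) {
    stop_input("labels must take exactly 2 values, got ", length(u))
  }
  list(codes = as.integer(labels == u[2]), populations = u)
}

#' Total grid entropy of a labelled 2D point set
#'
#' Places a sector grid over the points' bounding box (optionally shifted by
#' a fraction of the sector size), computes the Shannon index of the
#' two-population proportions in each sector, and sums over sectors. Empty
#' and single-population sectors contribute 0. Points on the right/top edge
#' of the box are clamped into the last sector.
#'
#' @param points2d C x 2 numeric matrix.
#' @param labels per-point population label (exactly 2 distinct values, each
#'   with >= 1 point).
#' @param grid a [grid_spec()].
#' @return total Shannon index (nats).
#' @export
grid_total_entropy <- function(points2d, labels, grid = grid_spec()) {
  points2d <- as.matrix(points2d)
  check_finite_matrix(points2d, "points2d")
  if (ncol(points2d) != 2) stop_input("points2d must have 2 columns")
  if (nrow(points2d) != length(labels)) {
    stop_input("labels length must match point count")
  }
  lc <- label_codes(labels)
  if (sum(lc$codes) == 0 || sum(lc$codes) == length(lc$codes)) {
    stop_input("each population needs at least one point")
  }
  cpp_grid_entropy(points2d, lc$codes,
                   grid$sectors_per_axis[1], grid$sectors_per_axis[2],
                   grid$shift_fractions[1], grid$shift_fractions[2])
}

entropy_result <- function(total_SI, grid, view, n_per_pop) {
  structure(list(total_SI = total_SI, grid = grid, view = view,
                 n_cells_per_population = n_per_pop),
            class = "EntropyResult")
}

#' @export
print.EntropyResult <- function(x, ...) {
  cat(sprintf("EntropyResult: total SI = %.6g nats (%s)\n", x$total_SI,
              if (is.null(x$view)) "2D"
              else sprintf("best angle [%.3f, %.3f, %.3f]",
                           x$view$direction[1], x$view$direction[2],
                           x$view$direction[3])))
  invisible(x)
}

#' Minimum grid entropy over stepwise grid shifts
#'
#' Evaluates [grid_total_entropy()] at every shift on an
#' `n_shift_steps x n_shift_steps` lattice of shift fractions
#' `k / n_shift_steps` (always including the unshifted grid) and keeps the
#' lowest total, so the grid placement itself does not drive the score. Ties
#' keep the first-evaluated (row-major) shift.
#'
#' @inheritParams grid_total_entropy
#' @param sectors_per_axis sectors per axis, recycled to length 2.
#' @param n_shift_steps shift lattice size per axis (>= 1).
#' @return an `EntropyResult` with the achieving `GridSpec`.
#' @export
min_entropy_over_shifts <- function(points2d, labels,
                                    sectors_per_axis = c(10, 10),
                                    n_shift_steps = 5) {
  points2d <- as.matrix(points2d)
  check_finite_matrix(points2d, "points2d")
  if (ncol(points2d) != 2) stop_input("points2d must have 2 columns")
  if (n_shift_steps < 1) stop_input("n_shift_steps must be >= 1")
  lc <- label_codes(labels)
  if (sum(lc$codes) == 0 || sum(lc$codes) == length(lc$codes)) {
    stop_input("each population needs at least one point")
  }
  s <- rep(as.integer(sectors_per_axis), length.out = 2)
  res <- cpp_entropy_shift_scan(points2d, lc$codes, s[1], s[2],
                                as.integer(n_shift_steps))
  g <- grid_spec(s, c(res$fx, res$fy))
  g$bounding_box <- apply(points2d, 2, range)
  entropy_result(res$total_si, g, NULL,
                 stats::setNames(c(sum(lc$codes == 0), sum(lc$codes == 1)),
                                 lc$populations))
}

# Cells belonging to a population, from a CellTypeTable or a named
# label vector/factor.
population_cells <- function(annotations, pop) {
  if (inherits(annotations, "CellTypeTable")) {
    if (!pop %in% annotations$type_names) {
      stop_input("unknown population '", pop, "'; available: ",
                 paste(annotations$type_names, collapse = ", "))
    }
    annotations$cell_ids[annotations$membership[, pop] == 1]
  } else {
    labs <- as.character(annotations)
    ids <- names(annotations)
    if (is.null(ids)) stop_input("annotation vector must be named by cell ID")
    if (!pop %in% labs) {
      stop_input("unknown population '", pop, "'; available: ",
                 paste(sort(unique(labs)), collapse = ", "))
    }
    ids[labs == pop]
  }
}

subset_pair <- function(embedding, annotations, pop_a, pop_b) {
  a_ids <- population_cells(annotations, pop_a)
  b_ids <- population_cells(annotations, pop_b)
  a_idx <- match(a_ids, embedding$cell_ids)
  b_idx <- match(b_ids, embedding$cell_ids)
  if (any(is.na(a_idx)) || any(is.na(b_idx))) {
    stop_input("annotation cell IDs missing from embedding")
  }
  if (length(a_idx) == 0 || length(b_idx) == 0) {
    stop_input("both populations must be non-empty")
  }
  list(points = embedding$coords[c(a_idx, b_idx), , drop = FALSE],
       labels = rep(c(pop_a, pop_b), c(length(a_idx), length(b_idx))))
}

#' Pairwise entropy overlap in a 2D embedding
#'
#' Restricts the embedding to the two populations, builds the sector grid
#' over that subset's bounding box, and minimizes the total Shannon index
#' over grid shifts.
#'
#' @param embedding a 2D [embedding_table()].
#' @param annotations a [celltype_table()] or named label vector.
#' @param pop_a,pop_b population names to compare.
#' @param sectors_per_axis,n_shift_steps grid parameters
#'   (see [min_entropy_over_shifts()]).
#' @return an `EntropyResult`.
#' @export
entropy_overlap_pair_2d <- function(embedding, annotations, pop_a, pop_b,
                                    sectors_per_axis = c(10, 10),
                                    n_shift_steps = 5) {
  pts <- embedding_points_2d(embedding)
  sub <- subset_pair_points(pts, embedding$cell_ids, annotations, pop_a, pop_b)
  min_entropy_over_shifts(sub$points, sub$labels, sectors_per_axis,
                          n_shift_steps)
}

#' Best-angle entropy overlap in a 3D embedding
#'
#' For every sampled viewing direction the two populations are flattened to
#' 2D and scored with [min_entropy_over_shifts()]; the lowest total over all
#' directions is returned together with the achieving direction (ties keep
#' the lowest direction index).
#'
#' @param embedding a 3D [embedding_table()].
#' @inheritParams entropy_overlap_pair_2d
#' @param angles an `AngleSet` from [sample_viewing_angles()].
#' @return an `EntropyResult` whose `view` is the best `ViewingDirection`;
#'   attribute `"per_angle"` holds the score at every direction.
#' @export
entropy_overlap_pair_3d <- function(embedding, annotations, pop_a, pop_b,
                                    angles = sample_viewing_angles(2048),
                                    sectors_per_axis = c(10, 10),
                                    n_shift_steps = 5) {
  if (embedding_dim(embedding) != 3) stop_input("embedding must be 3D")
  sub <- subset_pair(embedding, annotations, pop_a, pop_b)
  lc <- label_codes(sub$labels)
  s <- rep(as.integer(sectors_per_axis), length.out = 2)
  res <- cpp_entropy_angle_scan(sub$points, lc$codes, angles$rotations,
                                s[1], s[2], as.integer(n_shift_steps))
  g <- grid_spec(s, c(res$fx, res$fy))
  out <- entropy_result(res$total_si, g, angle_view(angles, res$angle_index),
                        stats::setNames(c(sum(lc$codes == 0), sum(lc$codes == 1)),
                                        lc$populations))
  attr(out, "per_angle") <- res$per_angle
  out
}

# 2D point matrix from an EmbeddingTable that is either natively 2D or a
# z-padded 3D table (constant third coordinate, as written by write_mds).
embedding_points_2d <- function(embedding) {
  coords <- embedding$coords
  if (ncol(coords) == 2) return(coords)
  zr <- range(coords[, 3])
  if (zr[1] == zr[2]) return(coords[, 1:2, drop = FALSE])
  stop_input("embedding '", embedding$name,
             "' is 3D; a 2D (or constant-z) embedding is required")
}

subset_pair_points <- function(points, cell_ids, annotations, pop_a, pop_b) {
  a_ids <- population_cells(annotations, pop_a)
  b_ids <- population_cells(annotations, pop_b)
  a_idx <- match(a_ids, cell_ids)
  b_idx <- match(b_ids, cell_ids)
  if (any(is.na(a_idx)) || any(is.na(b_idx))) {
    stop_input("annotation cell IDs missing from embedding")
  }
  if (length(a_idx) == 0 || length(b_idx) == 0) {
    stop_input("both populations must be non-empty")
  }
  list(points = points[c(a_idx, b_idx), , drop = FALSE],
       labels = rep(c(pop_a, pop_b), c(length(a_idx), length(b_idx))))
}
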