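#' Convex hull of a 2D point set (Quickhull)
#'
#' Computes the convex hull with the Quickhull algorithm. Degenerate inputs
#' (fewer than 3 distinct points, or all collinear) yield a polygon of area
#' 0; collinear boundary points are not retained as vertices.
#'
#' @param points C x 2 numeric matrix (C >= 1).
#' @return an object of class `ConvexPolygon`: list with `vertices` (ordered
#'   counter-clockwise) and `area` (shoelace formula).
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
#' convex_hull_2d(sq)$area # 1
#' @export
convex_hull_2d <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop_input("points must be non-empty")
  if (ncol(points) != 2) stop_input("points must have 2 columns")
  check_finite_matrix(points, "points")
  idx <- cpp_quickhull(points)
  vertices <- points[idx, , drop = FALSE]
  structure(list(vertices = vertices, area = polygon_area(vertices)),
            class = "ConvexPolygon")
}

#' @export
print.ConvexPolygon <- function(x, ...) {
  cat(sprintf("ConvexPolygon: %d vertices, area %.6g\n",
              nrow(x$vertices), x$area))
  invisible(x)
}

#' Shoelace area of an ordered polygon
#' @param vertices ordered 2D vertex matrix.
#' @return non-negative area (absolute value of the signed shoelace sum).
#' @export
polygon_area <- function(vertices) {
  vertices <- as.matrix(vertices)
  n <- nrow(vertices)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(vertices[, 1] * vertices[j, 2] - vertices[j, 1] * vertices[, 2])) / 2
}

as_polygon <- function(p) {
  if (inherits(p, "ConvexPolygon")) return(p)
  convex_hull_2d(p)
}

#' Intersection area of two convex polygons
#'
#' Convex-convex clipping (Sutherland-Hodgman): the first polygon is clipped
#' successively by each edge of the second, and the shoelace area of the
#' remainder is returned. Disjoint or degenerate (area-0) inputs give 0;
#' polygons that only touch at an edge or vertex give 0.
#'
#' @param p,q `ConvexPolygon`s (or point matrices, which are hulled first).
#' @return intersection area, clamped to `[0, min(area(p), area(q))]`.
#' @export
polygon_intersection_area <- function(p, q) {
  p <- as_polygon(p); q <- as_polygon(q)
  if (p$area <= 0 || q$area <= 0) return(0)
  cpp_convex_intersection_area(p$vertices, q$vertices)
}

hull_overlap_result <- function(lst, view = NULL) {
  structure(list(overlap_percent = lst$overlap_percent,
                 intersection_area = lst$intersection_area,
                 area_a = lst$area_a, area_b = lst$area_b,
                 degenerate = lst$degenerate, view = view),
            class = "HullOverlapResult")
}

#' @export
print.HullOverlapResult <- function(x, ...) {
  cat(sprintf("HullOverlapResult: %.2f%% of the smaller hull%s%s\n",
              x$overlap_percent,
              if (x$degenerate) " (degenerate hull)" else "",
              if (is.null(x$view)) ""
              else sprintf(", best angle [%.3f, %.3f, %.3f]",
                           x$view$direction[1], x$view$direction[2],
                           x$view$direction[3])))
  invisible(x)
}

#' Convex-hull overlap between two populations in 2D
#'
#' Builds both hulls and reports the intersection area as a percentage of
#' the smaller hull. If the smaller hull is degenerate (area 0) the overlap
#' is defined as 0 and flagged.
#'
#' @param points_a,points_b 2D point matrices (each >= 1 point).
#' @return a `HullOverlapResult`.
#' @export
hull_overlap_percent_2d <- function(points_a, points_b) {
  points_a <- as.matrix(points_a); points_b <- as.matrix(points_b)
  if (nrow(points_a) == 0 || nrow(points_b) == 0) {
    stop_input("both populations must be non-empty")
  }
  hull_overlap_result(cpp_hull_overlap_2d(points_a, points_b))
}

#' Minimum hull overlap over viewing angles
#'
#' Flattens both 3D populations along every sampled direction, evaluates
#' [hull_overlap_percent_2d()], and returns the direction with the least
#' overlap (exhaustive search; ties keep the lowest direction index).
#'
#' @param points3d_a,points3d_b C x 3 point matrices.
#' @param angles an `AngleSet` from [sample_viewing_angles()].
#' @return a `HullOverlapResult` with the best `ViewingDirection`; attribute
#'   `"per_angle"` holds the overlap percentage at every direction.
#' @export
min_hull_overlap_over_angles <- function(points3d_a, points3d_b,
                                         angles = sample_viewing_angles(2048)) {
  points3d_a <- as.matrix(points3d_a); points3d_b <- as.matrix(points3d_b)
  if (nrow(points3d_a) == 0 || nrow(points3d_b) == 0) {
    stop_input("both populations must be non-empty")
  }
  if (ncol(points3d_a) != 3 || ncol(points3d_b) != 3) {
    stop_input("points must have 3 columns")
  }
  stopifnot(inherits(angles, "AngleSet"))
  res <- cpp_hull_angle_scan(points3d_a, points3d_b, angles$rotations)
  out <- hull_overlap_result(res, angle_view(angles, res$angle_index))
  attr(out, "per_angle") <- res$per_angle
  out
}
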