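#' Build the rotation matrix for a viewing direction
#'
#' The rotation maps world coordinates to view coordinates; its third row is
#' the collapsed axis (the viewing direction). The in-plane orientation is
#' fixed by a deterministic up-vector rule: the view "up" axis is the
#' normalized projection of the world z-axis onto the viewing plane, falling
#' back to the world x-axis when the direction is within ~2.5 degrees of
#' +/- z (`|direction . z| > 0.999`).
#'
#' @param direction unit 3-vector to collapse.
#' @return an object of class `ViewingDirection`: list with `direction` and
#'   the 3 x 3 orthonormal `rotation` (determinant +1).
#' @export
view_direction <- function(direction) {
  direction <- as.numeric(direction)
  if (length(direction) != 3 || !all(is.finite(direction))) {
    stop_input("direction must be a finite 3-vector")
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop_input("direction must be non-zero")
  d <- direction / nrm
  ref <- if (abs(d[3]) > 0.999) c(1, 0, 0) else c(0, 0, 1)
  up <- ref - sum(ref * d) * d
  up <- up / sqrt(sum(up^2))
  e1 <- c(up[2] * d[3] - up[3] * d[2],
          up[3] * d[1] - up[1] * d[3],
          up[1] * d[2] - up[2] * d[1]) # up x d, so (e1, up, d) is right-handed
  rotation <- rbind(e1, up, d)
  dimnames(rotation) <- NULL
  structure(list(direction = d, rotation = rotation),
            class = "ViewingDirection")
}

#' Deterministically sample viewing directions on the unit sphere
#'
#' Uses the Fibonacci (golden-angle) spiral, which places `n` nearly uniform
#' points on the sphere and is bit-reproducible for a given `n`. Each
#' direction carries a rotation built by [view_direction()].
#'
#' @param n number of directions (>= 1); 2048 matches the published
#'   exhaustive search.
#' @return an object of class `AngleSet`: list with `n`, `directions`
#'   (n x 3), and `rotations` (n x 9, rows are the row-major 3 x 3 matrices).
#' @examples
#' a <- sample_viewing_angles(64)
#' range(sqrt(rowSums(a$directions^2))) # all unit norm
#' @export
sample_viewing_angles <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    stop_input("n must be a positive integer")
  }
  n <- as.integer(n)
  i <- seq_len(n) - 1L
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  directions <- cbind(r * cos(phi), r * sin(phi), z)
  rotations <- matrix(0, n, 9)
  for (k in seq_len(n)) {
    rotations[k, ] <- as.vector(t(view_direction(directions[k, ])$rotation))
  }
  structure(list(n = n, directions = directions, rotations = rotations),
            class = "AngleSet")
}

#' @export
print.AngleSet <- function(x, ...) {
  cat(sprintf("AngleSet: %d viewing directions (Fibonacci sphere)\n", x$n))
  invisible(x)
}

#' Extract one ViewingDirection from an AngleSet
#' @param angles an `AngleSet`.
#' @param i direction index (1-based).
#' @return a `ViewingDirection`.
#' @export
angle_view <- function(angles, i) {
  stopifnot(inherits(angles, "AngleSet"), i >= 1, i <= angles$n)
  structure(list(direction = angles$directions[i, ],
                 rotation = matrix(angles$rotations[i, ], 3, 3, byrow = TRUE)),
            class = "ViewingDirection")
}

#' Orthographically flatten 3D points along a viewing direction
#'
#' Returns the first two view coordinates of `rotation %*% p` for every
#' point; the collapsed axis is `view$direction`, emulating what a viewer
#' sees from that angle.
#'
#' @param points numeric C x 3 matrix.
#' @param view a `ViewingDirection` (see [view_direction()]).
#' @return C x 2 matrix of in-plane coordinates.
#' @export
flatten <- function(points, view) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop_input("points must have 3 columns")
  check_finite_matrix(points, "points")
  stopifnot(inherits(view, "ViewingDirection"))
  points %*% t(view$rotation[1:2, , drop = FALSE])
}
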