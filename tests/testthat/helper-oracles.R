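# Independent oracles, written from scratch so they never share code with the
# implementation paths they check.

# Shannon index by direct arithmetic on a proportion vector.
oracle_si <- function(p) {
  s <- 0
  for (pi in p) if (pi > 0) s <- s - pi * log(pi)
  s
}

# Total grid entropy by explicit per-point sector assignment (loops, no
# vectorized tricks). Mirrors the documented convention: half-open sectors,
# right/top edge clamped into the last sector, shifted grids gain one extra
# sector row/column.
oracle_grid_entropy <- function(pts, labels, sx, sy, fx = 0, fy = 0) {
  u <- sort(unique(labels))
  stopifnot(length(u) == 2)
  rng_x <- range(pts[, 1]); rng_y <- range(pts[, 2])
  wx <- (rng_x[2] - rng_x[1]) / sx
  wy <- (rng_y[2] - rng_y[1]) / sy
  if (wx <= 0) { wx <- 1e-9 / sx; rng_x[1] <- rng_x[1] - 5e-10 }
  if (wy <= 0) { wy <- 1e-9 / sy; rng_y[1] <- rng_y[1] - 5e-10 }
  maxbx <- if (fx > 0) sx else sx - 1
  maxby <- if (fy > 0) sy else sy - 1
  counts <- list()
  for (i in seq_len(nrow(pts))) {
    ix <- floor((pts[i, 1] - (rng_x[1] - fx * wx)) / wx)
    iy <- floor((pts[i, 2] - (rng_y[1] - fy * wy)) / wy)
    ix <- max(0, min(ix, maxbx))
    iy <- max(0, min(iy, maxby))
    key <- paste(ix, iy)
    if (is.null(counts[[key]])) counts[[key]] <- c(0, 0)
    which_pop <- if (labels[i] == u[1]) 1 else 2
    counts[[key]][which_pop] <- counts[[key]][which_pop] + 1
  }
  total <- 0
  for (cnt in counts) {
    n <- sum(cnt)
    total <- total + oracle_si(cnt / n)
  }
  total
}

# Exact two-sided Wilcoxon p by full enumeration of group allocations.
oracle_wilcox_exact_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(n, n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Point-in-convex-polygon (CCW vertices), boundary counts as inside.
oracle_in_poly <- function(px, py, vx, vy) {
  n <- length(vx)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    cr <- (vx[j] - vx[i]) * (py - vy[i]) - (vy[j] - vy[i]) * (px - vx[i])
    if (cr < -1e-12) return(FALSE)
  }
  TRUE
}

# Monte-Carlo estimate of the intersection area of two convex polygons:
# rejection sampling over the joint bounding box. Returns the estimate and
# its standard error.
oracle_mc_intersection <- function(p, q, n = 20000, seed = 1) {
  set.seed(seed)
  bx <- range(c(p[, 1], q[, 1])); by <- range(c(p[, 2], q[, 2]))
  sx <- runif(n, bx[1], bx[2]); sy <- runif(n, by[1], by[2])
  inside <- logical(n)
  for (i in seq_len(n)) {
    inside[i] <- oracle_in_poly(sx[i], sy[i], p[, 1], p[, 2]) &&
      oracle_in_poly(sx[i], sy[i], q[, 1], q[, 2])
  }
  box_area <- diff(bx) * diff(by)
  phat <- mean(inside)
  list(estimate = phat * box_area,
       se = sqrt(phat * (1 - phat) / n) * box_area)
}

# Benjamini-Hochberg by the textbook definition, quadratic loop.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    m <- Inf
    for (j in i:n) m <- min(m, p[o[j]] * n / j)
    adj[o[i]] <- min(1, m)
  }
  adj
}

# Random convex-position polygon: convex hull of points on a noisy circle.
random_convex_polygon <- function(nv = 8, seed = 1) {
  set.seed(seed)
  th <- sort(runif(nv, 0, 2 * pi))
  r <- runif(nv, 0.5, 1.5)
  cx <- runif(1, -1, 1); cy <- runif(1, -1, 1)
  pts <- cbind(cx + r * cos(th), cy + r * sin(th))
  convex_hull_2d(pts)
}

# Random proper 3D rotation via QR decomposition.
random_rotation3 <- function(seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
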