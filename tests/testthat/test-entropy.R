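test_that("shannon_index matches direct evaluation and validates input", {
  expect_equal(shannon_index(c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_identical(shannon_index(c(1, 0)), 0)
  expect_equal(shannon_index(c(0.9, 0.1)), 0.325083, tolerance = 1e-6)
  expect_error(shannon_index(c(-0.1, 1.1)), "non-negative")
  expect_error(shannon_index(c(0.5, 0.6)), "sum to 1")

  set.seed(5)
  for (i in 1:50) {
    p1 <- runif(1)
    expect_equal(shannon_index(c(p1, 1 - p1)), oracle_si(c(p1, 1 - p1)),
                 tolerance = 1e-12)
  }
})

test_that("grid_total_entropy matches the hand-enumeration oracle", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(6:50, 1)
    pts <- matrix(runif(2 * n), n, 2)
    labels <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("A", "B")
    got <- grid_total_entropy(pts, labels, grid_spec(c(2, 2)))
    expect_equal(got, oracle_grid_entropy(pts, labels, 2, 2),
                 tolerance = 1e-10)
    # and at a shifted grid
    got_s <- grid_total_entropy(pts, labels,
                                grid_spec(c(3, 2), c(0.4, 0.2)))
    expect_equal(got_s, oracle_grid_entropy(pts, labels, 3, 2, 0.4, 0.2),
                 tolerance = 1e-10)
  }
})

test_that("grid_total_entropy handles canonical cases and preconditions", {
  # two populations in disjoint sectors -> 0
  pts <- rbind(cbind(runif(10, 0, 0.4), runif(10)),
               cbind(runif(10, 0.6, 1), runif(10)))
  labels <- rep(c("A", "B"), each = 10)
  expect_identical(grid_total_entropy(pts, labels, grid_spec(c(2, 1))), 0)
  # 4 points, 2 per population, one sector -> ln 2
  pts1 <- rbind(c(0, 0), c(1, 1), c(0.4, 0.6), c(0.7, 0.2))
  expect_equal(grid_total_entropy(pts1, c("A", "A", "B", "B"),
                                  grid_spec(c(1, 1))), log(2),
               tolerance = 1e-12)
  expect_error(grid_total_entropy(pts1, rep("A", 4), grid_spec()),
               "exactly 2")
  # coincident clouds: every sector perfectly mixed
  pts2 <- rbind(pts1, pts1)
  expect_equal(grid_total_entropy(pts2, rep(c("A", "B"), each = 4),
                                  grid_spec(c(1, 1))), log(2),
               tolerance = 1e-12)
})

test_that("min_entropy_over_shifts is optimal over its lattice", {
  set.seed(23)
  for (rep in 1:10) {
    n <- 40
    pts <- matrix(rnorm(2 * n), n, 2)
    labels <- rep(c("A", "B"), each = n / 2)
    res <- min_entropy_over_shifts(pts, labels, c(4, 4), n_shift_steps = 4)
    # brute force over the full lattice
    brute <- Inf
    for (fx in (0:3) / 4) for (fy in (0:3) / 4) {
      brute <- min(brute, grid_total_entropy(pts, labels,
                                             grid_spec(c(4, 4), c(fx, fy))))
    }
    expect_equal(res$total_SI, brute, tolerance = 1e-12)
    # never worse than the unshifted grid
    expect_lte(res$total_SI,
               grid_total_entropy(pts, labels, grid_spec(c(4, 4))) + 1e-12)
    # n_shift_steps = 1 reduces to the unshifted grid
    res1 <- min_entropy_over_shifts(pts, labels, c(4, 4), n_shift_steps = 1)
    expect_equal(res1$total_SI,
                 grid_total_entropy(pts, labels, grid_spec(c(4, 4))),
                 tolerance = 1e-12)
  }
})

test_that("a shift that isolates the populations reaches zero entropy", {
  # gap (0.3, 0.31); with 2 sectors of width 0.50835 the boundary lands in
  # the gap only at shift fraction 0.4
  set.seed(9)
  ax <- c(0, runif(20, 0, 0.3), 0.3)
  bx <- c(0.31, runif(20, 0.31, 1.0167), 1.0167)
  pts <- cbind(c(ax, bx), runif(length(ax) + length(bx)))
  labels <- rep(c("A", "B"), c(length(ax), length(bx)))
  unshifted <- grid_total_entropy(pts, labels, grid_spec(c(2, 1)))
  expect_gt(unshifted, 0)
  res <- min_entropy_over_shifts(pts, labels, c(2, 1), n_shift_steps = 5)
  expect_identical(res$total_SI, 0)
  expect_equal(res$grid$shift_fractions[1], 0.4, tolerance = 1e-12)
})

test_that("3D best-angle entropy dominates every sampled direction", {
  pair <- make_axis_hidden_pair(separation = 10, sigma = 0.5, n_per_pop = 60,
                                seed = 4)
  angles <- sample_viewing_angles(64)
  res <- entropy_overlap_pair_3d(pair$embedding3d, pair$celltypes,
                                 "pop1", "pop2", angles = angles,
                                 sectors_per_axis = c(6, 6))
  per_angle <- attr(res, "per_angle")
  expect_length(per_angle, 64)
  expect_equal(res$total_SI, min(per_angle), tolerance = 1e-12)
  expect_true(all(res$total_SI <= per_angle + 1e-12))
  # blobs separated along z at 20 sigma: some angle views the gap edge-on
  expect_identical(res$total_SI, 0)
  # the achieving view is recorded and reproduces the score
  f <- flatten(pair$embedding3d$coords, res$view)
  labels <- rep(c("pop1", "pop2"), each = 60)
  redo <- min_entropy_over_shifts(f, labels, c(6, 6), 5)
  expect_equal(redo$total_SI, res$total_SI, tolerance = 1e-12)
})

test_that("coincident populations mix identically at every angle", {
  set.seed(31)
  base <- matrix(rnorm(90), 30, 3)
  pts <- rbind(base, base)
  ids <- sprintf("c%02d", 1:60)
  emb <- embedding_table(pts, cell_ids = ids, name = "coincident")
  labels <- stats::setNames(rep(c("A", "B"), each = 30), ids)
  res <- entropy_overlap_pair_3d(emb, labels, "A", "B",
                                 angles = sample_viewing_angles(32))
  per_angle <- attr(res, "per_angle")
  # every non-empty sector is perfectly mixed, so each angle's total is an
  # integer multiple of ln 2 (the count of non-empty sectors, which varies
  # with the projection); no angle can reach below one mixed sector
  mult <- per_angle / log(2)
  expect_true(all(abs(mult - round(mult)) < 1e-9))
  expect_gte(res$total_SI, log(2) - 1e-12)
  expect_equal(res$total_SI, min(per_angle), tolerance = 1e-12)
})

test_that("entropy scores are label-swap symmetric and shift-lattice monotone", {
  pair <- make_axis_hidden_pair(separation = 3, sigma = 1, n_per_pop = 50,
                                seed = 6)
  ab <- entropy_overlap_pair_2d(pair$embedding2d, pair$celltypes,
                                "pop1", "pop2")
  ba <- entropy_overlap_pair_2d(pair$embedding2d, pair$celltypes,
                                "pop2", "pop1")
  expect_identical(ab$total_SI, ba$total_SI)

  pts <- pair$embedding2d$coords
  labels <- rep(c("A", "B"), each = 50)
  prev <- Inf
  for (steps in c(1, 2, 4, 8)) {
    cur <- min_entropy_over_shifts(pts, labels, c(5, 5), steps)$total_SI
    # lattices k=1,2,4,8 are nested (fractions j/k), so the min can't rise
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }

  pair3 <- entropy_overlap_pair_3d(pair$embedding3d, pair$celltypes,
                                   "pop1", "pop2",
                                   angles = sample_viewing_angles(32))
  pair3_rev <- entropy_overlap_pair_3d(pair$embedding3d, pair$celltypes,
                                       "pop2", "pop1",
                                       angles = sample_viewing_angles(32))
  expect_identical(pair3$total_SI, pair3_rev$total_SI)
  expect_error(entropy_overlap_pair_2d(pair$embedding2d, pair$celltypes,
                                       "pop1", "nope"), "unknown population")
})
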