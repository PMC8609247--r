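test_that("wilcoxon_rank_sum matches exact enumeration on small samples", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_true(res$exact)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  expect_equal(res$statistic, 6)

  # identical multisets -> p = 1
  expect_equal(wilcoxon_rank_sum(c(2, 4, 6), c(2, 4, 6))$p_value, 1,
               tolerance = 1e-9)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "at least one")

  # all two-group splits of n <= 8 distinct values vs enumeration oracle
  set.seed(101)
  for (n in 4:8) {
    vals <- sort(sample(seq(1, 99, by = 2), n)) # distinct, no ties
    for (n1 in 1:(n - 1)) {
      combos <- utils::combn(n, n1)
      pick <- combos[, seq(1, ncol(combos),
                           length.out = min(8, ncol(combos)))]
      pick <- matrix(pick, nrow = n1)
      for (k in seq_len(ncol(pick))) {
        x <- vals[pick[, k]]
        y <- vals[-pick[, k]]
        got <- wilcoxon_rank_sum(x, y)
        expect_true(got$exact)
        expect_equal(got$p_value, oracle_wilcox_exact_p(x, y),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("normal approximation tracks the exact distribution at moderate n", {
  # validate the DP null distribution once against full enumeration at n = 20
  x0 <- seq(1, 19, by = 2); y0 <- seq(2, 20, by = 2)
  got <- wilcoxon_rank_sum(x0, y0) # exact path
  expect_true(got$exact)
  r <- rank(c(x0, y0))
  combos <- utils::combn(20, 10)
  w_all <- colSums(matrix(r[combos], nrow = 10))
  p_enum <- min(1, 2 * min(mean(w_all <= got$statistic),
                           mean(w_all >= got$statistic)))
  expect_equal(got$p_value, p_enum, tolerance = 1e-12)

  # approximate path (n = 24 > exact cutoff) vs the validated exact
  # distribution, over 100 random draws
  set.seed(55)
  worst <- 0
  cdf <- embedsep:::ranksum_null_cdf(12, 12)
  sums <- seq_along(cdf) - 1
  for (rep in 1:100) {
    x <- rnorm(12) * 7; y <- rnorm(12) * 7 + rnorm(1)
    res <- wilcoxon_rank_sum(x, y)
    expect_false(res$exact)
    w <- res$statistic
    p_exact <- min(1, 2 * min(sum(cdf[sums <= w]), sum(cdf[sums >= w])))
    worst <- max(worst, abs(res$p_value - p_exact))
  }
  expect_lt(worst, 0.01)
})

test_that("ties use midranks and the tie-corrected variance", {
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  got <- wilcoxon_rank_sum(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  # same p as the reference normal-approximation implementation
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  # statistic is the rank sum: reference reports U = W - n1(n1+1)/2
  expect_equal(got$statistic - length(x) * (length(x) + 1) / 2,
               unname(ref$statistic), tolerance = 1e-12)
})

test_that("bh_adjust matches the textbook oracle and stays monotone", {
  set.seed(77)
  for (rep in 1:20) {
    p <- runif(sample(1:10, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj <= 1) && all(adj >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
  # frozen hand computation: p = (0.01, 0.02, 0.03, 0.04), n = 4
  # adj_i = min_j>=i (n/j) p_(j) = (0.04, 0.04, 0.04, 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
})

test_that("differential_expression ranks known DE genes first", {
  blobs <- make_blobs_3d(blob_config(cells_per_population = 40, seed = 9))
  sim <- make_expression(blobs$celltypes,
                         expr_sim_config(n_genes = 300, de_fraction = 0.1,
                                         effect = 2, seed = 9))
  groups <- selection_groups(
    blobs$celltypes$cell_ids,
    ifelse(blobs$celltypes$membership[, "pop1"] == 1, "red", "blue"))
  de <- differential_expression(sim$expr, groups)
  expect_s3_class(de, "DEResult")
  expect_true(all(de$p_value >= 0 & de$p_value <= 1))
  expect_true(all(de$fdr >= de$p_value - 1e-12))
  expect_setequal(de$gene, rownames(sim$expr))
  top30 <- head(de$gene, 30)
  expect_gt(length(intersect(top30, sim$de_genes)), 25)
  # direction points at the population carrying the shift (pop2 = "blue"...
  # effect is applied to population 2, labelled red/blue by pop1 membership)
  top_dirs <- head(de$direction, 20)
  expect_true(all(top_dirs == top_dirs[1]))
})

test_that("differential_expression handles >2 groups one-vs-rest", {
  blobs <- make_blobs_3d(blob_config(n_populations = 3,
                                     cells_per_population = 20,
                                     centers = diag(3) * 10, seed = 10))
  sim <- make_expression(blobs$celltypes,
                         expr_sim_config(n_genes = 100, seed = 10))
  lab <- c("a", "b", "c")[apply(blobs$celltypes$membership, 1, which.max)]
  groups <- selection_groups(blobs$celltypes$cell_ids, lab)
  res <- differential_expression(sim$expr, groups)
  expect_named(res, c("a", "b", "c"))
  expect_s3_class(res$a, "DEResult")
  expect_error(differential_expression(
    sim$expr, selection_groups(paste0("nope", 1:4), rep(c("x", "y"), 2))),
    "no selected cells")
})

test_that("select_and_order_markers truncates and clusters", {
  blobs <- make_blobs_3d(blob_config(cells_per_population = 25, seed = 11))
  sim <- make_expression(blobs$celltypes,
                         expr_sim_config(n_genes = 100, seed = 11))
  groups <- selection_groups(
    blobs$celltypes$cell_ids,
    ifelse(blobs$celltypes$membership[, 1] == 1, "g1", "g2"))
  de <- differential_expression(sim$expr, groups)
  ord <- select_and_order_markers(de, sim$expr) # N = 250 > G = 100
  expect_length(ord, 100)
  expect_setequal(ord, de$gene)

  ord10 <- select_and_order_markers(de, sim$expr,
                                    analytics_config(N_top_markers = 10))
  expect_length(ord10, 10)
  expect_identical(sort(ord10), sort(head(de$gene, 10)))

  # duplicated expression rows end up adjacent in leaf order
  m <- unclass(sim$expr)[1:20, ]
  m[2, ] <- m[1, ]
  dup_expr <- expression_matrix(m, gene_names = paste0("g", 1:20),
                                cell_ids = colnames(sim$expr))
  de_small <- de[de$gene %in% rownames(sim$expr)[1:20], ]
  de_small$gene <- paste0("g", match(de_small$gene, rownames(sim$expr)[1:20]))
  class(de_small) <- c("DEResult", "data.frame")
  ord_dup <- select_and_order_markers(de_small, dup_expr)
  expect_equal(abs(diff(match(c("g1", "g2"), ord_dup))), 1)
})

test_that("network_edges scores proportional genes highest", {
  set.seed(33)
  n_cells <- 30
  base <- matrix(rexp(20 * n_cells), 20, n_cells)
  base[2, ] <- base[1, ] # exact copy under another name
  base[3, ] <- 5         # constant gene
  expr <- expression_matrix(base, gene_names = paste0("tf", 1:20),
                            cell_ids = paste0("c", 1:n_cells))
  edges <- network_edges(expr, paste0("tf", 1:20))
  expect_identical(attr(edges, "excluded"), "tf3")
  expect_identical(sort(c(edges$gene_a[1], edges$gene_b[1])),
                   c("tf1", "tf2"))
  expect_equal(edges$score[1], 1, tolerance = 1e-12)
  # fewer than K pairs -> all pairs (19 usable genes -> 171 pairs < 130? no:
  # use a small matrix to check truncation semantics both ways)
  expect_identical(nrow(edges), 130L)
  small <- expression_matrix(base[4:8, ], gene_names = paste0("s", 1:5),
                             cell_ids = paste0("c", 1:n_cells))
  e_small <- network_edges(small, paste0("s", 1:5))
  expect_identical(nrow(e_small), 10L) # C(5,2) < 130
  expect_error(network_edges(small, "s1"), "fewer than 2")
  # pearson alternative
  e_p <- network_edges(expr, paste0("tf", 1:20),
                       analytics_config(edge_score_method = "pearson"))
  expect_equal(e_p$score[1], 1, tolerance = 1e-12)
})

test_that("partition_for_trajectory is seeded k-means with k clusters", {
  blobs <- make_blobs_3d(blob_config(n_populations = 4,
                                     cells_per_population = 25,
                                     centers = rbind(c(0, 0, 0), c(20, 0, 0),
                                                     c(0, 20, 0), c(0, 0, 20)),
                                     sigma = 1, seed = 13))
  pts <- blobs$embedding$coords
  rownames(pts) <- blobs$embedding$cell_ids
  lab1 <- partition_for_trajectory(pts)
  lab2 <- partition_for_trajectory(pts)
  expect_identical(lab1, lab2)
  expect_identical(sort(unique(unname(lab1))), 1:4)
  expect_named(lab1, blobs$embedding$cell_ids)
  # well-separated blobs are recovered exactly (up to label permutation)
  truth <- rep(1:4, each = 25)
  expect_equal(length(unique(paste(truth, lab1))), 4)
  expect_error(partition_for_trajectory(pts[1:3, ]), "at least 4")
})

test_that("pseudotime_bins yields contiguous near-equal groups", {
  set.seed(14)
  pt <- stats::setNames(runif(100), sprintf("c%03d", 1:100))
  bins <- pseudotime_bins(pt)
  expect_identical(as.integer(table(bins)), rep(10L, 10))
  # bin index non-decreasing in pseudotime rank
  expect_true(all(diff(bins[order(pt, names(pt))]) >= 0))

  pt103 <- stats::setNames(runif(103), sprintf("c%03d", 1:103))
  b103 <- pseudotime_bins(pt103)
  sizes <- as.integer(table(b103))
  expect_identical(sort(sizes, decreasing = TRUE),
                   c(rep(11L, 3), rep(10L, 7)))
  # deterministic under ties: tie broken by cell ID
  ptt <- stats::setNames(rep(c(1, 2), each = 5), sprintf("c%02d", 10:1))
  b1 <- pseudotime_bins(ptt, analytics_config(n_pseudotime_bins = 2))
  b2 <- pseudotime_bins(ptt, analytics_config(n_pseudotime_bins = 2))
  expect_identical(b1, b2)
  expect_error(pseudotime_bins(c(1, NA)), "finite")
})

test_that("correlate_to_pseudotime ranks by absolute correlation", {
  set.seed(15)
  n <- 50
  pt <- stats::setNames(seq_len(n) / n, paste0("c", 1:n))
  m <- rbind(up = pt * 2 + rnorm(n, sd = 0.01),
             down = 1.5 - pt + rnorm(n, sd = 0.01),
             flat = rep(1, n),
             noise = rnorm(n) + 2)
  m <- pmax(m, 0)
  expr <- expression_matrix(m, gene_names = rownames(m), cell_ids = names(pt))
  ranked <- correlate_to_pseudotime(expr, pt)
  expect_setequal(ranked$gene[1:2], c("down", "up"))
  expect_identical(ranked$correlation[ranked$gene == "flat"], 0)
  expect_lt(ranked$correlation[ranked$gene == "down"], 0)
  expect_error(correlate_to_pseudotime(expr, pt[1:10]), "all cells")
})

test_that("defaults match the published parameters", {
  cfg <- analytics_config()
  expect_identical(cfg$N_top_markers, 250L)
  expect_identical(cfg$K_top_edges, 130L)
  expect_identical(cfg$n_trajectory_clusters, 4L)
  expect_identical(cfg$n_pseudotime_bins, 10L)
  expect_identical(cfg$edge_score_method, "rho")
  ccfg <- comparison_config()
  expect_identical(ccfg$n_angles, 2048L)
})
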