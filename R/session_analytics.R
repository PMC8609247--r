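#' Parameters for the in-session selection statistics
#'
#' Defaults follow the tool's published behaviour: top 250 marker genes for
#' the heatmap, top 130 network edges, 4 trajectory clusters, 10 pseudotime
#' bins, and proportionality ("rho") edge scoring.
#'
#' @param N_top_markers markers kept for the heatmap (default 250).
#' @param K_top_edges network edges returned (default 130).
#' @param n_trajectory_clusters clusters for the trajectory partition
#'   (default 4).
#' @param n_pseudotime_bins equal-size pseudotime colour groups (default 10).
#' @param edge_score_method `"rho"` (proportionality, default) or
#'   `"pearson"`.
#' @return an object of class `AnalyticsConfig`.
#' @export
analytics_config <- function(N_top_markers = 250, K_top_edges = 130,
                             n_trajectory_clusters = 4, n_pseudotime_bins = 10,
                             edge_score_method = c("rho", "pearson")) {
  edge_score_method <- match.arg(edge_score_method)
  if (N_top_markers < 1 || K_top_edges < 1 || n_trajectory_clusters < 1 ||
      n_pseudotime_bins < 1) {
    stop_input("all AnalyticsConfig counts must be positive")
  }
  structure(list(N_top_markers = as.integer(N_top_markers),
                 K_top_edges = as.integer(K_top_edges),
                 n_trajectory_clusters = as.integer(n_trajectory_clusters),
                 n_pseudotime_bins = as.integer(n_pseudotime_bins),
                 edge_score_method = edge_score_method),
            class = "AnalyticsConfig")
}

# Exact null distribution of the rank-sum of n1 out of ranks 1..n, by dynamic
# programming over "number of subsets of size k with rank sum s".
ranksum_null_cdf <- function(n1, n2) {
  n <- n1 + n2
  maxsum <- sum((n - n1 + 1):n)
  # counts[k+1, s+1] = number of k-subsets of {1..i} summing to s
  counts <- matrix(0, n1 + 1, maxsum + 1)
  counts[1, 1] <- 1
  for (i in seq_len(n)) {
    for (k in min(i, n1):1) {
      s_range <- (maxsum - i):0
      counts[k + 1, s_range + i + 1] <- counts[k + 1, s_range + i + 1] +
        counts[k, s_range + 1]
    }
  }
  counts[n1 + 1, ] / choose(n, n1)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with midranks for ties. The exact null
#' distribution (enumerated by dynamic programming) is used when
#' `n1 + n2 <= 20` and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction is applied.
#'
#' @param x,y numeric samples (each >= 1 value).
#' @return list with `statistic` (rank sum of `x`), `p_value` (two-sided)
#'   and `exact` (logical).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value # 0.1
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) {
    stop_input("both groups need at least one value")
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n <= 20) {
    cdf <- ranksum_null_cdf(n1, n2)
    sums <- seq_along(cdf) - 1
    p_lo <- sum(cdf[sums <= w])
    p_hi <- sum(cdf[sums >= w])
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(statistic = w, p_value = p, exact = TRUE))
  }
  mu <- n1 * (n + 1) / 2
  tie_tab <- table(r)
  sigma2 <- n1 * n2 * (n + 1) / 12 -
    n1 * n2 * sum(tie_tab^3 - tie_tab) / (12 * n * (n - 1))
  if (sigma2 <= 0) return(list(statistic = w, p_value = 1, exact = FALSE))
  d <- w - mu
  z <- (d - sign(d) * 0.5) / sqrt(sigma2)
  list(statistic = w, p_value = min(1, 2 * pnorm(-abs(z))), exact = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: `p_(i) * n / i`, made monotone
#' from the largest p downward and capped at 1.
#'
#' @param p numeric vector of p-values.
#' @return adjusted values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  i <- n:1
  out <- numeric(n)
  out[o] <- pmin(1, cummin(n / i * p[o]))
  out
}

#' Differential expression between selected cell groups
#'
#' With exactly two groups each gene is tested with
#' [wilcoxon_rank_sum()]; p-values are BH-adjusted across genes and genes
#' ranked by p (ties: larger absolute group-mean difference first, then gene
#' name). With more than two groups each group is tested against the union
#' of the rest and a per-group result list is returned.
#'
#' @param expr an [expression_matrix()].
#' @param groups a [selection_groups()] object.
#' @param config an [analytics_config()] (reserved for extensions).
#' @return an object of class `DEResult`: data.frame with `gene`,
#'   `statistic`, `p_value`, `fdr`, `delta` (group-1 minus group-2 mean) and
#'   `direction`, ordered for the heatmap; or a named list of `DEResult`s
#'   for > 2 groups.
#' @export
differential_expression <- function(expr, groups, config = analytics_config()) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(groups, "SelectionGroups"))
  present <- groups$cell_ids %in% colnames(expr)
  if (!any(present)) stop_input("no selected cells found in expression matrix")
  ids <- groups$cell_ids[present]
  glab <- groups$group[present]
  gnames <- sort(unique(glab))
  if (length(gnames) > 2) {
    res <- lapply(gnames, function(g) {
      sg <- selection_groups(ids, ifelse(glab == g, g, "rest"))
      differential_expression(expr, sg, config)
    })
    names(res) <- gnames
    return(res)
  }
  ia <- ids[glab == gnames[1]]
  ib <- ids[glab == gnames[2]]
  if (length(ia) < 2 || length(ib) < 2) {
    warning("a group has fewer than 2 cells; test power is minimal")
  }
  xa <- expr[, ia, drop = FALSE]
  xb <- expr[, ib, drop = FALSE]
  tests <- lapply(seq_len(nrow(expr)), function(i) {
    wilcoxon_rank_sum(xa[i, ], xb[i, ])
  })
  pv <- vapply(tests, `[[`, numeric(1), "p_value")
  st <- vapply(tests, `[[`, numeric(1), "statistic")
  delta <- rowMeans(xa) - rowMeans(xb)
  df <- data.frame(gene = rownames(expr), statistic = st, p_value = pv,
                   fdr = bh_adjust(pv), delta = delta,
                   direction = ifelse(delta >= 0, paste0("up_", gnames[1]),
                                      paste0("up_", gnames[2])),
                   stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(df$p_value, -abs(df$delta), df$gene)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "groups") <- gnames
  class(df) <- c("DEResult", "data.frame")
  df
}

#' Select and order the top marker genes for a heatmap
#'
#' Takes the `min(N, G)` top-ranked genes from a DE result and orders them
#' by the leaf order of a hierarchical clustering (Euclidean distance on
#' per-gene standardized expression, complete linkage).
#'
#' @param de a `DEResult` from [differential_expression()].
#' @param expr the [expression_matrix()] the test was run on.
#' @param config an [analytics_config()]; `N_top_markers` is used.
#' @return character vector of genes in heatmap row order; the `hclust`
#'   object is attached as attribute `"hclust"`.
#' @export
select_and_order_markers <- function(de, expr, config = analytics_config()) {
  stopifnot(inherits(de, "DEResult"))
  top <- head(de$gene, min(config$N_top_markers, nrow(de)))
  if (length(top) < 3) return(top)
  m <- expr[top, , drop = FALSE]
  sdv <- apply(m, 1, sd)
  ctr <- m - rowMeans(m)
  std <- ctr / ifelse(sdv > 0, sdv, 1)
  hc <- hclust(dist(std, method = "euclidean"), method = "complete")
  out <- top[hc$order]
  attr(out, "hclust") <- hc
  out
}

#' Transcription-factor network edge selection
#'
#' Scores every pair of TF genes within the selected cells and returns the
#' top `K_top_edges` by absolute score. The default score is a
#' proportionality coefficient computed on `log1p` expression,
#' `rho = 2 cov(a, b) / (var(a) + var(b))` - a transparent stand-in for the
#' rho statistic of compositional-proportionality packages, not numerically
#' identical to them. `"pearson"` correlation is available as an
#' alternative. Constant (zero-variance) genes are excluded from scoring and
#' listed in the `"excluded"` attribute.
#'
#' @param expr an [expression_matrix()] restricted to the selected group
#'   (>= 3 cells).
#' @param tf_genes character vector of transcription-factor gene names
#'   (e.g. from an AnimalTFDB export); >= 2 must be present in `expr`.
#' @param config an [analytics_config()].
#' @return data.frame with `gene_a`, `gene_b`, `score`, ordered by
#'   decreasing absolute score.
#' @export
network_edges <- function(expr, tf_genes, config = analytics_config()) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (ncol(expr) < 3) stop_input("need at least 3 cells to score edges")
  tfs <- intersect(tf_genes, rownames(expr))
  if (length(tfs) < 2) stop_input("fewer than 2 TF genes present in matrix")
  m <- log1p(expr[tfs, , drop = FALSE])
  v <- apply(m, 1, var)
  excluded <- tfs[v == 0]
  tfs <- tfs[v > 0]
  if (length(tfs) < 2) stop_input("fewer than 2 non-constant TF genes")
  m <- m[tfs, , drop = FALSE]
  if (config$edge_score_method == "rho") {
    cv <- cov(t(m))
    vs <- diag(cv)
    score_mat <- 2 * cv / outer(vs, vs, `+`)
  } else {
    score_mat <- cor(t(m))
  }
  pair_idx <- which(upper.tri(score_mat), arr.ind = TRUE)
  edges <- data.frame(gene_a = tfs[pair_idx[, 1]], gene_b = tfs[pair_idx[, 2]],
                      score = score_mat[pair_idx], stringsAsFactors = FALSE)
  edges <- edges[order(-abs(edges$score), edges$gene_a, edges$gene_b), ]
  edges <- head(edges, config$K_top_edges)
  rownames(edges) <- NULL
  attr(edges, "excluded") <- excluded
  edges
}

#' Partition selected cells for trajectory inference
#'
#' K-means (fixed seed, 10 restarts) with `n_trajectory_clusters` clusters;
#' the labels are the input partition expected by an external trajectory
#' tool such as a slingshot run (which itself is out of scope here).
#'
#' @param points3d C x 3 coordinate matrix of the selected cells, rownames
#'   used as cell IDs when present.
#' @param config an [analytics_config()].
#' @param seed RNG seed for the k-means restarts (default 1).
#' @return named integer vector of cluster labels (1..k).
#' @export
partition_for_trajectory <- function(points3d, config = analytics_config(),
                                     seed = 1) {
  points3d <- as.matrix(points3d)
  k <- config$n_trajectory_clusters
  if (nrow(points3d) < k) {
    stop_input("need at least ", k, " cells for ", k, " clusters")
  }
  km <- with_seed(seed, kmeans(points3d, centers = k, nstart = 10))
  stats::setNames(km$cluster, rownames(points3d))
}

#' Split cells into equal-size pseudotime bins
#'
#' Cells are ranked by pseudotime (ties broken by cell ID) and cut into
#' `n_pseudotime_bins` contiguous groups whose sizes differ by at most one;
#' when the count does not divide evenly the earliest bins take the extra
#' cell.
#'
#' @param pseudotime numeric vector, named by cell ID (names optional but
#'   required for deterministic tie-breaking).
#' @param config an [analytics_config()].
#' @return integer bin index (1 = earliest) per cell, in input order.
#' @export
pseudotime_bins <- function(pseudotime, config = analytics_config()) {
  pt <- as.numeric(pseudotime)
  if (any(!is.finite(pt))) stop_input("pseudotime values must be finite")
  n <- length(pt)
  k <- min(config$n_pseudotime_bins, n)
  ids <- names(pseudotime)
  if (is.null(ids)) ids <- sprintf("%09d", seq_len(n))
  ord <- order(pt, ids)
  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  bins_sorted <- rep(seq_len(k), times = sizes)
  out <- integer(n)
  out[ord] <- bins_sorted
  stats::setNames(out, names(pseudotime))
}

#' Rank genes by correlation to pseudotime
#'
#' Pearson correlation of each gene's expression with the pseudotime value,
#' ranked by absolute correlation; constant genes get correlation 0.
#'
#' @param expr an [expression_matrix()] over the selected cells.
#' @param pseudotime numeric vector named by cell ID (or aligned to the
#'   matrix columns).
#' @return data.frame with `gene` and `correlation`, ordered by decreasing
#'   `|correlation|` (ties by gene name).
#' @export
correlate_to_pseudotime <- function(expr, pseudotime) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!is.null(names(pseudotime))) {
    if (!all(colnames(expr) %in% names(pseudotime))) {
      stop_input("pseudotime must be defined for all cells in the matrix")
    }
    pseudotime <- pseudotime[colnames(expr)]
  } else if (length(pseudotime) != ncol(expr)) {
    stop_input("pseudotime length must match the number of cells")
  }
  pt <- as.numeric(pseudotime)
  sds <- apply(expr, 1, sd)
  cc <- numeric(nrow(expr))
  ok <- sds > 0 & sd(pt) > 0
  if (any(ok)) {
    cc[ok] <- as.numeric(cor(t(expr[ok, , drop = FALSE]), pt))
  }
  df <- data.frame(gene = rownames(expr), correlation = cc,
                   stringsAsFactors = FALSE)
  df <- df[order(-abs(df$correlation), df$gene), ]
  rownames(df) <- NULL
  df
}
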