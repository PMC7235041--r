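#' Group-average node DMs for one region class
#'
#' For every node carrying `region_class` in the label map, the entry-wise
#' mean of the subjects' condensed DMs (subjects missing at a node are
#' skipped node-wise). Nodes averaging to a constant vector, or with no
#' contributing subject, are flagged degenerate and excluded from clustering.
#'
#' @param dm_maps List of [searchlight_dm_map()] results (one group, or a
#'   split-half subset of it).
#' @param labels A [overlay_and_cluster()] region label map.
#' @param region_class One of `"A_only"`, `"B_only"`, `"overlap"`.
#' @return `region_node_dms`: list with `region_class`, `group`, `nodes`
#'   (node indices), `dms` (condensed-pair x node matrix), `degenerate`
#'   (logical per node), `items`.
#' @export
region_average_dms <- function(dm_maps, labels, region_class) {
  region_class <- match.arg(region_class, c("A_only", "B_only", "overlap"))
  nodes <- which(labels$node_label == region_class)
  if (length(nodes) == 0L) {
    stop(sprintf("region class '%s' is empty", region_class), call. = FALSE)
  }
  n_pairs <- nrow(dm_maps[[1]]$dms)
  acc <- matrix(0, n_pairs, length(nodes))
  cnt <- integer(length(nodes))
  for (m in dm_maps) {
    ok <- !m$missing[nodes]
    acc[, ok] <- acc[, ok] + m$dms[, nodes[ok], drop = FALSE]
    cnt[ok] <- cnt[ok] + 1L
  }
  avg <- sweep(acc, 2, pmax(cnt, 1L), "/")
  sds <- apply(avg, 2, stats::sd)
  degenerate <- cnt == 0L | !is.finite(sds) |
    sds <= 1e-12 * pmax(1, apply(abs(avg), 2, max))
  avg[, degenerate] <- NA_real_
  structure(list(region_class = region_class, group = dm_maps[[1]]$group,
                 nodes = nodes, dms = avg, degenerate = degenerate,
                 items = dm_maps[[1]]$items),
            class = "region_node_dms")
}

# mean-center and unit-normalize each column (node DM) -> Ward feature space
normalize_columns <- function(x) {
  xc <- x - rep(colMeans(x), each = nrow(x))
  ss <- sqrt(colSums(xc^2))
  sweep(xc, 2, ss, "/")
}

ward_tree <- function(region) {
  use <- which(!region$degenerate)
  if (length(use) < 2L) stop("fewer than 2 usable region nodes", call. = FALSE)
  feats <- normalize_columns(region$dms[, use, drop = FALSE])
  h <- stats::hclust(stats::dist(t(feats)), method = "ward.D2")
  list(h = h, use = use)
}

#' Ward clustering of region node DMs
#'
#' Agglomerative Ward linkage (Euclidean distance on mean-centered,
#' unit-normalized condensed node DMs) cut at `k` clusters.
#'
#' @param region A [region_average_dms()] result.
#' @param k Number of clusters, `2 <= k <=` number of usable region nodes.
#' @return `cluster_solution`: list with `k`, `node_assignment` (integer per
#'   region node, `NA` for degenerate nodes), `nodes`, `linkage = "ward"`,
#'   and the underlying `hclust` tree.
#' @export
ward_cluster <- function(region, k) {
  wt <- ward_tree(region)
  if (k < 2 || k > length(wt$use)) {
    stop("`k` out of range [2, number of usable nodes]", call. = FALSE)
  }
  assignment <- rep(NA_integer_, length(region$nodes))
  assignment[wt$use] <- stats::cutree(wt$h, k = k)
  structure(list(k = as.integer(k), node_assignment = assignment,
                 nodes = region$nodes, linkage = "ward", tree = wt$h),
            class = "cluster_solution")
}

#' Split-half cross-validated selection of the cluster count
#'
#' For each repetition the group's subjects are randomly split into two
#' halves; each half's region-average node DMs are Ward-clustered at every
#' candidate `k`, and reproducibility(k) is the adjusted Rand index between
#' the two halves' node assignments (over nodes usable in both halves). The
#' selected `k_star` maximizes mean reproducibility, ties broken toward the
#' smallest `k`.
#'
#' @inheritParams region_average_dms
#' @param k_range Integer vector `c(k_min, k_max)` (default `c(2, 100)`);
#'   truncated with a warning to half the region's node count, because the
#'   adjusted Rand index between two near-singleton partitions is trivially
#'   close to 1 regardless of the data.
#' @param n_repetitions Number of random split-half repetitions.
#' @param seed Integer seed for the splits.
#' @return `k_selection_trace`: list with `ks`, `reproducibility_by_k`,
#'   `k_star`, `n_repetitions`, `seed`.
#' @export
select_k_split_half <- function(dm_maps, labels, region_class,
                                k_range = c(2, 100), n_repetitions = 100,
                                seed = 1) {
  n_sub <- length(dm_maps)
  if (n_sub < 4L) stop("need >= 4 subjects for split halves", call. = FALSE)
  nodes <- which(labels$node_label == region_class)
  if (length(nodes) < 2L) stop("region has fewer than 2 nodes", call. = FALSE)
  # ARI between two partitions degenerates to 1 as k approaches the node
  # count (all-singleton partitions are identical by construction), so k is
  # capped at half the region size -- clusters must average >= 2 nodes.
  k_max <- min(k_range[2], max(2L, floor(length(nodes) / 2)))
  if (k_max < k_range[2]) {
    warning(sprintf("k range truncated to [%d, %d] (region has %d nodes)",
                    k_range[1], k_max, length(nodes)))
  }
  ks <- seq.int(k_range[1], k_max)
  if (length(ks) == 0L) stop("empty k range after truncation", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rep_scores <- matrix(NA_real_, n_repetitions, length(ks))
  for (r in seq_len(n_repetitions)) {
    shuffled <- sample.int(n_sub)
    h1 <- shuffled[seq_len(floor(n_sub / 2))]
    h2 <- shuffled[(floor(n_sub / 2) + 1):n_sub]
    r1 <- region_average_dms(dm_maps[h1], labels, region_class)
    r2 <- region_average_dms(dm_maps[h2], labels, region_class)
    t1 <- ward_tree(r1)
    t2 <- ward_tree(r2)
    common <- intersect(t1$use, t2$use)
    if (length(common) < 2L) next
    kk <- ks[ks <= min(length(t1$use), length(t2$use))]
    if (length(kk) == 0L) next
    c1 <- as.matrix(stats::cutree(t1$h, k = kk))[match(common, t1$use), , drop = FALSE]
    c2 <- as.matrix(stats::cutree(t2$h, k = kk))[match(common, t2$use), , drop = FALSE]
    for (ki in seq_along(kk)) {
      rep_scores[r, match(kk[ki], ks)] <-
        mclust::adjustedRandIndex(c1[, ki], c2[, ki])
    }
  }
  mean_rep <- colMeans(rep_scores, na.rm = TRUE)
  k_star <- ks[which.max(mean_rep)]  # which.max returns first max: smallest k
  structure(list(ks = ks, reproducibility_by_k = mean_rep,
                 per_repetition = rep_scores, k_star = k_star,
                 n_repetitions = n_repetitions, seed = seed),
            class = "k_selection_trace")
}

#' @export
print.k_selection_trace <- function(x, ...) {
  cat(sprintf("<k_selection_trace> k in [%d, %d], %d repetitions: k* = %d (mean ARI %.3f)\n",
              min(x$ks), max(x$ks), x$n_repetitions, x$k_star,
              max(x$reproducibility_by_k)))
  invisible(x)
}

#' Define informational networks from a cluster solution
#'
#' One network per cluster, with stable ids ordered by decreasing node count
#' (ties toward the smallest member node index).
#'
#' @param solution A [ward_cluster()] result.
#' @param group,region_class Labels carried on each network.
#' @return List of `informational_network` objects (fields `network_id`,
#'   `group`, `region_class`, `nodes`), partitioning the clustered nodes.
#' @export
define_networks <- function(solution, group, region_class) {
  by_cluster <- split(solution$nodes[!is.na(solution$node_assignment)],
                      solution$node_assignment[!is.na(solution$node_assignment)])
  sizes <- lengths(by_cluster)
  mins <- vapply(by_cluster, min, numeric(1))
  ord <- order(-sizes, mins)
  lapply(seq_along(ord), function(rank) {
    structure(list(network_id = sprintf("%s_%s_net%02d", region_class, group, rank),
                   group = group, region_class = region_class,
                   nodes = sort(as.integer(by_cluster[[ord[rank]]]))),
              class = "informational_network")
  })
}

#' @export
print.informational_network <- function(x, ...) {
  cat(sprintf("<informational_network> %s: %d nodes (%s, %s)\n",
              x$network_id, length(x$nodes), x$group, x$region_class))
  invisible(x)
}
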