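#' Surface-searchlight DM map for one subject
#'
#' At every surface node, each item's feature vector is that item's pattern
#' values over the node's k-ring neighborhood, and the node's DM is the
#' correlation distance (`1 - Pearson r`) between all item pairs (see
#' [compute_item_dm()]). Nodes with a degenerate pattern (any zero-variance
#' item vector, or a neighborhood of fewer than 2 nodes) are flagged missing.
#'
#' @param betas Numeric matrix, items x nodes, of per-item pattern estimates
#'   (GLM beta-like, arbitrary units), item ids as row names.
#' @param mesh `whole_brain_surface` (or `surface_mesh`) the columns index.
#' @param rings Searchlight patch radius in edge hops (default 2).
#' @param neighborhoods Optional precomputed [all_neighborhoods()] list,
#'   reused across subjects for speed.
#' @param subject_id,group Labels carried on the result.
#' @return `subject_dm_map`: list with `dms` (condensed-pair x node matrix),
#'   `missing` (logical per node), `items`, `subject_id`, `group`, `rings`.
#' @export
searchlight_dm_map <- function(betas, mesh, rings = 2, neighborhoods = NULL,
                               subject_id = "subject", group = "groupA") {
  betas <- as.matrix(betas)
  n_items <- nrow(betas)
  if (n_items < 2L) stop("need at least 2 items", call. = FALSE)
  n_nodes <- length(mesh_adjacency(mesh))
  if (ncol(betas) != n_nodes) {
    stop("`betas` column count does not match mesh node count", call. = FALSE)
  }
  items <- rownames(betas)
  if (is.null(items)) items <- paste0("item", seq_len(n_items))
  if (is.null(neighborhoods)) neighborhoods <- all_neighborhoods(mesh, rings)

  n_pairs <- n_items * (n_items - 1) / 2
  dms <- matrix(NA_real_, n_pairs, n_nodes)
  missing <- logical(n_nodes)
  lower <- lower.tri(matrix(0, n_items, n_items))
  for (v in seq_len(n_nodes)) {
    X <- betas[, neighborhoods[[v]], drop = FALSE]
    if (ncol(X) < 2L) { missing[v] <- TRUE; next }
    xc <- X - rowMeans(X)
    ss <- rowSums(xc^2)
    if (any(ss == 0) || any(!is.finite(ss))) { missing[v] <- TRUE; next }
    r <- tcrossprod(xc / sqrt(ss))
    dms[, v] <- 1 - r[lower]
  }
  structure(list(dms = dms, missing = missing, items = items,
                 subject_id = subject_id, group = group, rings = rings),
            class = "subject_dm_map")
}

#' @export
print.subject_dm_map <- function(x, ...) {
  cat(sprintf("<subject_dm_map> %s (%s): %d items at %d nodes (%.1f%% missing)\n",
              x$subject_id, x$group, length(x$items), ncol(x$dms),
              100 * mean(x$missing)))
  invisible(x)
}

# Mean Fisher-z intersubject DM correlation per node for a list of condensed
# DM matrices (one per subject). `miss` is a subjects x nodes logical matrix.
node_mean_z <- function(dms_list, miss, clip_eps = 1e-7) {
  n_sub <- length(dms_list)
  n_nodes <- ncol(dms_list[[1]])
  z <- rep(NA_real_, n_nodes)
  for (v in seq_len(n_nodes)) {
    valid <- which(!miss[, v])
    if (length(valid) < 2L) next
    X <- vapply(dms_list[valid], function(d) d[, v], numeric(nrow(dms_list[[1]])))
    xc <- X - rep(colMeans(X), each = nrow(X))
    ss <- colSums(xc^2)
    ok <- ss > 0
    if (sum(ok) < 2L) next
    u <- xc[, ok, drop = FALSE] / rep(sqrt(ss[ok]), each = nrow(xc))
    r <- crossprod(u)
    z[v] <- mean(fisher_z(r[lower.tri(r)], clip_eps))
  }
  z
}

#' Within-group intersubject convergence map
#'
#' At every node: the Pearson correlation of condensed DM vectors for every
#' pair of subjects, Fisher z-transformed, then averaged. Subject pairs where
#' a subject is missing at a node (degenerate searchlight pattern) are
#' dropped node-wise; a node with fewer than one valid pair is missing.
#'
#' @param dm_maps List of [searchlight_dm_map()] results for one group
#'   (>= 2 subjects, identical mesh and item order).
#' @param clip_eps Clipping margin for [fisher_z()].
#' @return `convergence_map`: list with `node_z`, `n_subjects`, `n_pairs`,
#'   `group`, `items`.
#' @export
intersubject_convergence <- function(dm_maps, clip_eps = 1e-7) {
  if (length(dm_maps) < 2L) {
    stop("need at least 2 subjects in a group", call. = FALSE)
  }
  items <- dm_maps[[1]]$items
  for (m in dm_maps) {
    if (!identical(m$items, items) || ncol(m$dms) != ncol(dm_maps[[1]]$dms)) {
      stop("subject maps differ in items or mesh", call. = FALSE)
    }
  }
  miss <- do.call(rbind, lapply(dm_maps, function(m) m$missing))
  z <- node_mean_z(lapply(dm_maps, function(m) m$dms), miss, clip_eps)
  n <- length(dm_maps)
  structure(list(node_z = z, n_subjects = n, n_pairs = n * (n - 1) / 2,
                 group = dm_maps[[1]]$group, items = items),
            class = "convergence_map")
}

#' @export
print.convergence_map <- function(x, ...) {
  fin <- x$node_z[is.finite(x$node_z)]
  cat(sprintf("<convergence_map> group %s: %d subjects (%d pairs), %d nodes; z in [%.3f, %.3f]\n",
              x$group, x$n_subjects, x$n_pairs, length(x$node_z),
              min(fin), max(fin)))
  invisible(x)
}

#' Negative-extent noise threshold
#'
#' A negative intersubject DM correlation can only arise from noise, so the
#' magnitude of the map's negative extent estimates the range of chance
#' correlation values: the threshold is `|min(node_z)|` when the minimum is
#' negative and 0 (with a warning) otherwise. Downstream thresholding is
#' strict (`z > threshold`).
#'
#' @param map A [intersubject_convergence()] result.
#' @return Threshold z value with attribute `all_positive`.
#' @export
estimate_noise_threshold <- function(map) {
  vals <- map$node_z[is.finite(map$node_z)]
  if (length(vals) == 0L) stop("map has no finite nodes", call. = FALSE)
  mn <- min(vals)
  if (mn < 0) {
    structure(-mn, all_positive = FALSE)
  } else {
    warning("no negative correlations observed; noise threshold set to 0")
    structure(0, all_positive = TRUE)
  }
}

#' Permutation null distribution for the convergence map
#'
#' For each permutation, every subject's item labels are shuffled
#' independently but consistently across that subject's nodes (which permutes
#' the condensed DM entries), and the node-level mean-z map is recomputed.
#' Either the map-wise maximum or all node values are recorded.
#'
#' @inheritParams intersubject_convergence
#' @param n_permutations Number of permutations (>= 1).
#' @param seed Integer seed; fixed seed gives identical null values.
#' @param statistic `"max"` (map maximum per permutation, default) or
#'   `"nodewise"` (full node map per permutation).
#' @return `permutation_null`: list with `null_values` (vector, or matrix of
#'   permutations x nodes), `n_permutations`, `seed`, `scheme`.
#' @export
permutation_null <- function(dm_maps, n_permutations, seed,
                             statistic = c("max", "nodewise"),
                             clip_eps = 1e-7) {
  statistic <- match.arg(statistic)
  if (length(dm_maps) < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (n_permutations < 1) stop("`n_permutations` must be >= 1", call. = FALSE)
  n_items <- length(dm_maps[[1]]$items)
  pr <- which(lower.tri(matrix(0, n_items, n_items)), arr.ind = TRUE)
  pi_ <- pr[, "col"]  # pair (i, j), i < j, in dist order
  pj <- pr[, "row"]
  miss <- do.call(rbind, lapply(dm_maps, function(m) m$missing))
  dms <- lapply(dm_maps, function(m) m$dms)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- vector("list", n_permutations)
  for (p in seq_len(n_permutations)) {
    perm_dms <- lapply(dms, function(d) {
      perm <- sample.int(n_items)
      a <- pmin(perm[pi_], perm[pj])
      b <- pmax(perm[pi_], perm[pj])
      d[dist_pair_index(a, b, n_items), , drop = FALSE]
    })
    z <- node_mean_z(perm_dms, miss, clip_eps)
    out[[p]] <- if (statistic == "max") max(z[is.finite(z)]) else z
  }
  null_values <- if (statistic == "max") unlist(out) else do.call(rbind, out)
  structure(list(null_values = null_values, n_permutations = n_permutations,
                 seed = seed, statistic = statistic,
                 scheme = "within-subject item-label shuffle, consistent across nodes"),
            class = "permutation_null")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Overlay two group convergence maps and cluster-correct
#'
#' Labels each node `overlap` if both groups exceed the noise threshold
#' (strictly), `A_only`/`B_only` if exactly one does, `none` otherwise; then
#' removes, per label class, connected components smaller than
#' `min_cluster_size` contiguous nodes (shared-edge contiguity).
#'
#' @param map_a,map_b [intersubject_convergence()] maps on the same mesh.
#' @param threshold Non-negative z threshold (typically the stricter of the
#'   two groups' [estimate_noise_threshold()] values).
#' @param min_cluster_size Minimum surviving component size (default 5).
#' @param mesh The surface the maps live on.
#' @return `region_label_map`: list with `node_label` (factor with levels
#'   `A_only`, `B_only`, `overlap`, `none`), `threshold_used`,
#'   `min_cluster_size`.
#' @export
overlay_and_cluster <- function(map_a, map_b, threshold, min_cluster_size = 5,
                                mesh) {
  if (length(map_a$node_z) != length(map_b$node_z) ||
      length(map_a$node_z) != length(mesh_adjacency(mesh))) {
    stop("maps and mesh are incompatible", call. = FALSE)
  }
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)
  ex_a <- is.finite(map_a$node_z) & map_a$node_z > threshold
  ex_b <- is.finite(map_b$node_z) & map_b$node_z > threshold
  label <- rep("none", length(ex_a))
  label[ex_a & ex_b] <- "overlap"
  label[ex_a & !ex_b] <- "A_only"
  label[!ex_a & ex_b] <- "B_only"
  for (cls in c("A_only", "B_only", "overlap")) {
    comps <- connected_components(which(label == cls), mesh)
    for (comp in comps) {
      if (length(comp) < min_cluster_size) label[comp] <- "none"
    }
  }
  structure(list(node_label = factor(label,
                                     levels = c("A_only", "B_only", "overlap", "none")),
                 threshold_used = as.numeric(threshold),
                 min_cluster_size = min_cluster_size),
            class = "region_label_map")
}

#' @export
print.region_label_map <- function(x, ...) {
  tab <- table(x$node_label)
  cat(sprintf("<region_label_map> z > %.4f, min cluster %d: A_only %d, B_only %d, overlap %d, none %d\n",
              x$threshold_used, x$min_cluster_size,
              tab[["A_only"]], tab[["B_only"]], tab[["overlap"]], tab[["none"]]))
  invisible(x)
}
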