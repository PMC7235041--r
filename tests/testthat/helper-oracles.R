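# Independent brute-force oracles, kept free of the package's code paths.

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# pairwise correlation-distance DM by explicit double loop, dist pair order
oracle_dm <- function(patterns) {
  n <- nrow(patterns)
  out <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out <- c(out, 1 - oracle_pearson(patterns[i, ], patterns[j, ]))
    }
  }
  out
}

oracle_one_sample_t <- function(v) {
  n <- length(v)
  t <- mean(v) / (stats::sd(v) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

# union-find components of a node subset over mesh edges
oracle_components <- function(node_set, edges) {
  node_set <- sort(unique(node_set))
  parent <- stats::setNames(node_set, node_set)
  find <- function(x) {
    while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
    x
  }
  in_set <- edges[, 1] %in% node_set & edges[, 2] %in% node_set
  for (e in which(in_set)) {
    ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
    if (ra != rb) parent[[as.character(ra)]] <- rb
  }
  roots <- vapply(node_set, find, numeric(1))
  comps <- unname(split(node_set, roots))
  comps <- lapply(comps, sort)
  sizes <- lengths(comps)
  mins <- vapply(comps, min, numeric(1))
  comps[order(-sizes, mins)]
}

# mean Fisher-z intersubject correlation at one node, by explicit loops
oracle_node_z <- function(dms, clip_eps = 1e-7) {
  n <- length(dms)
  zs <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- oracle_pearson(dms[[i]], dms[[j]])
      r <- min(max(r, -1 + clip_eps), 1 - clip_eps)
      zs <- c(zs, atanh(r))
    }
  }
  mean(zs)
}

# build a subject_dm_map-shaped object directly from a condensed-DM matrix
fake_dm_map <- function(dms, items = NULL, subject_id = "s", group = "expert",
                        missing = NULL) {
  if (is.null(items)) {
    n <- (1 + sqrt(1 + 8 * nrow(dms))) / 2
    items <- paste0("item", seq_len(round(n)))
  }
  if (is.null(missing)) missing <- rep(FALSE, ncol(dms))
  structure(list(dms = dms, missing = missing, items = items,
                 subject_id = subject_id, group = group, rings = NA),
            class = "subject_dm_map")
}

# region label map covering given nodes with one class
fake_labels <- function(n_nodes, nodes, class = "A_only") {
  lab <- rep("none", n_nodes)
  lab[nodes] <- class
  structure(list(node_label = factor(lab, levels = c("A_only", "B_only",
                                                     "overlap", "none")),
                 threshold_used = 0, min_cluster_size = 1),
            class = "region_label_map")
}

default_items24 <- sprintf("item%02d", 1:24)
default_labels24 <- stats::setNames(
  rep(c("cantilever", "truss", "vertical_load"), each = 8), default_items24)
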