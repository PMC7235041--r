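#' Mechanical-category model DM
#'
#' Binary category model: pair dissimilarity 0 for items of the same
#' category (e.g., two cantilevers) and 1 for items of different categories
#' (cantilever vs truss vs vertical load).
#'
#' @param labels Factor or character vector of category labels, named by (or
#'   ordered as) the item ids.
#' @return A `model_dm`: an [item_dm()] with attributes `model_kind =
#'   "mechanical_category"` and `categories`.
#' @export
category_model_dm <- function(labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L) {
    stop("degenerate model: need >= 2 categories", call. = FALSE)
  }
  items <- names(labels)
  if (is.null(items)) items <- paste0("item", seq_along(labels))
  pairs <- condensed_pairs(items)
  same <- labels[match(pairs$item_a, items)] == labels[match(pairs$item_b, items)]
  dm <- item_dm(as.numeric(!same), items)
  attr(dm, "model_kind") <- "mechanical_category"
  attr(dm, "categories") <- stats::setNames(as.character(labels), items)
  dm
}

#' Network-average DM for one subject
#'
#' Entry-wise mean of the subject's condensed DMs over the network's
#' non-missing nodes.
#'
#' @param dm_map A [searchlight_dm_map()] result.
#' @param network An `informational_network` (or a bare node-index vector).
#' @return An [item_dm()], or `NA` (with a warning) if the subject is
#'   missing at every network node.
#' @export
network_average_dm <- function(dm_map, network) {
  nodes <- if (inherits(network, "informational_network")) network$nodes else
    as.integer(network)
  if (length(nodes) == 0L) stop("empty network", call. = FALSE)
  ok <- nodes[!dm_map$missing[nodes]]
  if (length(ok) == 0L) {
    warning("subject missing at all network nodes")
    return(NA)
  }
  item_dm(rowMeans(dm_map$dms[, ok, drop = FALSE]), dm_map$items)
}

#' Network-level RSA against a model DM
#'
#' For every network: each participant's network-average DM is correlated
#' with the model DM by normalized correlation (mean-centered, unit-norm dot
#' product), Fisher z-transformed, and the participants' z values are tested
#' against zero with a two-sided one-sample t-test. Participants with a
#' degenerate network DM are dropped with a warning; networks with fewer
#' than 2 remaining participants are skipped.
#'
#' @param networks List of `informational_network` objects.
#' @param dm_maps List of [searchlight_dm_map()] results for the group being
#'   tested (its members' z values enter the t-test).
#' @param model A model [item_dm()] (mechanical category or visual
#'   similarity).
#' @param model_kind Label recorded in the output (defaults to the model's
#'   `model_kind` attribute).
#' @param adjust_p If `TRUE`, append Benjamini-Hochberg adjusted p-values
#'   across networks.
#' @return Data frame with one row per network: `network_id`, `model_kind`,
#'   `n`, `mean_z`, `t`, `df`, `p`, `n_nodes` (and `p_adj` if requested),
#'   with the per-participant z values in attribute `participant_z`.
#' @export
network_rsa <- function(networks, dm_maps, model, model_kind = NULL,
                        adjust_p = FALSE) {
  if (is.null(model_kind)) {
    model_kind <- attr(model, "model_kind")
    if (is.null(model_kind)) model_kind <- "model"
  }
  rows <- list()
  zs <- list()
  for (net in networks) {
    z <- numeric(0)
    for (m in dm_maps) {
      avg <- network_average_dm(m, net)
      if (!inherits(avg, "item_dm")) next
      r <- tryCatch(normalized_correlation(avg, model), error = function(e) NA)
      if (is.na(r)) {
        warning(sprintf("participant %s degenerate in network %s; dropped",
                        m$subject_id, net$network_id))
        next
      }
      z <- c(z, fisher_z(r))
    }
    if (length(z) < 2L) {
      warning(sprintf("network %s skipped: fewer than 2 participants",
                      net$network_id))
      next
    }
    tt <- one_sample_t(z)
    rows[[length(rows) + 1L]] <- data.frame(
      network_id = net$network_id, model_kind = model_kind,
      n = length(z), mean_z = tt$mean, t = tt$statistic, df = tt$df,
      p = tt$p, n_nodes = length(net$nodes), stringsAsFactors = FALSE)
    zs[[net$network_id]] <- z
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(network_id = character(0))
  if (adjust_p && nrow(out) > 0) out$p_adj <- stats::p.adjust(out$p, "BH")
  attr(out, "participant_z") <- zs
  out
}

#' Node-wise informational gradient map
#'
#' Every node inherits the t statistic of the network it belongs to;
#' unassigned nodes are `NA`.
#'
#' @param stats A [network_rsa()] table.
#' @param networks The networks the table was computed over.
#' @param n_nodes Total mesh node count.
#' @return Numeric vector of per-node t values.
#' @export
gradient_map <- function(stats, networks, n_nodes) {
  map <- rep(NA_real_, n_nodes)
  for (net in networks) {
    row <- match(net$network_id, stats$network_id)
    if (is.na(row)) next
    map[net$nodes] <- stats$t[row]
  }
  map
}

#' Peak network of an RSA table
#'
#' The network with the maximal t statistic; ties broken toward the larger
#' network (node count), then the smaller network id.
#'
#' @inheritParams gradient_map
#' @return List with `network_id` and `stat` (the table row).
#' @export
find_peak_network <- function(stats) {
  if (is.null(stats) || nrow(stats) == 0L) stop("empty stats", call. = FALSE)
  ord <- order(-stats$t, -stats$n_nodes, stats$network_id)
  list(network_id = stats$network_id[ord[1]], stat = stats[ord[1], ])
}
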