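#!/usr/bin/env Rscript
# Stage 5: item-space visualization of the peak networks.
#
# The expert group's peak mechanical network DM (averaged over participants)
# is embedded in three dimensions by nonmetric MDS; each mechanical category
# receives a 95% concentration ellipsoid. The category structure visible in
# this embedding -- and its absence in the visual model embedding -- mirrors
# the informational gradients of stage 4.

library(repnets)

study <- readRDS("scratch/study.rds")
conv <- readRDS("scratch/convergence.rds")
nets <- readRDS("scratch/networks.rds")
rsa <- readRDS("scratch/rsa.rds")

labels <- factor(study$labels, levels = c("cantilever", "truss",
                                          "vertical_load"))
expert_maps <- conv$dm_maps[study$subjects$id[study$subjects$group == "expert"]]
all_nets <- unlist(nets$networks, recursive = FALSE)
net_ids <- vapply(all_nets, `[[`, character(1), "network_id")

embed_dm <- function(dm, tag) {
  emb <- nmds_embed(dm, dims = 3, n_starts = 8, seed = 3)
  message(sprintf("%s: NMDS stress %.4f", tag, emb$stress))
  coords <- data.frame(item = rownames(emb$points), category = labels,
                       emb$points)
  names(coords)[3:5] <- c("dim1", "dim2", "dim3")
  write.csv(coords, sprintf("results/nmds_%s.csv", tag), row.names = FALSE)
  for (cat in levels(labels)) {
    pts <- emb$points[labels == cat, ]
    ell <- suppressWarnings(concentration_ellipsoid(pts))
    if (any(ell$degenerate)) {
      message(sprintf("  %-14s cluster collapses to a point/plane; ellipsoid degenerate",
                      cat))
      next
    }
    inside <- mean(ellipsoid_contains(ell, pts))
    message(sprintf("  %-14s ellipsoid semi-axes %.2f/%.2f/%.2f (%.0f%% of own items inside)",
                    cat, ell$semi_axis_lengths[1], ell$semi_axis_lengths[2],
                    ell$semi_axis_lengths[3], 100 * inside))
  }
  invisible(emb)
}

# peak mechanical network, expert group: group-average network DM
pk_id <- rsa$peaks[["expert.mechanical_category"]]$stat$network_id
pk_net <- all_nets[[match(pk_id, net_ids)]]
avg <- Reduce(`+`, lapply(expert_maps, function(m)
  network_average_dm(m, pk_net)$condensed)) / length(expert_maps)
peak_dm <- item_dm(avg, study$category_dm$items)
embed_dm(peak_dm, "expert_mech_peak")

# the two model DMs for contrast
embed_dm(study$category_dm, "category_model")
embed_dm(study$visual_dm, "visual_model")

message("item-space embeddings written to results/nmds_*.csv")
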