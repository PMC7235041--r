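#!/usr/bin/env Rscript
# Stage 2: subject searchlight DM maps and group convergence maps.
#
# For every subject, an item-level DM is computed at each of the 1,284
# surface nodes from the patterns in the node's searchlight patch. Within
# each group, DMs are correlated between every subject pair at every node,
# Fisher z-transformed and averaged; the negative extent of each group map
# sets the noise threshold, the stricter of the two is applied to both, and
# the thresholded overlay is cluster-corrected (>= 5 contiguous nodes) into
# expert-only / novice-only / overlapping regions. A small permutation null
# validates the threshold.

library(repnets)

study <- readRDS("scratch/study.rds")
mesh <- study$mesh
rings <- study$config$searchlight_rings

message("searchlight DM maps (rings = ", rings, ") ...")
nb <- all_neighborhoods(mesh, rings)
dm_maps <- lapply(seq_len(nrow(study$subjects)), function(s)
  searchlight_dm_map(study$betas[[s]], mesh, rings, nb,
                     study$subjects$id[s], study$subjects$group[s]))
names(dm_maps) <- study$subjects$id
by_group <- split(dm_maps, study$subjects$group)

message("intersubject convergence maps ...")
convergence <- lapply(by_group, intersubject_convergence)
thresholds <- lapply(convergence, estimate_noise_threshold)
threshold <- max(unlist(thresholds))
message(sprintf("noise thresholds: expert %.4f, novice %.4f -> applied %.4f",
                thresholds$expert, thresholds$novice, threshold))

labels <- overlay_and_cluster(convergence$expert, convergence$novice,
                              threshold, min_cluster_size = 5, mesh)
print(labels)

message("permutation validation (100 permutations per group) ...")
null <- lapply(by_group, permutation_null, n_permutations = 100, seed = 2)
for (g in names(null)) {
  message(sprintf("  %s: observed map max %.3f vs null max 95th pct %.3f",
                  g, max(convergence[[g]]$node_z, na.rm = TRUE),
                  quantile(null[[g]]$null_values, 0.95)))
}

write_node_map(convergence$expert$node_z, "results/convergence_expert_z.csv")
write_node_map(convergence$novice$node_z, "results/convergence_novice_z.csv")
write_node_map(as.character(labels$node_label), "results/region_labels.csv")

saveRDS(list(dm_maps = dm_maps, convergence = convergence,
             threshold = threshold, labels = labels),
        "scratch/convergence.rds")
message("convergence stage written to scratch/convergence.rds")
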