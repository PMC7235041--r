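#!/usr/bin/env Rscript
# Stage 1: generate the reference synthetic study.
#
# Builds the L = 8 whole-brain surface, the 24-item stimulus set (8
# cantilevers, 8 trusses, 8 vertical loads), the HMAX C1 visual model DM,
# and two groups of subjects (16 experts, 15 novices) with planted
# representational structure: an expert-only category region, a shared
# visual region and a novice-only region, each carrying two prototype
# halves. Writes the study to scratch/ (binary intermediate) and the
# human-readable ground truth to results/.

library(repnets)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg <- study_config(seed = 1)
message("simulating reference study (seed ", cfg$seed, ", L = ",
        cfg$mesh_divisions, ") ...")
study <- simulate_study(cfg)
print(study)

# stimulus images and models
dir.create("results/stimuli", showWarnings = FALSE)
for (id in names(study$images)[c(1, 9, 17)]) {   # one example per category
  write_image_png(study$images[[id]], file.path("results/stimuli",
                                                paste0(id, ".png")))
}
write_item_dm(study$category_dm, "results/category_model_dm.csv", "square")
write_item_dm(study$visual_dm, "results/visual_model_dm.csv", "square")
message(sprintf("visual vs category model normalized correlation: %.3f",
                normalized_correlation(study$visual_dm, study$category_dm)))

# ground truth as a plain node map
write_node_map(study$ground_truth$role_map, "results/planted_role_map.csv")
write.csv(study$subjects, "results/subjects.csv", row.names = FALSE)

saveRDS(study, "scratch/study.rds")
message("study written to scratch/study.rds; ground truth under results/")
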