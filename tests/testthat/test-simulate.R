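test_that("study configuration validates its inputs", {
  expect_error(study_config(category_sizes = c(a = 8, b = 8)), "sum to n_items")
  expect_error(study_config(snr = -1), ">= 0")
  expect_error(study_config(subject_signal_cor = 1.5), "\\[0, 1\\]")
  cfg <- study_config(seed = 3)
  expect_equal(unname(cfg$group_sizes), c(16, 15))
  expect_equal(cfg$n_items, 24)
})

test_that("planted prototypes are reproducible and respect the snr contract", {
  model <- category_model_dm(default_labels24)
  proto0 <- planted_dm_prototype(model, 0)
  expect_error(planted_dm_prototype(model, -0.5), ">= 0")
  # covariance is a valid correlation matrix
  p <- planted_dm_prototype(model, 1)
  expect_equal(diag(p$sigma), rep(1, 24))
  expect_true(all(eigen(p$sigma, symmetric = TRUE, only.values = TRUE)$values > 0))

  set.seed(71)
  s1 <- prototype_signal(p, 10)
  set.seed(71)
  s2 <- prototype_signal(p, 10)
  expect_identical(s1, s2)

  # expected normalized correlation with the model: ~0 at snr = 0 and
  # monotone over the snr grid
  mean_r <- vapply(c(0, 0.5, 1, 2, 4), function(snr) {
    pr <- planted_dm_prototype(model, snr)
    set.seed(72)
    mean(replicate(150, {
      pat <- planted_patterns(pr, 12)
      normalized_correlation(compute_item_dm(pat)$condensed, model$condensed)
    }))
  }, numeric(1))
  expect_lt(abs(mean_r[1]), 0.05)
  expect_true(all(diff(mean_r) > 0))
  expect_gt(mean_r[5], 0.5)
})

test_that("stimulus images are deterministic, non-constant and well-formed", {
  labs <- default_labels24[c(1, 9, 17)]
  a <- generate_stimulus_images(labs, seed = 5, size = 96)
  b <- generate_stimulus_images(labs, seed = 5, size = 96)
  expect_identical(a, b)
  c_ <- generate_stimulus_images(labs, seed = 6, size = 96)
  expect_false(identical(a, c_))
  for (img in a) {
    expect_equal(dim(img), c(96, 96))
    expect_true(all(img >= 0 & img <= 1))
    expect_gt(sd(img), 0.01)                 # contrast present
  }
})

test_that("simulated studies are bit-reproducible and plant disjoint role regions", {
  vdm <- quick_visual_dm()
  cfg <- study_config(seed = 9, mesh_divisions = 4, region_radius = 2)
  mesh <- get_mesh(4)
  a <- simulate_study(cfg, visual_dm = vdm, mesh = mesh)
  b <- simulate_study(cfg, visual_dm = vdm, mesh = mesh)
  expect_identical(a$betas, b$betas)
  expect_identical(a$ground_truth, b$ground_truth)

  roles <- a$ground_truth$role_map
  expect_setequal(unique(roles), c("none", "expert_category", "both_visual",
                                   "novice_only"))
  # regions are disjoint discs split into two halves covering the region
  for (role in names(a$regions)) {
    r <- a$regions[[role]]
    expect_setequal(c(r$half1, r$half2), r$nodes)
    expect_length(intersect(r$half1, r$half2), 0)
  }
  expect_equal(nrow(a$subjects), 31)
  expect_equal(dim(a$betas[[1]]), c(24, mesh$n_nodes))
})

test_that("planted signal raises within-group convergence only for the planted group", {
  vdm <- quick_visual_dm()
  cfg <- study_config(seed = 10, mesh_divisions = 4, region_radius = 2,
                      group_sizes = c(expert = 8, novice = 8))
  st <- simulate_study(cfg, visual_dm = vdm, mesh = get_mesh(4))
  nb <- all_neighborhoods(st$mesh, 1)
  maps <- lapply(seq_len(nrow(st$subjects)), function(s)
    searchlight_dm_map(st$betas[[s]], st$mesh, 1, nb,
                       st$subjects$id[s], st$subjects$group[s]))
  by_group <- split(maps, st$subjects$group)
  conv <- lapply(by_group, intersubject_convergence)
  expert_nodes <- st$regions$expert_category$nodes
  novice_nodes <- st$regions$novice_only$nodes
  noise_nodes <- which(st$ground_truth$role_map == "none")
  expect_gt(mean(conv$expert$node_z[expert_nodes]),
            mean(conv$expert$node_z[noise_nodes]) + 0.05)
  expect_gt(mean(conv$novice$node_z[novice_nodes]),
            mean(conv$novice$node_z[noise_nodes]) + 0.05)
  # the non-planted group shows no lift in the other group's region
  expect_lt(abs(mean(conv$novice$node_z[expert_nodes]) -
                  mean(conv$novice$node_z[noise_nodes])), 0.05)
})

test_that("with no planted signal the convergence maps are noise-like", {
  vdm <- quick_visual_dm()
  labeled <- vapply(1:3, function(sd) {
    cfg <- study_config(seed = 100 + sd, mesh_divisions = 4, snr = 0,
                        region_radius = 2,
                        group_sizes = c(expert = 8, novice = 8))
    st <- simulate_study(cfg, visual_dm = vdm, mesh = get_mesh(4))
    res <- suppressWarnings(run_pipeline(st, n_repetitions = 5, seed = sd))
    sum(res$labels$node_label != "none")
  }, numeric(1))
  # after the negative-extent threshold and 5-node cluster correction almost
  # nothing survives on pure noise
  expect_lt(mean(labeled) / get_mesh(4)$n_nodes, 0.01)
})
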