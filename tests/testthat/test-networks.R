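# build subject DM maps over a small "region" with planted node prototypes:
# node j's DM = prototypes[[block(j)]] + subject noise
planted_region_maps <- function(n_sub, blocks, prototypes, noise_sd = 0.2,
                                n_pairs = 28) {
  lapply(seq_len(n_sub), function(s) {
    dms <- vapply(seq_along(blocks), function(j) {
      prototypes[[blocks[j]]] + rnorm(n_pairs, 0, noise_sd)
    }, numeric(n_pairs))
    fake_dm_map(dms, items = letters[1:8])
  })
}

test_that("region averaging equals the brute-force entry-wise mean and flags degeneracy", {
  set.seed(41)
  n_nodes <- 7
  maps <- lapply(1:5, function(s) fake_dm_map(matrix(rnorm(10 * n_nodes), 10),
                                              items = letters[1:5]))
  labels <- fake_labels(n_nodes, 2:6, "A_only")
  region <- region_average_dms(maps, labels, "A_only")
  expect_equal(region$nodes, 2:6)
  for (j in seq_along(region$nodes)) {
    manual <- rowMeans(vapply(maps, function(m) m$dms[, region$nodes[j]],
                              numeric(10)))
    expect_lt(max(abs(region$dms[, j] - manual)), 1e-12)
  }
  # all subjects identical -> average equals any subject's DM
  same <- lapply(1:4, function(s) maps[[1]])
  region2 <- region_average_dms(same, labels, "A_only")
  expect_equal(region2$dms[, 1], maps[[1]]$dms[, 2], tolerance = 1e-12)

  # v and -v + const average to a constant vector: degenerate node
  v <- rnorm(10)
  m1 <- fake_dm_map(cbind(v, v), items = letters[1:5])
  m2 <- fake_dm_map(cbind(-v + 2, v), items = letters[1:5])
  labels2 <- fake_labels(2, 1:2, "A_only")
  region3 <- region_average_dms(list(m1, m2), labels2, "A_only")
  expect_true(region3$degenerate[1])
  expect_false(region3$degenerate[2])
  expect_error(region_average_dms(maps, fake_labels(n_nodes, 2:6, "A_only"),
                                  "overlap"), "empty")
})

test_that("Ward clustering recovers planted blocks and produces monotone merges", {
  set.seed(42)
  protos <- list(rnorm(28), rnorm(28))
  blocks <- rep(1:2, each = 10)
  maps <- planted_region_maps(6, blocks, protos, noise_sd = 0.15)
  labels <- fake_labels(20, 1:20, "A_only")
  region <- region_average_dms(maps, labels, "A_only")
  sol <- ward_cluster(region, 2)
  # planted partition recovered exactly (up to label swap)
  tab <- table(sol$node_assignment, blocks)
  expect_equal(sort(as.integer(tab)), c(0, 0, 10, 10))
  # merge heights non-decreasing along the dendrogram
  expect_true(all(diff(sol$tree$height) >= -1e-12))
  # k = number of nodes -> all singletons
  sol_n <- ward_cluster(region, 20)
  expect_equal(length(unique(sol_n$node_assignment)), 20)
  expect_error(ward_cluster(region, 1), "out of range")
  expect_error(ward_cluster(region, 21), "out of range")
})

test_that("split-half k selection recovers a planted three-prototype region", {
  set.seed(43)
  hits <- 0
  for (rep in 1:5) {
    # equidistant (orthogonal, equal-norm) prototypes: with three equally
    # separated clusters no two-cluster merge is stable across halves, so
    # reproducibility peaks at the planted k = 3
    q <- qr.Q(qr(matrix(rnorm(28 * 3), 28, 3))) * sqrt(28)
    protos <- list(q[, 1], q[, 2], q[, 3])
    blocks <- rep(1:3, each = 8)
    maps <- planted_region_maps(8, blocks, protos, noise_sd = 0.35)
    labels <- fake_labels(24, 1:24, "A_only")
    trace <- select_k_split_half(maps, labels, "A_only", k_range = c(2, 8),
                                 n_repetitions = 30, seed = rep)
    if (trace$k_star == 3) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("k selection is reproducible, honors a single candidate, and caps the range", {
  set.seed(44)
  maps <- planted_region_maps(6, rep(1:2, each = 6),
                              list(rnorm(28), rnorm(28)), noise_sd = 0.3)
  labels <- fake_labels(12, 1:12, "A_only")
  a <- select_k_split_half(maps, labels, "A_only", c(2, 2), 10, seed = 5)
  expect_equal(a$k_star, 2)
  expect_equal(a$ks, 2)
  b <- suppressWarnings(select_k_split_half(maps, labels, "A_only", c(2, 100),
                                            10, seed = 5))
  expect_lte(max(b$ks), 6)          # capped at half the region's node count
  expect_warning(select_k_split_half(maps, labels, "A_only", c(2, 100), 5,
                                     seed = 5), "truncated")
  c1 <- select_k_split_half(maps, labels, "A_only", c(2, 5), 15, seed = 9)
  c2 <- select_k_split_half(maps, labels, "A_only", c(2, 5), 15, seed = 9)
  expect_identical(c1$reproducibility_by_k, c2$reproducibility_by_k)
  expect_identical(c1$k_star, c2$k_star)
  expect_error(select_k_split_half(maps[1:3], labels, "A_only", c(2, 5), 5, 1),
               ">= 4 subjects")
})

test_that("a structureless region yields a low, flat reproducibility profile", {
  set.seed(45)
  maps <- lapply(1:8, function(s) fake_dm_map(matrix(rnorm(28 * 20), 28),
                                              items = letters[1:8]))
  labels <- fake_labels(20, 1:20, "A_only")
  trace <- select_k_split_half(maps, labels, "A_only", c(2, 10), 25, seed = 2)
  expect_lt(max(trace$reproducibility_by_k), 0.3)
})

test_that("networks partition the clustered region with stable size-ordered ids", {
  set.seed(46)
  protos <- list(rnorm(28), rnorm(28))
  blocks <- c(rep(1, 16), rep(2, 9))        # nodes 3:16 and 17:22 in-region
  maps <- planted_region_maps(6, blocks, protos, noise_sd = 0.1)
  labels <- fake_labels(25, 3:22, "A_only")
  region <- region_average_dms(maps, labels, "A_only")
  sol <- ward_cluster(region, 2)
  nets <- define_networks(sol, "expert", "A_only")
  expect_length(nets, 2)
  expect_equal(nets[[1]]$network_id, "A_only_expert_net01")
  expect_gte(length(nets[[1]]$nodes), length(nets[[2]]$nodes))
  expect_setequal(unlist(lapply(nets, `[[`, "nodes")), 3:22)
  # membership reproduces the cluster assignment exactly
  for (net in nets) {
    cl <- unique(sol$node_assignment[match(net$nodes, sol$nodes)])
    expect_length(cl, 1)
  }
})
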