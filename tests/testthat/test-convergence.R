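test_that("searchlight DMs equal a brute-force per-node recomputation", {
  mesh <- icosa_mesh(1)                      # 12 nodes
  set.seed(31)
  betas <- matrix(rnorm(4 * 12), 4, 12, dimnames = list(letters[1:4], NULL))
  map <- searchlight_dm_map(betas, mesh, rings = 1)
  for (v in 1:12) {
    nb <- node_neighborhood(mesh, v, 1)
    expect_lt(max(abs(map$dms[, v] - oracle_dm(betas[, nb]))), 1e-10)
  }
  expect_false(any(map$missing))
})

test_that("zero-ring searchlights are degenerate and identical planted patterns give zero DMs", {
  mesh <- icosa_mesh(1)
  set.seed(32)
  betas <- matrix(rnorm(4 * 12), 4, 12)
  map0 <- searchlight_dm_map(betas, mesh, rings = 0)
  expect_true(all(map0$missing))             # single-feature vectors
  # all items share one pattern -> DM identically zero wherever defined
  shared <- matrix(rep(rnorm(12), each = 4), 4, 12)
  map <- searchlight_dm_map(shared, mesh, rings = 1)
  expect_lt(max(abs(map$dms[, !map$missing])), 1e-10)
})

test_that("intersubject convergence matches a hand-built oracle and ignores subject order", {
  set.seed(33)
  n_nodes <- 6
  maps <- lapply(1:3, function(s) fake_dm_map(matrix(rnorm(3 * n_nodes), 3),
                                              items = letters[1:3]))
  conv <- intersubject_convergence(maps)
  for (v in seq_len(n_nodes)) {
    expect_lt(abs(conv$node_z[v] -
                    oracle_node_z(lapply(maps, function(m) m$dms[, v]))), 1e-10)
  }
  expect_equal(conv$n_pairs, 3)
  perm <- intersubject_convergence(maps[c(3, 1, 2)])
  expect_equal(perm$node_z, conv$node_z, tolerance = 1e-12)
  expect_error(intersubject_convergence(maps[1]), "at least 2")
})

test_that("perfect convergence yields the clipped-maximal z and missing subjects are dropped node-wise", {
  d <- matrix(c(0.1, 0.8, 1.3), 3, 4)        # same non-constant DM at 4 nodes
  maps <- lapply(1:3, function(s) fake_dm_map(d, items = letters[1:3]))
  conv <- intersubject_convergence(maps)
  expect_equal(conv$node_z, rep(atanh(1 - 1e-7), 4))

  maps[[1]]$missing[2] <- TRUE               # subject 1 missing at node 2
  maps[[1]]$dms[, 3] <- c(5, 1, 0)           # subject 1 deviant at node 3
  conv <- intersubject_convergence(maps)
  expect_equal(conv$node_z[2], atanh(1 - 1e-7))  # pair (2,3) still perfect
  expect_lt(conv$node_z[3], conv$node_z[1])
})

test_that("noise threshold is the negative extent with a strict downstream inequality", {
  mk <- function(z) structure(list(node_z = z), class = "convergence_map")
  expect_equal(as.numeric(estimate_noise_threshold(mk(c(-0.02, 0.1, 0.3)))), 0.02)
  expect_equal(as.numeric(estimate_noise_threshold(mk(c(-0.05, -0.01, 0.3)))), 0.05)
  expect_warning(thr <- estimate_noise_threshold(mk(c(0.01, 0.2))),
                 "threshold set to 0")
  expect_equal(as.numeric(thr), 0)
  expect_true(attr(thr, "all_positive"))
  expect_error(estimate_noise_threshold(mk(rep(NA_real_, 3))), "no finite")
})

test_that("overlay labels, strict threshold and minimum cluster extent behave as specified", {
  mesh <- icosa_mesh(2)                      # 42 nodes
  n <- mesh$n_nodes
  za <- rep(0, n); zb <- rep(0, n)
  za[c(1, 2)] <- 0.5
  zb[c(2, 3)] <- 0.5
  mk <- function(z) structure(list(node_z = z), class = "convergence_map")
  lab <- overlay_and_cluster(mk(za), mk(zb), threshold = 0.02,
                             min_cluster_size = 1, mesh = mesh)
  expect_equal(as.character(lab$node_label[1:3]), c("A_only", "overlap", "B_only"))
  expect_true(all(lab$node_label[4:n] == "none"))

  # node exactly at threshold is not labeled (z > threshold is strict)
  za2 <- rep(0, n); za2[5] <- 0.02
  lab2 <- overlay_and_cluster(mk(za2), mk(rep(0, n)), 0.02, 1, mesh)
  expect_equal(as.character(lab2$node_label[5]), "none")

  # a 4-node component dies under the 5-node extent rule; a 5-node one lives
  comp4 <- c(1, setdiff(node_neighborhood(mesh, 1, 1), 1)[1:3])
  comp5 <- c(30, setdiff(node_neighborhood(mesh, 30, 1), 30)[1:4])
  # ensure the two sets are disjoint and each is internally connected
  expect_length(intersect(comp4, comp5), 0)
  za3 <- rep(0, n); za3[comp4] <- 0.5
  zb3 <- rep(0, n)
  lab3 <- overlay_and_cluster(mk(za3), mk(zb3), 0.02, 5, mesh)
  expect_true(all(lab3$node_label == "none"))
  za4 <- rep(0, n); za4[comp5] <- 0.5
  lab4 <- overlay_and_cluster(mk(za4), mk(zb3), 0.02, 5, mesh)
  expect_equal(sum(lab4$node_label == "A_only"), length(comp5))

  # output is a partition: exactly one label per node
  expect_length(lab4$node_label, n)
  expect_false(any(is.na(lab4$node_label)))
})

test_that("permutation null is reproducible under a fixed seed and shuffles within subjects", {
  set.seed(34)
  maps <- lapply(1:4, function(s) fake_dm_map(matrix(rnorm(6 * 8), 6),
                                              items = letters[1:4]))
  a <- permutation_null(maps, n_permutations = 10, seed = 99)
  b <- permutation_null(maps, n_permutations = 10, seed = 99)
  expect_identical(a$null_values, b$null_values)
  expect_length(a$null_values, 10)
  expect_match(a$scheme, "within-subject")
  c_ <- permutation_null(maps, n_permutations = 10, seed = 100)
  expect_false(identical(a$null_values, c_$null_values))
  expect_error(permutation_null(maps, 0, 1), "must be >= 1")

  nodewise <- permutation_null(maps, n_permutations = 5, seed = 7,
                               statistic = "nodewise")
  expect_equal(dim(nodewise$null_values), c(5, 8))
})

test_that("permuting item labels relocates convergence but preserves its magnitude", {
  # all subjects share a DM: any common relabeling keeps z maximal, and the
  # null for shared structure concentrates below the observed value
  set.seed(35)
  base_dm <- runif(6, 0.2, 1.6)
  maps <- lapply(1:5, function(s) fake_dm_map(matrix(base_dm, 6, 3),
                                              items = letters[1:4]))
  obs <- intersubject_convergence(maps)
  null <- permutation_null(maps, n_permutations = 30, seed = 3)
  # independent shuffles break the alignment: null values below the ceiling
  expect_true(mean(null$null_values < max(obs$node_z)) > 0.8)
})
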