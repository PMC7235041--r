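test_that("category model DM is binary with the right pair counts", {
  dm <- category_model_dm(setNames(c("a", "a", "b"), c("i1", "i2", "i3")))
  expect_equal(dm$condensed, c(0, 1, 1))
  dm24 <- category_model_dm(default_labels24)
  expect_equal(sum(dm24$condensed == 0), 3 * choose(8, 2))   # 84 within
  expect_equal(sum(dm24$condensed == 1), 276 - 84)           # 192 between
  expect_error(category_model_dm(rep("a", 5)), ">= 2 categories")
})

test_that("category model relabeling permutes the condensed entries consistently", {
  labs <- setNames(c("a", "b", "a", "c"), paste0("i", 1:4))
  dm <- category_model_dm(labs)
  perm <- c(3, 1, 4, 2)
  dmp <- category_model_dm(labs[perm])
  mp <- as.matrix(dmp)
  m <- as.matrix(dm)
  expect_equal(mp[names(labs)[perm], names(labs)[perm]],
               m[names(labs)[perm], names(labs)[perm]])
})

test_that("network-average DMs equal entry-wise means over non-missing nodes", {
  set.seed(51)
  dms <- matrix(rnorm(10 * 12), 10)
  map <- fake_dm_map(dms, items = letters[1:5])
  net <- structure(list(network_id = "n1", group = "expert",
                        region_class = "A_only", nodes = 4L),
                   class = "informational_network")
  expect_equal(network_average_dm(map, net)$condensed, dms[, 4])
  expect_equal(network_average_dm(map, c(2, 7))$condensed,
               (dms[, 2] + dms[, 7]) / 2)
  nodes10 <- c(1:5, 8:12)
  expect_lt(max(abs(network_average_dm(map, nodes10)$condensed -
                      rowMeans(dms[, nodes10]))), 1e-12)
  map$missing[2] <- TRUE
  expect_equal(network_average_dm(map, c(2, 7))$condensed, dms[, 7])
  map$missing[] <- TRUE
  expect_warning(res <- network_average_dm(map, c(2, 7)), "missing at all")
  expect_false(inherits(res, "item_dm"))
})

test_that("network RSA reproduces the per-participant z -> t path and its contracts", {
  set.seed(52)
  model <- category_model_dm(setNames(rep(c("x", "y"), each = 4), letters[1:8]))
  n_pairs <- 28
  mk_maps <- function(n, f) lapply(seq_len(n), function(s)
    fake_dm_map(cbind(f(s)), items = letters[1:8], subject_id = paste0("s", s)))
  net <- structure(list(network_id = "net", group = "expert",
                        region_class = "A_only", nodes = 1L),
                   class = "informational_network")

  maps <- mk_maps(10, function(s) model$condensed + rnorm(n_pairs, 0, 0.5))
  stats <- network_rsa(list(net), maps, model)
  expect_equal(stats$n, 10)
  expect_equal(stats$df, 9)
  # cross-check against the explicit oracle computation
  z <- vapply(maps, function(m) atanh(oracle_pearson(m$dms[, 1],
                                                     model$condensed)),
              numeric(1))
  want <- oracle_one_sample_t(z)
  expect_lt(abs(stats$t - want$t), 1e-8)
  expect_lt(abs(stats$p - want$p), 1e-8)
  expect_gt(stats$mean_z, 0)

  # every participant DM equal to the model: zero variance must surface
  same <- mk_maps(5, function(s) model$condensed)
  expect_error(suppressWarnings(network_rsa(list(net), same, model)),
               "zero variance")

  # degenerate participants are dropped; too few left skips the network
  degen <- mk_maps(3, function(s) if (s < 3) rep(1, n_pairs) else
    model$condensed + rnorm(n_pairs))
  expect_warning(out <- network_rsa(list(net), degen, model), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("model-independent calibration: z values are centered at zero under the null", {
  set.seed(53)
  model <- category_model_dm(default_labels24)
  zs <- replicate(300, {
    dm <- compute_item_dm(matrix(rnorm(24 * 7), 24))
    fisher_z(normalized_correlation(dm$condensed, model$condensed))
  })
  expect_lt(abs(mean(zs)), 0.02)
})

test_that("gradient maps inherit the network t and peaks break ties as documented", {
  nets <- list(
    structure(list(network_id = "a", nodes = 1:3), class = "informational_network"),
    structure(list(network_id = "b", nodes = 4:9), class = "informational_network"))
  stats <- data.frame(network_id = c("a", "b"), t = c(1, 3),
                      n_nodes = c(3, 6), stringsAsFactors = FALSE)
  g <- gradient_map(stats, nets, 12)
  expect_equal(g[1:3], rep(1, 3))
  expect_equal(g[4:9], rep(3, 6))
  expect_true(all(is.na(g[10:12])))

  expect_equal(find_peak_network(stats)$network_id, "b")
  stats2 <- data.frame(network_id = c("a", "b", "c"), t = c(1.2, 2.27, 0.3),
                       n_nodes = c(5, 5, 5))
  expect_equal(find_peak_network(stats2)$network_id, "b")
  # tie on t -> larger network wins; tie on size -> smaller id
  stats3 <- data.frame(network_id = c("a", "b"), t = c(2, 2), n_nodes = c(3, 9))
  expect_equal(find_peak_network(stats3)$network_id, "b")
  stats4 <- data.frame(network_id = c("b", "a"), t = c(2, 2), n_nodes = c(5, 5))
  expect_equal(find_peak_network(stats4)$network_id, "a")
  # brute-force max over random tables
  set.seed(54)
  for (i in 1:100) {
    st <- data.frame(network_id = paste0("n", 1:10), t = rnorm(10),
                     n_nodes = sample(3:50, 10))
    expect_equal(find_peak_network(st)$network_id,
                 st$network_id[which.max(st$t)])
  }
  expect_error(find_peak_network(stats[0, ]), "empty")
})

test_that("optional BH adjustment appends monotone adjusted p-values", {
  set.seed(55)
  model <- category_model_dm(setNames(rep(c("x", "y"), each = 4), letters[1:8]))
  maps <- lapply(1:6, function(s) fake_dm_map(matrix(rnorm(28 * 4), 28),
                                              items = letters[1:8]))
  nets <- lapply(1:4, function(j) structure(
    list(network_id = paste0("net", j), nodes = j), class = "informational_network"))
  out <- network_rsa(nets, maps, model, adjust_p = TRUE)
  expect_true("p_adj" %in% names(out))
  expect_true(all(out$p_adj >= out$p - 1e-12))
})
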