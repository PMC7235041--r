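#' Nonmetric MDS embedding of an item DM
#'
#' Kruskal nonmetric scaling ([MASS::isoMDS()]) of the condensed
#' dissimilarities into `dims` dimensions, restarted from `n_starts` random
#' configurations (plus the classical-scaling start); the solution with the
#' lowest final stress is kept. Stress is reported on the [0, 1] scale.
#'
#' @param dm An [item_dm()] (non-degenerate).
#' @param dims Embedding dimensionality (default 3).
#' @param n_starts Number of random restarts (default 8).
#' @param seed Integer seed for the restarts.
#' @return `embedding3d`: list with `points` (items x dims matrix), `stress`
#'   (in `[0, 1]`), `dims`, `n_starts`, `seed`.
#' @export
nmds_embed <- function(dm, dims = 3, n_starts = 8, seed = 1) {
  d <- as.matrix(dm)
  # a constant positive DM (e.g., an equilateral configuration) is a valid
  # embedding target; only an all-zero DM carries no geometry at all
  if (max(dm$condensed) <= 1e-12) {
    stop("degenerate DM: no non-zero dissimilarities", call. = FALSE)
  }
  # isoMDS requires positive off-diagonal dissimilarities
  eps <- max(1e-9, 1e-6 * max(d))
  d[d <= 0] <- eps
  diag(d) <- 0

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  best <- NULL
  starts <- vector("list", n_starts + 1L)
  starts[[1]] <- stats::cmdscale(d, k = dims)
  for (s in seq_len(n_starts)) {
    starts[[s + 1L]] <- matrix(stats::rnorm(dm$n_items * dims),
                               dm$n_items, dims)
  }
  for (y0 in starts) {
    if (ncol(y0) < dims) next   # cmdscale can return fewer columns
    fit <- tryCatch(MASS::isoMDS(d, y = y0, k = dims, trace = FALSE),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  if (is.null(best)) stop("NMDS failed from every start", call. = FALSE)
  pts <- best$points
  rownames(pts) <- dm$items
  structure(list(points = pts, stress = best$stress / 100, dims = dims,
                 n_starts = n_starts, seed = seed),
            class = "embedding3d")
}

#' Concentration ellipsoid of a point cloud
#'
#' The region containing a stated probability mass of a multivariate normal
#' fitted to the points: center = mean, axes = covariance eigenvectors,
#' semi-axis lengths = `sqrt(eigenvalue * qchisq(probability, df = dims))`.
#'
#' @param points Numeric matrix (>= 4 rows for 3-D), one point per row; or a
#'   list with `center` and `cov` to use population parameters directly.
#' @param probability Coverage probability (default 0.95).
#' @return `concentration_ellipsoid`: list with `center`, `axes`
#'   (orthonormal columns), `semi_axis_lengths`, `cov`, `probability`,
#'   `degenerate` (logical per axis: non-positive eigenvalue).
#' @export
concentration_ellipsoid <- function(points, probability = 0.95) {
  if (is.list(points) && !is.null(points$cov)) {
    center <- points$center
    covm <- points$cov
  } else {
    points <- as.matrix(points)
    if (nrow(points) < ncol(points) + 1L) {
      stop(sprintf("need at least %d points", ncol(points) + 1L), call. = FALSE)
    }
    center <- colMeans(points)
    covm <- stats::cov(points)
  }
  e <- eigen(covm, symmetric = TRUE)
  degenerate <- e$values <= max(abs(e$values)) * 1e-10
  if (any(degenerate)) warning("rank-deficient covariance: degenerate axis flagged")
  q <- stats::qchisq(probability, df = ncol(covm))
  structure(list(center = center, axes = e$vectors,
                 semi_axis_lengths = sqrt(pmax(e$values, 0) * q),
                 cov = covm, probability = probability,
                 degenerate = degenerate),
            class = "concentration_ellipsoid")
}

#' Test points against a concentration ellipsoid
#'
#' @param ellipsoid A [concentration_ellipsoid()].
#' @param points Numeric matrix, one point per row.
#' @return Logical vector: is each point inside (Mahalanobis distance within
#'   the chi-square bound)?
#' @export
ellipsoid_contains <- function(ellipsoid, points) {
  points <- as.matrix(points)
  md <- stats::mahalanobis(points, ellipsoid$center, ellipsoid$cov)
  md <= stats::qchisq(ellipsoid$probability, df = ncol(points))
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes searchlight DM maps for every subject, within-group intersubject
#' convergence maps, negative-extent noise thresholding (the stricter of the
#' two group thresholds is applied to both), overlay with surface cluster
#' correction, split-half-validated Ward clustering into informational
#' networks per (group, region class), and normalized-correlation RSA of
#' every network against the mechanical category model and the visual
#' similarity model, with gradient maps and peak identification. Group
#' "expert" is overlay class `A_only`; group "novice" is `B_only`.
#'
#' @param study A [simulate_study()] result (or compatible list).
#' @param k_range Candidate cluster counts (default `c(2, 100)`, truncated
#'   per region).
#' @param n_repetitions Split-half repetitions per region (default 100).
#' @param min_cluster_size Surface cluster-correction extent (default 5).
#' @param n_permutations Optional permutation-null size per group (0 = skip).
#' @param seed Seed for split-half draws and permutations.
#' @return `pipeline_result`: list with `dm_maps`, `convergence`,
#'   `thresholds`, `threshold` (applied), `labels`, `networks`, `k_traces`,
#'   `rsa` (per group, both models), `gradients`, `peaks`, `permutation`,
#'   `manifest` (parameters, timings).
#' @export
run_pipeline <- function(study, k_range = c(2, 100), n_repetitions = 100,
                         min_cluster_size = 5, n_permutations = 0, seed = 1) {
  t0 <- proc.time()[["elapsed"]]
  mesh <- study$mesh
  rings <- study$config$searchlight_rings
  nb <- all_neighborhoods(mesh, rings)
  dm_maps <- lapply(seq_len(nrow(study$subjects)), function(s) {
    searchlight_dm_map(study$betas[[s]], mesh, rings = rings,
                       neighborhoods = nb,
                       subject_id = study$subjects$id[s],
                       group = study$subjects$group[s])
  })
  names(dm_maps) <- study$subjects$id
  by_group <- split(dm_maps, study$subjects$group)
  t1 <- proc.time()[["elapsed"]]

  convergence <- lapply(by_group, intersubject_convergence)
  thresholds <- lapply(convergence, estimate_noise_threshold)
  threshold <- max(unlist(thresholds))
  labels <- overlay_and_cluster(convergence$expert, convergence$novice,
                                threshold, min_cluster_size, mesh)
  permutation <- NULL
  if (n_permutations > 0) {
    permutation <- lapply(by_group, permutation_null,
                          n_permutations = n_permutations, seed = seed)
  }
  t2 <- proc.time()[["elapsed"]]

  class_for <- c(expert = "A_only", novice = "B_only")
  combos <- expand.grid(group = c("expert", "novice"),
                        region_class = c("A_only", "B_only", "overlap"),
                        stringsAsFactors = FALSE)
  networks <- list()
  k_traces <- list()
  ci <- 0L
  for (i in seq_len(nrow(combos))) {
    g <- combos$group[i]
    cls <- combos$region_class[i]
    if (sum(labels$node_label == cls) < 2L) next
    ci <- ci + 1L
    trace <- select_k_split_half(by_group[[g]], labels, cls,
                                 k_range = k_range,
                                 n_repetitions = n_repetitions,
                                 seed = seed + ci)
    region <- region_average_dms(by_group[[g]], labels, cls)
    sol <- ward_cluster(region, trace$k_star)
    nets <- define_networks(sol, g, cls)
    key <- paste(g, cls, sep = ".")
    networks[[key]] <- nets
    k_traces[[key]] <- trace
  }
  t3 <- proc.time()[["elapsed"]]

  models <- list(mechanical_category = study$category_dm,
                 visual_similarity = study$visual_dm)
  rsa <- list()
  gradients <- list()
  peaks <- list()
  for (g in c("expert", "novice")) {
    nets_g <- unlist(networks[grep(paste0("^", g, "\\."), names(networks))],
                     recursive = FALSE)
    if (length(nets_g) == 0L) next
    for (mk in names(models)) {
      stats_g <- network_rsa(nets_g, by_group[[g]], models[[mk]],
                             model_kind = mk)
      key <- paste(g, mk, sep = ".")
      rsa[[key]] <- stats_g
      gradients[[key]] <- gradient_map(stats_g, nets_g, mesh$n_nodes)
      if (nrow(stats_g) > 0) peaks[[key]] <- find_peak_network(stats_g)
    }
  }
  t4 <- proc.time()[["elapsed"]]

  manifest <- list(
    parameters = list(searchlight_rings = rings, k_range = k_range,
                      n_repetitions = n_repetitions,
                      min_cluster_size = min_cluster_size,
                      n_permutations = n_permutations, seed = seed,
                      study_seed = study$config$seed),
    timings = c(searchlight = t1 - t0, convergence = t2 - t1,
                networks = t3 - t2, rsa = t4 - t3))
  structure(list(dm_maps = dm_maps, convergence = convergence,
                 thresholds = thresholds, threshold = threshold,
                 labels = labels, networks = networks, k_traces = k_traces,
                 rsa = rsa, gradients = gradients, peaks = peaks,
                 permutation = permutation, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  tab <- table(x$labels$node_label)
  cat(sprintf("<pipeline_result> threshold z > %.4f; A_only %d, B_only %d, overlap %d nodes; %d network sets\n",
              x$threshold, tab[["A_only"]], tab[["B_only"]], tab[["overlap"]],
              length(x$networks)))
  for (key in names(x$peaks)) {
    st <- x$peaks[[key]]$stat
    cat(sprintf("  peak %-25s %s: t(%d) = %.2f, p = %.3f\n", key,
                st$network_id, st$df, st$t, st$p))
  }
  invisible(x)
}

#' Score recovery of the planted regions
#'
#' Compares a pipeline's region label map with a study's ground truth:
#' Jaccard index per planted role (`expert_category` vs `A_only`,
#' `novice_only` vs `B_only`, `both_visual` vs `overlap`), whether each
#' group/model peak network lies (by majority of its nodes) inside the
#' corresponding planted region, and the selected cluster counts.
#'
#' @param study The [simulate_study()] ground truth.
#' @param result The [run_pipeline()] output on that study.
#' @return List with `jaccard` (named per role), `k_star` (named per
#'   group/region class), `peak_in_planted` (named per group/model), and
#'   `novice_mech_p_at_expert_peak` (novice-group mechanical RSA p-value over
#'   the expert group's peak mechanical network nodes, `NA` if unavailable).
#' @export
score_recovery <- function(study, result) {
  role_map <- study$ground_truth$role_map
  pairing <- c(expert_category = "A_only", novice_only = "B_only",
               both_visual = "overlap")
  jaccard <- vapply(names(pairing), function(role) {
    planted <- which(role_map == role)
    recovered <- which(result$labels$node_label == pairing[[role]])
    length(intersect(planted, recovered)) / length(union(planted, recovered))
  }, numeric(1))

  k_star <- vapply(result$k_traces, function(tr) tr$k_star, numeric(1))

  peak_region <- c(expert.mechanical_category = "expert_category",
                   novice.mechanical_category = "expert_category",
                   expert.visual_similarity = "both_visual",
                   novice.visual_similarity = "both_visual")
  peak_in_planted <- vapply(names(result$peaks), function(key) {
    pk <- result$peaks[[key]]
    nets <- unlist(result$networks, recursive = FALSE)
    net <- nets[[which(vapply(nets, function(n) n$network_id, character(1)) ==
                         pk$network_id)[1]]]
    mean(role_map[net$nodes] == peak_region[[key]]) > 0.5
  }, logical(1))

  novice_p <- NA_real_
  pk <- result$peaks[["expert.mechanical_category"]]
  if (!is.null(pk)) {
    nets <- unlist(result$networks, recursive = FALSE)
    net <- nets[[which(vapply(nets, function(n) n$network_id, character(1)) ==
                         pk$network_id)[1]]]
    nov_maps <- result$dm_maps[study$subjects$id[study$subjects$group == "novice"]]
    z <- vapply(nov_maps, function(m) {
      avg <- network_average_dm(m, net)
      if (!inherits(avg, "item_dm")) return(NA_real_)
      fisher_z(normalized_correlation(avg, study$category_dm))
    }, numeric(1))
    z <- z[is.finite(z)]
    if (length(z) >= 2) novice_p <- one_sample_t(z)$p
  }

  list(jaccard = jaccard, k_star = k_star, peak_in_planted = peak_in_planted,
       novice_mech_p_at_expert_peak = novice_p)
}
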