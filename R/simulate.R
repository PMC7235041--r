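#' Synthetic study configuration
#'
#' Bundles every parameter of the synthetic-study generator. Defaults encode
#' the reference study conditions: two groups (16 "expert" and 15 "novice"
#' participants), 24 items in three equal mechanical categories, a test-scale
#' L = 8 whole-brain surface, and three planted disc regions (one per role)
#' each split into two prototype halves.
#'
#' @param seed Master integer seed for the study.
#' @param mesh_divisions Icosahedron linear divisions (8 for test scale,
#'   32 for the full standard mesh).
#' @param n_items Number of stimulus items.
#' @param category_sizes Per-category item counts (must sum to `n_items`).
#' @param group_sizes Named vector `c(expert = ..., novice = ...)`.
#' @param snr Planted signal-to-noise ratio: variance of the planted pattern
#'   component relative to unit subject noise variance. `snr = 0` plants
#'   nothing.
#' @param subject_signal_cor Across-subject correlation of the planted signal
#'   (default 0.3): each subject's signal is
#'   `sqrt(rho) * shared core + sqrt(1 - rho) * subject-specific draw`, both
#'   from the prototype covariance. Subjects thus share representational
#'   geometry (the prototype) without sharing identical patterns, as in real
#'   groups of brains.
#' @param searchlight_rings Searchlight patch radius used downstream; the
#'   reference test-scale value is 1 ring because an L = 8 mesh is four times
#'   coarser than the standard L = 32 mesh, so one ring spans a comparable
#'   cortical fraction to a multi-ring patch at full scale.
#' @param region_radius Planted disc radius in mesh rings.
#' @param stimulus_seed Seed of the synthetic stimulus set (fixed by default
#'   so that, as in a real study, the same stimuli serve every simulated
#'   study).
#' @param image_size Stimulus image side in pixels.
#' @return A `study_config` list.
#' @export
study_config <- function(seed = 1, mesh_divisions = 8, n_items = 24,
                         category_sizes = c(cantilever = 8, truss = 8,
                                            vertical_load = 8),
                         group_sizes = c(expert = 16, novice = 15),
                         snr = 1.0, subject_signal_cor = 0.3,
                         searchlight_rings = 1, region_radius = 5,
                         stimulus_seed = 101, image_size = 128) {
  if (sum(category_sizes) != n_items) {
    stop("category sizes must sum to n_items", call. = FALSE)
  }
  if (length(group_sizes) != 2L || any(group_sizes < 2)) {
    stop("need two groups of >= 2 subjects", call. = FALSE)
  }
  if (snr < 0) stop("`snr` must be >= 0", call. = FALSE)
  if (subject_signal_cor < 0 || subject_signal_cor > 1) {
    stop("`subject_signal_cor` must be in [0, 1]", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), mesh_divisions = mesh_divisions,
                 n_items = n_items, category_sizes = category_sizes,
                 group_sizes = group_sizes, snr = snr,
                 subject_signal_cor = subject_signal_cor,
                 searchlight_rings = searchlight_rings,
                 region_radius = region_radius,
                 stimulus_seed = as.integer(stimulus_seed),
                 image_size = image_size),
            class = "study_config")
}

#' Pattern prototype targeting a model DM
#'
#' Builds an item-level covariance whose induced correlation-distance DM has
#' an expected normalized correlation with the target model DM that grows
#' monotonically with `snr` (and is 0 at `snr = 0`): the item similarity
#' `1 - dm` has its off-diagonal entries standardized to a fixed structured
#' contrast (z-scored and scaled to sd 0.3, so every target model plants
#' comparably strong structure at equal `snr`; normalized correlation with
#' the original model is invariant to this affine transform) and is projected
#' to the nearest positive-semidefinite correlation
#' matrix `Sigma`, and patterns are generated as
#' `sqrt(snr) * signal + noise` with `signal` columns drawn from
#' `N(0, Sigma)` and unit Gaussian noise.
#'
#' @param model A model [item_dm()] (or any `item_dm` to act as target).
#' @param snr Signal-to-noise variance ratio (>= 0).
#' @return `dm_prototype`: list with `sigma`, its transposed Cholesky factor,
#'   `snr`, `n_items`, `items`, `model_kind`.
#' @export
planted_dm_prototype <- function(model, snr) {
  if (snr < 0) stop("`snr` must be >= 0", call. = FALSE)
  sigma <- nearest_correlation(standardize_similarity(1 - as.matrix(model)))
  structure(list(sigma = sigma, chol_t = t(chol(sigma)), snr = snr,
                 n_items = model$n_items, items = model$items,
                 model_kind = attr(model, "model_kind") %||% "target"),
            class = "dm_prototype")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Standardize a similarity matrix's off-diagonal structure: z-score the
# off-diagonal entries and scale them to a fixed contrast (sd = `tau`), so
# every planted prototype carries equally strong structure at equal snr.
# Normalized correlation against the original model DM is invariant to this
# affine transform; z-scores are clipped at +/- 3 to keep entries valid.
standardize_similarity <- function(sim, tau = 0.3) {
  off <- sim[lower.tri(sim)]
  if (stats::sd(off) > 0) {
    z <- pmin(pmax((off - mean(off)) / stats::sd(off), -3), 3)
    sim[lower.tri(sim)] <- tau * z
    sim[upper.tri(sim)] <- t(sim)[upper.tri(sim)]
  }
  diag(sim) <- 1
  sim
}

# clip eigenvalues and rescale to unit diagonal (PSD repair with small ridge)
nearest_correlation <- function(m, ridge = 1e-3) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  out <- e$vectors %*% diag(vals) %*% t(e$vectors)
  out <- out + diag(ridge, nrow(m))
  stats::cov2cor(out)
}

# item-exchangeable random prototype (low-rank + ridge correlation), drawn
# from the current RNG stream
random_prototype <- function(n_items, items, snr, rank = 3) {
  g <- matrix(stats::rnorm(n_items * rank), n_items, rank)
  sigma <- stats::cov2cor(tcrossprod(g) + diag(0.1, n_items))
  sigma <- nearest_correlation(standardize_similarity(sigma))
  structure(list(sigma = sigma, chol_t = t(chol(sigma)), snr = snr,
                 n_items = n_items, items = items, model_kind = "random"),
            class = "dm_prototype")
}

#' Shared signal component of a prototype
#'
#' Draws an items x features signal matrix whose columns are independent
#' `N(0, Sigma)` draws; across many features the items' feature vectors have
#' pairwise correlation `Sigma`.
#'
#' @param proto A [planted_dm_prototype()].
#' @param n_features Number of feature columns (e.g., region nodes).
#' @return Numeric matrix, items x features.
#' @export
prototype_signal <- function(proto, n_features) {
  proto$chol_t %*% matrix(stats::rnorm(proto$n_items * n_features),
                          proto$n_items, n_features)
}

#' Generate planted item patterns
#'
#' `sqrt(snr) * signal + unit Gaussian noise`; the correlation-distance DM of
#' the result correlates with the prototype's target DM increasingly with
#' `snr` and is independent of it at `snr = 0`.
#'
#' @inheritParams prototype_signal
#' @param signal Optional precomputed [prototype_signal()] (to share one
#'   signal across subjects); drawn fresh if `NULL`.
#' @return Numeric matrix, items x features.
#' @export
planted_patterns <- function(proto, n_features, signal = NULL) {
  if (is.null(signal)) signal <- prototype_signal(proto, n_features)
  sqrt(proto$snr) * signal +
    matrix(stats::rnorm(proto$n_items * n_features), proto$n_items, n_features)
}

#' Synthetic stimulus images
#'
#' Renders simple grayscale line drawings per mechanical category --
#' cantilever (wall-anchored horizontal beam with a tie and end load), truss
#' (triangulated span), vertical load (column under a block mass) -- with
#' randomized rotation, scale, translation, distractor strokes and smooth
#' background texture, so that low-level visual similarity does not trivially
#' encode the category.
#'
#' @param labels Named character/factor vector: item id -> category in
#'   `c("cantilever", "truss", "vertical_load")`.
#' @param seed Integer seed (fixed seed gives identical pixels).
#' @param size Image side in pixels (>= 64).
#' @return Named list of `size x size` matrices with values in `[0, 1]`.
#' @export
generate_stimulus_images <- function(labels, seed = 101, size = 128) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  items <- names(labels)
  if (is.null(items)) items <- paste0("item", seq_along(labels))
  out <- stats::setNames(vector("list", length(labels)), items)
  for (i in seq_along(labels)) {
    out[[i]] <- draw_structure(as.character(labels[[i]]), size)
  }
  out
}

# --- raster drawing helpers (pixel coordinates in [1, size]) ---------------

blank_canvas <- function(size) {
  bg <- smooth_noise(size, coarse = 7)
  bg <- (bg - min(bg)) / (max(bg) - min(bg) + 1e-12)
  0.10 + 0.15 * bg
}

smooth_noise <- function(n, coarse = 7) {
  g <- matrix(stats::rnorm(coarse^2), coarse, coarse)
  xi <- seq(1, coarse, length.out = n)
  tmp <- apply(g, 2, function(col) stats::approx(seq_len(coarse), col, xi)$y)
  t(apply(tmp, 1, function(row) stats::approx(seq_len(coarse), row, xi)$y))
}

draw_segment <- function(canvas, x0, y0, x1, y1, width = 2.5, value = 0.95) {
  n <- nrow(canvas)
  px <- matrix(rep(seq_len(n), n), n, n)          # row coordinate
  py <- matrix(rep(seq_len(n), each = n), n, n)   # column coordinate
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx^2 + dy^2
  tt <- if (len2 == 0) 0 else pmin(pmax(((px - x0) * dx + (py - y0) * dy) / len2, 0), 1)
  d <- sqrt((px - (x0 + tt * dx))^2 + (py - (y0 + tt * dy))^2)
  alpha <- pmin(pmax(width / 2 + 0.5 - d, 0), 1)  # 1-px anti-aliased edge
  pmax(canvas, value * alpha)
}

# rotate/scale/translate local [-0.5, 0.5]^2 coordinates into pixels
place_segments <- function(canvas, segs, theta, scale, shift, size,
                           width = 2.5, value = 0.95) {
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  for (s in segs) {
    p0 <- rot %*% (scale * s[1:2]) + shift
    p1 <- rot %*% (scale * s[3:4]) + shift
    canvas <- draw_segment(canvas,
                           (p0[1] + 0.5) * (size - 1) + 1,
                           (p0[2] + 0.5) * (size - 1) + 1,
                           (p1[1] + 0.5) * (size - 1) + 1,
                           (p1[2] + 0.5) * (size - 1) + 1,
                           width = width, value = value)
  }
  canvas
}

structure_segments <- function(category) {
  switch(category,
    cantilever = list(
      c(-0.42, -0.35, -0.42, 0.35),        # wall
      c(-0.42, 0.05, 0.40, 0.05),          # beam
      c(-0.42, 0.32, 0.05, 0.05),          # diagonal tie
      c(0.40, 0.05, 0.40, -0.12)),         # end load tick
    truss = {
      xs <- seq(-0.45, 0.45, length.out = 5)
      segs <- list(c(-0.45, -0.15, 0.45, -0.15))           # bottom chord
      top <- xs[2:4]
      segs <- c(segs, list(c(top[1], 0.2, top[3], 0.2)))   # top chord
      for (i in 1:3) {                                     # diagonals
        segs <- c(segs, list(c(xs[i], -0.15, top[i], 0.2)),
                  list(c(top[i], 0.2, xs[i + 1], -0.15)))
      }
      segs
    },
    vertical_load = list(
      c(0, -0.42, 0, 0.18),                # column
      c(-0.35, -0.42, 0.35, -0.42),        # ground
      c(-0.16, 0.18, 0.16, 0.18),          # block mass (filled by strokes)
      c(-0.16, 0.26, 0.16, 0.26),
      c(-0.16, 0.34, 0.16, 0.34),
      c(-0.16, 0.18, -0.16, 0.34),
      c(0.16, 0.18, 0.16, 0.34)),
    stop("unknown category: ", category))
}

draw_structure <- function(category, size) {
  canvas <- blank_canvas(size)
  theta <- stats::runif(1, -pi / 4, pi / 4)
  scale <- stats::runif(1, 0.65, 0.95)
  shift <- stats::runif(2, -0.06, 0.06)
  width <- stats::runif(1, 2, 3.2)
  canvas <- place_segments(canvas, structure_segments(category), theta, scale,
                           shift, size, width = width)
  for (d in seq_len(2)) {                  # background distractor strokes
    seg <- list(stats::runif(4, -0.48, 0.48))
    canvas <- place_segments(canvas, seg, 0, 1, c(0, 0), size,
                             width = stats::runif(1, 1, 2), value = 0.45)
  }
  canvas <- canvas + matrix(stats::rnorm(size^2, 0, 0.02), size, size)
  pmin(pmax(canvas, 0), 1)
}

# --- study assembly --------------------------------------------------------

region_layout <- function(mesh, radius) {
  left_rel <- sweep(mesh$left$coords, 2, c(-2.5, 0, 0))
  right_rel <- sweep(mesh$right$coords, 2, c(2.5, 0, 0))
  centers <- c(expert_category = which.max(left_rel[, 3]),
               novice_only = which.min(left_rel[, 3]),
               both_visual = mesh$node_index_offset + which.max(right_rel[, 3]))
  lapply(centers, function(ctr) {
    nodes <- node_neighborhood(mesh, ctr, radius)
    rel <- if (ctr <= mesh$node_index_offset) {
      left_rel[nodes, , drop = FALSE]
    } else {
      right_rel[nodes - mesh$node_index_offset, , drop = FALSE]
    }
    cdir <- rel[match(ctr, nodes), ] / sqrt(sum(rel[match(ctr, nodes), ]^2))
    tang <- c(1, 0, 0) - sum(c(1, 0, 0) * cdir) * cdir
    tang <- tang / sqrt(sum(tang^2))
    coord <- as.numeric(rel %*% tang)
    ord <- order(coord, nodes)
    half1 <- sort(nodes[ord[seq_len(ceiling(length(nodes) / 2))]])
    list(center = unname(ctr), nodes = nodes, half1 = half1,
         half2 = sort(setdiff(nodes, half1)))
  })
}

#' Simulate a complete synthetic study
#'
#' Generates the whole-brain mesh, two groups of subjects with per-node item
#' pattern estimates, category labels, stimulus images (or a supplied visual
#' model DM) and ground truth. Three disjoint disc regions are planted, one
#' per role, each split into two halves carrying distinct shared prototypes:
#'
#' * `expert_category` (left hemisphere): experts share a
#'   mechanical-category-model prototype in one half and an arbitrary
#'   non-model prototype in the other; novices get pure noise.
#' * `both_visual` (right hemisphere): both groups share a
#'   visual-model prototype in one half and an arbitrary shared prototype in
#'   the other.
#' * `novice_only` (left hemisphere): novices share two arbitrary non-model
#'   prototypes; experts get pure noise.
#'
#' Everywhere else patterns are independent unit Gaussian noise; planted
#' halves add `sqrt(snr)` times a group-shared signal (see
#' [planted_patterns()]). All quantities are in arbitrary beta-like units.
#'
#' @param config A [study_config()].
#' @param visual_dm Optional precomputed visual model [item_dm()] over the
#'   study's items; when `NULL`, stimulus images are generated (from
#'   `config$stimulus_seed`) and encoded with [visual_model_dm()].
#' @param mesh Optional prebuilt [whole_brain_surface()] matching
#'   `config$mesh_divisions` (reused across simulations for speed).
#' @return `synthetic_study`: list with `config`, `mesh`, `betas` (named list
#'   of items x nodes matrices), `subjects` (data frame id/group), `labels`
#'   (category per item), `category_dm`, `visual_dm`, `images` (or `NULL`),
#'   `regions`, `ground_truth` (per-node role map and per-half prototype
#'   descriptions).
#' @export
simulate_study <- function(config, visual_dm = NULL, mesh = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(mesh)) mesh <- whole_brain_surface(config$mesh_divisions)
  if (mesh$linear_divisions != config$mesh_divisions) {
    stop("supplied mesh does not match config", call. = FALSE)
  }
  items <- sprintf("item%02d", seq_len(config$n_items))
  labels <- stats::setNames(rep(names(config$category_sizes),
                                config$category_sizes), items)
  category_dm <- category_model_dm(stats::setNames(factor(labels), items))

  images <- NULL
  if (is.null(visual_dm)) {
    images <- generate_stimulus_images(labels, seed = config$stimulus_seed,
                                       size = config$image_size)
    visual_dm <- visual_model_dm(images)
  } else if (visual_dm$n_items != config$n_items) {
    stop("`visual_dm` does not match the item count", call. = FALSE)
  }

  regions <- region_layout(mesh, config$region_radius)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  n_items <- config$n_items
  cat_proto <- planted_dm_prototype(category_dm, config$snr)
  vis_target <- item_dm(visual_dm$condensed, items)
  attr(vis_target, "model_kind") <- "visual_similarity"
  vis_proto <- planted_dm_prototype(vis_target, config$snr)
  halves <- list(
    list(region = "expert_category", half = "half1", nodes = regions$expert_category$half1,
         groups = "expert", proto = cat_proto, kind = "mechanical_category"),
    list(region = "expert_category", half = "half2", nodes = regions$expert_category$half2,
         groups = "expert", proto = random_prototype(n_items, items, config$snr),
         kind = "random"),
    list(region = "both_visual", half = "half1", nodes = regions$both_visual$half1,
         groups = c("expert", "novice"), proto = vis_proto, kind = "visual_similarity"),
    list(region = "both_visual", half = "half2", nodes = regions$both_visual$half2,
         groups = c("expert", "novice"),
         proto = random_prototype(n_items, items, config$snr), kind = "random"),
    list(region = "novice_only", half = "half1", nodes = regions$novice_only$half1,
         groups = "novice", proto = random_prototype(n_items, items, config$snr),
         kind = "random"),
    list(region = "novice_only", half = "half2", nodes = regions$novice_only$half2,
         groups = "novice", proto = random_prototype(n_items, items, config$snr),
         kind = "random"))
  for (h in seq_along(halves)) {
    halves[[h]]$signal <- prototype_signal(halves[[h]]$proto,
                                           length(halves[[h]]$nodes))
  }

  subjects <- data.frame(
    id = c(sprintf("expert%02d", seq_len(config$group_sizes[["expert"]])),
           sprintf("novice%02d", seq_len(config$group_sizes[["novice"]]))),
    group = rep(c("expert", "novice"), config$group_sizes),
    stringsAsFactors = FALSE)
  betas <- stats::setNames(vector("list", nrow(subjects)), subjects$id)
  amp <- sqrt(config$snr)
  rho <- config$subject_signal_cor
  for (s in seq_len(nrow(subjects))) {
    b <- matrix(stats::rnorm(n_items * mesh$n_nodes), n_items, mesh$n_nodes,
                dimnames = list(items, NULL))
    for (h in halves) {
      if (subjects$group[s] %in% h$groups) {
        own <- prototype_signal(h$proto, length(h$nodes))
        b[, h$nodes] <- b[, h$nodes] +
          amp * (sqrt(rho) * h$signal + sqrt(1 - rho) * own)
      }
    }
    betas[[s]] <- b
  }

  role_map <- rep("none", mesh$n_nodes)
  for (role in names(regions)) role_map[regions[[role]]$nodes] <- role
  ground_truth <- list(
    role_map = role_map,
    halves = do.call(rbind, lapply(halves, function(h) {
      data.frame(region = h$region, half = h$half, kind = h$kind,
                 n_nodes = length(h$nodes),
                 nodes = I(list(h$nodes)), stringsAsFactors = FALSE)
    })))

  structure(list(config = config, mesh = mesh, betas = betas,
                 subjects = subjects, labels = labels,
                 category_dm = category_dm, visual_dm = visual_dm,
                 images = images, regions = regions,
                 ground_truth = ground_truth),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> seed %d: L = %d (%d nodes), %d + %d subjects, %d items, snr = %g\n",
              x$config$seed, x$config$mesh_divisions, x$mesh$n_nodes,
              x$config$group_sizes[["expert"]], x$config$group_sizes[["novice"]],
              x$config$n_items, x$config$snr))
  invisible(x)
}
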