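# Expensive shared fixtures, built once per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

get_mesh <- function(L) {
  cached(paste0("mesh", L), whole_brain_surface(L))
}

# visual model DM of the shipped synthetic stimulus set (default seed)
get_visual_dm <- function() {
  cached("visual_dm", {
    imgs <- generate_stimulus_images(default_labels24, seed = 101, size = 128)
    visual_model_dm(imgs)
  })
}

# deterministic stand-in DM with realistic structure, for tests that need a
# valid "visual-like" model without running the encoder
quick_visual_dm <- function() {
  cached("quick_visual_dm", {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(424242)
    dm <- compute_item_dm(matrix(rnorm(24 * 40), 24, 40,
                                 dimnames = list(default_items24, NULL)))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    attr(dm, "model_kind") <- "visual_similarity"
    dm
  })
}

# full reference-configuration pipeline runs shared by acceptance tests
get_reference_runs <- function(n_seeds = 20) {
  cached("reference_runs", {
    vdm <- get_visual_dm()
    mesh <- get_mesh(8)
    lapply(seq_len(n_seeds), function(sd) {
      st <- simulate_study(study_config(seed = sd), visual_dm = vdm,
                           mesh = mesh)
      res <- suppressWarnings(
        run_pipeline(st, n_repetitions = 50, seed = sd + 1000))
      score_recovery(st, res)
    })
  })
}
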