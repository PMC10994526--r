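# Shared fixtures, built in code at test time.

# A down-scaled configuration for structural tests: small grid, small
# groups. Recovery-strength claims use the full default config instead.
tiny_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, grid_dims = c(10L, 12L, 10L),
             group_sizes = c(dAD = 12L, bvFTD = 8L, bvAD = 4L, aAD = 6L),
             n_controls = 20L, ...)
}

# Lazily build and cache one tiny cohort per test run.
.cohort_cache <- new.env(parent = emptyenv())
tiny_cohort <- function(seed = 1L) {
  key <- paste0("c", seed)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(tiny_config(seed = seed))
  .cohort_cache[[key]]
}

# One full-size cohort (234 subjects, ~5100 mask voxels) with its fitted
# pipeline, cached across test files; used wherever a claim needs the
# default study conditions rather than the down-scaled grid.
full_pipeline <- function() {
  if (is.null(.cohort_cache$full)) {
    coh <- generate_cohort(sim_config(seed = 101L))
    res <- decompose_cohort(coh$images, coh$grid, fwhm_mm = 6,
                            n_null = 30L, seed = 101L)
    .cohort_cache$full <- list(cohort = coh, pipeline = res)
  }
  .cohort_cache$full
}

# A small grid with an off-centre reference block, for image-model tests.
test_grid <- function(dims = c(8L, 9L, 7L)) synthetic_grid(dims, voxel_mm = 6)

# A reproducible random image on a grid.
random_image <- function(grid, seed = 1L, id = "rnd", offset = 5) {
  set.seed(seed)
  subject_image(id, array(offset + stats::rnorm(prod(grid$dims)), grid$dims))
}
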