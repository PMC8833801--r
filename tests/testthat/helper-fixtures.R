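# Shared fixtures, built in code at test time.

# a discretized_volume built directly from a level array (0 = outside mask)
make_disc <- function(levels, n_bins = max(levels), spacing = c(1, 1, 1)) {
  structure(
    list(levels = levels, n_bins = as.integer(n_bins), bin_width = 1,
         min_masked = 0, spacing = spacing),
    class = "discretized_volume"
  )
}

rand_levels <- function(dim3, ng, seed, mask_frac = 1) {
  set.seed(seed)
  lev <- array(sample.int(ng, prod(dim3), replace = TRUE), dim = dim3)
  if (mask_frac < 1) {
    drop <- runif(prod(dim3)) > mask_frac
    lev[drop] <- 0L
  }
  lev
}

ball_mask <- function(n = 25, r = 8) {
  c0 <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  array((g$x - c0)^2 + (g$y - c0)^2 + (g$z - c0)^2 <= r^2, dim = c(n, n, n))
}

# small cohort for pipeline-level unit tests (cheap: 32^3 phantoms)
small_cohort_cfg <- function(n_subjects = 10, seed = 42) {
  cohort_config(
    n_subjects = n_subjects, volume_shape = c(32, 32, 32),
    n_cells_per_condition = 4, seed = seed
  )
}

# cache shared across test files within one run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_cohort <- function() {
  cached("small_cohort", {
    cfg <- small_cohort_cfg()
    suppressWarnings(generate_cohort(cfg, include_tracks = FALSE))
  })
}
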