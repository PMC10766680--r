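# shared fixtures: small landscapes and stationary climates built in code

# 36 x 36 m landscape (2 x 2 coarse cells at 18 m, 180^2 fine cells)
small_landscape <- function(seed = 3, water_fraction = 0, ...) {
  generate_synthetic_landscape(2, coarse_res = 18, water_fraction = water_fraction,
                               seed = seed, ...)
}

# 99 x 99 m desk-scale landscape used by the scenario checks
desk_landscape <- function(seed = 3, ...) {
  generate_synthetic_landscape(3, coarse_res = 33, seed = seed, ...)
}

stationary_climate <- function(n_years, seed = 2, ...) {
  generate_synthetic_climate(n_years, seed = seed, ...)
}

# a small populated tree table for impact tests
make_stand <- function(n = 50, width = 36, species = 1L, heights = NULL,
                       seed = 99) {
  set.seed(seed)
  h <- heights %||% runif(n, 50, 1200)
  df <- data.frame(id = seq_len(n), species = species, x = runif(n) * width,
                   y = runif(n) * width, height = h, crown_base = 0.35 * h,
                   age = pmax(1, round(h / 15)), alive = TRUE,
                   cone_seeds = 0, death_year = NA_integer_)
  class(df) <- c("fl_trees", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
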