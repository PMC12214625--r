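# Shared fixtures, built in code.

# two blocks on a line with two sites; distances chosen by hand
tiny_instance <- function() {
  blocks <- data.frame(
    block_id = c("b1", "b2"), x = c(0, 1000), y = 0,
    population = c(1, 1), stringsAsFactors = FALSE
  )
  sites <- data.frame(
    site_id = c("s1", "s2"), x = c(100, 700), y = 0,
    status = c("existing", "candidate"), stringsAsFactors = FALSE
  )
  d <- data.frame(
    block_id = rep(c("b1", "b2"), each = 2),
    site_id = rep(c("s1", "s2"), 2),
    meters = c(100, 700, 900, 300),
    stringsAsFactors = FALSE
  )
  access_instance(blocks, sites, d)
}

# small seeded random city for solver tests
small_city <- function(seed, grid_n = 5, n_existing = 2, n_candidates = 9,
                       ...) {
  generate_city(synthetic_city_config(
    seed = seed, grid_n = grid_n, cell_m = 200,
    n_existing = n_existing, n_candidates = n_candidates, ...))
}

# seeded random access distribution
random_dist <- function(seed, n = 30) {
  set.seed(seed)
  access_dist(stats::rexp(n, 1 / 500), stats::rpois(n, 20) + 1)
}
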