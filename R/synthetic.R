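# Seeded synthetic-city generator: grid-of-blocks instances with the
# statistical structure the siting method assumes — spatially clustered
# population, sparse existing stores biased toward demand, candidate
# sites at coarse-grid centroids, and metric (manhattan or grid-graph
# shortest-path) distances.

# run code under a seed, restoring the caller's RNG state afterwards
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic-city generator
#'
#' The generated city emulates the data the siting method consumes:
#' demand blocks on a regular grid (census blocks), a handful of existing
#' stores placed preferentially where people live (as real stores track
#' demand), candidate sites at the centroids of coarse super-cells
#' (block-group-centroid granularity, which is deliberately coarse —
#' ambitious access targets can be infeasible on it), and a complete
#' block-to-site distance matrix from a true metric.
#'
#' @param seed integer; fully determines the instance.
#' @param grid_n blocks per side (grid_n^2 blocks).
#' @param cell_m block spacing in metres (default 200).
#' @param pop_model `"gaussian-clusters"` (default) or `"uniform"`.
#' @param n_clusters number of population clusters (gaussian model).
#' @param cluster_spread cluster standard deviation as a fraction of the
#'   city extent (default 0.15).
#' @param pop_mean mean block population (default 40 persons).
#' @param n_existing number of existing stores.
#' @param n_candidates number of candidate sites (coarse-grid centroids).
#' @param store_bias_gamma existing stores are sampled with probability
#'   proportional to population^gamma (default 1): stores track demand.
#' @param distance_metric `"manhattan"` (default) or
#'   `"grid-graph-shortest-path"` (lattice with seeded random street
#'   closures, shortest paths via igraph).
#' @param edge_removal_frac fraction of lattice edges removed in the
#'   grid-graph metric (connectivity always preserved; default 0.1).
#' @param density_range optional c(lo, hi) housing-density range
#'   (units/km^2) for filter testing; by default density is derived from
#'   population at 2.5 persons per housing unit over the cell area.
#' @return A `synthetic_city_config` list.
#' @export
synthetic_city_config <- function(seed,
                                  grid_n = 12,
                                  cell_m = 250,
                                  pop_model = c("gaussian-clusters", "uniform"),
                                  n_clusters = 3,
                                  cluster_spread = 0.15,
                                  pop_mean = 40,
                                  n_existing = 3,
                                  n_candidates = 16,
                                  store_bias_gamma = 1,
                                  distance_metric = c("manhattan",
                                                      "grid-graph-shortest-path"),
                                  edge_removal_frac = 0.1,
                                  density_range = NULL) {
  pop_model <- match.arg(pop_model)
  distance_metric <- match.arg(distance_metric)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single integer", call. = FALSE)
  if (grid_n < 2) stop("grid_n must be at least 2", call. = FALSE)
  if (n_existing < 0 || n_existing > grid_n^2)
    stop("n_existing must be between 0 and grid_n^2", call. = FALSE)
  if (n_candidates < 1 || n_candidates > grid_n^2)
    stop("n_candidates must be between 1 and grid_n^2", call. = FALSE)
  structure(
    list(seed = as.integer(seed), grid_n = as.integer(grid_n),
         cell_m = cell_m, pop_model = pop_model, n_clusters = n_clusters,
         cluster_spread = cluster_spread, pop_mean = pop_mean,
         n_existing = as.integer(n_existing),
         n_candidates = as.integer(n_candidates),
         store_bias_gamma = store_bias_gamma,
         distance_metric = distance_metric,
         edge_removal_frac = edge_removal_frac,
         density_range = density_range),
    class = "synthetic_city_config"
  )
}

#' Generate a synthetic city instance
#'
#' Deterministic under the config seed: the same config always yields an
#' identical instance.
#'
#' @param config a [synthetic_city_config()].
#' @return An [access_instance()].
#' @examples
#' inst <- generate_city(synthetic_city_config(seed = 1))
#' inst
#' @export
generate_city <- function(config) {
  stopifnot(inherits(config, "synthetic_city_config"))
  .with_seed(config$seed, .generate_city_impl(config))
}

.generate_city_impl <- function(cfg) {
  n <- cfg$grid_n
  cell <- cfg$cell_m
  gx <- rep(seq_len(n), each = n)      # column index
  gy <- rep(seq_len(n), times = n)     # row index
  x <- (gx - 0.5) * cell
  y <- (gy - 0.5) * cell
  nb <- n * n

  # population surface
  if (cfg$pop_model == "uniform") {
    lam <- rep(cfg$pop_mean, nb)
  } else {
    extent <- n * cell
    cx <- stats::runif(cfg$n_clusters, 0, extent)
    cy <- stats::runif(cfg$n_clusters, 0, extent)
    sig <- cfg$cluster_spread * extent
    w <- rowSums(vapply(seq_len(cfg$n_clusters), function(c_)
      exp(-((x - cx[c_])^2 + (y - cy[c_])^2) / (2 * sig^2)),
      numeric(nb)))
    w <- w + 1e-9
    lam <- cfg$pop_mean * nb * w / sum(w)
  }
  pop <- stats::rpois(nb, lam)
  if (sum(pop) == 0) pop[which.max(lam)] <- max(1, round(cfg$pop_mean))

  area_km2 <- (cell / 1000)^2
  if (is.null(cfg$density_range)) {
    housing_density <- ceiling(pop / 2.5) / area_km2
  } else {
    housing_density <- stats::runif(nb, cfg$density_range[1],
                                    cfg$density_range[2])
  }

  blocks <- data.frame(
    block_id = sprintf("b%03d", seq_len(nb)),
    x = x, y = y, population = pop,
    housing_density = housing_density,
    area_km2 = area_km2,
    stringsAsFactors = FALSE
  )

  # existing stores track demand: sample blocks with prob ~ pop^gamma
  prob <- (pop + 1)^cfg$store_bias_gamma
  ex_idx <- if (cfg$n_existing > 0)
    sample.int(nb, cfg$n_existing, prob = prob) else integer(0)

  # candidate sites: centroids of coarse super-cells, spread evenly
  b <- max(1L, floor(n / ceiling(sqrt(cfg$n_candidates))))
  n_sc <- ceiling(n / b)
  sc_x <- (pmin((seq_len(n_sc) - 1) * b + b / 2, n - 0.001)) * cell
  cand_grid <- expand.grid(cx = sc_x, cy = sc_x)
  pick <- unique(round(seq(1, nrow(cand_grid),
                           length.out = cfg$n_candidates)))
  while (length(pick) < cfg$n_candidates) {   # top up if rounding collided
    extra <- setdiff(seq_len(nrow(cand_grid)), pick)
    pick <- sort(c(pick, extra[seq_len(cfg$n_candidates - length(pick))]))
  }
  cand_xy <- cand_grid[pick, , drop = FALSE]

  if (cfg$distance_metric == "grid-graph-shortest-path") {
    # snap all sites to cell centres so distances form a true graph metric
    snap <- function(v) (pmax(1, pmin(n, round(v / cell + 0.5))) - 0.5) * cell
    cand_xy$cx <- snap(cand_xy$cx)
    cand_xy$cy <- snap(cand_xy$cy)
  }

  sites <- data.frame(
    site_id = c(sprintf("e%02d", seq_along(ex_idx)),
                sprintf("c%02d", seq_len(nrow(cand_xy)))),
    x = c(x[ex_idx], cand_xy$cx),
    y = c(y[ex_idx], cand_xy$cy),
    status = c(rep("existing", length(ex_idx)),
               rep("candidate", nrow(cand_xy))),
    stringsAsFactors = FALSE
  )

  D <- switch(cfg$distance_metric,
    "manhattan" = outer(seq_len(nb), seq_len(nrow(sites)),
      function(i, j) abs(x[i] - sites$x[j]) + abs(y[i] - sites$y[j])),
    "grid-graph-shortest-path" =
      .grid_graph_distances(n, cell, cfg$edge_removal_frac,
                            cbind(x, y), cbind(sites$x, sites$y))
  )
  dimnames(D) <- list(blocks$block_id, sites$site_id)

  access_instance(blocks, sites, D, crs = "planar")
}

# Lattice shortest-path distances with seeded random street closures.
# Edges are removed one at a time only if the graph stays connected, so
# every distance is finite; igraph::distances gives the metric (symmetric,
# triangle inequality holds by construction).
.grid_graph_distances <- function(n, cell, removal_frac, block_xy, site_xy) {
  g <- igraph::make_lattice(c(n, n))
  igraph::E(g)$weight <- cell
  ne <- igraph::ecount(g)
  n_remove <- floor(removal_frac * ne)
  if (n_remove > 0) {
    all_ends <- igraph::ends(g, igraph::E(g))   # endpoints survive deletions
    order_try <- sample.int(ne)
    removed <- 0L
    for (e in order_try) {
      if (removed >= n_remove) break
      eid <- igraph::get_edge_ids(g, all_ends[e, ])
      if (eid == 0) next
      g2 <- igraph::delete_edges(g, eid)
      if (igraph::is_connected(g2)) {
        g <- g2
        removed <- removed + 1L
      }
    }
  }
  # igraph::make_lattice(c(n, n)) numbers vertices column-major over
  # (row, col); our blocks are laid out with gy fastest, matching vertex
  # id = gy + (gx - 1) * n
  to_vertex <- function(xy) {
    gx <- pmax(1, pmin(n, round(xy[, 1] / cell + 0.5)))
    gy <- pmax(1, pmin(n, round(xy[, 2] / cell + 0.5)))
    gy + (gx - 1) * n
  }
  vb <- to_vertex(block_xy)
  vs <- to_vertex(site_xy)
  Dv <- igraph::distances(g, v = sort(unique(vb)), to = sort(unique(vs)))
  Dv[match(vb, sort(unique(vb))), match(vs, sort(unique(vs))), drop = FALSE]
}

#' Inflate the access of a population tail
#'
#' Creates the motivating situation for inequality-aware siting: a
#' fraction of the population with substantially worse access than
#' average. Blocks are ranked by their current (existing-store) access
#' distance; the worst-served blocks holding `tail_fraction` of the
#' population have all their distances multiplied by `tail_multiplier`
#' (as if relocated further out). This widens the EDE-mean gap without
#' touching the rest of the city.
#'
#' @param instance an [access_instance()] with at least one existing site.
#' @param tail_fraction fraction of total population in the tail (0-1).
#' @param tail_multiplier factor >= 1 applied to the tail blocks'
#'   distances.
#' @return A new [access_instance()].
#' @export
perturb_access_inequality <- function(instance, tail_fraction = 0.1,
                                      tail_multiplier = 3) {
  stopifnot(inherits(instance, "access_instance"))
  if (tail_fraction <= 0 || tail_fraction >= 1)
    stop("tail_fraction must be in (0, 1)", call. = FALSE)
  if (tail_multiplier < 1)
    stop("tail_multiplier must be >= 1", call. = FALSE)
  base <- nearest_distances(instance)
  ord <- order(base$distances, decreasing = TRUE)
  cum <- cumsum(instance$blocks$population[ord])
  n_tail <- which(cum >= tail_fraction * instance$total_population)[1]
  tail_rows <- ord[seq_len(n_tail)]
  D <- instance$D
  D[tail_rows, ] <- D[tail_rows, , drop = FALSE] * tail_multiplier
  access_instance(instance$blocks, instance$sites, D, crs = instance$crs)
}
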