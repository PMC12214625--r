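# The city instance model: demand blocks, existing/candidate sites,
# the block x site walking-distance matrix, preprocessing filters,
# nearest-facility access, and CSV/GeoJSON I/O.

#' Build a validated access instance
#'
#' An access instance is the unit of analysis: a set of demand blocks R
#' with populations, a set of facility sites S partitioned into existing
#' stores C and candidate locations, and a complete matrix of walking
#' distances d[r, s] in metres. Distances always come from this matrix,
#' never from coordinates; coordinates are carried only for geometry
#' (boundary buffers) and map output.
#'
#' @param blocks data.frame with columns `block_id`, `x`, `y`,
#'   `population`, and optionally `housing_density` (units/km^2) and
#'   `area_km2`.
#' @param sites data.frame with columns `site_id`, `x`, `y`, `status`
#'   (each `"existing"` or `"candidate"`).
#' @param distances either a long-form data.frame with columns
#'   `block_id`, `site_id`, `meters` covering every block x site pair, or
#'   a dense numeric matrix with block ids as rownames and site ids as
#'   colnames.
#' @param crs `"planar"` if x/y are metres (default), `"lonlat"` if
#'   degrees. Lon/lat is used only for buffer geometry.
#' @return An object of class `access_instance`: list with `blocks`,
#'   `sites`, `D` (dense metres matrix, blocks x sites),
#'   `total_population` (over positive-population blocks), `crs`.
#' @examples
#' b <- data.frame(block_id = c("b1", "b2"), x = c(0, 100), y = 0,
#'                 population = c(10, 20))
#' s <- data.frame(site_id = c("s1", "s2"), x = c(0, 200), y = 0,
#'                 status = c("existing", "candidate"))
#' d <- expand.grid(block_id = b$block_id, site_id = s$site_id)
#' d$meters <- abs(b$x[match(d$block_id, b$block_id)] -
#'                 s$x[match(d$site_id, s$site_id)])
#' inst <- access_instance(b, s, d)
#' @export
access_instance <- function(blocks, sites, distances, crs = c("planar", "lonlat")) {
  crs <- match.arg(crs)
  blocks <- as.data.frame(blocks)
  sites <- as.data.frame(sites)

  need_b <- c("block_id", "x", "y", "population")
  if (!all(need_b %in% names(blocks)))
    stop("blocks table must have columns: ", paste(need_b, collapse = ", "),
         call. = FALSE)
  need_s <- c("site_id", "x", "y", "status")
  if (!all(need_s %in% names(sites)))
    stop("sites table must have columns: ", paste(need_s, collapse = ", "),
         call. = FALSE)

  blocks$block_id <- as.character(blocks$block_id)
  sites$site_id <- as.character(sites$site_id)
  sites$status <- as.character(sites$status)

  if (anyDuplicated(blocks$block_id))
    stop("duplicate block_id: ",
         paste(unique(blocks$block_id[duplicated(blocks$block_id)]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(sites$site_id))
    stop("duplicate site_id: ",
         paste(unique(sites$site_id[duplicated(sites$site_id)]),
               collapse = ", "), call. = FALSE)
  if (!all(sites$status %in% c("existing", "candidate")))
    stop("site status must be 'existing' or 'candidate'", call. = FALSE)
  if (anyNA(blocks$population) || any(!is.finite(blocks$population)) ||
      any(blocks$population < 0))
    stop("block populations must be finite and non-negative", call. = FALSE)
  if (nrow(blocks) == 0L) stop("instance has no blocks", call. = FALSE)
  if (nrow(sites) == 0L) stop("instance has no sites", call. = FALSE)

  D <- .as_dense_distances(distances, blocks$block_id, sites$site_id)

  total <- sum(blocks$population)
  if (total <= 0)
    stop("instance total population must be positive", call. = FALSE)

  structure(
    list(blocks = blocks, sites = sites, D = D,
         total_population = total, crs = crs),
    class = "access_instance"
  )
}

# Coerce long-form or dense distance input to a complete blocks x sites
# matrix; a missing pair is a hard error (silent infinities would corrupt
# the alpha scaling), as are negative or non-finite distances.
.as_dense_distances <- function(distances, block_ids, site_ids) {
  if (is.matrix(distances)) {
    if (is.null(rownames(distances)) || is.null(colnames(distances)))
      stop("dense distance matrix needs block ids as rownames and site ids as colnames",
           call. = FALSE)
    missing_b <- setdiff(block_ids, rownames(distances))
    missing_s <- setdiff(site_ids, colnames(distances))
    if (length(missing_b) || length(missing_s))
      stop("distance matrix missing blocks [",
           paste(utils::head(missing_b, 5), collapse = ", "),
           "] / sites [", paste(utils::head(missing_s, 5), collapse = ", "),
           "]", call. = FALSE)
    D <- distances[block_ids, site_ids, drop = FALSE]
  } else {
    distances <- as.data.frame(distances)
    need <- c("block_id", "site_id", "meters")
    if (!all(need %in% names(distances)))
      stop("long-form distance table must have columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    distances$block_id <- as.character(distances$block_id)
    distances$site_id <- as.character(distances$site_id)
    bad_b <- setdiff(distances$block_id, block_ids)
    bad_s <- setdiff(distances$site_id, site_ids)
    if (length(bad_b) || length(bad_s))
      stop("distance table references unknown ids: ",
           paste(utils::head(c(bad_b, bad_s), 5), collapse = ", "),
           call. = FALSE)
    D <- matrix(NA_real_, length(block_ids), length(site_ids),
                dimnames = list(block_ids, site_ids))
    D[cbind(distances$block_id, distances$site_id)] <- distances$meters
    if (anyNA(D)) {
      miss <- which(is.na(D), arr.ind = TRUE)
      ex <- apply(utils::head(miss, 5), 1, function(ij)
        paste0("(", block_ids[ij[1]], ", ", site_ids[ij[2]], ")"))
      stop("distance table missing ", nrow(miss), " (block, site) pair(s), e.g. ",
           paste(ex, collapse = ", "), call. = FALSE)
    }
  }
  if (any(!is.finite(D)))
    stop("all distances must be finite", call. = FALSE)
  if (any(D < 0))
    stop("all distances must be non-negative", call. = FALSE)
  D
}

#' @export
print.access_instance <- function(x, ...) {
  ne <- sum(x$sites$status == "existing")
  cat("Access instance:", nrow(x$blocks), "blocks,",
      nrow(x$sites), "sites (", ne, "existing,",
      nrow(x$sites) - ne, "candidate ),",
      format(round(x$total_population), big.mark = ","), "residents\n")
  invisible(x)
}

#' Ids of existing / candidate sites
#' @param instance an [access_instance()].
#' @return Character vector of site ids.
#' @export
existing_sites <- function(instance) {
  instance$sites$site_id[instance$sites$status == "existing"]
}

#' @rdname existing_sites
#' @export
candidate_sites <- function(instance) {
  instance$sites$site_id[instance$sites$status == "candidate"]
}

#' Nearest-facility access distances for a set of open sites
#'
#' Access is measured as the distance to the nearest open facility:
#' z[r] = min over open sites s of d[r, s]. Ties are broken by the
#' lexicographically smallest site id in the reported assignment.
#'
#' @param instance an [access_instance()].
#' @param open_sites character vector of site ids treated as open;
#'   defaults to the existing stores.
#' @return An [access_dist()] carrying block populations, with attributes
#'   `assignment` (data.frame block_id, site_id, meters) for reporting.
#' @export
nearest_distances <- function(instance, open_sites = existing_sites(instance)) {
  stopifnot(inherits(instance, "access_instance"))
  open_sites <- as.character(open_sites)
  if (length(open_sites) == 0L)
    stop("nearest_distances: open site set is empty", call. = FALSE)
  unknown <- setdiff(open_sites, instance$sites$site_id)
  if (length(unknown))
    stop("nearest_distances: unknown site id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  open_sites <- sort(unique(open_sites))   # lowest-id tie-break via which.min
  Dsub <- instance$D[, open_sites, drop = FALSE]
  j <- apply(Dsub, 1L, which.min)
  z <- Dsub[cbind(seq_len(nrow(Dsub)), j)]
  dist <- access_dist(z, instance$blocks$population)
  attr(dist, "assignment") <- data.frame(
    block_id = instance$blocks$block_id,
    site_id = open_sites[j],
    meters = z,
    stringsAsFactors = FALSE
  )
  dist
}

#' Equity parameters from the baseline (existing-store) access
#'
#' Computes the data scaling alpha on the current access distribution —
#' nearest distances to the existing stores only — and returns the
#' resulting parameters with kappa = alpha * epsilon. These parameters are
#' then held constant through optimization: kappa depends on the distance
#' distribution, so treating it as a constant calibrated on the baseline is
#' what makes the linear proxy objective exact for a fixed kappa.
#'
#' @param instance an [access_instance()] with at least one existing site.
#' @param epsilon inequality aversion, negative for burdens (default -1).
#' @return A [kp_params()] object.
#' @export
baseline_equity_params <- function(instance, epsilon = -1) {
  stopifnot(inherits(instance, "access_instance"))
  ex <- existing_sites(instance)
  if (length(ex) == 0L)
    stop("baseline_equity_params: instance has no existing sites",
         call. = FALSE)
  base <- nearest_distances(instance, ex)
  kp_params(kp_alpha(base), epsilon = epsilon)
}

#' Restrict an instance to blocks above a housing-density threshold
#'
#' Walkable access is most feasible in moderately dense areas; demand
#' blocks at or below the threshold (default 200 housing units per km^2,
#' roughly moderate suburban density) are dropped, and their populations
#' leave the instance total. The filter applies to demand blocks only,
#' never to candidate sites. If the blocks carry no `housing_density`
#' column (nor `housing_units` + `area_km2` to derive one), the instance
#' is returned unchanged with a warning.
#'
#' @param instance an [access_instance()].
#' @param threshold density cut-off in housing units per km^2; blocks are
#'   kept when strictly greater.
#' @return A filtered [access_instance()].
#' @export
filter_blocks_by_density <- function(instance, threshold = 200) {
  stopifnot(inherits(instance, "access_instance"))
  b <- instance$blocks
  dens <- b$housing_density
  if (is.null(dens) && all(c("housing_units", "area_km2") %in% names(b)))
    dens <- b$housing_units / b$area_km2
  if (is.null(dens)) {
    warning("blocks carry no housing-density information; density filter not applied")
    return(instance)
  }
  keep <- !is.na(dens) & dens > threshold
  if (!any(keep))
    stop("density filter removed every block (threshold ", threshold,
         " units/km^2)", call. = FALSE)
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message("density filter: dropped ", n_drop, " of ", nrow(b),
            " blocks (<= ", threshold, " units/km^2)")
  access_instance(b[keep, , drop = FALSE], instance$sites,
                  instance$D[keep, , drop = FALSE], crs = instance$crs)
}

#' Apply the city-boundary buffer rule to sites
#'
#' Existing stores are retained if they lie inside the city boundary or
#' within `buffer_m` of it (stores just beyond the city limit still serve
#' residents near the edge). Candidate sites are in-city locations by
#' construction, so candidates outside the boundary are dropped regardless
#' of the buffer.
#'
#' @param instance an [access_instance()].
#' @param boundary a polygon: either a two-column matrix/data.frame of
#'   vertex coordinates (closed or open ring) in the instance's CRS, or a
#'   path to a GeoJSON file whose first feature is a Polygon.
#' @param buffer_m buffer width in metres (default 5000).
#' @return A filtered [access_instance()].
#' @export
buffer_filter_sites <- function(instance, boundary, buffer_m = 5000) {
  stopifnot(inherits(instance, "access_instance"))
  ring <- .as_ring(boundary)
  pts <- cbind(instance$sites$x, instance$sites$y)
  if (instance$crs == "lonlat") {
    # local equirectangular projection for buffer geometry only
    lat0 <- mean(ring[, 2]) * pi / 180
    proj <- function(m) cbind(m[, 1] * 111320 * cos(lat0), m[, 2] * 110540)
    ring <- proj(ring); pts <- proj(pts)
  }
  inside <- .point_in_polygon(pts, ring)
  dist_to_edge <- .point_ring_distance(pts, ring)
  is_cand <- instance$sites$status == "candidate"
  keep <- ifelse(is_cand, inside, inside | dist_to_edge <= buffer_m)
  if (!any(keep)) stop("buffer filter removed every site", call. = FALSE)
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message("boundary filter: dropped ", n_drop, " of ", nrow(instance$sites),
            " sites")
  access_instance(instance$blocks,
                  instance$sites[keep, , drop = FALSE],
                  instance$D[, keep, drop = FALSE], crs = instance$crs)
}

.as_ring <- function(boundary) {
  if (is.character(boundary) && length(boundary) == 1L) {
    gj <- jsonlite::fromJSON(boundary, simplifyVector = FALSE)
    geom <- if (!is.null(gj$type) && gj$type == "FeatureCollection")
      gj$features[[1]]$geometry
    else if (!is.null(gj$type) && gj$type == "Feature") gj$geometry
    else gj
    if (is.null(geom$type) || geom$type != "Polygon")
      stop("boundary GeoJSON must contain a Polygon", call. = FALSE)
    ring <- do.call(rbind, lapply(geom$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
  } else {
    ring <- as.matrix(boundary)
  }
  if (!is.numeric(ring) || ncol(ring) != 2L || nrow(ring) < 3L)
    stop("malformed boundary polygon", call. = FALSE)
  # drop duplicated closing vertex if present
  if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  if (nrow(ring) < 3L) stop("malformed boundary polygon", call. = FALSE)
  ring
}

# Even-odd ray casting; points exactly on an edge count as inside.
.point_in_polygon <- function(pts, ring) {
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  vapply(seq_len(nrow(pts)), function(i) {
    px <- pts[i, 1]; py <- pts[i, 2]
    inside <- FALSE
    j <- n
    for (k in seq_len(n)) {
      xi <- xs[k]; yi <- ys[k]; xj <- xs[j]; yj <- ys[j]
      if ((yi > py) != (yj > py)) {
        xc <- (xj - xi) * (py - yi) / (yj - yi) + xi
        if (px < xc) inside <- !inside
        if (px == xc) return(TRUE)
      }
      j <- k
    }
    inside
  }, logical(1))
}

# Minimum Euclidean distance from each point to the polygon outline.
.point_ring_distance <- function(pts, ring) {
  n <- nrow(ring)
  a <- ring
  b <- ring[c(2:n, 1), , drop = FALSE]
  vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    dx <- b[, 1] - a[, 1]; dy <- b[, 2] - a[, 2]
    len2 <- dx^2 + dy^2
    t <- ifelse(len2 > 0,
                pmin(1, pmax(0, ((p[1] - a[, 1]) * dx + (p[2] - a[, 2]) * dy) / len2)),
                0)
    qx <- a[, 1] + t * dx; qy <- a[, 2] + t * dy
    sqrt(min((p[1] - qx)^2 + (p[2] - qy)^2))
  }, numeric(1))
}

#' Read an access instance from CSV tables
#'
#' Canonical schemas: `blocks.csv` (block_id, x, y, population, optional
#' housing_density, area_km2), `sites.csv` (site_id, x, y, status), and
#' `distances.csv` either long-form (block_id, site_id, meters) or, with
#' `dense = TRUE`, a matrix layout whose first column holds block ids and
#' whose header row holds site ids.
#'
#' @param blocks_file,sites_file,distances_file CSV paths.
#' @param dense logical; is the distance file a dense matrix layout?
#' @param crs `"planar"` or `"lonlat"`.
#' @return An [access_instance()].
#' @export
read_instance <- function(blocks_file, sites_file, distances_file,
                          dense = FALSE, crs = "planar") {
  blocks <- utils::read.csv(blocks_file, stringsAsFactors = FALSE)
  sites <- utils::read.csv(sites_file, stringsAsFactors = FALSE)
  if (dense) {
    d <- utils::read.csv(distances_file, stringsAsFactors = FALSE,
                         check.names = FALSE)
    D <- as.matrix(d[, -1, drop = FALSE])
    rownames(D) <- as.character(d[[1]])
    access_instance(blocks, sites, D, crs = crs)
  } else {
    d <- utils::read.csv(distances_file, stringsAsFactors = FALSE)
    access_instance(blocks, sites, d, crs = crs)
  }
}

#' Write an access instance to CSV tables
#'
#' Inverse of [read_instance()]; writes the long-form distance layout.
#'
#' @param instance an [access_instance()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written (blocks, sites, distances).
#' @export
write_instance <- function(instance, dir) {
  stopifnot(inherits(instance, "access_instance"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("blocks.csv", "sites.csv", "distances.csv"))
  utils::write.csv(instance$blocks, paths[1], row.names = FALSE)
  utils::write.csv(instance$sites, paths[2], row.names = FALSE)
  long <- data.frame(
    block_id = rep(rownames(instance$D), times = ncol(instance$D)),
    site_id = rep(colnames(instance$D), each = nrow(instance$D)),
    meters = as.vector(instance$D),
    stringsAsFactors = FALSE
  )
  utils::write.csv(long, paths[3], row.names = FALSE)
  invisible(paths)
}
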