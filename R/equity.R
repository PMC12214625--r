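# Kolm-Pollak equity mathematics: data-scaled inequality aversion,
# the EDE itself, its linear proxy, and walk-time conversions.

#' Default walking speed used for walk-time conversions
#'
#' 80 metres per minute, the constant implied by the standard planning
#' equivalences 1200 m = 15 min, 800 m = 10 min and 400 m = 5 min.
#' Every conversion function accepts a `speed` argument to override it.
#' @export
WALK_M_PER_MIN <- 80

#' Access distribution: nearest-facility distances with population weights
#'
#' Bundles a vector of per-block nearest-facility walking distances (metres)
#' with the corresponding block populations. All equity statistics
#' ([kp_ede()], [kp_alpha()], [summarize_access()]) operate on this object.
#' Zero-weight entries are permitted (blocks with no residents occur in
#' census data) and contribute nothing to any statistic.
#'
#' @param distances numeric vector of non-negative, finite distances in
#'   metres, one per demand block.
#' @param weights numeric vector of non-negative block populations, same
#'   length as `distances`. Defaults to equal weights.
#' @return An object of class `access_dist`: a list with elements
#'   `distances`, `weights` and `total_population`.
#' @examples
#' d <- access_dist(c(100, 300, 900), c(10, 5, 1))
#' d$total_population
#' @export
access_dist <- function(distances, weights = rep(1, length(distances))) {
  distances <- as.numeric(distances)
  weights <- as.numeric(weights)
  if (length(distances) == 0L)
    stop("access_dist: empty distribution", call. = FALSE)
  if (length(weights) != length(distances))
    stop("access_dist: distances and weights must have equal length",
         call. = FALSE)
  if (anyNA(distances) || any(!is.finite(distances)))
    stop("access_dist: distances must be finite", call. = FALSE)
  if (any(distances < 0))
    stop("access_dist: distances must be non-negative", call. = FALSE)
  if (anyNA(weights) || any(!is.finite(weights)) || any(weights < 0))
    stop("access_dist: weights must be finite and non-negative",
         call. = FALSE)
  total <- sum(weights)
  if (total <= 0)
    stop("access_dist: total population must be positive", call. = FALSE)
  structure(
    list(distances = distances, weights = weights, total_population = total),
    class = "access_dist"
  )
}

#' @export
print.access_dist <- function(x, ...) {
  cat("Access distribution:", length(x$distances), "blocks,",
      format(x$total_population, big.mark = ","), "residents\n")
  cat(sprintf("  weighted mean distance: %.1f m\n", weighted_mean(x)))
  invisible(x)
}

#' Population-weighted mean of an access distribution
#'
#' @param dist an [access_dist()] object.
#' @return Weighted mean distance in metres.
#' @export
weighted_mean <- function(dist) {
  stopifnot(inherits(dist, "access_dist"))
  sum(dist$weights * dist$distances) / dist$total_population
}

#' Data-derived scaling of the inequality-aversion parameter
#'
#' The dimensionless aversion epsilon is scaled to the data through
#' \deqn{\alpha = \frac{\sum_r p_r z_r}{\sum_r p_r z_r^2},}
#' which has units 1/metres and makes the resulting EDE unit-invariant:
#' rescaling every distance by c rescales alpha by 1/c.
#'
#' @param dist an [access_dist()] object.
#' @return alpha (1/metres), strictly positive.
#' @examples
#' kp_alpha(access_dist(c(1, 3)))  # 4/10
#' @export
kp_alpha <- function(dist) {
  stopifnot(inherits(dist, "access_dist"))
  num <- sum(dist$weights * dist$distances)
  den <- sum(dist$weights * dist$distances^2)
  if (den <= 0)
    stop("kp_alpha: degenerate distribution (all positive-weight distances zero)",
         call. = FALSE)
  num / den
}

#' Equity parameters: aversion epsilon, scaling alpha, and kappa
#'
#' For undesirable quantities such as distance, `epsilon < 0` (default -1);
#' `kappa = alpha * epsilon` is the appropriately data-scaled aversion and
#' is negative under the default convention. All downstream formulas assume
#' this sign: the EDE then sits at or above the population-weighted mean.
#'
#' @param alpha positive data-derived scaling (1/metres), usually from
#'   [kp_alpha()] on the baseline distribution.
#' @param epsilon inequality-aversion scalar, negative for burdens.
#' @return An object of class `kp_params` with fields `epsilon`, `alpha`,
#'   `kappa`.
#' @examples
#' kp_params(alpha = 0.4)           # kappa = -0.4
#' @export
kp_params <- function(alpha, epsilon = -1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop("kp_params: alpha must be a positive finite scalar", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon))
    stop("kp_params: epsilon must be a finite scalar", call. = FALSE)
  if (epsilon == 0)
    stop("kp_params: epsilon = 0 gives kappa = 0; use the weighted mean instead",
         call. = FALSE)
  structure(
    list(epsilon = epsilon, alpha = alpha, kappa = alpha * epsilon),
    class = "kp_params"
  )
}

#' @export
print.kp_params <- function(x, ...) {
  cat(sprintf(
    "Kolm-Pollak parameters: epsilon = %g, alpha = %.6g /m, kappa = %.6g /m\n",
    x$epsilon, x$alpha, x$kappa))
  invisible(x)
}

.check_params <- function(params) {
  if (!inherits(params, "kp_params"))
    stop("expected a kp_params object (see kp_params())", call. = FALSE)
  if (params$kappa == 0)
    stop("kappa = 0 is invalid here; the limiting statistic is the weighted mean",
         call. = FALSE)
  invisible(params)
}

#' Kolm-Pollak equally-distributed-equivalent (EDE) distance
#'
#' The uniform distance a population would accept in exchange for its actual
#' unequal distribution:
#' \deqn{K(z) = -\frac{1}{\kappa}\,\ln\!\Big[\frac{1}{T}\sum_r p_r e^{-\kappa z_r}\Big],}
#' with T the total population. For kappa < 0 (aversion to inequality in a
#' burden) the EDE is at or above the weighted mean, with equality exactly
#' when all positive-weight distances are equal.
#'
#' Evaluated with a log-sum-exp shift (subtract the largest exponent) so
#' multi-kilometre distances cannot overflow.
#'
#' @param dist an [access_dist()] object.
#' @param params a [kp_params()] object with `kappa != 0`.
#' @return EDE in metres.
#' @examples
#' d <- access_dist(c(1, 3))
#' p <- kp_params(kp_alpha(d))     # kappa = -0.4
#' kp_ede(d, p)                    # about 2.195, above the mean of 2
#' @export
kp_ede <- function(dist, params) {
  stopifnot(inherits(dist, "access_dist"))
  .check_params(params)
  k <- params$kappa
  keep <- dist$weights > 0
  a <- -k * dist$distances[keep]          # exponents
  w <- dist$weights[keep] / dist$total_population
  if (max(abs(a)) < 50) {
    # small-exponent path: 1/T sum p e^a = 1 + sum (p/T) expm1(a), so the
    # log does not cancel against 1/kappa as kappa -> 0
    -log1p(sum(w * expm1(a))) / k
  } else {
    m <- max(a)
    -(m + log(sum(w * exp(a - m)))) / k   # shifted log-sum-exp: no overflow
  }
}

#' Linear proxy of the Kolm-Pollak EDE
#'
#' \deqn{\bar K(z) = \sum_r p_r e^{-\kappa z_r}.}
#' For fixed kappa and total population this is a strictly monotone
#' transform of the EDE, which is what makes the siting problem solvable
#' with a linear objective: minimizing the proxy minimizes the EDE.
#'
#' @inheritParams kp_ede
#' @return The proxy value (persons scale).
#' @seealso [proxy_to_ede()] for the inverse transform.
#' @export
kp_proxy <- function(dist, params) {
  stopifnot(inherits(dist, "access_dist"))
  .check_params(params)
  keep <- dist$weights > 0
  sum(dist$weights[keep] * exp(-params$kappa * dist$distances[keep]))
}

#' Convert a proxy objective value to an EDE distance
#'
#' Inverts the proxy: EDE = -(1/kappa) ln(proxy / T). Strictly increasing
#' in the proxy for kappa < 0.
#'
#' @param proxy positive proxy value.
#' @param total_population total population T > 0.
#' @param params a [kp_params()] object.
#' @return EDE in metres.
#' @export
proxy_to_ede <- function(proxy, total_population, params) {
  .check_params(params)
  if (!is.numeric(proxy) || proxy <= 0)
    stop("proxy_to_ede: proxy must be positive", call. = FALSE)
  if (total_population <= 0)
    stop("proxy_to_ede: total population must be positive", call. = FALSE)
  -log(proxy / total_population) / params$kappa
}

#' Convert a target EDE to a proxy-scale bound
#'
#' For a target access level of at most `target_ede` metres, the equivalent
#' bound on the linear proxy is L = T e^{-kappa * target}; proxy <= L
#' if and only if EDE <= target (kappa < 0). Used as the right-hand side of
#' the access constraint when minimizing the number of new facilities.
#'
#' @param target_ede non-negative target EDE in metres.
#' @param total_population total population T > 0.
#' @param params a [kp_params()] object.
#' @return Bound L on the proxy scale.
#' @export
ede_target_to_bound <- function(target_ede, total_population, params) {
  .check_params(params)
  if (!is.numeric(target_ede) || target_ede < 0)
    stop("ede_target_to_bound: target must be non-negative", call. = FALSE)
  if (total_population <= 0)
    stop("ede_target_to_bound: total population must be positive",
         call. = FALSE)
  total_population * exp(-params$kappa * target_ede)
}

#' Walk-time / distance conversions
#'
#' Linear conversion at 80 m per minute by default, the constant implied by
#' the planning equivalences 15 min = 1200 m, 10 min = 800 m, 5 min = 400 m.
#'
#' @param minutes non-negative walk time in minutes.
#' @param meters non-negative distance in metres.
#' @param speed walking speed in metres per minute.
#' @return Distance in metres, or time in minutes.
#' @examples
#' walk_time_to_distance(15)   # 1200
#' distance_to_walk_time(800)  # 10
#' @export
walk_time_to_distance <- function(minutes, speed = WALK_M_PER_MIN) {
  if (any(!is.finite(minutes)) || any(minutes < 0))
    stop("walk_time_to_distance: minutes must be non-negative", call. = FALSE)
  minutes * speed
}

#' @rdname walk_time_to_distance
#' @export
distance_to_walk_time <- function(meters, speed = WALK_M_PER_MIN) {
  if (any(!is.finite(meters)) || any(meters < 0))
    stop("distance_to_walk_time: meters must be non-negative", call. = FALSE)
  meters / speed
}
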