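# Distributional summaries and the study-style tables: population-weighted
# box-plot statistics, baseline-access city ranking, and target sweeps.

#' Population-weighted quantiles
#'
#' Inverse empirical CDF with lower interpolation: the q-quantile is the
#' smallest observed value whose cumulative weight reaches q of the total.
#' Duplicating every observation (doubling all weights) leaves every
#' quantile unchanged.
#'
#' @param x numeric values.
#' @param w non-negative weights.
#' @param probs probabilities in [0, 1].
#' @return Quantiles, one per element of `probs`.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0,
            all(probs >= 0 & probs <= 1))
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(q) x[which(cw >= q - 1e-12)[1]], numeric(1))
}

#' Population-weighted access summary
#'
#' The statistics behind a population-weighted box plot of access, plus
#' the equity numbers: weighted mean, Kolm-Pollak EDE, their gap (the
#' visual signature of inequality — residents substantially worse off
#' than average), weighted quartiles, 1.5 x IQR whisker bounds clipped to
#' the data range, and the EDE expressed as a walk time.
#'
#' @param dist an [access_dist()].
#' @param params a [kp_params()].
#' @return An `access_summary` list.
#' @export
summarize_access <- function(dist, params) {
  stopifnot(inherits(dist, "access_dist"))
  .check_params(params)
  m <- weighted_mean(dist)
  ede <- kp_ede(dist, params)
  qs <- weighted_quantile(dist$distances, dist$weights, c(0.25, 0.5, 0.75))
  iqr <- qs[3] - qs[1]
  lo_fence <- qs[1] - 1.5 * iqr
  hi_fence <- qs[3] + 1.5 * iqr
  keep <- dist$weights > 0
  z <- dist$distances[keep]
  structure(
    list(
      weighted_mean = m,
      ede = ede,
      ede_minus_mean = ede - m,
      q1 = qs[1], median = qs[2], q3 = qs[3],
      whisker_low = min(z[z >= lo_fence]),
      whisker_high = max(z[z <= hi_fence]),
      walk_time_ede = distance_to_walk_time(ede),
      total_population = dist$total_population,
      kappa = params$kappa
    ),
    class = "access_summary"
  )
}

#' @export
print.access_summary <- function(x, ...) {
  cat(sprintf("  weighted mean: %8.1f m\n", x$weighted_mean))
  cat(sprintf("  EDE:           %8.1f m  (%.1f min walk)\n",
              x$ede, x$walk_time_ede))
  cat(sprintf("  EDE - mean:    %8.1f m  (inequality gap)\n",
              x$ede_minus_mean))
  cat(sprintf("  quartiles:     Q1 %.1f | median %.1f | Q3 %.1f m\n",
              x$q1, x$median, x$q3))
  cat(sprintf("  whiskers:      [%.1f, %.1f] m\n",
              x$whisker_low, x$whisker_high))
  invisible(x)
}

#' Rank instances by baseline access EDE
#'
#' Ranks cities (instances) by their existing-store access EDE, best
#' (smallest) first, each with its own data-scaled alpha. Ties share a
#' dense rank, ordered among themselves by first occurrence in the input.
#'
#' @param instances named list of [access_instance()] objects.
#' @param epsilon inequality aversion used for every instance.
#' @return data.frame with columns `name`, `ede_m`, `mean_m`,
#'   `population`, `rank`, sorted best first.
#' @export
rank_instances <- function(instances, epsilon = -1) {
  stopifnot(is.list(instances), length(instances) > 0)
  nm <- names(instances)
  if (is.null(nm) || any(nm == ""))
    stop("instances must be a named list", call. = FALSE)
  rows <- lapply(nm, function(name) {
    inst <- instances[[name]]
    params <- baseline_equity_params(inst, epsilon = epsilon)
    base <- nearest_distances(inst)
    data.frame(name = name,
               ede_m = kp_ede(base, params),
               mean_m = weighted_mean(base),
               population = inst$total_population,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$ede_m)            # stable: ties keep input order
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- cumsum(!duplicated(tab$ede_m))   # dense ranking
  rownames(tab) <- NULL
  tab
}

#' Required new facilities across a sweep of access targets
#'
#' Runs [solve_min_stores()] for each target EDE and tabulates the
#' minimum number of new facilities, with `NA` marking infeasible targets
#' (the candidate grid is too coarse to reach them). Counts are
#' non-increasing as the target loosens.
#'
#' @param instance an [access_instance()].
#' @param targets numeric vector of target EDEs in metres.
#' @param params [kp_params()]; defaults to the baseline calibration.
#' @param solver_opts passed through to the solves.
#' @return data.frame with columns `target_m`, `target_min` (walk time),
#'   `n_new` (NA when infeasible), `achieved_ede_m`, `status`.
#' @export
target_sweep <- function(instance, targets,
                         params = baseline_equity_params(instance),
                         solver_opts = list()) {
  stopifnot(is.numeric(targets), length(targets) > 0)
  rows <- lapply(targets, function(t_m) {
    plan <- solve_min_stores(instance, t_m, params, solver_opts)
    data.frame(
      target_m = t_m,
      target_min = distance_to_walk_time(t_m),
      n_new = if (plan$solver_status == "infeasible") NA_integer_ else plan$k,
      achieved_ede_m = if (plan$solver_status == "infeasible") NA_real_
                       else plan$achieved_ede,
      status = plan$solver_status,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}
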