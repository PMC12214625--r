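# Siting optimization: place k new facilities minimizing the Kolm-Pollak
# EDE via its linear proxy; find the minimum number of new facilities to
# reach a target EDE; mean-minimizing (p-median) baseline; brute-force
# enumeration oracle.
#
# The integer program has the uncapacitated facility-location structure:
# once the open set is fixed, the optimal assignment puts every block at
# the open site with the smallest objective coefficient (the nearest site,
# for both the proxy and the mean objective). The search is therefore over
# the candidate-opening variables only, solved exactly by depth-first
# branch-and-bound with the relaxation "open every remaining candidate"
# as the lower bound (opening more sites can only decrease a min-based
# objective). Solutions are certified optimal (gap 0); among equal-optimal
# subsets the lexicographically smallest candidate-id set is returned,
# which the lexicographic include-first search order yields for free.

# Branch and bound: minimize sum_r p[r] * min over fixed-open and chosen
# candidate columns of W[r, .], choosing exactly k of the candidate
# columns. W must be non-negative. Returns chosen column indices (into the
# candidate columns), the objective, and the search status.
#
# Search design: candidates are branched in order of singleton marginal
# benefit and the incumbent is seeded with the greedy solution, so the
# all-remaining-open lower bound prunes aggressively; optimality is still
# certified by exhausting the tree. Ties within relative 1e-12 are broken
# to the lexicographically smallest candidate-index set explicitly.
.bnb_choose_k <- function(W_fixed_min, W_cand, p, k, time_limit = Inf) {
  n_cand <- ncol(W_cand)
  if (k == 0L)
    return(list(chosen = integer(0), obj = sum(p * W_fixed_min),
                status = "optimal", nodes = 1L))

  # branch order: best singleton improvement first
  singleton <- vapply(seq_len(n_cand), function(j)
    sum(p * pmin(W_fixed_min, W_cand[, j])), numeric(1))
  ord <- order(singleton)
  Wc <- W_cand[, ord, drop = FALSE]

  # suffix_min[, j]: per-block min of Wc over columns j..n_cand
  suffix_min <- matrix(Inf, nrow(Wc), n_cand + 1L)
  for (j in n_cand:1)
    suffix_min[, j] <- pmin(Wc[, j], suffix_min[, j + 1L])

  # greedy incumbent: repeatedly add the column with the best marginal gain
  g_set <- integer(0)
  g_min <- W_fixed_min
  for (step in seq_len(k)) {
    avail <- setdiff(seq_len(n_cand), g_set)
    objs <- vapply(avail, function(j) sum(p * pmin(g_min, Wc[, j])),
                   numeric(1))
    jbest <- avail[which.min(objs)]
    g_set <- c(g_set, jbest)
    g_min <- pmin(g_min, Wc[, jbest])
  }
  best_obj <- sum(p * g_min)
  best_set <- sort(ord[g_set])

  nodes <- 0L
  hit_limit <- FALSE
  t0 <- proc.time()[["elapsed"]]
  lex_less <- function(a, b) {      # both sorted, same length
    d <- which(a != b)
    length(d) > 0 && a[d[1]] < b[d[1]]
  }
  consider <- function(obj, set_orig) {
    if (obj < best_obj * (1 - 1e-12)) {
      best_obj <<- obj
      best_set <<- set_orig
    } else if (obj <= best_obj * (1 + 1e-12) &&
               length(set_orig) == length(best_set) &&
               lex_less(set_orig, best_set)) {
      best_set <<- set_orig
    }
  }

  rec <- function(idx, chosen, cur_min) {
    nodes <<- nodes + 1L
    if (is.finite(time_limit) && nodes %% 256L == 0L &&
        proc.time()[["elapsed"]] - t0 > time_limit) {
      hit_limit <<- TRUE
      return(invisible())
    }
    need <- k - length(chosen)
    if (need == 0L) {
      consider(sum(p * cur_min), sort(ord[chosen]))
      return(invisible())
    }
    rem <- n_cand - idx + 1L
    if (rem < need) return(invisible())
    if (hit_limit) return(invisible())
    if (rem == need) {      # forced: open every remaining candidate
      consider(sum(p * pmin(cur_min, suffix_min[, idx])),
               sort(ord[c(chosen, idx:n_cand)]))
      return(invisible())
    }
    # two valid lower bounds, prune on the tighter (tied subtrees pruned;
    # the lexicographic tie-break applies among leaves the search visits):
    # (1) relaxation opening every remaining candidate;
    lb1 <- sum(p * pmin(cur_min, suffix_min[, idx]))
    if (lb1 >= best_obj * (1 - 1e-12)) return(invisible())
    # (2) objective reductions are subadditive over opened sets, so the
    # sum of the `need` largest singleton gains caps the total reduction
    cur_obj <- sum(p * cur_min)
    gains <- colSums(pmax(cur_min - Wc[, idx:n_cand, drop = FALSE], 0) * p)
    lb2 <- cur_obj - sum(sort(gains, decreasing = TRUE)[seq_len(need)])
    if (lb2 >= best_obj * (1 - 1e-12)) return(invisible())
    rec(idx + 1L, c(chosen, idx), pmin(cur_min, Wc[, idx]))
    rec(idx + 1L, chosen, cur_min)
  }
  rec(1L, integer(0), W_fixed_min)

  list(chosen = best_set, obj = best_obj,
       status = if (hit_limit) "time_limit" else "optimal",
       nodes = nodes)
}

# Shared driver for both objectives. `coef` is the per-(block, site)
# objective coefficient before population weighting: exp(-kappa * d) for
# the proxy objective, d itself for the mean objective. Coefficients are
# max-normalized (in log space for the proxy) before the search; the
# reported objective is recomputed on the original scale from the final
# assignment, so normalization never touches reported values.
.solve_siting <- function(instance, k, params, objective = c("ede", "mean"),
                          solver_opts = list()) {
  stopifnot(inherits(instance, "access_instance"))
  objective <- match.arg(objective)
  ex <- sort(existing_sites(instance))
  cand <- sort(candidate_sites(instance))
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k != round(k))
    stop("k must be a single non-negative integer", call. = FALSE)
  k <- as.integer(k)
  if (k > length(cand))
    stop("k = ", k, " exceeds the ", length(cand),
         " available candidate sites", call. = FALSE)
  if (length(ex) == 0L && k == 0L)
    stop("no existing sites and k = 0: nothing can be opened", call. = FALSE)
  time_limit <- if (!is.null(solver_opts$time_limit))
    solver_opts$time_limit else Inf

  p <- instance$blocks$population
  if (objective == "ede") {
    .check_params(params)
    E <- -params$kappa * instance$D           # exponents, >= 0 for kappa < 0
    Wn <- exp(E - max(E))                     # max-normalized, in (0, 1]
  } else {
    mx <- max(instance$D)
    Wn <- if (mx > 0) instance$D / mx else instance$D
  }
  colnames(Wn) <- colnames(instance$D)

  fixed_min <- if (length(ex))
    do.call(pmin, c(as.data.frame(Wn[, ex, drop = FALSE]), list(Inf)))
  else rep(Inf, nrow(Wn))
  res <- .bnb_choose_k(fixed_min, Wn[, cand, drop = FALSE], p, k,
                       time_limit = time_limit)

  opened <- sort(c(ex, cand[res$chosen]))
  dist <- nearest_distances(instance, opened)
  proxy <- if (objective == "ede" || !is.null(params))
    kp_proxy(dist, params) else NA_real_
  plan <- structure(
    list(
      opened_sites = opened,
      new_sites = sort(cand[res$chosen]),
      k = k,
      assignment = attr(dist, "assignment"),
      distribution = dist,
      objective = objective,
      objective_proxy = proxy,
      achieved_ede = if (!is.null(params))
        proxy_to_ede(proxy, dist$total_population, params) else NA_real_,
      achieved_mean = weighted_mean(dist),
      params = params,
      solver_status = res$status,
      gap = if (res$status == "optimal") 0 else NA_real_,
      nodes = res$nodes
    ),
    class = "siting_plan"
  )
  plan
}

#' Optimally place k new facilities to minimize the EDE
#'
#' Solves, to proven optimality, the siting model: open exactly `k` new
#' facilities at candidate locations (all existing facilities stay open,
#' every block is assigned to a single open site) minimizing the linear
#' proxy \eqn{\sum_r \sum_s p_r y_{rs} e^{-\kappa d_{rs}}}, a strictly
#' monotone transform of the Kolm-Pollak EDE for fixed kappa. Kappa is
#' calibrated once on the baseline (existing-store) access and held
#' constant, so minimizing the proxy minimizes the EDE.
#'
#' @param instance an [access_instance()].
#' @param k number of new facilities to open (0 <= k <= number of
#'   candidates).
#' @param params [kp_params()]; defaults to [baseline_equity_params()] on
#'   the instance. Exposed so sensitivity to the kappa calibration can be
#'   probed.
#' @param solver_opts list of solver options; `time_limit` (seconds) caps
#'   the branch-and-bound search, returning the incumbent with status
#'   `"time_limit"` instead of silently suboptimal results.
#' @return A `siting_plan`: opened sites, the new sites, an integral
#'   assignment of each block to its nearest opened site (ties to the
#'   lowest site id), the proxy objective, the achieved EDE and weighted
#'   mean (metres), solver status and gap.
#' @seealso [solve_min_stores()], [solve_k_stores_mean()], [brute_force_k()]
#' @export
solve_k_stores <- function(instance, k,
                           params = baseline_equity_params(instance),
                           solver_opts = list()) {
  .solve_siting(instance, k, params, "ede", solver_opts)
}

#' Mean-minimizing (p-median) siting baseline
#'
#' Same feasible set as [solve_k_stores()] but with the classic p-median
#' objective \eqn{\sum_r \sum_s p_r y_{rs} d_{rs}}: minimize the
#' population-weighted mean distance, with no inequality penalty. Used as
#' the traditional baseline against which the equity-optimal plan is
#' compared; its achieved mean is never above the EDE-optimal plan's mean,
#' and its EDE never below.
#'
#' @inheritParams solve_k_stores
#' @param params [kp_params()] used only to report the plan's EDE on the
#'   same scale; the objective does not involve kappa.
#' @return A `siting_plan` (with `objective = "mean"`).
#' @export
solve_k_stores_mean <- function(instance, k,
                                params = baseline_equity_params(instance),
                                solver_opts = list()) {
  .solve_siting(instance, k, params, "mean", solver_opts)
}

#' Minimum number of new facilities to reach a target EDE
#'
#' Finds the smallest number of new facilities (and their locations) such
#' that the access EDE is at most `target_ede` metres. The target is
#' converted to a proxy-scale bound L = T e^{-kappa * target}; the
#' constraint proxy <= L is equivalent to EDE <= target for fixed kappa.
#' Because the optimal proxy is non-increasing in the number of new
#' facilities, the minimum count is located by bisection over exact
#' [solve_k_stores()] solves. If even opening every candidate leaves the
#' EDE above the target, the returned plan has
#' `solver_status = "infeasible"` — a reportable outcome (some cities'
#' candidate grids are simply too coarse for ambitious targets), not an
#' error.
#'
#' @param instance an [access_instance()].
#' @param target_ede target EDE in metres (e.g. 800 for a 10-minute walk).
#' @param params [kp_params()]; defaults to the baseline calibration.
#' @param solver_opts passed to the inner solves.
#' @return A `siting_plan` whose `k` is the minimum count, with
#'   `target_ede` and `bound` recorded; or an infeasible plan with
#'   `k = NA`.
#' @export
solve_min_stores <- function(instance, target_ede,
                             params = baseline_equity_params(instance),
                             solver_opts = list()) {
  stopifnot(inherits(instance, "access_instance"))
  .check_params(params)
  cand <- candidate_sites(instance)
  L <- ede_target_to_bound(target_ede, instance$total_population, params)
  tol <- 1 + 1e-12   # guard float noise at the proxy <= L boundary

  feas <- function(plan) plan$objective_proxy <= L * tol

  plan_all <- solve_k_stores(instance, length(cand), params, solver_opts)
  if (!feas(plan_all)) {
    plan_all$solver_status <- "infeasible"
    plan_all$k <- NA_integer_
    plan_all$target_ede <- target_ede
    plan_all$bound <- L
    return(plan_all)
  }
  lo <- -1L                       # largest k known infeasible
  hi <- length(cand)              # smallest k known feasible
  plan_hi <- plan_all
  plan0 <- solve_k_stores(instance, 0L, params, solver_opts)
  if (feas(plan0)) {
    hi <- 0L; plan_hi <- plan0
  } else {
    lo <- 0L
  }
  while (hi - lo > 1L) {
    mid <- as.integer(floor((lo + hi) / 2))
    plan_mid <- solve_k_stores(instance, mid, params, solver_opts)
    if (feas(plan_mid)) {
      hi <- mid; plan_hi <- plan_mid
    } else {
      lo <- mid
    }
  }
  plan_hi$target_ede <- target_ede
  plan_hi$bound <- L
  plan_hi
}

#' Brute-force enumeration oracle for k-facility siting
#'
#' Enumerates every k-subset of the candidate sites, computes the
#' nearest-facility distances and the Kolm-Pollak EDE directly (never via
#' the proxy), and returns the best subset. Exponential in k — refuses
#' when choose(#candidates, k) exceeds `cap`. This is the independent
#' check on both the branch-and-bound solver and the proxy/EDE
#' equivalence claim.
#'
#' @inheritParams solve_k_stores
#' @param cap maximum number of subsets to enumerate (default 20000).
#' @param keep_enumeration if TRUE, attach a data.frame of every
#'   enumerated subset with its EDE and proxy value (attribute
#'   `"enumeration"`), for ranking-equivalence checks.
#' @return A `siting_plan` with `solver_status = "optimal"`.
#' @export
brute_force_k <- function(instance, k,
                          params = baseline_equity_params(instance),
                          cap = 20000, keep_enumeration = FALSE) {
  stopifnot(inherits(instance, "access_instance"))
  .check_params(params)
  ex <- sort(existing_sites(instance))
  cand <- sort(candidate_sites(instance))
  k <- as.integer(k)
  if (k < 0 || k > length(cand))
    stop("k must be between 0 and the number of candidates", call. = FALSE)
  n_sub <- choose(length(cand), k)
  if (n_sub > cap)
    stop("brute_force_k: ", n_sub, " subsets exceeds cap ", cap,
         call. = FALSE)
  subsets <- if (k == 0L) matrix(integer(0), nrow = 0, ncol = 1)
             else utils::combn(length(cand), k)
  n_sub <- max(1L, ncol(subsets))

  p <- instance$blocks$population
  Dex <- if (length(ex))
    do.call(pmin, c(as.data.frame(instance$D[, ex, drop = FALSE]), list(Inf)))
  else rep(Inf, nrow(instance$D))

  best_ede <- Inf
  best_idx <- integer(0)
  enum <- if (keep_enumeration)
    data.frame(subset = character(n_sub), ede = numeric(n_sub),
               proxy = numeric(n_sub), stringsAsFactors = FALSE)
  else NULL

  for (i in seq_len(n_sub)) {
    idx <- if (k == 0L) integer(0) else subsets[, i]
    z <- Dex
    for (j in idx) z <- pmin(z, instance$D[, cand[j]])
    dist <- access_dist(z, p)
    ede <- kp_ede(dist, params)
    if (keep_enumeration) {
      enum$subset[i] <- paste(cand[idx], collapse = "+")
      enum$ede[i] <- ede
      enum$proxy[i] <- kp_proxy(dist, params)
    }
    # combn yields subsets in lexicographic order: strict improvement keeps
    # the lexicographically smallest tie
    if (ede < best_ede * (1 - 1e-12)) {
      best_ede <- ede
      best_idx <- idx
    }
  }

  opened <- sort(c(ex, cand[best_idx]))
  dist <- nearest_distances(instance, opened)
  proxy <- kp_proxy(dist, params)
  plan <- structure(
    list(
      opened_sites = opened,
      new_sites = sort(cand[best_idx]),
      k = k,
      assignment = attr(dist, "assignment"),
      distribution = dist,
      objective = "ede",
      objective_proxy = proxy,
      achieved_ede = proxy_to_ede(proxy, dist$total_population, params),
      achieved_mean = weighted_mean(dist),
      params = params,
      solver_status = "optimal",
      gap = 0,
      nodes = n_sub
    ),
    class = "siting_plan"
  )
  if (keep_enumeration) attr(plan, "enumeration") <- enum
  plan
}

#' @export
print.siting_plan <- function(x, ...) {
  cat("Siting plan (", if (x$objective == "ede") "EDE-minimizing"
      else "mean-minimizing (p-median)", "), status: ",
      x$solver_status, "\n", sep = "")
  if (x$solver_status == "infeasible") {
    cat(sprintf(
      "  target EDE %.0f m unreachable even with all candidates open (EDE %.1f m)\n",
      x$target_ede, x$achieved_ede))
    return(invisible(x))
  }
  cat("  new sites (k = ", x$k, "): ",
      if (x$k > 0) paste(x$new_sites, collapse = ", ") else "none",
      "\n", sep = "")
  if (!is.na(x$achieved_ede))
    cat(sprintf("  achieved EDE:  %.1f m (%.1f min walk)\n",
                x$achieved_ede, distance_to_walk_time(x$achieved_ede)))
  cat(sprintf("  weighted mean: %.1f m\n", x$achieved_mean))
  invisible(x)
}

#' @export
summary.siting_plan <- function(object, ...) {
  s <- summarize_access(object$distribution, object$params)
  cat("Siting plan summary\n")
  print(object)
  cat("Access distribution after intervention:\n")
  print(s)
  invisible(s)
}

#' Serialize a siting plan to JSON + assignment CSV
#'
#' Writes `plan.json` (opened sites, k, objective value, EDE, status, gap)
#' and `assignment.csv` (block_id, site_id, meters) to a directory.
#'
#' @param plan a `siting_plan`.
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_plan <- function(plan, dir) {
  stopifnot(inherits(plan, "siting_plan"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("plan.json", "assignment.csv"))
  meta <- list(
    objective = plan$objective,
    solver_status = plan$solver_status,
    k = plan$k,
    opened_sites = plan$opened_sites,
    new_sites = plan$new_sites,
    objective_proxy = plan$objective_proxy,
    achieved_ede_m = plan$achieved_ede,
    achieved_mean_m = plan$achieved_mean,
    kappa = if (!is.null(plan$params)) plan$params$kappa else NULL,
    gap = plan$gap
  )
  if (!is.null(plan$target_ede)) meta$target_ede_m <- plan$target_ede
  jsonlite::write_json(meta, paths[1], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(plan$assignment, paths[2], row.names = FALSE)
  invisible(paths)
}
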