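# Siting optimization: exactness against enumeration, Q2 semantics,
# p-median comparison, monotonicity and determinism.

test_that("k = 0 reproduces the baseline; k = all opens everything", {
  inst <- small_city(1)
  params <- baseline_equity_params(inst)
  base <- nearest_distances(inst)

  p0 <- solve_k_stores(inst, 0, params)
  expect_equal(sort(p0$opened_sites), sort(existing_sites(inst)))
  expect_equal(p0$achieved_ede, kp_ede(base, params), tolerance = 1e-12)

  kall <- length(candidate_sites(inst))
  pall <- solve_k_stores(inst, kall, params)
  expect_setequal(pall$opened_sites, inst$sites$site_id)
  all_open <- nearest_distances(inst, inst$sites$site_id)
  expect_equal(pall$achieved_ede, kp_ede(all_open, params),
               tolerance = 1e-12)

  expect_error(solve_k_stores(inst, kall + 1), "exceeds")
})

test_that("solver plans satisfy the model's structural constraints", {
  inst <- small_city(2)
  plan <- solve_k_stores(inst, 2)
  # all existing stores stay open
  expect_true(all(existing_sites(inst) %in% plan$opened_sites))
  # exactly k new sites, all candidates
  expect_length(plan$new_sites, 2)
  expect_true(all(plan$new_sites %in% candidate_sites(inst)))
  # every block assigned exactly once, to an opened site at its nearest
  a <- plan$assignment
  expect_equal(a$block_id, inst$blocks$block_id)
  expect_true(all(a$site_id %in% plan$opened_sites))
  z_min <- apply(inst$D[, plan$opened_sites, drop = FALSE], 1, min)
  expect_equal(a$meters, unname(z_min))
  # reported EDE is exactly the proxy converted
  expect_equal(plan$achieved_ede,
               proxy_to_ede(plan$objective_proxy, inst$total_population,
                            plan$params), tolerance = 1e-12)
  expect_equal(plan$solver_status, "optimal")
  expect_equal(plan$gap, 0)
})

test_that("branch-and-bound matches brute-force enumeration", {
  for (s in 1:12) {
    inst <- small_city(s, grid_n = 4, n_existing = 2, n_candidates = 8)
    params <- baseline_equity_params(inst)
    for (k in 1:2) {
      bb <- solve_k_stores(inst, k, params)
      bf <- brute_force_k(inst, k, params)
      expect_equal(bb$achieved_ede, bf$achieved_ede, tolerance = 1e-9,
                   label = sprintf("seed %d, k %d", s, k))
      expect_equal(bb$new_sites, bf$new_sites,
                   label = sprintf("sites seed %d, k %d", s, k))
    }
  }
})

test_that("p-median solve matches enumeration on the mean objective", {
  for (s in c(4, 9)) {
    inst <- small_city(s, grid_n = 4, n_candidates = 6)
    pm <- solve_k_stores_mean(inst, 2)
    # enumerate all 2-subsets by hand
    cand <- candidate_sites(inst)
    ex <- existing_sites(inst)
    combs <- utils::combn(cand, 2)
    means <- apply(combs, 2, function(cc)
      weighted_mean(nearest_distances(inst, c(ex, cc))))
    expect_equal(pm$achieved_mean, min(means), tolerance = 1e-12)
  }
})

test_that("achieved EDE is non-increasing in k and never worsens any block", {
  inst <- small_city(6)
  params <- baseline_equity_params(inst)
  prev <- NULL
  prev_z <- nearest_distances(inst)$distances
  for (k in 0:4) {
    plan <- solve_k_stores(inst, k, params)
    if (!is.null(prev)) expect_lte(plan$achieved_ede, prev + 1e-9)
    z <- nearest_distances(inst, plan$opened_sites)$distances
    expect_true(all(z <= prev_z + 1e-9))   # adding stores only helps
    prev <- plan$achieved_ede
  }
})

test_that("minimum-store solve brackets the target and handles trivial cases", {
  inst <- small_city(8)
  params <- baseline_equity_params(inst)
  base_ede <- solve_k_stores(inst, 0, params)$achieved_ede
  # target at/above baseline: nothing to do
  p <- solve_min_stores(inst, base_ede * 1.01, params)
  expect_equal(p$k, 0L)
  expect_equal(p$solver_status, "optimal")
  # achievable target below baseline: bracketing property
  all_ede <- solve_k_stores(inst, length(candidate_sites(inst)),
                            params)$achieved_ede
  target <- all_ede + 0.4 * (base_ede - all_ede)
  q <- solve_min_stores(inst, target, params)
  expect_equal(q$solver_status, "optimal")
  expect_lte(q$achieved_ede, target * (1 + 1e-9))
  expect_gte(q$k, 1)
  worse <- solve_k_stores(inst, q$k - 1L, params)
  expect_gt(worse$achieved_ede, target)
})

test_that("unreachable targets report infeasible, not an error", {
  inst <- small_city(5)
  params <- baseline_equity_params(inst)
  all_ede <- solve_k_stores(inst, length(candidate_sites(inst)),
                            params)$achieved_ede
  p <- solve_min_stores(inst, all_ede * 0.5, params)
  expect_equal(p$solver_status, "infeasible")
  expect_true(is.na(p$k))
})

test_that("p-median and EDE plans trade off as their objectives dictate", {
  for (s in 1:6) {
    inst <- perturb_access_inequality(small_city(s), 0.15, 3)
    params <- baseline_equity_params(inst)
    pe <- solve_k_stores(inst, 2, params)
    pm <- solve_k_stores_mean(inst, 2, params)
    expect_lte(pm$achieved_mean, pe$achieved_mean + 1e-9)
    expect_lte(pe$achieved_ede, pm$achieved_ede + 1e-9)
  }
})

test_that("identical inputs give identical plans (lexicographic ties)", {
  inst <- small_city(10)
  p1 <- solve_k_stores(inst, 2)
  p2 <- solve_k_stores(inst, 2)
  expect_identical(p1$opened_sites, p2$opened_sites)
  expect_identical(p1$assignment, p2$assignment)
  # duplicated candidate (same coordinates/distances, higher id): plan
  # still picks the lowest-id representative
  sites2 <- inst$sites
  dup <- sites2[sites2$site_id == p1$new_sites[1], ]
  dup$site_id <- "zz_dup"
  D2 <- cbind(inst$D, zz_dup = inst$D[, p1$new_sites[1]])
  inst2 <- access_instance(inst$blocks, rbind(sites2, dup), D2)
  p3 <- solve_k_stores(inst2, 2, baseline_equity_params(inst2))
  expect_false("zz_dup" %in% p3$new_sites)
  expect_equal(p3$new_sites, p1$new_sites)
})

test_that("brute force refuses when the enumeration cap is exceeded", {
  inst <- small_city(1, n_candidates = 16, grid_n = 6)
  expect_error(brute_force_k(inst, 8, cap = 100), "cap")
})

test_that("plan serialization writes JSON and assignment CSV", {
  inst <- small_city(4, grid_n = 4)
  plan <- solve_k_stores(inst, 1)
  dir <- tempfile()
  paths <- write_plan(plan, dir)
  meta <- jsonlite::fromJSON(paths[1])
  expect_equal(meta$k, 1)
  expect_equal(meta$solver_status, "optimal")
  expect_equal(meta$achieved_ede_m, plan$achieved_ede, tolerance = 1e-9)
  a <- utils::read.csv(paths[2])
  expect_equal(nrow(a), nrow(inst$blocks))
})
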