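# Instance model: validation, nearest-facility access, preprocessing
# filters, I/O round trip.

test_that("instance construction validates ids, coverage and signs", {
  inst <- tiny_instance()
  expect_s3_class(inst, "access_instance")
  expect_equal(inst$total_population, 2)
  expect_equal(dim(inst$D), c(2, 2))

  blocks <- inst$blocks; sites <- inst$sites
  long <- data.frame(block_id = rep(c("b1", "b2"), each = 2),
                     site_id = rep(c("s1", "s2"), 2),
                     meters = c(100, 700, 900, 300))
  # missing pair named in the error
  expect_error(access_instance(blocks, sites, long[-3, ]),
               "missing 1 .*\\(b2, s1\\)")
  # duplicate ids
  expect_error(access_instance(rbind(blocks, blocks[1, ]), sites,
                               long), "duplicate block_id: b1")
  expect_error(access_instance(blocks, rbind(sites, sites[2, ]), long),
               "duplicate site_id: s2")
  # negative values
  bad <- long; bad$meters[1] <- -5
  expect_error(access_instance(blocks, sites, bad), "non-negative")
  bb <- blocks; bb$population[1] <- -1
  expect_error(access_instance(bb, sites, long), "non-negative")
  # dense matrix input equivalent to long form
  D <- matrix(c(100, 900, 700, 300), 2, 2,
              dimnames = list(c("b1", "b2"), c("s1", "s2")))
  inst2 <- access_instance(blocks, sites, D)
  expect_equal(inst2$D, inst$D)
})

test_that("nearest distances take the min over open sites with low-id ties", {
  inst <- tiny_instance()
  # one open site: every block at its distance to that site
  d1 <- nearest_distances(inst, "s1")
  expect_equal(d1$distances, c(100, 900))
  # both open: {(100, 700), (900, 300)} -> [100, 300]
  d2 <- nearest_distances(inst, c("s1", "s2"))
  expect_equal(d2$distances, c(100, 300))
  expect_equal(attr(d2, "assignment")$site_id, c("s1", "s2"))
  # superset monotonicity
  expect_true(all(d2$distances <= d1$distances))
  expect_error(nearest_distances(inst, character(0)), "empty")
  # tie broken to the lowest site id
  Dt <- matrix(c(50, 50), 1, 2, dimnames = list("b1", c("s2", "s1")))
  instt <- access_instance(
    data.frame(block_id = "b1", x = 0, y = 0, population = 1),
    data.frame(site_id = c("s2", "s1"), x = 0, y = 0,
               status = c("existing", "existing")), Dt)
  expect_equal(attr(nearest_distances(instt), "assignment")$site_id, "s1")
})

test_that("all-open distances are a pointwise lower envelope", {
  inst <- small_city(7)
  all_open <- nearest_distances(inst, inst$sites$site_id)
  for (s in inst$sites$site_id[c(1, 3, 5)]) {
    expect_true(all(all_open$distances <=
                      nearest_distances(inst, s)$distances + 1e-12))
  }
})

test_that("baseline equity params use existing stores only and scale with epsilon", {
  blocks <- data.frame(block_id = c("b1", "b2"), x = 0, y = 0,
                       population = c(1, 1))
  sites <- data.frame(site_id = c("s1", "s2"), x = 0, y = 0,
                      status = c("existing", "candidate"))
  # baseline distances to the existing store: [1, 3] -> kappa = -0.4
  long <- data.frame(block_id = c("b1", "b1", "b2", "b2"),
                     site_id = c("s1", "s2", "s1", "s2"),
                     meters = c(1, 0.1, 3, 0.1))
  inst <- access_instance(blocks, sites, long)
  expect_equal(baseline_equity_params(inst)$kappa, -0.4)
  expect_equal(baseline_equity_params(inst, epsilon = -2)$kappa, -0.8)
  # constant baseline z = d -> kappa = -1/d
  long$meters[c(1, 3)] <- 500
  expect_equal(baseline_equity_params(access_instance(blocks, sites, long))$kappa,
               -1 / 500)
})

test_that("density filter keeps blocks strictly above the threshold", {
  blocks <- data.frame(block_id = paste0("b", 1:3), x = 1:3, y = 0,
                       population = c(10, 20, 30),
                       housing_density = c(150, 250, 600))
  sites <- data.frame(site_id = "s1", x = 0, y = 0, status = "existing")
  long <- data.frame(block_id = blocks$block_id, site_id = "s1",
                     meters = c(100, 200, 300))
  inst <- access_instance(blocks, sites, long)
  f <- suppressMessages(filter_blocks_by_density(inst, 200))
  expect_equal(f$blocks$block_id, c("b2", "b3"))
  expect_equal(f$total_population, 50)   # removed population leaves T
  # threshold 0 with positive densities: identity
  expect_equal(filter_blocks_by_density(inst, 0)$blocks$block_id,
               blocks$block_id)
  # all below: error, downstream needs at least one block
  expect_error(suppressMessages(filter_blocks_by_density(inst, 1000)),
               "every block")
  # no density fields: warning, no-op
  inst2 <- access_instance(blocks[, 1:4], sites, long)
  expect_warning(f2 <- filter_blocks_by_density(inst2), "density")
  expect_equal(f2$blocks$block_id, blocks$block_id)
})

test_that("boundary buffer keeps near-edge existing stores, drops outside candidates", {
  # unit-km square city
  ring <- rbind(c(0, 0), c(10000, 0), c(10000, 10000), c(0, 10000))
  blocks <- data.frame(block_id = "b1", x = 5000, y = 5000, population = 1)
  sites <- data.frame(
    site_id = c("in_e", "near_e", "far_e", "in_c", "out_c"),
    x = c(5000, 13000, 18000, 6000, 11000),
    y = c(5000, 5000, 5000, 6000, 5000),
    status = c("existing", "existing", "existing", "candidate", "candidate"))
  long <- expand.grid(block_id = "b1", site_id = sites$site_id)
  long$meters <- 1000
  inst <- access_instance(blocks, sites, long)
  f <- suppressMessages(buffer_filter_sites(inst, ring, buffer_m = 5000))
  # existing 3 km outside: kept; existing 8 km outside: dropped;
  # candidate 1 km outside: dropped despite the buffer
  expect_setequal(f$sites$site_id, c("in_e", "near_e", "in_c"))
  expect_error(buffer_filter_sites(inst, ring[1:2, ]), "malformed")
})

test_that("GeoJSON boundaries are accepted for the buffer rule", {
  gj <- tempfile(fileext = ".geojson")
  writeLines(paste0(
    '{"type":"Feature","geometry":{"type":"Polygon","coordinates":',
    '[[[0,0],[10000,0],[10000,10000],[0,10000],[0,0]]]},"properties":{}}'),
    gj)
  blocks <- data.frame(block_id = "b1", x = 5000, y = 5000, population = 1)
  sites <- data.frame(site_id = c("s1", "s2"), x = c(5000, 30000),
                      y = 5000, status = "existing")
  long <- expand.grid(block_id = "b1", site_id = sites$site_id)
  long$meters <- 500
  inst <- access_instance(blocks, sites, long)
  f <- suppressMessages(buffer_filter_sites(inst, gj))
  expect_equal(f$sites$site_id, "s1")
})

test_that("filter order does not matter (density then buffer = buffer then density)", {
  inst <- small_city(13, grid_n = 6)
  thr <- stats::median(inst$blocks$housing_density)   # keeps some, drops some
  ring <- rbind(c(-100, -100), c(900, -100), c(900, 900), c(-100, 900))
  a <- suppressMessages(
    buffer_filter_sites(filter_blocks_by_density(inst, thr), ring, 400))
  b <- suppressMessages(
    filter_blocks_by_density(buffer_filter_sites(inst, ring, 400), thr))
  expect_equal(a$blocks, b$blocks)
  expect_equal(a$sites, b$sites)
  expect_equal(a$D, b$D)
})

test_that("write then read round-trips an instance", {
  inst <- small_city(3, grid_n = 4)
  dir <- tempfile()
  write_instance(inst, dir)
  back <- read_instance(file.path(dir, "blocks.csv"),
                        file.path(dir, "sites.csv"),
                        file.path(dir, "distances.csv"))
  expect_equal(back$blocks$block_id, inst$blocks$block_id)
  expect_equal(back$blocks$population, inst$blocks$population)
  expect_equal(back$sites, inst$sites)
  expect_equal(back$D, inst$D)
  expect_equal(back$total_population, inst$total_population)
})
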