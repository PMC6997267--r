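test_that("geography tessellates the unit square, deterministically per seed", {
  cfg <- sim_config(n_zones = 200, seed = 1)
  z1 <- generate_geography(cfg)
  z2 <- generate_geography(cfg)
  expect_equal(n_zones(z1), 200)
  expect_equal(sum(zone_areas(z1)), 1.0, tolerance = 1e-9)
  expect_identical(z1$geometry, z2$geometry)
  expect_identical(z1$population, z2$population)
  # different seed changes the draw
  z3 <- generate_geography(sim_config(n_zones = 200, seed = 2))
  expect_false(identical(z1$population, z3$population))
})

test_that("zone populations match the configured mean and peripheral zones are larger", {
  z <- generate_geography(sim_config(n_zones = 200, mean_population = 760, seed = 1))
  expect_lt(abs(mean(z$population) - 760) / 760, 0.10)
  # centre-dense seeds: central polygons smaller than peripheral on average
  cen <- zone_centroids(z)
  d <- sqrt((cen[, 1] - 0.5)^2 + (cen[, 2] - 0.5)^2)
  a <- zone_areas(z)
  expect_gt(mean(a[d > stats::median(d)]), mean(a[d <= stats::median(d)]))
})

test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(n_zones = 5), "n_zones")
  expect_error(sim_config(mean_population = 0), "mean_population")
  expect_error(sim_config(deprivation_smoothness = -1), "smoothness")
  expect_error(sim_config(quintile_relative_risks = c(1, 2, 3)), "relative_risks")
  expect_error(sim_config(quintile_relative_risks = c(1, 1, 1, 1, -2)), "relative_risks")
  expect_error(sim_config(base_rates = list(dfu = 1.2, lea = 0, death = 0)), "base_rates")
  expect_error(sim_config(window = c(2016, 2002)), "window")
})

test_that("deprivation quintiles are balanced, rank 1 = most deprived", {
  z <- generate_geography(sim_config(n_zones = 10, seed = 3))
  z <- assign_deprivation(z, smoothness = 0.1, seed = 3)
  expect_equal(as.vector(table(z$quintile)), rep(2L, 5))
  z2 <- generate_geography(sim_config(n_zones = 203, seed = 3))
  z2 <- assign_deprivation(z2, 0.1, seed = 3)
  expect_true(all(abs(tabulate(z2$quintile, 5) - 203 / 5) < 1))
  expect_error(assign_deprivation(z, -0.5, seed = 1), "smoothness")
})

test_that("deprivation smoothness controls spatial autocorrelation of quintiles", {
  # permutation oracle: fraction of queen-neighbour pairs sharing a quintile,
  # compared against the label-shuffled null
  z <- generate_geography(sim_config(n_zones = 150, seed = 11))
  qw <- queen_contiguity(z)
  pairs <- do.call(rbind, lapply(seq_along(qw$nb), function(i) {
    j <- qw$nb[[i]]; j <- j[j > i]
    if (length(j)) cbind(i, j) else NULL
  }))
  same_frac <- function(q) mean(q[pairs[, 1]] == q[pairs[, 2]])
  null_dist <- function(q, reps = 999) {
    vapply(seq_len(reps), function(k) same_frac(sample(q)), 0)
  }
  withr::with_seed(42, {
    z_rough <- assign_deprivation(z, smoothness = 0, seed = 21)
    obs_r <- same_frac(z_rough$quintile)
    null_r <- null_dist(z_rough$quintile)
    expect_lt(abs(obs_r - mean(null_r)), 2 * stats::sd(null_r))

    z_smooth <- assign_deprivation(z, smoothness = 0.5, seed = 21)
    obs_s <- same_frac(z_smooth$quintile)
    null_s <- null_dist(z_smooth$quintile)
    expect_gt(obs_s, stats::quantile(null_s, 0.975))
  })
})

test_that("risk surface multiplies baseline, quintile and planted effects", {
  z <- grid_zone_set(4, 5, quintile = rep_len(1:5, 20))
  # all multipliers 1: every probability equals the baseline
  cfg1 <- sim_config(n_zones = 20, quintile_relative_risks = rep(1, 5),
                     base_rates = list(dfu = 0.04, lea = 0.01, death = 0.2))
  s1 <- build_risk_surface(z, cfg1)
  expect_equal(s1$dfu, rep(0.04, 20))
  expect_equal(s1$lea, rep(0.01, 20))
  # quintile multiplier: quintile-1 zones doubled
  cfg2 <- sim_config(n_zones = 20, quintile_relative_risks = c(2, 1, 1, 1, 1),
                     base_rates = list(dfu = 0.04, lea = 0.01, death = 0.2))
  s2 <- build_risk_surface(z, cfg2)
  expect_equal(s2$dfu[z$quintile == 1], rep(0.08, sum(z$quintile == 1)))
  expect_equal(s2$dfu[z$quintile != 1], rep(0.04, sum(z$quintile != 1)))
  # planted hot cluster of radius 1 covers exactly the centre + queen neighbours
  cfg3 <- sim_config(n_zones = 20, quintile_relative_risks = rep(1, 5),
                     base_rates = list(dfu = 0.04, lea = 0.01, death = 0.2),
                     planted_hot = list(list(center = 8, radius = 1, rr = 3)))
  s3 <- build_risk_surface(z, cfg3)
  qw <- queen_contiguity(z)
  covered <- sort(c(8L, qw$nb[[8]]))
  expect_equal(which(s3$dfu > 0.04), covered)
  expect_equal(s3$dfu[covered], rep(0.12, length(covered)))
  # probabilities capped at 0.99
  cfg4 <- sim_config(n_zones = 20, quintile_relative_risks = rep(30, 5),
                     base_rates = list(dfu = 0.5, lea = 0.01, death = 0.2))
  expect_equal(max(build_risk_surface(z, cfg4)$dfu), 0.99)
  # unknown centre zone
  cfg5 <- sim_config(n_zones = 20,
                     planted_hot = list(list(center = 99, radius = 1, rr = 3)))
  expect_error(build_risk_surface(z, cfg5), "unknown cluster center")
  # quintiles must be assigned first
  z_noq <- zone_set(z$zone_id, z$geometry, z$population)
  expect_error(build_risk_surface(z_noq, cfg1), "quintile")
})

test_that("cohort simulation matches its binomial and coupling targets", {
  # one big zone so the binomial check is clean; LEA off so the DFU marginal
  # is exactly the surface probability
  z <- zone_set("Z1", list(list(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))),
                population = 10000L, quintile = 3L)
  cfg <- sim_config(n_zones = 10, seed = 5, quintile_relative_risks = rep(1, 5),
                    base_rates = list(dfu = 0.046, lea = 0, death = 0))
  surf <- build_risk_surface(z, cfg)
  coh <- simulate_cohort(z, surf, cfg)
  expect_equal(nrow(coh), 10000)
  n_dfu <- sum(!is.na(coh$dfu_date))
  expect_lt(abs(n_dfu - 460), 3 * sqrt(10000 * 0.046 * 0.954))
  expect_true(all(is.na(coh$lea_date)))
  expect_true(all(is.na(coh$death_date)))

  # zero probability everywhere -> zero events
  cfg0 <- sim_config(n_zones = 10, seed = 5, quintile_relative_risks = rep(1, 5),
                     base_rates = list(dfu = 0, lea = 0, death = 0))
  coh0 <- simulate_cohort(z, build_risk_surface(z, cfg0), cfg0)
  expect_true(all(is.na(coh0$dfu_date)) && all(is.na(coh0$death_date)))

  # seed determinism
  coh2 <- simulate_cohort(z, surf, cfg)
  expect_identical(coh, coh2)
})

test_that("about 80% of amputation cases have a prior ulcer on record", {
  z <- zone_set("Z1", list(list(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))),
                population = 40000L, quintile = 3L)
  cfg <- sim_config(n_zones = 10, seed = 9, quintile_relative_risks = rep(1, 5),
                    base_rates = list(dfu = 0.046, lea = 0.013, death = 0.25))
  coh <- simulate_cohort(z, build_risk_surface(z, cfg), cfg)
  lea <- !is.na(coh$lea_date)
  n_lea <- sum(lea)
  prior <- !is.na(coh$dfu_date[lea]) & coh$dfu_date[lea] <= coh$lea_date[lea]
  expect_lt(abs(mean(prior) - 0.8), 3 * sqrt(0.8 * 0.2 / n_lea))
  # death only ever follows a DFU or LEA history, never precedes events
  expect_silent(validate_records(coh, z))
  died <- !is.na(coh$death_date)
  expect_true(all(!is.na(coh$dfu_date[died]) | !is.na(coh$lea_date[died])))
})

test_that("the deprivation gradient in simulated cases is monotone in direction", {
  # quintile-1 share of DFU cases exceeds quintile-5 share under the default
  # (2.5, 1.5, 1.0, 0.8, 0.6) relative risks at study scale
  study <- simulate_study(sim_config(n_zones = 200, seed = 13))
  coh <- study$cohort
  q <- study$zones$quintile[match(coh$zone_id, study$zones$zone_id)]
  cases <- !is.na(coh$dfu_date)
  share <- tabulate(q[cases], 5) / sum(cases)
  expect_gt(share[1], share[5])
  expect_gt(share[1], 0.2)   # over-represented relative to zone share
})
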