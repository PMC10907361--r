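test_that("species pool generation is a pure function of its seed", {
  p1 <- generate_species_pool(10, seed = 1)
  p2 <- generate_species_pool(10, seed = 1)
  expect_identical(p1, p2)
  p3 <- generate_species_pool(10, seed = 2)
  expect_false(identical(p1$true_sti, p3$true_sti))
  expect_error(generate_species_pool(10, sti_sd = -1), "non-negative")
})

test_that("degenerate STI distribution collapses to its mean", {
  p <- generate_species_pool(10, sti_mean = 12, sti_sd = 0, seed = 3)
  expect_equal(p$true_sti, rep(12, 10))
  expect_true(all(p$true_breadth > 0))
  expect_true(all(p$body_size_m > 0))
})

test_that("pool STI sample mean obeys the CLT bound at n = 10000", {
  p <- generate_species_pool(10000, sti_mean = 12, sti_sd = 4, seed = 11)
  # 4 sigma/sqrt(n) band around the programmed mean
  expect_lt(abs(mean(p$true_sti) - 12), 4 * 4 / sqrt(10000))
})

test_that("genus blocks group consecutive species", {
  p <- generate_species_pool(12, genus_size = 5, seed = 1)
  expect_equal(as.integer(table(p$genus)), c(5L, 5L, 2L))
  expect_true(all(startsWith(p$species, p$genus)))
})

test_that("landscape construction matches its stated temperature model", {
  sc <- fast_scenario(warming_rate = 0, annual_noise_sd = 0, amplitude = 8)
  g <- generate_landscape(sc)
  for (y in sc$years)
    expect_equal(g$layers[[paste0("annual_", y)]], g$layers$bio01)

  sc <- fast_scenario(warming_rate = 0.05, annual_noise_sd = 0,
                      amplitude = 8)
  g <- generate_landscape(sc)
  # every cell's yearly series has OLS slope exactly the warming rate
  series <- sapply(sc$years, function(y) g$layers[[paste0("annual_", y)]][5, 7])
  expect_equal(unname(coef(lm(series ~ sc$years))[2]), 0.05)
  expect_equal(attr(g, "cell_warming")[3, 3], 0.05)
  # seasonal half-amplitude 8 -> cell-wise breadth 16 everywhere
  expect_equal(g$layers$bio10 - g$layers$bio11,
               matrix(16, sc$grid_nrow, sc$grid_ncol))
})

test_that("a latitudinal amplitude range varies bio10 - bio11 by row", {
  g <- generate_landscape(fast_scenario(amplitude = c(6, 10)))
  d <- g$layers$bio10 - g$layers$bio11
  expect_equal(d[1, 1], 20, tolerance = 0.5)      # northern edge
  expect_equal(d[nrow(d), 1], 12, tolerance = 0.5)  # southern edge
  expect_true(all(diff(d[, 1]) < 0))
})

test_that("occurrence generation is seeded, injects duplicates and errors", {
  pool <- generate_species_pool(5, seed = 1)
  g <- generate_landscape(fast_scenario())
  o1 <- generate_occurrences(pool, g, 50, seed = 4)
  o2 <- generate_occurrences(pool, g, 50, seed = 4)
  expect_identical(o1, o2)
  expect_equal(nrow(o1), 5 * 50)

  o3 <- generate_occurrences(pool, g, 50, duplicate_fraction = 0.2, seed = 4)
  expect_gt(sum(duplicated(o3[c("species", "latitude", "longitude")])), 0)
  o4 <- generate_occurrences(pool, g, 50, invalid_fraction = 0.1, seed = 4)
  expect_gt(sum(o4$latitude > 90), 0)
})

test_that("a species with no suitable habitat yields a warning, no records", {
  pool <- generate_species_pool(1, sti_mean = 90, sti_sd = 0,
                                breadth_meanlog = log(0.5), breadth_sdlog = 0,
                                seed = 1)
  g <- generate_landscape(fast_scenario())
  expect_warning(o <- generate_occurrences(pool, g, 20, seed = 1),
                 "suitability")
  expect_equal(nrow(o), 0L)
})

test_that("occurrence temperature distribution approaches the landscape's
           marginal as breadth becomes very large", {
  pool <- generate_species_pool(1, sti_mean = 10, sti_sd = 0,
                                breadth_meanlog = log(4000), breadth_sdlog = 0,
                                seed = 1)
  sc <- fast_scenario()
  g <- generate_landscape(sc)
  occ <- generate_occurrences(pool, g, 4000, k = 1, seed = 5)
  loc <- locate_cell(g, occ$latitude, occ$longitude)
  temps <- grid_values(g, "bio01", loc$row, loc$col)
  # direct uniform sampling over cells is the oracle for the flat-suitability
  # limit; compare distributions
  oracle <- sample(as.vector(g$layers$bio01), 4000, replace = TRUE)
  expect_gt(suppressWarnings(ks.test(temps, oracle)$p.value), 0.001)
  expect_lt(abs(mean(temps) - mean(g$layers$bio01)), 0.3)
})

test_that("a ubiquitous species persists every year with no adds or losses", {
  pool <- generate_species_pool(1, sti_mean = 10, sti_sd = 0,
                                breadth_meanlog = log(4000), breadth_sdlog = 0,
                                seed = 1)
  sc <- fast_scenario(n_sites = 5, n_species = 1, detection_prob = 1,
                      min_site_years = 12)
  g <- generate_landscape(sc)
  sim <- generate_community_timeseries(pool, g, sc)
  for (s in unique(sim$observations$site_id)) {
    sets <- species_sets(sim$observations[sim$observations$site_id == s, ])
    expect_equal(length(sets), length(sc$years))
    tr <- classify_fates(sets)
    expect_true(all(vapply(tr, function(t) length(t$added) == 0L, TRUE)))
    expect_true(all(vapply(tr, function(t) length(t$lost) == 0L, TRUE)))
  }
})

test_that("community simulation is reproducible and carries ground truth", {
  sc <- fast_scenario()
  g <- generate_landscape(sc)
  pool <- generate_species_pool(sc$n_species, seed = 2)
  s1 <- generate_community_timeseries(pool, g, sc, seed = 9)
  s2 <- generate_community_timeseries(pool, g, sc, seed = 9)
  expect_identical(s1$observations, s2$observations)
  expect_true(all(c("true_warming", "baseline_temp", "study_id") %in%
                    names(s1$sites)))
  expect_equal(anyDuplicated(s1$sites[c("latitude", "longitude")]), 0L)
})

test_that("realised site rates regress positively on true warming slopes", {
  sc <- fast_scenario(n_sites = 150, warming_rate = c(0, 0.08),
                      grid_nrow = 30, grid_ncol = 30, rng_seed = 21)
  sim <- simulate_dataset(sc)
  series <- cti_series(sim$observations, true_profiles(sim$pool))
  rates <- site_rates(series, sim$sites)
  fit <- summary(lm(slope ~ true_warming, data = rates))
  expect_gt(fit$coefficients["true_warming", "Estimate"], 0)
  expect_lt(fit$coefficients["true_warming", "Pr(>|t|)"], 0.01)
})
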