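test_that("site temperature trend is the windowed OLS slope", {
  expect_equal(site_temperature_trend(c(2000, 2010), c(10, 11)), 0.1)
  expect_equal(site_temperature_trend(2000:2010, rep(7.3, 11)), 0)
  expect_equal(site_temperature_trend(1990:2010, c(rep(0, 10), 5:15),
                                      window = c(2000, 2010)), 1)
  expect_error(site_temperature_trend(2000, 5), "2 distinct years")
})

test_that("noise-free landscapes give every site its programmed trend", {
  sc <- fast_scenario(warming_rate = 0.05, annual_noise_sd = 0)
  sim <- simulate_dataset(sc)
  for (i in c(1, 10, 25)) {
    ann <- annual_series(sim$grid, sim$sites$latitude[i],
                         sim$sites$longitude[i])
    expect_equal(site_temperature_trend(ann$year, ann$temperature), 0.05)
  }
})

test_that("z-scoring uses the sample sd and rejects constants", {
  expect_equal(zscore(1:3), c(-1, 0, 1))
  z <- zscore(rnorm(50, 5, 3))
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  expect_equal(zscore(z), z, tolerance = 1e-10)  # idempotent on re-use
  expect_error(zscore(c(5, 5)), "zero variance")
})

test_that("predictor correlation screen flags collinear and constant
           columns", {
  set.seed(2)
  x <- data.frame(a = rnorm(100), b = rnorm(100))
  x$dup <- x$a
  expect_warning(r <- predictor_correlations(x), "r = 1")
  expect_equal(r["a", "dup"], 1)
  x2 <- data.frame(a = rnorm(1000), b = rnorm(1000), k = 1)
  r2 <- suppressWarnings(predictor_correlations(x2))
  expect_lt(abs(r2["a", "b"]), 0.1)
  expect_true(all(is.na(r2["k", ])))
  expect_equal(attr(r2, "flags"), "k")
})

test_that("predictors assemble from rates, grid, profiles and traits", {
  pr <- make_profiles(c(sp1 = 10, sp2 = 12, sp3 = 14),
                      breadth = c(sp1 = 10, sp2 = 16, sp3 = 13))
  traits <- data.frame(species = c("sp1", "sp2"),
                       body_size_m = c(0.1, 0.3), stringsAsFactors = FALSE)
  ann <- setNames(lapply(0:10, function(i) matrix(10 + 0.1 * i, 1, 1)),
                  2000:2010)
  g <- make_grid(matrix(10, 1, 1), annual = ann)
  obs <- make_obs("A", rep(c(2000, 2010), each = 3),
                  rep(c("sp1", "sp2", "sp3"), 2))
  rates <- data.frame(site_id = "A", slope = 0.02, se = 0.01, n_years = 11L,
                      first_year = 2000L, last_year = 2010L, realm = "terrestrial",
                      taxon_group = "plants", study_id = "st1",
                      latitude = 9.5, longitude = 0.5,
                      stringsAsFactors = FALSE)
  expect_warning(sr <- assemble_predictors(rates, g, pr, traits, obs),
                 "coverage")  # 2/3 < 0.7
  expect_equal(sr$temp_change, 0.1)
  expect_equal(sr$mean_niche_breadth, 13)
  expect_equal(sr$mean_body_size, 0.2)
  expect_equal(sr$trait_coverage, 2 / 3, tolerance = 1e-12)
  expect_equal(sr$series_length, 10)
  expect_equal(sr$richness, 3L)
  # baseline over the 1980-2010 window: only years 2000-2010 exist
  expect_equal(sr$baseline_temp, mean(10 + 0.1 * (0:10)))
})

test_that("fit_lmm with no random or spatial terms is exactly OLS", {
  set.seed(9)
  d <- data.frame(y = rnorm(40), x1 = rnorm(40), x2 = rnorm(40))
  fit <- fit_lmm(d, y ~ x1 + x2)
  X <- cbind(1, d$x1, d$x2)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)[, 1]
  expect_lt(max(abs(fit$terms$estimate - beta)), 1e-8)
  # intercept-only: grand mean and REML (sample) variance
  fit0 <- fit_lmm(d, y ~ 1)
  expect_equal(fit0$terms$estimate, mean(d$y))
  expect_equal(unname(fit0$varcomp["Residual"]^2), var(d$y))
})

test_that("fit_lmm errors on singular designs, naming the aliased term", {
  d <- data.frame(y = rnorm(20), x = rnorm(20))
  d$x_copy <- d$x
  expect_error(fit_lmm(d, y ~ x + x_copy), "aliased.*x_copy")
})

test_that("fit_lmm recovers a fixed effect and variance components from
           data simulated under the model", {
  set.seed(14)
  n_g <- 100; m <- 10
  d <- data.frame(study_id = rep(sprintf("g%03d", 1:n_g), each = m),
                  x = rnorm(n_g * m))
  d$y <- 0.5 * d$x + rep(rnorm(n_g, 0, 1), each = m) + rnorm(n_g * m, 0, 0.5)
  fit <- fit_lmm(d, y ~ x, random = "study")
  tx <- fit_term(fit, "x")
  expect_lt(abs(tx$estimate - 0.5), 2 * tx$se)
  sds <- unname(fit$varcomp)
  expect_lt(abs(sds[1] - 1), 0.3)     # group-intercept sd within 30%
  expect_lt(abs(sds[2] - 0.5), 0.15)  # residual sd within 30%
})

test_that("Gaussian spatial correlation range is recovered from spatially
           autocorrelated residuals", {
  set.seed(15)
  n <- 150
  d <- data.frame(study_id = "s1",
                  longitude = runif(n, 0, 2), latitude = runif(n, 44, 46))
  lat0 <- mean(d$latitude) * pi / 180
  xy <- cbind(111.32 * cos(lat0) * d$longitude, 110.574 * d$latitude)
  dist2 <- as.matrix(dist(xy))^2
  rho_true <- 40  # km
  S <- 0.9 * exp(-dist2 / rho_true^2) + 0.1 * diag(n)
  d$y <- 1 + drop(t(chol(S)) %*% rnorm(n)) * 0.3
  fit <- fit_lmm(d, y ~ 1, random = "none", spatial = "gauss",
                 nugget = TRUE)
  expect_true(is.finite(fit$rho))
  expect_gt(fit$rho, 10); expect_lt(fit$rho, 160)
})

test_that("outlier refit excludes exactly the injected gross outlier, once", {
  set.seed(16)
  d <- data.frame(site_id = sprintf("s%02d", 1:30), x = seq(0, 1, length.out = 30))
  d$y <- 2 + 3 * d$x + rnorm(30, 0, 0.05)
  d$y[17] <- d$y[17] + 5
  fit <- fit_lmm(d, y ~ x)
  refit <- refit_without_outliers(fit, k_sd = 2)
  expect_equal(refit$excluded, "s17")
  expect_equal(refit$n, 29L)
  # all residuals equal -> nothing excluded, fit unchanged
  d2 <- data.frame(x = 1:10, y = 2 * (1:10))
  f2 <- fit_lmm(d2, y ~ x)
  expect_identical(refit_without_outliers(f2, 2)$n, 10L)
  # infinite cutoff excludes nothing
  expect_equal(refit_without_outliers(fit, Inf)$n, 30L)
})

test_that("realm comparison detects a programmed offset and rejects
           single-realm input", {
  set.seed(17)
  n <- 200
  mk <- function(realm, shift) data.frame(
    site_id = paste0(realm, 1:n), realm = realm,
    taxon_group = sample(c("t1", "t2"), n, TRUE),
    study_id = sample(sprintf("%s_st%d", realm, 1:10), n, TRUE),
    longitude = runif(n, 0, 5), latitude = runif(n, 40, 50),
    temp_change = rnorm(n, 0.03, 0.015),
    rate = rnorm(n, 0.01 + shift, 0.02), stringsAsFactors = FALSE)
  d <- rbind(mk("terrestrial", 0), mk("freshwater", 0.02))
  cmp <- realm_comparison(d, spatial = "none")
  tr <- cmp$realm$terms
  i <- grep("realm", tr$term)
  expect_lt(tr$p[i], 0.05)
  expect_true("temp_change:realmterrestrial" %in% cmp$interaction$terms$term)
  expect_error(realm_comparison(mk("terrestrial", 0)), "both realms")
})

test_that("taxon comparison reports a joint F test per realm and skips
           single-taxon realms", {
  set.seed(18)
  n <- 150
  d <- data.frame(
    site_id = paste0("s", 1:n), realm = "freshwater",
    taxon_group = sample(c("fish", "zooplankton", "aquatic_insects"), n, TRUE),
    study_id = sample(sprintf("st%d", 1:12), n, TRUE),
    longitude = runif(n), latitude = runif(n, 40, 42),
    rate = rnorm(n, 0.01, 0.02), stringsAsFactors = FALSE)
  d$rate[d$taxon_group == "fish"] <- d$rate[d$taxon_group == "fish"] + 0.05
  out <- taxon_comparison(d)
  expect_named(out, "freshwater")
  expect_lt(out$freshwater$joint$p, 0.05)
  expect_equal(out$freshwater$joint$df_num, 2)
  d1 <- d; d1$taxon_group <- "fish"
  expect_warning(out1 <- taxon_comparison(d1), "single taxon")
  expect_length(out1, 0L)
})

test_that("the full pipeline recovers the sign of the programmed warming
           effect", {
  hits <- 0L
  for (rep in 1:4) {
    sc <- simulation_scenario(n_sites = 70, n_species = 80,
                              years = 2000:2011, grid_nrow = 25,
                              grid_ncol = 25, rng_seed = 100 + rep)
    res <- run_warming_study(sc, config = analysis_config(
      n_rarefaction_reps = 9), n_occ_records = 120, spatial = "none")
    tt <- fit_term(res$driver, "temp_change")
    if (tt$estimate > 0 && tt$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 3L)
})
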