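test_that("occurrence cleaning removes duplicates, bad coordinates and
           preserved specimens", {
  occ <- data.frame(
    species = c("a", "a", "a", "a", "b"),
    latitude = c(1, 1, 0, 95, 2),
    longitude = c(2, 2, 0, 10, 3),
    basis = c(NA, NA, NA, NA, "PRESERVED_SPECIMEN"),
    stringsAsFactors = FALSE)
  out <- clean_occurrences(occ)
  rep <- attr(out, "report")
  expect_equal(nrow(out), 2L)  # duplicate, (0,0) and lat 95 removed
  expect_equal(rep$n[rep$reason == "duplicate"], 1L)
  expect_equal(rep$n[rep$reason == "zero_zero"], 1L)
  expect_equal(rep$n[rep$reason == "invalid_coordinate"], 1L)

  out2 <- clean_occurrences(occ, drop_preserved = TRUE)
  expect_false("b" %in% out2$species)
  expect_equal(attr(out2, "report")$n[4], 1L)  # one duplicate still counted
  expect_equal(nrow(clean_occurrences(occ[0, ])), 0L)
})

test_that("STI is the mean bio01 over unique occupied cells", {
  g <- make_grid(matrix(c(5, 7, 9, 11), 2, byrow = TRUE))
  occ <- data.frame(species = "x",
                    latitude = c(9.5, 9.5, 8.5),
                    longitude = c(0.5, 1.5, 0.5))
  pr <- estimate_sti(occ, g, min_records = 1)
  expect_equal(pr$sti, mean(c(5, 7, 9)))
  expect_equal(pr$n_records, 3L)
  expect_equal(pr$provenance, "species")
})

test_that("STI averages cells, not records: a cell counts once however
           densely it is sampled", {
  g <- make_grid(matrix(4, 1, 1))
  many <- data.frame(species = "x",
                     latitude = runif(100, 9.01, 9.99),
                     longitude = runif(100, 0.01, 0.99))
  one <- many[1, ]
  expect_equal(estimate_sti(many, g, min_records = 1)$sti, 4)
  expect_equal(estimate_sti(one, g, min_records = 1)$sti, 4)
  # per-record averaging is available behind the flag
  g2 <- make_grid(matrix(c(4, 8), 1, 2))
  occ <- data.frame(species = "x", latitude = rep(9.5, 3),
                    longitude = c(0.5, 0.5, 1.5))
  expect_equal(estimate_sti(occ, g2, min_records = 1, cells = FALSE)$sti,
               (4 + 4 + 8) / 3)
})

test_that("species under the record threshold are excluded and reported", {
  g <- make_grid(matrix(1:4, 2, byrow = TRUE))
  occ <- data.frame(species = rep("x", 4),
                    latitude = c(9.5, 9.5, 8.5, 8.5),
                    longitude = c(0.5, 1.5, 0.5, 1.5))
  pr <- estimate_sti(occ, g, min_records = 5)
  expect_equal(nrow(pr), 0L)
  exc <- attr(pr, "excluded")
  expect_equal(exc$species, "x")
  expect_equal(exc$reason, "too_few_records")
  expect_equal(exc$n_records, 4L)
  # all records out of extent is reported, not an error
  far <- data.frame(species = "y", latitude = -50, longitude = 100)
  exc2 <- attr(estimate_sti(far, g, min_records = 1), "excluded")
  expect_equal(exc2$reason, "out_of_extent")
})

test_that("STI is invariant to record order and bounded by occupied-cell
           temperatures", {
  g <- make_grid(matrix(seq(2, 24, length.out = 12), 3, 4, byrow = TRUE))
  set.seed(5)
  occ <- data.frame(species = sample(c("a", "b"), 60, TRUE),
                    latitude = runif(60, 7.01, 9.99),
                    longitude = runif(60, 0.01, 3.99))
  pr1 <- estimate_sti(occ, g, min_records = 1)
  pr2 <- estimate_sti(occ[sample(60), ], g, min_records = 1)
  expect_equal(pr1[order(pr1$species), ], pr2[order(pr2$species), ],
               ignore_attr = TRUE)
  loc <- locate_cell(g, occ$latitude, occ$longitude)
  for (sp in pr1$species) {
    temps <- grid_values(g, "bio01", loc$row, loc$col)[occ$species == sp]
    expect_gte(pr1$sti[pr1$species == sp], min(temps))
    expect_lte(pr1$sti[pr1$species == sp], max(temps))
  }
})

test_that("niche breadth is the difference of range-wide quarter means", {
  g <- make_grid(matrix(12, 1, 1), amplitude = 8)  # bio10 20, bio11 4
  occ <- data.frame(species = "x", latitude = 9.5, longitude = 0.5)
  expect_equal(estimate_niche_breadth(occ, g, min_records = 1)$niche_breadth,
               16)
  # two cells: mean(bio10) - mean(bio11) = 21 - 5
  g2 <- temperature_grid(10, 0, 1, list(
    bio01 = matrix(c(12, 14), 1, 2),
    bio10 = matrix(c(20, 22), 1, 2),
    bio11 = matrix(c(4, 6), 1, 2)))
  occ2 <- data.frame(species = "x", latitude = c(9.5, 9.5),
                     longitude = c(0.5, 1.5))
  expect_equal(estimate_niche_breadth(occ2, g2,
                                      min_records = 1)$niche_breadth, 16)
  expect_equal(estimate_niche_breadth(occ2, g2, min_records = 1,
                                      mode = "cell_diff_mean")$niche_breadth,
               16)
})

test_that("constant seasonal amplitude gives every species the same
           breadth", {
  sc <- fast_scenario(amplitude = 8)
  g <- generate_landscape(sc)
  pool <- generate_species_pool(20, seed = 6)
  occ <- generate_occurrences(pool, g, 30, seed = 6)
  br <- estimate_niche_breadth(occ, g, min_records = 1)
  expect_equal(br$niche_breadth, rep(16, nrow(br)))
})

test_that("genus and complex aggregation take unweighted member means", {
  pr <- make_profiles(c(`Poa alpina` = 10, `Poa annua` = 14,
                        `Carex alba` = 9.5, `Baetis a` = 8,
                        `Baetis b` = 10))
  agg <- aggregate_sti(pr,
                       complexes = data.frame(
                         complex = c("cx1", "cx1", "cx1", "cx2"),
                         species = c("Baetis a", "Baetis b", "Baetis c",
                                     "Zz zz"),
                         stringsAsFactors = FALSE))
  expect_equal(agg$sti[agg$species == "Poa"], 12)
  expect_equal(agg$provenance[agg$species == "Poa"], "genus_mean")
  expect_equal(agg$sti[agg$species == "Carex"], 9.5)  # singleton identity
  # unprofiled member dropped from the complex mean
  expect_equal(agg$sti[agg$species == "cx1"], 9)
  # complex with no profiled members gets no entry, is reported
  expect_false("cx2" %in% agg$species)
  expect_true("cx2" %in% attr(agg, "skipped"))
})

test_that("temporal STI stability is exact for time-invariant records and
           degenerate for empty bins", {
  g <- make_grid(matrix(seq(2, 24, length.out = 12), 3, 4, byrow = TRUE))
  set.seed(8)
  base <- data.frame(species = rep(sprintf("sp%02d", 1:8), each = 6),
                     latitude = runif(48, 7.01, 9.99),
                     longitude = runif(48, 0.01, 3.99))
  occ <- do.call(rbind, lapply(c(1985, 1995, 2005, 2015), function(y)
    transform(base, year = y)))
  st <- sti_temporal_stability(occ, g, min_records = 1)
  off <- st$correlation[upper.tri(st$correlation)]
  expect_equal(off, rep(1, length(off)))

  st2 <- sti_temporal_stability(occ[occ$year > 1990, ], g, min_records = 1)
  expect_true(all(is.na(st2$correlation["<=1990", ])))
  expect_equal(st2$n_shared["<=1990", "1991-2000"], 0L)
})

test_that("STIs estimated from generated occurrences recover the truth", {
  sc <- fast_scenario(baseline_temp_range = c(0, 20))
  g <- generate_landscape(sc)
  pool <- generate_species_pool(100, sti_mean = 10, sti_sd = 3, seed = 10)
  expect_gt(diff(range(pool$true_sti)), 10)
  occ <- generate_occurrences(pool, g, 200, seed = 10)
  pr <- estimate_sti(occ, g)
  m <- match(pr$species, pool$species)
  expect_gt(cor(pr$sti, pool$true_sti[m]), 0.9)
})
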