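test_that("moment-matched truncated normal hits its target moments", {
  set.seed(19)
  for (par in list(c(0.56, 0.46), c(1.38, 0.72), c(20.31, 0.38), c(539.6, 49.4))) {
    x <- rtnorm_match(5e4, par[1], par[2])
    expect_true(all(x >= 0))
    expect_lt(abs(mean(x) - par[1]), 4 * par[2] / sqrt(5e4))
    expect_lt(abs(sd(x) - par[2]), 0.02 * par[2])
  }
  expect_equal(rtnorm_match(5, 3, 0), rep(3, 5))
  expect_error(rtnorm_match(5, 1, 1.5), "not reachable")
})

test_that("same seed gives bit-identical cohorts", {
  cfg <- tiny_config()
  expect_identical(generate_cohort(cfg, seed = 4), generate_cohort(cfg, seed = 4))
  a <- generate_cohort(cfg, seed = 4)
  b <- generate_cohort(cfg, seed = 5)
  expect_false(identical(a$biometrics, b$biometrics))
})

test_that("zero standard deviations produce constant draws at the group mean", {
  cfg <- tiny_config(sd_scale = 0)
  coh <- generate_cohort(cfg, seed = 8)
  expect_true(all(coh$biometrics$body_weight == 500))
  # fatty acids are renormalized to exactly 100, so constants are rescaled by
  # the closure factor of the configured means (here 100/100 = 1)
  p16 <- coh$fatty_acids$percent[coh$fatty_acids$fa_name == "16:0"]
  expect_equal(p16, rep(30, length(p16)), tolerance = 1e-12)
  tab <- carbonylation_table(coh$densitometry, detection_limit = cfg$detection_limit)
  idx1 <- tab$index[tab$spot_id == "1"]
  expect_equal(idx1, rep(0.8, length(idx1)), tolerance = 1e-12)
})

test_that("fatty-acid profiles close to 100 percent per animal", {
  coh <- generate_cohort(tiny_config(), seed = 21)
  sums <- as.numeric(tapply(coh$fatty_acids$percent, coh$fatty_acids$animal_id, sum))
  expect_equal(sums, rep(100, length(sums)), tolerance = 1e-9)
})

test_that("renormalization perturbs draws mildly at study-scale dispersion", {
  # per-animal closure factor 100/S: mean absolute relative perturbation
  # stays below 2 percent when s.d. values are at the published scale
  cfg <- default_cohort_config(n_per_group = 100)
  set.seed(77)
  fa <- cfg$fatty_acids
  for (g in cfg$groups) {
    tab <- fa[fa$diet_group == g, ]
    draws <- vapply(seq_len(nrow(tab)),
                    function(i) rtnorm_match(100, tab$mean[i], max(tab$sd[i], 0)),
                    numeric(100))
    rel <- abs(100 / rowSums(draws) - 1)
    expect_lt(mean(rel), 0.02)
  }
})

test_that("low-abundance analogue spots are always undefined downstream", {
  cfg <- default_cohort_config()
  dens <- generate_densitometry(cfg, seed = 31)
  tab <- carbonylation_table(dens, detection_limit = cfg$detection_limit)
  low <- tab[tab$spot_id %in% cfg$low_abundance_spots, ]
  expect_equal(nrow(low), 27 * 5)
  expect_true(all(!low$defined))
  expect_true(all(tab$defined[!tab$spot_id %in% cfg$low_abundance_spots]))
})

test_that("invalid configurations fail before any draw", {
  cfg <- tiny_config()
  bad <- cfg; bad$variables$sd[1] <- -1
  expect_error(generate_cohort(bad, seed = 1), "sd < 0")
  bad2 <- cfg; bad2$fatty_acids$diet_group[1] <- "KETO"
  expect_error(generate_cohort(bad2, seed = 1), "unknown diet group")
  expect_error(cohort_config(cfg$variables, cfg$fatty_acids, cfg$spots,
                             n_per_group = 1), ">= 2")
})

test_that("sample means recover configured means at large n", {
  cfg <- default_cohort_config(n_per_group = 500)
  coh <- generate_cohort(cfg, seed = 12)
  rec <- mean_recovery(coh)
  expect_equal(nrow(rec), 234)
  expect_gte(mean(rec$recovered), 0.99)
  # fatty-acid means specifically (law-of-large-numbers example)
  fa <- rec[rec$kind == "fatty_acid", ]
  expect_gte(mean(fa$recovered), 0.99)
})

test_that("densitometry round trip recovers configured spot indexes", {
  cfg <- default_cohort_config(n_per_group = 500)
  set.seed(44)
  dens <- generate_densitometry(cfg)
  tab <- carbonylation_table(dens, detection_limit = cfg$detection_limit)
  tab$diet_group2 <- dens$diet_group[match(tab$animal_id, dens$animal_id)]
  ok <- mapply(function(s, g, m, sdv) {
    x <- tab$index[tab$spot_id == s & tab$diet_group2 == g]
    if (sdv == 0) all(abs(x - m) < 1e-10) else
      abs(mean(x) - m) <= 3 * sdv / sqrt(length(x))
  }, cfg$spots$spot_id, cfg$spots$diet_group, cfg$spots$mean, cfg$spots$sd)
  expect_gte(mean(ok), 0.99)
})

test_that("configurations survive a JSON round trip", {
  cfg <- default_cohort_config()
  path <- tempfile(fileext = ".json")
  write_cohort_config(cfg, path)
  cfg2 <- read_cohort_config(path)
  expect_equal(cfg2$variables, cfg$variables)
  expect_equal(cfg2$fatty_acids, cfg$fatty_acids)
  expect_equal(cfg2$spots, cfg$spots)
  expect_identical(generate_cohort(cfg, 3), generate_cohort(cfg2, 3))
  # the shipped default configuration matches the in-code one
  shipped <- read_cohort_config(system.file("extdata", "study_cohort_config.json",
                                            package = "dietredox"))
  expect_equal(shipped$spots, cfg$spots)
  expect_equal(shipped$fatty_acids, cfg$fatty_acids)
})
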