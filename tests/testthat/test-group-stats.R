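three_groups <- function(n = 9, means = c(0, 0, 0), sds = c(1, 1, 1)) {
  data.frame(value = c(rnorm(n, means[1], sds[1]), rnorm(n, means[2], sds[2]),
                       rnorm(n, means[3], sds[3])),
             diet_group = rep(c("STD", "HFHS", "HFHS+w3"), each = n))
}

test_that("two-group Fisher LSD equals the pooled-variance t-test", {
  set.seed(101)
  for (i in 1:100) {
    na <- sample(4:12, 1); nb <- sample(4:12, 1)
    a <- rnorm(na, sd = runif(1, 0.5, 2)); b <- rnorm(nb, mean = runif(1, -1, 1))
    lsd <- fisher_lsd(c(a, b), rep(c("A", "B"), c(na, nb)))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(lsd$p, tt$p.value, tolerance = 1e-10)
    expect_equal(abs(lsd$t), abs(unname(tt$statistic)), tolerance = 1e-10)
  }
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(55)
  for (i in 1:20) {
    a <- rnorm(7); b <- rnorm(9, 0.5)
    om <- omnibus_test(c(a, b), rep(c("A", "B"), c(7, 9)), "parametric")
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(om$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(om$p.value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("identical groups give p near 1 and no direction", {
  v <- rep(c(1, 2, 3), times = 3)
  g <- rep(c("A", "B", "C"), each = 3)
  lsd <- fisher_lsd(v, g)
  expect_true(all(lsd$direction == "none"))
  expect_true(all(lsd$p > 0.999))
})

test_that("degenerate inputs route nonparametric with a warning", {
  v <- rep(c(1, 1, 1), each = 5)
  g <- rep(c("A", "B", "C"), each = 5)
  expect_warning(chk <- check_assumptions(v, g), "nonparametric")
  expect_equal(chk$route, "nonparametric")
  # all observations tied across groups: Kruskal-Wallis p = 1
  om <- omnibus_test(v, g, "nonparametric")
  expect_equal(om$p.value, 1)
  # zero within-group variance: LSD p undefined
  lsd <- fisher_lsd(v, g)
  expect_true(all(is.na(lsd$p)))
})

test_that("gross variance heterogeneity is detected and routed nonparametric", {
  set.seed(77)
  detected <- replicate(200, {
    d <- three_groups(n = 9, sds = c(1, 10, 1))  # 100-fold variance inflation
    suppressWarnings(check_assumptions(d$value, d$diet_group))$route == "nonparametric"
  })
  expect_gt(mean(detected), 0.95)
})

test_that("null normal data mostly stay on the parametric route", {
  set.seed(3)
  routes <- replicate(500, {
    d <- three_groups(n = 9)
    suppressWarnings(check_assumptions(d$value, d$diet_group))$route
  })
  # four alpha = 0.05 screens (3 Shapiro + Levene) reject one in five nulls
  expect_gt(mean(routes == "parametric"), 0.75)
  expect_lt(mean(routes == "parametric"), 0.95)
})

test_that("omnibus ANOVA holds its nominal level on pooled null draws", {
  set.seed(29)
  rej <- replicate(1000, {
    d <- three_groups(n = 9)
    omnibus_test(d$value, d$diet_group, "parametric")$p.value < 0.05
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("missing values shrink their own group only", {
  set.seed(201)
  d <- three_groups(n = 9, means = c(0, 1, 2))
  cmp_full <- suppressWarnings(group_compare(value ~ diet_group, d))
  d2 <- d
  d2$value[d2$diet_group == "STD"][1:3] <- NA
  cmp_miss <- suppressWarnings(group_compare(value ~ diet_group, d2))
  for (g in c("HFHS", "HFHS+w3")) {
    expect_equal(cmp_miss$groups$mean[cmp_miss$groups$group == g],
                 cmp_full$groups$mean[cmp_full$groups$group == g])
    expect_equal(cmp_miss$groups$sd[cmp_miss$groups$group == g],
                 cmp_full$groups$sd[cmp_full$groups$group == g])
  }
  expect_equal(cmp_miss$groups$n[cmp_miss$groups$group == "STD"], 6L)
  expect_error(group_compare(value ~ diet_group,
                             data.frame(value = c(1, NA, NA, 2, 3, NA),
                                        diet_group = rep(c("A", "B"), each = 3))),
               "at least 2 groups")
})

test_that("direction always matches the sign of the group-mean difference", {
  set.seed(303)
  for (i in 1:25) {
    d <- three_groups(n = 6, means = rnorm(3, sd = 2))
    cmp <- suppressWarnings(group_compare(value ~ diet_group, d))
    pw <- annotate_comparison(cmp)
    expect_true(all(pw$direction[pw$diff > 0] == "up"))
    expect_true(all(pw$direction[pw$diff < 0] == "down"))
    expect_true(all(pw$arrow %in% c("", "+", "-")))
    expect_true(all(pw$diff[pw$arrow == "+"] > 0))
    expect_true(all(pw$diff[pw$arrow == "-"] < 0))
  }
})

test_that("star and arrow thresholds are strict", {
  fake <- structure(list(pairwise = data.frame(
    group_a = "STD", group_b = rep("HFHS", 4),
    diff = c(1, 1, 1, 1), t = NA_real_, df = NA_real_,
    p = c(0.049, 0.05, 0.2, 0.009),
    direction = "up", stringsAsFactors = FALSE)), class = "group_comparison")
  pw <- annotate_comparison(fake)
  expect_equal(pw$star, c("*", "", "", "**"))
  expect_equal(pw$arrow, c("+", "", "", "+"))
})

test_that("the comparison object carries route, omnibus and reference flags", {
  set.seed(9)
  d <- three_groups(n = 9, means = c(0, 3, 0))
  cmp <- suppressWarnings(group_compare(value ~ diet_group, d, reference = "STD"))
  expect_s3_class(cmp, "group_comparison")
  expect_true(cmp$route %in% c("parametric", "nonparametric"))
  expect_true("HFHS" %in% names(cmp$flags))
  expect_equal(cmp$flags[["HFHS"]], "**")
  expect_output(print(cmp), "Three-group comparison")
})

test_that("compare_variables flattens a tidy table into one row per variable", {
  set.seed(12)
  tidy <- rbind(
    data.frame(variable = "v1", animal_id = 1:27,
               diet_group = rep(c("STD", "HFHS", "HFHS+w3"), each = 9),
               value = rnorm(27)),
    data.frame(variable = "v2", animal_id = 1:27,
               diet_group = rep(c("STD", "HFHS", "HFHS+w3"), each = 9),
               value = rnorm(27, rep(c(0, 5, 0), each = 9))))
  out <- compare_variables(tidy)
  expect_equal(out$variable, c("v1", "v2"))
  expect_true(all(c("mean_STD", "sd_HFHS", "p_HFHS_vs_STD", "star_HFHS_vs_STD")
                  %in% names(out)))
  expect_equal(out$star_HFHS_vs_STD[2], "**")
})
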