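test_that("Mann-Whitney exact path equals permutation enumeration at small n", {
  cases <- list(
    list(x = c(1, 2, 3), y = c(10, 11, 12)),
    list(x = c(1, 5, 9, 13), y = c(2, 3, 4)),
    list(x = c(2.5, 7, 11), y = c(1, 4, 6, 8, 12)),
    list(x = c(1, 2, 3, 4, 5, 6), y = c(3.5, 7.5))
  )
  for (cs in cases) {
    p <- mann_whitney(cs$x, cs$y)
    expect_true(attr(p, "exact"))
    expect_equal(as.numeric(p), oracle_mw_exact(cs$x, cs$y), tolerance = 1e-12)
  }
  # the fully separated case has U = 0 and exact two-sided p = 2/20
  expect_equal(as.numeric(mann_whitney(c(1, 2, 3), c(10, 11, 12))), 0.1)
})

test_that("Mann-Whitney approximation handles identical samples and strong shifts", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  expect_equal(as.numeric(mann_whitney(x, x)), 1)
  set.seed(8)
  a <- rnorm(150); b <- rnorm(150, mean = 2)
  expect_lt(as.numeric(mann_whitney(a, b)), 0.001)
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("chi-squared matches the hand formula and degenerate margins error", {
  tab <- matrix(c(10, 10, 10, 10), 2)
  p <- chi_square(tab)
  expect_equal(attr(p, "statistic"), 0)
  expect_equal(as.numeric(p), 1)

  tab <- matrix(c(30, 10, 15, 25), 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(attr(chi_square(tab), "statistic"),
               sum((tab - expected)^2 / expected), tolerance = 1e-12)

  expect_error(chi_square(matrix(c(5, 0, 7, 0), 2, byrow = TRUE)), "degenerate")
})

test_that("adjusted comparison recovers a planted group shift and reports complete cases", {
  set.seed(21)
  n <- 600
  cov <- make_covariates(n)
  group <- rep(c("control", "player"), each = n / 2)
  y <- 5 + 0.03 * cov$age + 2 * (group == "player") + rnorm(n)
  res <- adjusted_comparison(y, group, cov, metric = "toy")
  expect_equal(res$estimate, 2, tolerance = 0.3)
  expect_lt(res$p_adjusted, 1e-6)
  expect_equal(res$n_used, n)

  # with covariates orthogonal to group, the coefficient is the raw mean gap
  x <- rep(c(0, 1, 2, 3), times = n / 4)
  y2 <- c(rnorm(n / 2), rnorm(n / 2) + 1.5)
  res2 <- adjusted_comparison(y2, group, data.frame(age = x),
                              spec = covariate_spec("age"))
  raw_gap <- mean(y2[group == "player"]) - mean(y2[group == "control"])
  expect_equal(res2$estimate, raw_gap, tolerance = 1e-9)
})

test_that("rank-deficient designs error naming the collinear column", {
  n <- 80
  cov <- make_covariates(n, seed = 3)
  cov$income <- cov$age * 1000  # income_k duplicates age
  group <- rep(c("control", "player"), each = n / 2)
  y <- rnorm(n)
  expect_error(
    adjusted_comparison(y, group, cov,
                        spec = covariate_spec(c("age", "income"))),
    "collinear.*(income_k|age)")
  expect_error(
    adjusted_comparison(y, group, cov[, "age", drop = FALSE],
                        spec = covariate_spec(c("age", "income"))),
    "missing covariate column: income")
})

test_that("group-coefficient recovery: power > 90% under a planted sex-composition effect and calibrated size under the null", {
  # fixed nine-alter rosters isolate the planted sex-composition effect
  # from roster-size variation; size heterogeneity is exercised elsewhere
  run_rep <- function(p_male_players, seed, size = 9) {
    set.seed(seed)
    n <- 300
    p_male <- rep(c(0.5, p_male_players), each = n)
    div <- vapply(seq_len(2 * n), function(i) {
      sex <- runif(size) < p_male[i]
      iqv(c(sum(sex), sum(!sex)))
    }, 0)
    cov <- make_covariates(2 * n)
    group <- rep(c("control", "player"), each = n)
    adjusted_comparison(div, group, cov)$p_adjusted
  }
  p_alt <- vapply(1:200, function(s) run_rep(0.65, 1000 + s), 0)
  expect_gt(mean(p_alt < 0.05), 0.9)
  p_null <- vapply(1:200, function(s) run_rep(0.50, 3000 + s), 0)
  rate <- mean(p_null < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("descriptive table reports medians, counts and percentages per group", {
  recs <- c(
    lapply(1:6, function(i) make_record(id = paste0("p", i), group = "player",
                                        n = 2, ties = "full")),
    lapply(1:4, function(i) make_record(id = paste0("c", i), group = "control",
                                        n = 2, ties = "full"))
  )
  recs[[1]]$chronic_condition <- TRUE
  recs[[2]]$chronic_condition <- TRUE
  tab <- descriptive_table(recs)
  chronic <- tab[tab$variable == "chronic_condition" & tab$level == "present", ]
  expect_equal(chronic$n_player, 2)
  expect_equal(chronic$pct_player, 100 * 2 / 6)
  expect_equal(chronic$n_control, 0)
  age <- tab[tab$variable == "age", ]
  expect_equal(age$median_player, 50)

  solo <- recs[1:6]  # players only
  expect_error(descriptive_table(solo), "two nonempty groups")
})

test_that("stratified contrasts partition players and respect overlapping illness types", {
  tabsim <- simulate_cohort(default_synthetic_config(120, 100), seed = 5)
  met <- compute_metrics(tabsim)
  players <- met[met$group == "player", ]

  res <- stratified_comparison(met, "race_2way",
                               metric_names = c("network_size", "diversity_race"))
  expect_true(all(c("strata_rule", "contrast", "p_adjusted") %in% names(res)))
  expect_setequal(unique(res$strata_rule), "race_2way")
  expect_equal(sum(players$race == "White") + sum(players$race != "White"),
               nrow(players))

  res_ty <- stratified_comparison(met, "illness_type",
                                  metric_names = "network_size")
  # overlapping membership: the per-type counts must match the raw flags
  for (ty in c("sleep", "pain", "cardiometabolic")) {
    row <- res_ty[grep(ty, res_ty$contrast), ]
    if (!nrow(row)) next
    n_type <- sum(players[[paste0("chronic_", ty)]] %in% TRUE &
                    !is.na(players$network_size))
    n_none <- sum(players$n_chronic %in% 0 & !is.na(players$network_size))
    expect_equal(row$n_used[1], n_type + n_none)
  }
})

test_that("single-group metrics tables cannot be compared", {
  tabsim <- simulate_cohort(default_synthetic_config(20, 20), seed = 9)
  met <- compute_metrics(tabsim)
  expect_error(compare_metrics(met[met$group == "player", ]), "two groups")
})
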