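test_that("growth-rate endpoints are exact on constructed trajectories", {
  # pure exponential: slope of ln V recovers the rate exactly
  ds <- trial_dataset(data.frame(
    tumor_id = "T", arm = "A", animal_id = "m1",
    day = c(0, 7, 14), volume = 100 * exp(0.1 * c(0, 7, 14))))
  ev <- endpoint_values(ds, "growth_rate", "slope_log")
  expect_equal(ev$value, 0.1, tolerance = 1e-12)

  # constant volume: rate 0 under all three methods
  dsc <- trial_dataset(data.frame(
    tumor_id = "T", arm = "A", animal_id = "m1",
    day = c(0, 7, 14), volume = c(80, 80, 80)))
  for (m in c("slope_log", "ratio_log", "diff")) {
    expect_equal(endpoint_values(dsc, "growth_rate", m)$value, 0)
  }

  # V0 = 100, V21 = 400: ratio_log = ln(4)/21
  dsr <- trial_dataset(data.frame(
    tumor_id = "T", arm = "A", animal_id = "m1",
    day = c(0, 21), volume = c(100, 400)))
  expect_equal(endpoint_values(dsr, "growth_rate", "ratio_log")$value,
               log(4) / 21)
  expect_equal(endpoint_values(dsr, "growth_rate", "diff")$value, 300 / 21)

  # log methods exclude animals with non-positive volumes
  dsz <- trial_dataset(data.frame(
    tumor_id = "T", arm = "A", animal_id = c("m1", "m1", "m2", "m2"),
    day = c(0, 7, 0, 7), volume = c(100, 0, 100, 200)))
  expect_warning(evz <- endpoint_values(dsz, "growth_rate", "slope_log"),
                 "non-positive")
  expect_identical(evz$animal_id, "m2")
})

test_that("end-volume endpoint uses the last day common to all animals", {
  ds <- trial_dataset(data.frame(
    tumor_id = "T", arm = c("A", "A", "A", "B", "B"),
    animal_id = c("m1", "m1", "m1", "m2", "m2"),
    day = c(0, 7, 14, 0, 7), volume = c(100, 150, 200, 90, 120)))
  ev <- endpoint_values(ds, "end_volume")
  expect_equal(sort(ev$value), c(120, 150))  # day 7 is the last common day
})

test_that("one-way tests match closed-form oracles", {
  # identical groups: F = 0, p = 1
  r <- one_way_test(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # closed-form rank computation: H = 12/(6*7) * (36/3 + 225/3) - 21
  rk <- one_way_test(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3),
                     parametric = FALSE)
  expect_equal(rk$statistic, 12 / 42 * (36 / 3 + 225 / 3) - 21,
               tolerance = 1e-12)
  expect_equal(rk$df, 1)

  # all values identical: parametric F undefined, KW degenerates to H=0,p=1
  expect_error(one_way_test(rep(5, 6), rep(c("A", "B"), each = 3)),
               "identical")
  kw0 <- one_way_test(rep(5, 6), rep(c("A", "B"), each = 3),
                      parametric = FALSE)
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)
})

test_that("Kruskal-Wallis H is invariant under monotone transforms", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(15)
    g <- rep(c("A", "B", "C"), each = 5)
    h1 <- one_way_test(x, g, parametric = FALSE)$statistic
    h2 <- one_way_test(exp(2 * x) + 1, g, parametric = FALSE)$statistic
    expect_equal(h1, h2, tolerance = 1e-12)
  }
})

test_that("Scheirer-Ray-Hare matches a naive rank two-way ANOVA oracle", {
  set.seed(11)
  for (i in 1:10) {
    d <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"), rep = 1:4)
    x <- rnorm(nrow(d), mean = as.integer(factor(d$a)) +
                 0.5 * as.integer(factor(d$b)))
    res <- scheirer_ray_hare(x, d$a, d$b)
    oracle <- srh_oracle(x, d$a, d$b)
    expect_equal(res$terms$h, unname(oracle), tolerance = 1e-9)
  }
})

test_that("SRH with a single-level second factor reproduces Kruskal-Wallis", {
  set.seed(12)
  x <- c(rnorm(6), rnorm(6, 1), rnorm(6, 2))
  g <- rep(c("A", "B", "C"), each = 6)
  srh <- scheirer_ray_hare(x, g, rep("only", 18))
  kw <- one_way_test(x, g, parametric = FALSE)
  expect_equal(srh$terms$h[srh$terms$term == "factor_a"], kw$statistic,
               tolerance = 1e-9)
  expect_equal(srh$terms$p_value[1], kw$p_value, tolerance = 1e-9)

  # constant values: all H = 0, p = 1
  cst <- scheirer_ray_hare(rep(3, 8), rep(c("A", "B"), 4), rep(c("x", "y"), each = 4))
  expect_true(all(cst$terms$h == 0))
  expect_true(all(cst$terms$p_value == 1))

  # empty cells are refused
  expect_error(
    scheirer_ray_hare(1:6, c("A", "A", "A", "B", "B", "B"),
                      c("x", "x", "x", "y", "y", "x")),
    "empty cell")
})

test_that("mixed-ANOVA between-arm F equals one-way ANOVA on subject means", {
  # balanced 2-arm x 3-animal x 3-day constructed dataset
  set.seed(21)
  d <- expand.grid(arm = c("Vehicle", "Drug"), animal = 1:3,
                   day = c(0, 7, 14), stringsAsFactors = FALSE)
  d$volume <- 100 + 10 * (d$arm == "Drug") + 2 * d$day +
    rnorm(nrow(d), sd = 5)
  ds <- trial_dataset(data.frame(
    tumor_id = "T", arm = d$arm,
    animal_id = paste0(d$arm, "_m", d$animal),
    day = d$day, volume = d$volume), control_arm = "Vehicle")
  res <- mixed_anova(ds)
  means <- tapply(d$volume, paste(d$arm, d$animal), mean)
  grp <- sub(" .*", "", names(means))
  f_oneway <- anova(lm(means ~ grp))$`F value`[1]
  f_between <- res$terms$statistic[res$terms$term == "arm"]
  expect_equal(f_between, f_oneway, tolerance = 1e-9)
})

test_that("mixed ANOVA degenerates correctly and enforces preconditions", {
  # identical animals across arms: between and interaction F are 0
  d <- expand.grid(arm = c("A", "B"), animal = 1:2, day = c(0, 7, 14),
                   stringsAsFactors = FALSE)
  d$volume <- 100 + 5 * d$day
  ds <- trial_dataset(data.frame(
    tumor_id = "T", arm = d$arm, animal_id = paste0(d$arm, d$animal),
    day = d$day, volume = d$volume))
  res <- mixed_anova(ds)
  expect_equal(res$terms$statistic[res$terms$term == "arm"], 0,
               tolerance = 1e-9)
  expect_equal(res$terms$statistic[res$terms$term == "arm:day"], 0,
               tolerance = 1e-9)

  ds1 <- trial_dataset(data.frame(
    tumor_id = "T", arm = c("A", "A", "B", "B"),
    animal_id = c("m1", "m1", "m2", "m2"),
    day = c(0, 7, 0, 7), volume = c(1, 2, 3, 4)))
  expect_error(mixed_anova(ds1), ">= 2 animals")
})

test_that("the linear mixed model recovers noise-free slope differences", {
  # zero residual noise, distinct slopes: the day:arm contrast is exact
  d <- expand.grid(arm = c("Vehicle", "Drug"), animal = 1:4,
                   day = seq(0, 21, 3), stringsAsFactors = FALSE)
  b <- c(Vehicle = 0.10, Drug = 0.04)
  v0 <- c(180, 190, 200, 210)
  d$volume <- v0[d$animal] * exp(b[d$arm] * d$day)
  ds <- trial_dataset(data.frame(
    tumor_id = "T", arm = d$arm, animal_id = paste0(d$arm, "_m", d$animal),
    day = d$day, volume = d$volume), control_arm = "Vehicle")
  res <- suppressWarnings(fit_lmm(ds, response_scale = "log",
                                  random = "intercept"))
  est <- unname(res$terms$estimate[res$terms$term == "day:armDrug"])
  # log(V+1) adds a tiny curvature, hence the loose-but-small tolerance
  expect_equal(est, -0.06, tolerance = 5e-3)
  expect_lt(res$p_value, 1e-6)
})

test_that("lmm arm contrasts are near zero for identical arms", {
  set.seed(31)
  d <- expand.grid(arm = c("Vehicle", "Drug"), animal = 1:6,
                   day = seq(0, 21, 3), stringsAsFactors = FALSE)
  d$volume <- 200 * exp(0.08 * d$day) * exp(rnorm(nrow(d), sd = 0.1))
  ds <- trial_dataset(data.frame(
    tumor_id = "T", arm = d$arm, animal_id = paste0(d$arm, "_m", d$animal),
    day = d$day, volume = d$volume), control_arm = "Vehicle")
  res <- fit_lmm(ds)
  est <- res$terms$estimate[res$terms$term == "day:armDrug"]
  se <- res$terms$se[res$terms$term == "day:armDrug"]
  expect_lt(abs(est / se), 4)
})

test_that("the permutation test is exact, deterministic and order-invariant", {
  ds <- separated_pair_trial()
  res <- permutation_curve_test(ds, n_perm = 100, seed = 5)
  expect_identical(res$mode, "exhaustive")
  expect_identical(res$n_assignments, 20L)
  expect_equal(res$p_raw, 2 / 20)

  # permuting input row order leaves the p-value unchanged
  shuffled <- trial_dataset(tibble::as_tibble(ds)[rev(seq_len(nrow(ds))), ],
                            control_arm = "Vehicle")
  res2 <- permutation_curve_test(shuffled, n_perm = 100, seed = 5)
  expect_equal(res2$p_raw, res$p_raw)

  # Monte-Carlo mode is reproducible given the seed
  big <- simulate_trial(sim_config("1AN", n_arms = 1, n_animals = 10,
                                   seed = 9))
  m1 <- permutation_curve_test(big, n_perm = 300, seed = 17,
                               exhaustive_limit = 10)
  m2 <- permutation_curve_test(big, n_perm = 300, seed = 17,
                               exhaustive_limit = 10)
  expect_identical(m1$mode, "monte-carlo")
  expect_equal(m1$p_raw, m2$p_raw)
})

test_that("Monte-Carlo permutation p agrees with the exhaustive value", {
  ds <- simulate_trial(sim_config("1AN", n_arms = 1, n_animals = 5,
                                  arm_effects = c(Treatment_1 = 0.03),
                                  seed = 13))
  ex <- permutation_curve_test(ds, n_perm = 10, seed = 1)
  expect_identical(ex$mode, "exhaustive")
  mc <- permutation_curve_test(ds, n_perm = 10000, seed = 2,
                               exhaustive_limit = 10)
  p <- ex$p_raw
  expect_lt(abs(mc$p_raw - p), 3 * sqrt(p * (1 - p) / 10000) + 1e-9)
})

test_that("rank-sum variant and degenerate-day handling work", {
  ds <- separated_pair_trial()
  res <- permutation_curve_test(ds, stat = "mean_wilcox", n_perm = 100,
                                seed = 5)
  expect_equal(res$p_raw, 2 / 20)  # separation is rank-complete too

  # a day identical in both groups is skipped with a note
  d <- tibble::as_tibble(ds)
  d$volume[d$day == 0] <- 100
  dsk <- trial_dataset(d, control_arm = "Vehicle")
  res2 <- permutation_curve_test(dsk, n_perm = 100, seed = 5)
  expect_match(res2$note, "skipped")
  expect_equal(res2$n_days, 3L)
})

test_that("p-value adjustment follows the hand-worked Holm rule", {
  p <- c(0.01, 0.04, 0.03)
  # Holm by hand: sort 0.01, 0.03, 0.04 -> 3*0.01, 2*0.03, 1*0.04,
  # cummax -> 0.03, 0.06, 0.06; back in input order:
  expect_equal(adjust_pvalues(p, "holm"), c(0.03, 0.06, 0.06))
  expect_equal(adjust_pvalues(0.2, "holm"), 0.2)
  expect_equal(adjust_pvalues(0.2, "BH"), 0.2)
  expect_equal(adjust_pvalues(rep(1, 4), "bonferroni"), rep(1, 4))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  # adjusted never below raw
  set.seed(2)
  pr <- runif(10)
  for (m in c("holm", "bonferroni", "BH")) {
    expect_true(all(adjust_pvalues(pr, m) >= pr))
  }
})
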