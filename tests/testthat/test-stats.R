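# Independent oracle: studentized-range CDF by direct numerical integration
# over the scale distribution s ~ sqrt(chisq_df / df) and the range kernel.
ptukey_oracle <- function(q, k, df) {
  inner <- function(s) {
    vapply(s, function(si) {
      g <- function(z)
        stats::dnorm(z) *
          (stats::pnorm(z) - stats::pnorm(z - q * si))^(k - 1)
      k * stats::integrate(g, -8, 8, rel.tol = 1e-10)$value
    }, numeric(1))
  }
  fs <- function(s)
    2 * (df / 2)^(df / 2) / gamma(df / 2) * s^(df - 1) *
      exp(-df * s^2 / 2)
  stats::integrate(function(s) fs(s) * inner(s), 0, 10,
                   rel.tol = 1e-8)$value
}

make_table <- function(values, hemi, time, animal = NULL) {
  data.frame(animal_id = if (is.null(animal))
    sprintf("a%02d", seq_along(values)) else animal,
    hemisphere_label = hemi, timepoint_label = time, value = values)
}

test_that("identical responses give F = 0 and p = 1 for every effect", {
  tbl <- expand.grid(hemisphere_label = c("c", "i"),
                     timepoint_label = c("t1", "t2"),
                     rep = 1:3)
  tbl$animal_id <- sprintf("a%02d", seq_len(nrow(tbl)))
  tbl$value <- 0.4
  res <- two_way_anova(tbl)
  expect_equal(res$effects$F, c(0, 0, 0))
  expect_equal(res$effects$p, c(1, 1, 1))
})

test_that("two-way F statistics match hand-computed sums of squares", {
  set.seed(5)
  n <- 4
  tbl <- expand.grid(hemisphere_label = c("c", "i"),
                     timepoint_label = c("t1", "t2"), rep = seq_len(n))
  tbl$animal_id <- sprintf("a%02d", seq_len(nrow(tbl)))
  tbl$value <- stats::rnorm(nrow(tbl)) +
    2 * (tbl$hemisphere_label == "i") + 0.5 * (tbl$timepoint_label == "t2")
  # manual balanced two-way decomposition
  y <- tbl$value
  gm <- mean(y)
  mA <- tapply(y, tbl$hemisphere_label, mean)
  mB <- tapply(y, tbl$timepoint_label, mean)
  mAB <- tapply(y, interaction(tbl$hemisphere_label, tbl$timepoint_label),
                mean)
  ssA <- 2 * n * sum((mA - gm)^2)
  ssB <- 2 * n * sum((mB - gm)^2)
  ssCells <- n * sum((mAB - gm)^2)
  ssAB <- ssCells - ssA - ssB
  ssE <- sum((y - ave(y, tbl$hemisphere_label, tbl$timepoint_label))^2)
  dfe <- nrow(tbl) - 4
  manual_F <- c(ssA / 1, ssB / 1, ssAB / 1) / (ssE / dfe)
  res <- two_way_anova(tbl)
  expect_equal(res$effects$F, manual_F, tolerance = 1e-8)
  expect_equal(res$effects$df, c(1, 1, 1))
  expect_equal(res$df_residual, dfe)
})

test_that("empty or thin design cells are reported by name", {
  tbl <- make_table(rnorm(6), rep(c("c", "i"), 3), rep("t1", 6))
  tbl2 <- rbind(tbl, make_table(rnorm(1), "c", "t2", "b01"))
  expect_error(two_way_anova(tbl2), "fewer than 2")
})

test_that("one-way ANOVA of two groups squares the pooled t statistic", {
  set.seed(7)
  tbl <- data.frame(animal_id = sprintf("a%02d", 1:16),
                    timepoint_label = rep(c("g1", "g2"), each = 8),
                    value = stats::rnorm(16, mean = rep(c(0, 1), each = 8)))
  res <- one_way_anova(tbl)
  tt <- stats::t.test(value ~ timepoint_label, data = tbl, var.equal = TRUE)
  expect_equal(res$effects$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$effects$p[1], tt$p.value, tolerance = 1e-10)
})

test_that("a three-sd group shift is detected in nearly every replicate", {
  set.seed(21)
  p_small <- replicate(200, {
    tbl <- data.frame(animal_id = sprintf("a%02d", 1:20),
                      timepoint_label = rep(c("g1", "g2"), each = 10),
                      value = stats::rnorm(20, rep(c(0, 3), each = 10)))
    one_way_anova(tbl)$effects$p[1]
  })
  expect_gte(mean(p_small < 1e-3), 0.99)
})

test_that("repeated-measures ANOVA blocks on the animal", {
  animals <- rep(sprintf("m%02d", 1:6), each = 4)
  times <- rep(c("b", "t1", "t2", "t3"), 6)
  # constant within animal: time effect exactly zero
  tbl <- data.frame(animal_id = animals, timepoint_label = times,
                    value = rep(stats::rnorm(6), each = 4))
  res <- repeated_measures_anova(tbl)
  tline <- res$effects[res$effects$term == "timepoint_label", ]
  expect_equal(tline$F, 0)
  expect_equal(tline$p, 1)
  # additive subject offsets leave the time F unchanged
  set.seed(3)
  base <- stats::rnorm(24)
  tbl1 <- data.frame(animal_id = animals, timepoint_label = times,
                     value = base)
  tbl2 <- tbl1
  tbl2$value <- tbl2$value + rep(stats::rnorm(6, sd = 5), each = 4)
  f1 <- repeated_measures_anova(tbl1)$effects
  f2 <- repeated_measures_anova(tbl2)$effects
  expect_equal(f1$F[f1$term == "timepoint_label"],
               f2$F[f2$term == "timepoint_label"], tolerance = 1e-8)
  # unbalanced panels are rejected
  expect_error(repeated_measures_anova(tbl1[-1, ]), "unbalanced|balanced")
})

test_that("Tukey HSD adjusted p-values behave and match a q-integration oracle", {
  set.seed(13)
  tbl <- data.frame(animal_id = sprintf("a%02d", 1:18),
                    timepoint_label = rep(c("b", "t1", "t2"), each = 6),
                    value = stats::rnorm(18, rep(c(0, 0.8, 1.6), each = 6)))
  res <- tukey_hsd(one_way_anova(tbl))
  ph <- res$posthoc
  expect_equal(nrow(ph), 3L)
  expect_true(all(ph$p_adjusted >= ph$p_unadjusted - 1e-12))
  for (r in seq_len(nrow(ph))) {
    oracle <- 1 - ptukey_oracle(ph$q[r], k = 3, df = res$df_residual)
    expect_equal(ph$p_adjusted[r], oracle, tolerance = 1e-5)
  }
  # identical groups: adjusted p of 1
  tbl0 <- tbl; tbl0$value <- 1
  ph0 <- tukey_hsd(one_way_anova(tbl0))$posthoc
  expect_true(all(ph0$p_adjusted == 1))
  # two levels: Tukey degenerates to the two-sided pooled t-test
  tbl2 <- tbl[tbl$timepoint_label != "t2", ]
  ph2 <- tukey_hsd(one_way_anova(tbl2))$posthoc
  expect_equal(ph2$p_adjusted, ph2$p_unadjusted, tolerance = 1e-6)
})

test_that("two-group t-test conventions and symmetry", {
  a <- c(1.2, -0.4, 0.8, 2.2)
  tbl <- data.frame(animal_id = sprintf("a%02d", 1:8),
                    group_label = rep(c("ctl", "plx"), each = 4),
                    value = c(-a, a))
  r1 <- two_group_ttest(tbl)
  tbl_fl <- tbl; tbl_fl$value <- -tbl_fl$value
  r2 <- two_group_ttest(tbl_fl)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
  ref <- stats::t.test(value ~ group_label, data = tbl, var.equal = TRUE)
  expect_equal(r1$statistic, unname(ref$statistic))
  expect_equal(r1$p_value, ref$p.value)
  # identical constant groups
  tbl0 <- tbl; tbl0$value <- 3
  r0 <- two_group_ttest(tbl0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_error(two_group_ttest(tbl[1:4, ]), "two groups|2 levels")
})

test_that("results are invariant to row order and affine response rescaling", {
  set.seed(31)
  tbl <- expand.grid(hemisphere_label = c("c", "i"),
                     timepoint_label = c("t1", "t2", "t3"), rep = 1:5)
  tbl$animal_id <- sprintf("a%02d", seq_len(nrow(tbl)))
  tbl$value <- stats::rnorm(nrow(tbl))
  r_ref <- two_way_anova(tbl)
  r_shuf <- two_way_anova(tbl[sample(nrow(tbl)), ])
  expect_equal(r_ref$effects$F, r_shuf$effects$F, tolerance = 1e-10)
  tbl_aff <- tbl; tbl_aff$value <- 12.5 * tbl_aff$value - 3
  r_aff <- two_way_anova(tbl_aff)
  expect_equal(r_ref$effects$F, r_aff$effects$F, tolerance = 1e-8)
  expect_equal(r_ref$effects$p, r_aff$effects$p, tolerance = 1e-8)
  expect_true(all(r_ref$effects$p >= 0 & r_ref$effects$p <= 1))
  expect_true(all(r_ref$effects$F >= 0))
})

test_that("group tables reject duplicates and non-finite responses", {
  tbl <- data.frame(animal_id = c("a", "a"), group_label = "g",
                    timepoint_label = "t", hemisphere_label = "c",
                    value = c(1, 2))
  expect_error(group_table(tbl), "duplicate")
  tbl2 <- data.frame(animal_id = c("a", "b"), value = c(1, NA))
  expect_error(group_table(tbl2), "finite")
})

test_that("simulated cohort tables carry the programmed elevations", {
  tbl <- simulate_ratio_table(seed = 4)
  expect_identical(tbl, simulate_ratio_table(seed = 4))
  expect_equal(nrow(tbl), 10 * 5 * 2)
  agg <- tapply(tbl$value,
                list(tbl$hemisphere_label, tbl$timepoint_label), mean)
  expect_gt(agg["injured", "7d"], agg["contralateral", "7d"])
  sham <- simulate_ratio_table(elevation_pct = 0, group_label = "Sham",
                               n_animals = 5, seed = 4)
  expect_equal(nrow(sham), 5 * 5 * 2)
})
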