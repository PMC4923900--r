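test_that("blocked two-way ANOVA matches a projection-based SS oracle", {
  set.seed(14)
  d <- expand.grid(rep = 1:3, treatment = c("control", "ba"),
                   time = c(1, 27))
  d$batch <- rep(1:2, length.out = nrow(d))
  y <- rnorm(nrow(d)) + 2 * (d$treatment == "ba") + 0.5 * (d$time == 27)
  res <- two_way_anova_blocked(y, d$treatment, d$time, d$batch)

  mm <- function(f) model.matrix(f, data = d)[, -1, drop = FALSE]
  oracle <- seq_ss_oracle(y, list(
    batch = mm(~ factor(batch)),
    treatment = mm(~ factor(treatment)),
    time = mm(~ factor(time)),
    interaction = mm(~ factor(treatment) * factor(time))))
  got <- setNames(res$table$sum_sq, res$table$term)
  expect_equal(unname(got["batch"]), unname(oracle["batch"]),
               tolerance = 1e-10)
  expect_equal(unname(got["treatment"]), unname(oracle["treatment"]),
               tolerance = 1e-10)
  expect_equal(unname(got["time"]), unname(oracle["time"]), tolerance = 1e-10)
  expect_equal(unname(got["treatment:time"]),
               unname(oracle["interaction"]), tolerance = 1e-10)
  expect_equal(unname(got["Residuals"]), unname(oracle["residual"]),
               tolerance = 1e-10)
  # additivity: term SS + residual = total SS
  expect_equal(sum(res$table$sum_sq), sum((y - mean(y))^2),
               tolerance = 1e-8)
})

test_that("a constant shift of one batch is absorbed by the block term", {
  set.seed(15)
  d <- expand.grid(rep = 1:4, treatment = c("control", "ba", "gh"),
                   time = c(1, 3, 7))
  d$batch <- rep(1:2, length.out = nrow(d))
  y <- rnorm(nrow(d))
  base <- two_way_anova_blocked(y, d$treatment, d$time, d$batch)
  y2 <- y + 7 * (d$batch == 2)
  shifted <- two_way_anova_blocked(y2, d$treatment, d$time, d$batch)
  for (term in c("treatment", "time", "treatment:time")) {
    expect_equal(base$table$statistic[base$table$term == term],
                 shifted$table$statistic[shifted$table$term == term],
                 tolerance = 1e-8)
  }
  expect_error(two_way_anova_blocked(y[d$treatment != "gh" | d$time != 3],
                                     d$treatment[d$treatment != "gh" | d$time != 3],
                                     d$time[d$treatment != "gh" | d$time != 3],
                                     d$batch[d$treatment != "gh" | d$time != 3]),
               "cell")
})

test_that("one-way ANOVA identities hold", {
  set.seed(16)
  # two groups: F equals the squared pooled t statistic
  a <- rnorm(8); b <- rnorm(9, 1)
  res <- one_way_anova(c(a, b), rep(c("x", "y"), c(8, 9)))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$table$statistic[1], unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(res$table$p[1], tt$p.value, tolerance = 1e-10)

  # hand-computed three-group toy
  y <- c(1, 2, 3, 4, 5, 6, 10, 11, 12)
  g <- rep(c("a", "b", "c"), each = 3)
  res3 <- one_way_anova(y, g)
  gm <- tapply(y, g, mean)
  ssb <- sum(3 * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  expect_equal(res3$table$sum_sq, c(ssb, ssw), tolerance = 1e-10)
  expect_equal(res3$table$statistic[1], (ssb / 2) / (ssw / 6),
               tolerance = 1e-10)
  expect_equal(res3$mse, ssw / 6, tolerance = 1e-10)

  expect_error(one_way_anova(y, rep("a", 9)), "2 groups")
})

test_that("SED follows its closed form", {
  expect_equal(sed(2, 10, 10), 0.6325, tolerance = 1e-4)
  expect_equal(sed(0, 5, 5), 0)
  expect_equal(sed(1.7, 10, 15), sed(1.7, 15, 10))
  expect_equal(sed(3, 4, 6), sqrt(3 * (1 / 4 + 1 / 6)), tolerance = 1e-12)
  expect_error(sed(-1, 2, 2), ">= 0")
})

test_that("Monte-Carlo Dunnett agrees with multcomp and behaves at extremes", {
  set.seed(17)
  y <- c(rnorm(10), rnorm(10, 1.2), rnorm(10, 0.3))
  g <- rep(c("control", "ba", "gh"), each = 10)
  res <- dunnett_test(y, g, n_sim = 2e5, seed = 99)
  expect_identical(res$comparison, c("ba - control", "gh - control"))
  if (requireNamespace("multcomp", quietly = TRUE)) {
    fit <- stats::aov(y ~ factor(g, levels = c("control", "ba", "gh")))
    glht <- multcomp::glht(fit, linfct = multcomp::mcp(
      `factor(g, levels = c("control", "ba", "gh"))` = "Dunnett"))
    ref <- summary(glht)$test$pvalues
    expect_lt(max(abs(res$p_adjusted - as.numeric(ref))), 0.01)
  }
  # a huge shift is always detected
  y2 <- c(rnorm(8), rnorm(8, 10), rnorm(8))
  res2 <- dunnett_test(y2, rep(c("control", "ba", "gh"), each = 8),
                       n_sim = 1e5, seed = 3)
  expect_lt(res2$p_adjusted[res2$comparison == "ba - control"], 0.001)
  # identical groups at large n: adjusted p far from significance
  set.seed(18)
  y3 <- rnorm(300)
  res3 <- dunnett_test(y3, rep(c("control", "ba", "gh"), 100),
                       n_sim = 5e4, seed = 4)
  expect_true(all(res3$p_adjusted > 0.05))
  expect_error(dunnett_test(y3, rep(c("a", "b"), 150)), "control")
})

test_that("Dunnett adjustment is never anti-conservative", {
  set.seed(19)
  for (i in 1:10) {
    y <- rnorm(24, sd = runif(1, 0.5, 2))
    g <- rep(c("control", "ba", "gh"), each = 8)
    res <- dunnett_test(y, g, n_sim = 2e4, seed = i)
    expect_true(all(res$p_adjusted >= res$p_unadjusted - 1e-12))
  }
})

test_that("phenotype recipe gates Dunnett on the interaction", {
  set.seed(20)
  d <- expand.grid(rep = 1:5, treatment = c("control", "ba", "gh"),
                   day = c(1, 3, 7, 13, 27))
  d$batch <- rep(1:3, length.out = nrow(d))
  # no interaction: additive treatment effect only
  d$carcass_kg <- rnorm(nrow(d), 70) + 2 * (d$treatment == "ba")
  res <- phenotype_stats(d, "carcass_kg", dunnett = "auto", seed = 2)
  expect_true(res$dunnett_run)
  expect_s3_class(res$dunnett, "dunnett_result")
  # strong interaction: the auto gate withholds Dunnett
  d$vlat_g <- rnorm(nrow(d), 300, 2) +
    30 * (d$treatment == "ba") * (d$day >= 13)
  res2 <- phenotype_stats(d, "vlat_g", dunnett = "auto", seed = 2)
  expect_false(res2$dunnett_run)
  expect_null(res2$dunnett)
  res3 <- phenotype_stats(d, "vlat_g", dunnett = "always", seed = 2)
  expect_true(res3$dunnett_run)
})
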