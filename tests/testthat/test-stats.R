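test_that("Mauchly's test is exact for k = 2 and calibrated under the null", {
  set.seed(1)
  Y2 <- matrix(rnorm(80), 40, 2)
  m2 <- mauchly_test(Y2)
  expect_equal(m2$W, 1)
  expect_equal(m2$p, 1)
  expect_equal(m2$df, 0L)

  # compound-symmetric (spherical) data: nominal rejection rate
  set.seed(2)
  n <- 40; k <- 6
  rej <- replicate(800, {
    Y <- matrix(rnorm(n * k), n, k) + rnorm(n)
    mauchly_test(Y)$p < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
  expect_equal(mauchly_test(matrix(rnorm(n * k), n, k))$df,
               as.integer(k * (k - 1) / 2 - 1))
})

test_that("Mauchly's test detects strong variance heterogeneity", {
  set.seed(3)
  n <- 40; k <- 6
  scales <- c(0.2, 0.5, 1, 2, 4, 8)
  rej <- replicate(200, {
    base <- rnorm(n)
    Y <- outer(base, rep(1, k)) +
      matrix(rnorm(n * k), n, k) %*% diag(scales)
    mauchly_test(Y)$p < 0.05
  })
  expect_gt(mean(rej), 0.8)
})

test_that("Mauchly and GG agree with the multivariate-model reference", {
  skip_if_not_installed("car")
  set.seed(19)
  n <- 30; k <- 4
  Y <- matrix(rnorm(n * k), n, k) %*% matrix(runif(k * k, -0.4, 0.6), k, k)
  g <- factor(rep(c("a", "b"), n / 2))
  X <- model.matrix(~g)
  mod <- lm(Y ~ g)
  av <- car::Anova(mod, idata = data.frame(m = factor(1:k)), idesign = ~m,
                   type = 3)
  s <- summary(av, multivariate = FALSE)
  expect_equal(mauchly_test(Y, X)$W,
               unname(s$sphericity.tests[1, "Test statistic"]),
               tolerance = 1e-8)
  expect_equal(gg_epsilon(Y, X),
               unname(s$pval.adjustments[1, "GG eps"]), tolerance = 1e-8)
})

test_that("GG epsilon spans its theoretical range", {
  # spherical population: epsilon near 1
  set.seed(4)
  Y <- matrix(rnorm(500 * 4), 500, 4)
  expect_gt(gg_epsilon(Y), 0.95)
  # rank-1 contrast covariance attains the lower bound 1/(k-1)
  k <- 6
  v <- c(1, -1, rep(0, k - 2))
  Yr <- outer(rnorm(40), v)
  expect_equal(gg_epsilon(Yr), 1 / (k - 1), tolerance = 1e-9)
  expect_equal(gg_epsilon(matrix(rnorm(60), 30, 2)), 1)
})

test_that("mixed ANCOVA F values match the balanced cell-means oracle", {
  set.seed(7)
  n <- 8; k <- 3
  a <- rep(c("a1", "a2"), each = 4)
  b <- rep(c("b1", "b2", "b1", "b2"), each = 2)
  Y <- matrix(sample(1:40, n * k, replace = TRUE), n, k)
  oracle <- balanced_mixed_anova_oracle(Y, a, b)
  res <- mixed_rm_ancova(Y, data.frame(A = a, B = b))
  g <- function(eff) res$F[res$effect == eff]
  expect_equal(g("A"), oracle$F_a, tolerance = 1e-8)
  expect_equal(g("B"), oracle$F_b, tolerance = 1e-8)
  expect_equal(g("A:B"), oracle$F_ab, tolerance = 1e-8)
  expect_equal(g("block"), oracle$F_block, tolerance = 1e-8)
  expect_equal(g("block:A"), oracle$F_a_block, tolerance = 1e-8)
  expect_equal(g("block:B"), oracle$F_b_block, tolerance = 1e-8)
  expect_equal(g("block:A:B"), oracle$F_ab_block, tolerance = 1e-8)
})

test_that("mixed ANCOVA matches the multivariate-model reference with age", {
  skip_if_not_installed("car")
  set.seed(8)
  n <- 54; k <- 6
  Y <- matrix(rnorm(n * k, 40, 12), n, k) + rnorm(n, 0, 8)
  bt <- data.frame(ptsd = rep(c(TRUE, FALSE), c(25, 29)),
                   mtbi = sample(c(TRUE, FALSE), n, replace = TRUE))
  age <- round(runif(n, 22, 64))
  res <- mixed_rm_ancova(Y, bt, age)
  dat <- data.frame(ptsd = factor(bt$ptsd), mtbi = factor(bt$mtbi),
                    age_c = age - mean(age))
  mod <- lm(Y ~ age_c + ptsd * mtbi, data = dat,
            contrasts = list(ptsd = "contr.sum", mtbi = "contr.sum"))
  av <- car::Anova(mod, idata = data.frame(block = factor(1:k)),
                   idesign = ~block, type = 3)
  s <- summary(av, multivariate = FALSE)
  ref <- s$univariate.tests
  pick <- function(eff) unname(ref[eff, "F value"])
  expect_equal(res$F[res$effect == "ptsd"], pick("ptsd"), tolerance = 1e-7)
  expect_equal(res$F[res$effect == "mtbi"], pick("mtbi"), tolerance = 1e-7)
  expect_equal(res$F[res$effect == "ptsd:mtbi"], pick("ptsd:mtbi"),
               tolerance = 1e-7)
  expect_equal(res$F[res$effect == "age"], pick("age_c"), tolerance = 1e-7)
  expect_equal(res$F[res$effect == "block"], pick("block"), tolerance = 1e-7)
  expect_equal(res$F[res$effect == "block:ptsd"], pick("ptsd:block"),
               tolerance = 1e-7)
  expect_equal(res$F[res$effect == "block:ptsd:mtbi"],
               pick("ptsd:mtbi:block"), tolerance = 1e-7)
  # published df structure: between 1,49; within 5,245 for n=54, k=6
  expect_equal(res$df_den[res$effect == "ptsd"], 49)
  expect_equal(res$df_num[res$effect == "block"], 5)
  expect_equal(res$df_den[res$effect == "block"], 245)
  expect_equal(unname(attr(res, "mauchly")$W),
               unname(s$sphericity.tests[1, "Test statistic"]),
               tolerance = 1e-8)
})

test_that("ANCOVA is invariant to location shifts and GG never helps", {
  set.seed(9)
  n <- 24; k <- 4
  Y <- matrix(rnorm(n * k, 30, 10), n, k)
  bt <- data.frame(A = rep(c(TRUE, FALSE), each = 12),
                   B = rep(c(TRUE, FALSE), 12))
  age <- runif(n, 20, 60)
  r1 <- mixed_rm_ancova(Y, bt, age)
  r2 <- mixed_rm_ancova(Y + 1000, bt, age)
  expect_equal(r1$F, r2$F, tolerance = 1e-8)
  within <- r1$stratum == "within"
  expect_true(all(r1$gg_epsilon[within] >= 1 / (k - 1) &
                    r1$gg_epsilon[within] <= 1))
  # shrinking both df by epsilon <= 1 inflates the p-value wherever the
  # effect is anywhere near significance (the claim reverses deep in the
  # null region, where it is irrelevant to inference)
  set.seed(10)
  for (rep_i in 1:50) {
    Yb <- matrix(rnorm(n * k), n, k) %*% matrix(runif(k * k, -1, 1), k, k)
    Yb <- sweep(Yb, 2, 3 * seq_len(k))  # strong block effect
    r <- mixed_rm_ancova(Yb, bt, age)
    w <- r$stratum == "within" & r$p_uncorrected <= 0.1
    expect_true(all(r$p_gg[w] >= r$p_uncorrected[w] - 1e-12))
  }
})

test_that("ANCOVA rejects deficient designs", {
  Y <- matrix(rnorm(12), 6, 2)
  bt <- data.frame(A = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_error(mixed_rm_ancova(Y, bt), "cell")
  bt2 <- data.frame(A = rep(c(TRUE, FALSE), each = 3))
  expect_error(mixed_rm_ancova(Y, bt2, covariate = rep(1, 6)), "constant")
})

test_that("Bonferroni adjustment is the capped product", {
  expect_equal(bonferroni_adjust(0.01, 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, 4), 1.0)
  expect_equal(bonferroni_adjust(c(0.2, 0.04), 1), c(0.2, 0.04))
  expect_error(bonferroni_adjust(1.2), "pvals")
})

test_that("Helmert contrasts compare Low against the better learners", {
  g <- factor(rep(c("LOW", "MID", "HIGH"), each = 5),
              levels = c("LOW", "MID", "HIGH"))
  y <- rep(c(0, 1, 1), each = 5) + rnorm(15, 0, 1e-8)
  hc <- helmert_contrasts(y, g)
  expect_equal(hc$estimate[hc$contrast == "first_vs_rest"], -1,
               tolerance = 1e-6)
  expect_equal(hc$estimate[hc$contrast == "second_vs_third"], 0,
               tolerance = 1e-6)
  expect_equal(unique(hc$df), 12L)

  # arithmetic oracle on unbalanced groups
  set.seed(11)
  y2 <- rnorm(20, rep(c(5, 8, 9), c(6, 7, 7)), 2)
  g2 <- factor(rep(c("LOW", "MID", "HIGH"), c(6, 7, 7)),
               levels = c("LOW", "MID", "HIGH"))
  hc2 <- helmert_contrasts(y2, g2)
  m <- tapply(y2, g2, mean)
  expect_equal(hc2$estimate[1], unname(m[1] - (m[2] + m[3]) / 2),
               tolerance = 1e-10)
  expect_equal(hc2$estimate[2], unname(m[2] - m[3]), tolerance = 1e-10)
  expect_error(helmert_contrasts(y2, rep(c("a", "b"), 10)), "3")
})

test_that("Helmert contrast type-I rate is nominal under equal means", {
  set.seed(12)
  rej <- replicate(2000, {
    y <- rnorm(24)
    g <- factor(rep(c("LOW", "MID", "HIGH"), each = 8),
                levels = c("LOW", "MID", "HIGH"))
    helmert_contrasts(y, g)$p[1] < 0.05
  })
  expect_gt(mean(rej), 0.035)
  expect_lt(mean(rej), 0.065)
})

test_that("pooled t-test reproduces published df conventions", {
  x <- rnorm(20); y <- rnorm(14)
  tt <- two_sample_t(x, y)
  expect_equal(tt$df, 32L)
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # F = t^2 identity for two groups
  a <- one_way_anova(c(x, y), rep(c("x", "y"), c(20, 14)))
  expect_equal(a$F, tt$t^2, tolerance = 1e-10)
  expect_equal(a$df2, 32L)
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
})

test_that("one-way ANOVA decomposition and effect size are standard", {
  set.seed(13)
  y <- rnorm(30, rep(c(0, 0, 3), each = 10))
  g <- rep(c("a", "b", "c"), each = 10)
  a <- one_way_anova(y, g)
  ref <- summary(aov(y ~ factor(g)))[[1]]
  expect_equal(a$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(a$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(a$partial_eta_sq,
               ref$`Sum Sq`[1] / sum(ref$`Sum Sq`), tolerance = 1e-10)
})

test_that("the no-effect simulate-score-ANCOVA chain has nominal size", {
  # flat learning, balanced groups, no planted group effect anywhere
  set.seed(15)
  n <- 24; k <- 6
  rej <- replicate(1000, {
    cr <- matrix(runif(n * k * 10) < 0.3, n, k * 10)
    Y <- t(apply(cr, 1, function(tr) block_cr_percent(tr)))
    bt <- data.frame(ptsd = rep(c(TRUE, FALSE), each = n / 2),
                     mtbi = rep(c(TRUE, FALSE), n / 2))
    age <- runif(n, 20, 60)
    res <- mixed_rm_ancova(Y, bt, age)
    res$p_uncorrected[res$effect == "ptsd"] < 0.05
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})
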