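test_that("Welch test matches the closed-form statistic", {
  x <- c(1, 2, 3, 5, 8)
  y <- c(11, 12.5, 13, 15, 18.2, 20)
  got <- welch_t_test(x, y)
  want <- welch_oracle(x, y)
  expect_equal(got$t, want$t)
  expect_equal(got$df, want$df)
  expect_equal(got$p, want$p)
  # identical groups: t = 0, p = 1
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # invariance under common affine rescaling
  a <- welch_t_test(x, y)
  b <- welch_t_test(3 * x + 7, 3 * y + 7)
  expect_equal(a$t, b$t)
  expect_equal(a$p, b$p)
})

test_that("degenerate zero-variance groups follow the stated conventions", {
  expect_equal(welch_t_test(c(2, 2, 2), c(2, 2))$p, 1)
  expect_warning(res <- welch_t_test(c(2, 2, 2), c(5, 5)), "zero variance")
  expect_equal(res$p, 0)
  expect_true(res$degenerate)
})

test_that("signed-rank p equals full enumeration for small n", {
  withr::with_seed(42, {
    for (i in 1:10) {
      n <- sample(4:8, 1)
      x <- round(rnorm(n, 0, 2), 2)
      y <- round(rnorm(n, 0.8, 2), 2)
      while (any(x == y) || any(duplicated(abs(x - y))))
        y <- round(rnorm(n, 0.8, 2), 2)
      got <- wilcoxon_signed_rank(x, y)
      expect_true(got$exact)
      expect_equal(got$p, signed_rank_enumeration(x - y))
    }
  })
  # antisymmetry: swapping the members of each pair preserves p
  x <- c(1.2, 3.4, 2.2, 5.1, 0.3)
  y <- c(2.0, 1.1, 4.4, 5.0, 1.9)
  expect_equal(wilcoxon_signed_rank(x, y)$p, wilcoxon_signed_rank(y, x)$p)
})

test_that("all-zero paired differences give p = 1 with a warning", {
  expect_warning(res <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)),
                 "zero")
  expect_equal(res$p, 1)
  expect_equal(res$n_used, 0L)
})

test_that("balanced two-way ANOVA reproduces explicit sums of squares", {
  d <- withr::with_seed(1, {
    g <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"))
    d <- g[rep(1:4, each = 3), ]
    d$y <- 10 + 2 * (d$a == "a2") + 3 * (d$b == "b2") +
      1.5 * (d$a == "a2") * (d$b == "b2") + rnorm(12, 0, 1)
    d
  })
  got <- factorial_anova(d, "y", c("a", "b"))
  want <- balanced_two_way_oracle(d$y, d$a, d$b)
  expect_equal(got$F[got$effect == "a"], unname(want$F1))
  expect_equal(got$F[got$effect == "b"], unname(want$F2))
  expect_equal(got$F[got$effect == "a:b"], unname(want$F12))
  expect_equal(unique(got$df2), want$dfe)
  expect_match(attr(got, "ss_type"), "sequential")
  # location invariance: adding a constant leaves every F unchanged
  d2 <- d; d2$y <- d2$y + 100
  expect_equal(factorial_anova(d2, "y", c("a", "b"))$F, got$F)
})

test_that("unbalanced designs switch to marginal sums of squares", {
  d <- withr::with_seed(2, {
    data.frame(a = rep(c("a1", "a2"), c(8, 14)),
               b = sample(c("b1", "b2"), 22, replace = TRUE),
               y = rnorm(22))
  })
  got <- factorial_anova(d, "y", c("a", "b"))
  expect_match(attr(got, "ss_type"), "Type III")
  expect_identical(nrow(got), 3L)
  d$c1 <- "only_level"
  expect_error(factorial_anova(d, "y", c("a", "c1")), "fewer than 2")
})

test_that("label permutation calibrates F around 1 under the null", {
  d0 <- withr::with_seed(3, {
    data.frame(a = rep(c("a1", "a2"), each = 12),
               b = rep(c("b1", "b2"), 12), y = rnorm(24))
  })
  fbar <- withr::with_seed(4, {
    mean(vapply(1:200, function(i) {
      d <- d0
      d$y <- sample(d$y)
      factorial_anova(d, "y", c("a", "b"))$F[1]
    }, numeric(1)))
  })
  expect_lt(abs(fbar - 1), 0.35)
})

test_that("Tukey HSD matches the studentized-range computation", {
  d <- withr::with_seed(5, {
    data.frame(g = rep(c("g1", "g2", "g3"), c(6, 9, 7)),
               y = rnorm(22) + rep(c(0, 1.2, 0.4), c(6, 9, 7)))
  })
  got <- tukey_hsd(d, "y", "g")
  fit <- aov(y ~ g, data = d)
  mse <- sum(residuals(fit)^2) / df.residual(fit)
  ns <- table(d$g)
  means <- tapply(d$y, d$g, mean)
  for (i in seq_len(nrow(got))) {
    pair <- strsplit(got$comparison[i], "-", fixed = TRUE)[[1]]
    want_p <- tukey_pair_oracle(means[[pair[1]]] - means[[pair[2]]], mse,
                                ns[[pair[1]]], ns[[pair[2]]], 3,
                                df.residual(fit))
    expect_equal(got$p_adj[i], want_p, tolerance = 1e-8)
    # adjusted p is never smaller than the unadjusted pairwise p
    raw_p <- 2 * pt(-got$q[i] / sqrt(2), df.residual(fit))
    expect_gte(got$p_adj[i] + 1e-12, raw_p)
  }
})

test_that("equal group means give adjusted p of 1 and q of 0", {
  d <- data.frame(g = rep(c("g1", "g2"), each = 4), y = rep(1:4, 2))
  got <- tukey_hsd(d, "y", "g")
  expect_equal(got$q, 0)
  expect_equal(got$p_adj, 1)
  # a single group yields an empty comparison table
  d1 <- data.frame(g = "g1", y = rnorm(5))
  expect_equal(nrow(tukey_hsd(d1, "y", "g")), 0L)
})

test_that("three-way factorial cohorts separate stage-by-pathway effects", {
  # complementary-rows design: each sample contributes its HR and NHEJ
  # relative percentages as two rows of a pathway factor
  build_rows <- function(label, n, seed) {
    prof <- preset_profile(label)
    rel <- withr::with_seed(seed, pmin(100, pmax(0,
      rnorm(n, prof$rel_HR_truth, 7))))
    data.frame(stage = prof$tissue, sex = prof$sex,
               pathway = rep(c("HR", "NHEJ"), each = n),
               value = c(rel, 100 - rel))
  }
  d <- rbind(build_rows("larval_brain_male", 23, 1),
             build_rows("larval_brain_female", 25, 2),
             build_rows("adult_head_male", 38, 3),
             build_rows("adult_head_female", 38, 4))
  got <- factorial_anova(d, "value", c("stage", "sex", "pathway"))
  f_stage_path <- got$F[got$effect == "stage:pathway"]
  p_sex <- got$p[got$effect == "sex"]
  expect_gt(f_stage_path, 100)
  expect_gt(p_sex, 0.05)
})
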