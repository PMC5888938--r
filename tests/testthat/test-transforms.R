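test_that("log-z transform normalizes right-skewed positive data", {
  x <- exp(rnorm(200, 1, 0.5))
  z <- log_z_transform(x)
  expect_lt(abs(mean(z)), 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)

  expect_error(log_z_transform(c(1, 2, 0)), "positive")
  expect_error(log_z_transform(c(-1, 2, 3)), "positive")
  expect_error(log_z_transform(rep(4, 10)), "zero variance")

  # normality improves after the transform for lognormal samples
  set.seed(77)
  better <- replicate(100, {
    x <- exp(rnorm(500, 3, 0.8))
    stats::shapiro.test(log_z_transform(x))$statistic >
      stats::shapiro.test(scale(x)[, 1])$statistic
  })
  expect_gte(mean(better), 0.95)
})

test_that("Cohen's d uses the RMS-of-SDs convention and reproduces published values", {
  expect_equal(round(cohens_d(110, 89.48, 55.19, 22.2), 2), 0.84)
  expect_equal(round(cohens_d(2.12, 1.25, 1.04, 0.05), 2), 1.22)
  expect_equal(cohens_d(5, 2, 5, 3), 0)
  expect_equal(cohens_d(1, 2, 4, 3), cohens_d(4, 3, 1, 2))
  expect_error(cohens_d(1, 0, 2, 0), "both SDs")
  # the n-weighted pooled-SD convention would NOT reproduce 1.22
  pooled <- abs(2.12 - 1.04) / sqrt(((74 - 1) * 1.25^2 + (55 - 1) * 0.05^2) / 127)
  expect_false(round(pooled, 2) == 1.22)
})

test_that("group comparisons dispatch t / ANOVA+Tukey / chi-square correctly", {
  tab <- data.frame(g = rep(c("a", "b"), each = 10),
                    x = c(rnorm(10, 0), rnorm(10, 2)),
                    sex = rep(c("f", "m"), 10))
  r <- group_comparison(tab, "x", "g")
  expect_equal(r$test, "t")
  expect_lt(r$p, 0.05)

  # identical groups -> t = 0, p = 1
  tab2 <- data.frame(g = rep(c("a", "b"), each = 6), x = rep(1:6, 2))
  r2 <- group_comparison(tab2, "x", "g")
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p, 1)

  set.seed(4)
  tab3 <- data.frame(g = rep(c("a", "b", "c"), each = 15),
                     x = rnorm(45) + rep(c(0, 0, 2), each = 15))
  r3 <- group_comparison(tab3, "x", "g")
  expect_equal(r3$test, "anova")
  expect_equal(nrow(r3$tukey), 3)
  expect_lt(r3$tukey["c-a", "p adj"], 0.05)

  cat_tab <- data.frame(g = rep(c("a", "b"), c(74, 55)),
                        sex = c(rep(c("f", "m"), c(42, 32)),
                                rep(c("f", "m"), c(34, 21))))
  r4 <- group_comparison(cat_tab, "sex", "g")
  expect_equal(r4$test, "chisq")
  expect_equal(round(r4$p, 3), 0.563)

  expect_error(group_comparison(data.frame(g = "a", x = 1), "x", "g"),
               "2 groups")
})

test_that("the Bonferroni alpha gate flags primary analyses at 0.0125 strictly", {
  res <- data.frame(p = c(0.008, 0.018, 0.0125, 0.03, 0.06),
                    primary = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  out <- apply_alpha_gate(res)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE, TRUE, FALSE))
})
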