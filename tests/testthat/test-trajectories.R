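# Inject a known outcome into a simulated cohort's MC stratum (keeping the
# covariate structure) so order selection can be tested against a known
# generating polynomial.
inject_outcome <- function(tab, fun, noise_sd = 1, seed = 1) {
  set.seed(seed)
  x <- tab$eyo - mean(tab$eyo)
  tab$mmse <- pmin(30, pmax(0, 25 + fun(x) + rnorm(nrow(tab), 0, noise_sd)))
  tab
}

test_that("AICc order selection finds linear and cubic generating trends", {
  picks_lin <- picks_cub <- integer(20)
  for (r in 1:20) {
    base <- simulate_cohort("DIAN", n_per_group = c(MC = 300, NC = 20),
                            rng_seed = 900 + r)
    lin <- inject_outcome(base, function(x) 0.15 * x, seed = r)
    f <- quiet_poly(lin, "mmse", "eyo", "MC", "DIAN")
    picks_lin[r] <- f$chosen_order

    cub <- inject_outcome(base, function(x) 0.1 * x - 0.012 * x^2 + 8e-4 * x^3,
                          seed = r)
    f3 <- quiet_poly(cub, "mmse", "eyo", "MC", "DIAN")
    picks_cub[r] <- f3$chosen_order
  }
  expect_gte(mean(picks_lin == 1), 0.80)
  expect_gte(mean(picks_cub == 3), 0.80)
})

test_that("an outcome independent of the axis yields null axis coefficients", {
  base <- simulate_cohort("DIAN", n_per_group = c(MC = 200, NC = 20),
                          rng_seed = 31)
  flat <- inject_outcome(base, function(x) 0 * x, seed = 31)
  f <- quiet_poly(flat, "mmse", "eyo", "MC", "DIAN")
  cf <- f$coefficients
  ax <- grepl("^x[0-9]$", rownames(cf))
  expect_true(all(abs(cf$beta[ax]) < 3 * cf$se[ax]))
})

test_that("with plain AIC the order penalty is exactly 2 per added term", {
  base <- simulate_cohort("DIAN", n_per_group = c(MC = 150, NC = 20),
                          rng_seed = 55)
  f <- quiet_poly(base, "mmse", "eyo", "MC", "DIAN", criterion = "aic")
  # log-likelihood is non-decreasing in order for nested ML fits, so each
  # extra term can raise the AIC by at most its penalty of 2
  expect_true(all(diff(f$aic_per_order) <= 2 + 1e-6))
})

test_that("difference curves behave as closed forms dictate", {
  tab <- simulate_cohort("DIAN", rng_seed = 13)
  f1 <- quiet_poly(tab, "mmse", "eyo", "MC", "DIAN")
  psd <- sd(tab$mmse)

  dc0 <- predict_difference_curve(f1, f1, psd)
  expect_true(all(dc0$standardized_difference == 0))
  expect_equal(range(dc0$axis_value), c(-20, 10))

  # shifting one model's intercept by delta gives a flat curve delta/psd
  f2 <- f1
  f2$coefficients["(Intercept)", "beta"] <- f2$coefficients["(Intercept)", "beta"] + 2.5
  dc <- predict_difference_curve(f2, f1, psd)
  expect_equal(dc$standardized_difference, rep(2.5 / psd, nrow(dc)),
               tolerance = 1e-10)

  f3 <- quiet_poly(tab, "lm_delayed", "eyo", "MC", "DIAN")
  expect_error(predict_difference_curve(f1, f3, psd), "different outcomes")
  expect_error(predict_difference_curve(f1, f1, 0), "pooled_sd")
})

test_that("adding a constant to the outcome leaves the difference curve unchanged", {
  tab <- simulate_cohort("DIAN", rng_seed = 17)
  psd <- sd(tab$mmse)
  f1 <- quiet_poly(tab, "mmse", "eyo", "MC", "DIAN")
  f2 <- quiet_poly(tab, "mmse", "eyo", "NC", "DIAN")
  dc <- predict_difference_curve(f1, f2, psd)

  tab2 <- tab
  tab2$mmse <- tab2$mmse - 5   # stays inside [0, 30]
  g1 <- quiet_poly(tab2, "mmse", "eyo", "MC", "DIAN")
  g2 <- quiet_poly(tab2, "mmse", "eyo", "NC", "DIAN")
  dc2 <- predict_difference_curve(g1, g2, psd)
  expect_equal(dc2$standardized_difference, dc$standardized_difference,
               tolerance = 1e-4)
})

test_that("the generating sigmoid delays decline for high connectivity", {
  g <- seq(-20, 10, 0.5)
  hi <- sigmoid_generating_curve(g, conn_z = 1)
  lo <- sigmoid_generating_curve(g, conn_z = -1)
  cross <- function(cv, thr) g[which(cv < thr)[1]]
  expect_gt(cross(hi, -2), cross(lo, -2))
  # high-connectivity curve is everywhere at or above the low one
  expect_true(all(hi >= lo))
})

test_that("median split labels strictly-above-median high, ties low", {
  expect_equal(median_split(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_equal(median_split(c(1, 2, 2, 3)), c("low", "low", "low", "high"))
  expect_error(median_split(rep(3, 5)), "distinct")

  # balance: with a non-data median the split is even to within 1; when the
  # median is a data value, all its ties go low, so the imbalance is
  # bounded by 2 * ties (low gains what high loses)
  set.seed(2)
  for (r in 1:20) {
    v <- sample(1:6, 30, replace = TRUE)
    s <- median_split(v)
    ties <- sum(v == median(v))
    expect_lte(abs(sum(s == "high") - sum(s == "low")), max(2 * ties, 1))
    expect_lte(sum(s == "high"), sum(s == "low") + 1)
  }
})
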