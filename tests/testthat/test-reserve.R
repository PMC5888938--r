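test_that("reported betas are standardized: affine rescaling of inputs changes nothing", {
  tab <- simulate_cohort("DIAN", rng_seed = 21)
  f0 <- quiet_reserve(tab, "mmse", "eyo", "LFC", "MC", "DIAN")

  tab2 <- tab
  tab2$mmse <- tab2$mmse * 3 + 7          # outcome affine
  tab2$eyo <- tab2$eyo / 2 - 1            # severity affine
  tab2$conn_lfc <- tab2$conn_lfc * 10     # connectivity positive scaling
  f1 <- quiet_reserve(tab2, "mmse", "eyo", "LFC", "MC", "DIAN")
  expect_equal(f1$terms$beta, f0$terms$beta, tolerance = 1e-8)
  expect_equal(f1$terms$se, f0$terms$se, tolerance = 1e-8)

  # the education model is likewise invariant to the education unit
  e0 <- suppressWarnings(fit_education_model(tab, "MC", "DIAN"))
  tab3 <- tab; tab3$education <- tab3$education * 2
  e1 <- suppressWarnings(fit_education_model(tab3, "MC", "DIAN"))
  expect_equal(e1$terms["education", "beta"], e0$terms["education", "beta"],
               tolerance = 1e-8)
})

test_that("a null interaction is recovered as null and a strong one wins the AIC comparison", {
  inside <- prefer <- logical(40)
  for (r in 1:40) {
    tab <- simulate_cohort("DIAN", n_per_group = c(MC = 200, NC = 20),
                           interaction_beta = 0, rng_seed = 400 + r)
    f <- quiet_reserve(tab, "mmse", "eyo", "LFC", "MC", "DIAN")
    b <- f$terms[f$interaction_term, ]
    inside[r] <- abs(b$beta) < 3 * b$se

    tab2 <- simulate_cohort("DIAN", n_per_group = c(MC = 200, NC = 20),
                            interaction_beta = 0.4, rng_seed = 700 + r)
    f2 <- quiet_reserve(tab2, "mmse", "eyo", "LFC", "MC", "DIAN")
    prefer[r] <- f2$aic_comparison$full_preferred
  }
  expect_gte(mean(inside), 0.90)
  expect_gte(mean(prefer), 0.90)
})

test_that("the interaction test keeps its type-I error near the nominal level", {
  # spec-scale: 1000 null simulations at n = 100; type-I error <= 7%
  hits <- logical(1000)
  for (r in seq_along(hits)) {
    tab <- simulate_cohort("DIAN", n_per_group = c(MC = 100, NC = 10),
                           interaction_beta = 0, rng_seed = 5000 + r)
    f <- quiet_reserve(tab, "mmse", "eyo", "LFC", "MC", "DIAN")
    hits[r] <- f$terms[f$interaction_term, "p"] < 0.05
  }
  expect_lte(mean(hits), 0.07)
})

test_that("cohorts are never pooled and strata are validated", {
  dian <- simulate_cohort("DIAN", rng_seed = 1)
  delcode <- simulate_cohort("DELCODE", rng_seed = 1)
  mixed <- rbind(dian, delcode)
  expect_error(fit_reserve_interaction(mixed, "mmse", "csf_tau", "LFC",
                                       "MC", "DIAN"), "never pooled")
  expect_error(fit_group_ancova(mixed, "conn_lfc", "group"), "never pooled")
  expect_error(group_comparison(mixed, "mmse", "group"), NA)  # descriptives take any table

  expect_error(fit_reserve_interaction(dian, "mmse", "eyo", "LFC",
                                       "Abeta+", "DIAN"), "MC")
  expect_error(fit_reserve_interaction(delcode, "mmse", "csf_tau", "LFC",
                                       "MC", "DELCODE"), "Abeta")
  expect_error(fit_reserve_interaction(dian, "adas_recall", "eyo", "LFC",
                                       "MC", "DIAN"), "DELCODE")
  expect_error(fit_reserve_interaction(delcode, "mmse", "eyo", "LFC",
                                       "Abeta+", "DELCODE"), "DIAN")
})

test_that("the group ANCOVA is calibrated under the null and powered for a d = 0.5 shift", {
  # null: connectivity group effect removed -> p approximately uniform
  set.seed(8)
  p_null <- replicate(60, {
    tab <- simulate_cohort("DIAN", n_per_group = c(MC = 40, NC = 40),
                           group_effect_d = c(conn_lfc = 0),
                           rng_seed = sample.int(1e6, 1))
    suppressWarnings(fit_group_ancova(tab, "conn_lfc", "group"))$p_group
  })
  expect_gt(stats::ks.test(p_null, "punif")$p.value, 0.01)

  # planted d = 0.5 at the published sample sizes
  p_alt <- replicate(40, {
    tab <- simulate_cohort("DIAN", group_effect_d = c(conn_lfc = 0.5),
                           rng_seed = sample.int(1e6, 1))
    suppressWarnings(fit_group_ancova(tab, "conn_lfc", "group"))$p_group
  })
  expect_gte(mean(p_alt < 0.05), 0.5)

  # permuting the group labels destroys the planted effect
  tab <- simulate_cohort("DIAN", group_effect_d = c(conn_lfc = 1.0),
                         rng_seed = 3)
  p_true <- suppressWarnings(fit_group_ancova(tab, "conn_lfc", "group"))$p_group
  expect_lt(p_true, 0.05)
  p_perm <- replicate(20, {
    tab$group <- sample(tab$group)
    suppressWarnings(fit_group_ancova(tab, "conn_lfc", "group"))$p_group
  })
  expect_lte(mean(p_perm < 0.05), 0.25)
})

test_that("single-site tables fall back to a fixed-intercept model with a warning", {
  tab <- simulate_cohort("DIAN", n_sites = 1, rng_seed = 6)
  w <- testthat::capture_warnings(
    f <- fit_reserve_interaction(tab, "mmse", "eyo", "LFC", "MC", "DIAN"))
  expect_true(any(grepl("one site", w)))   # full and reduced fits both warn
  expect_equal(f$random_effect, "none")
  expect_true(is.finite(f$aic))
})
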