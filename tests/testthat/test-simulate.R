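test_that("generators are pure functions of their seed", {
  a <- simulate_bold_run(grid_shape = c(8, 8, 8), n_volumes = 40, rng_seed = 3)
  b <- simulate_bold_run(grid_shape = c(8, 8, 8), n_volumes = 40, rng_seed = 3)
  expect_identical(a$run$data, b$run$data)
  expect_identical(a$motion, b$motion)
  c <- simulate_bold_run(grid_shape = c(8, 8, 8), n_volumes = 40, rng_seed = 4)
  expect_false(identical(a$run$data, c$run$data))

  t1 <- simulate_cohort("DIAN", rng_seed = 9)
  t2 <- simulate_cohort("DIAN", rng_seed = 9)
  expect_identical(t1, t2)
  t3 <- simulate_cohort("DELCODE", rng_seed = 9)
  expect_identical(t3, simulate_cohort("DELCODE", rng_seed = 9))
})

test_that("generated tables satisfy the phenotype invariants", {
  for (coh in c("DIAN", "DELCODE")) {
    tab <- simulate_cohort(coh, rng_seed = 44)
    expect_true(all(tab$mmse >= 0 & tab$mmse <= 30))
    expect_true(all(tab$education >= 0))
    expect_identical(tab$abeta_status == "pos", tab$csf_abeta_ratio < 0.1)
    expect_true(all(tab$csf_tau > 0))
    expect_true(all(tab$conn_lfc > 0))
    expect_equal(unique(tab$cohort), coh)
  }
  tab <- simulate_cohort("DELCODE", rng_seed = 44)
  expect_setequal(unique(tab$group), c("CN", "SCD", "MCI", "ADD"))
  expect_true(all(tab$abeta_status[tab$group %in% c("MCI", "ADD")] == "pos"))
  expect_true(all(is.na(tab$eyo)))
  dian <- simulate_cohort("DIAN", rng_seed = 44)
  expect_true(all(dian$eyo >= -30 & dian$eyo <= 15))
  # the MMSE ceiling clamp is a rare safety net, not a feature of the data
  expect_lt(mean(dian$mmse == 30), 0.05)
})

test_that("planted seed-voxel coupling hits its target correlation", {
  sim <- simulate_bold_run(grid_shape = c(8, 8, 8), n_volumes = 200,
                           coupled_fraction = 1, coupling_rho = 0.5,
                           motion_spike_prob = 0, rng_seed = 12)
  # the planted rho is the correlation of the latent signals; measure it
  # after the nuisance structure (drift, WM/CSF leakage) is removed
  V <- denoise_run(sim$run, sim$motion, sim$wm_mask, sim$csf_mask)
  seed_ts <- rowMeans(V[, as.vector(sim$seed_mask), drop = FALSE])
  tgt <- which(as.vector(sim$gm_mask) & !as.vector(sim$seed_mask))
  r <- as.vector(cor(seed_ts, V[, tgt]))
  expect_gt(mean(r), 0.45)
  expect_lt(mean(r), 0.55)
})

test_that("an uncoupled run scores at the null level predicted by a Monte-Carlo oracle", {
  scores <- sapply(1:4, function(s) {
    sim <- simulate_bold_run(grid_shape = c(7, 7, 7), n_volumes = 120,
                             coupled_fraction = 0, motion_spike_prob = 0,
                             rng_seed = 60 + s)
    # fwhm 0: smoothing would leak seed signal into neighbouring voxels,
    # which is a real (tested elsewhere) effect but not the null being
    # checked here
    compute_global_connectivity(sim$run, sim$motion, sim$gm_mask, sim$wm_mask,
                                sim$csf_mask, seeds = "LFC", fwhm_mm = 0)$score
  })
  # oracle: mean positive Fisher z between independent band-limited series
  # of the same retained length (band-passing leaves few effective dof, so
  # null correlations are far from the iid case)
  set.seed(99)
  tr <- 2.23
  sims <- replicate(400, {
    # match the pipeline's residual degrees of freedom: each series loses
    # the same 8 smooth confounds plus intercept
    conf <- cbind(1, bandpass_butterworth(matrix(rnorm(120 * 8), 120), tr))
    a <- qr.resid(qr(conf), bandpass_butterworth(rnorm(120), tr))
    b <- qr.resid(qr(conf), bandpass_butterworth(rnorm(120), tr))
    r <- cor(a, b)
    if (r > 0) atanh(min(r, 1 - 1e-7)) else NA_real_
  })
  oracle <- mean(sims, na.rm = TRUE)
  se <- sqrt(sd(scores)^2 / length(scores) +
               var(sims, na.rm = TRUE) / sum(!is.na(sims)))
  expect_lt(abs(mean(scores) - oracle), 2 * se + 0.02)
})

test_that("group effect-size targets are hit at large n (RMS convention)", {
  tab <- simulate_cohort("DIAN", n_per_group = c(MC = 10000, NC = 10000),
                         rng_seed = 123)
  mc <- tab$csf_tau[tab$group == "MC"]; nc <- tab$csf_tau[tab$group == "NC"]
  d <- cohens_d(mean(mc), sd(mc), mean(nc), sd(nc))
  expect_gte(d, 0.80)
  expect_lte(d, 0.88)

  # connectivity gap (carriers lower) and education-connectivity link
  d_conn <- cohens_d(mean(tab$conn_lfc[tab$group == "MC"]),
                     sd(tab$conn_lfc[tab$group == "MC"]),
                     mean(tab$conn_lfc[tab$group == "NC"]),
                     sd(tab$conn_lfc[tab$group == "NC"]))
  expect_lt(abs(d_conn - 0.43), 0.08)
  # pooled correlation exceeds the planted within-group 0.25 slightly
  # because carriers are lower on both education and connectivity
  r_edu <- cor(tab$education, log(tab$conn_lfc))
  expect_gt(r_edu, 0.20); expect_lt(r_edu, 0.33)

  expect_error(simulate_cohort("DIAN", group_effect_d = c(conn_lfc = 10),
                               rng_seed = 1), "infeasible")
})
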