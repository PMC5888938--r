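test_that("global connectivity matches the brute-force per-voxel oracle", {
  for (s in 1:3) {
    toy <- make_toy_cleaned(seed = s)
    res <- global_connectivity(toy$M, toy$seed_mask, toy$gm)
    expect_equal(res$score, oracle_score(toy$M, toy$seed_mask, toy$gm),
                 tolerance = 1e-10)
    expect_equal(res$n_gm_voxels, sum(toy$gm) - sum(toy$seed_mask))
  }
})

test_that("degenerate correlation structures give the documented scores", {
  grid <- c(4, 4, 2); nt <- 64
  seed_mask <- array(FALSE, grid); seed_mask[1:2, 1, 1] <- TRUE
  gm <- array(TRUE, grid)
  tt <- seq_len(nt)

  # every non-seed voxel orthogonal to the seed series -> score ~ 0
  M <- matrix(0, nt, prod(grid))
  M[, as.vector(seed_mask)] <- sin(2 * pi * tt / 16)
  M[, !as.vector(seed_mask)] <- cos(2 * pi * tt / 16)
  res <- global_connectivity(M, seed_mask, gm)
  expect_lt(res$score, 1e-6)

  # all voxels positively proportional to the seed -> r = 1 clipped
  M2 <- matrix(0, nt, prod(grid))
  base <- sin(2 * pi * tt / 16) + 0.3 * cos(2 * pi * tt / 5)
  for (j in seq_len(prod(grid))) M2[, j] <- base * (0.2 + j / 10)
  res2 <- global_connectivity(M2, seed_mask, gm)
  expect_equal(res2$score, atanh(1 - 1e-7))
  expect_equal(res2$n_positive_voxels, res2$n_gm_voxels)

  # all anti-correlated -> no positive voxels, score 0 with a warning
  M3 <- M2; M3[, !as.vector(seed_mask)] <- -M2[, !as.vector(seed_mask)]
  expect_warning(res3 <- global_connectivity(M3, seed_mask, gm), "no positive")
  expect_equal(res3$score, 0)
  expect_equal(res3$n_positive_voxels, 0)
})

test_that("the score is invariant to voxel order and positive rescaling, and bounded", {
  toy <- make_toy_cleaned(seed = 9)
  base <- global_connectivity(toy$M, toy$seed_mask, toy$gm)$score

  # positive rescaling of any voxel's series
  M2 <- toy$M
  M2[, 40] <- M2[, 40] * 17.3
  M2[, 70] <- M2[, 70] * 0.01
  expect_equal(global_connectivity(M2, toy$seed_mask, toy$gm)$score, base,
               tolerance = 1e-12)

  # permuting non-seed voxel order (masks permuted consistently)
  set.seed(1)
  perm <- sample(prod(toy$grid))
  M3 <- toy$M[, perm]
  sm3 <- array(as.vector(toy$seed_mask)[perm], dim = toy$grid)
  expect_equal(global_connectivity(M3, sm3, toy$gm)$score, base,
               tolerance = 1e-12)

  for (s in 1:5) {
    toy <- make_toy_cleaned(grid = c(4, 4, 3), nt = 40, seed = 100 + s)
    sc <- global_connectivity(toy$M, toy$seed_mask, toy$gm)$score
    expect_gte(sc, 0)
    expect_lte(sc, atanh(1 - 1e-7))
  }
})

test_that("QC refusals and errors are enforced", {
  toy <- make_toy_cleaned()
  excl <- build_censor_mask(c(0, rep(0.9, 30), rep(0, toy$nt - 31)))
  expect_true(excl$excluded)
  expect_error(global_connectivity(toy$M, toy$seed_mask, toy$gm, excl),
               "excluded by QC")

  few <- build_censor_mask(c(rep(0, 5), rep(0.9, toy$nt - 5)),
                           exclusion_fraction = 0.999)
  expect_error(global_connectivity(toy$M, toy$seed_mask, toy$gm, few),
               "fewer than 10")

  Mz <- toy$M
  Mz[, as.vector(toy$seed_mask)] <- 5
  expect_error(global_connectivity(Mz, toy$seed_mask, toy$gm), "zero variance")
})

test_that("the full per-subject pipeline reproduces the oracle on a planted run and drops excluded subjects", {
  sim <- simulate_bold_run(grid_shape = c(8, 8, 8), n_volumes = 80,
                           coupled_fraction = 0.4, coupling_rho = 0.4,
                           rng_seed = 5)
  sc <- compute_global_connectivity(sim$run, sim$motion, sim$gm_mask,
                                    sim$wm_mask, sim$csf_mask, seeds = "LFC",
                                    subject_id = "s1")
  expect_false(sc$excluded)
  cleaned <- denoise_run(smooth_volumes(sim$run, 8), sim$motion,
                         sim$wm_mask, sim$csf_mask)
  cm <- build_censor_mask(compute_framewise_displacement(sim$motion))
  spec <- seed_specs()[1, ]
  roi <- make_sphere_roi(c(spec$x, spec$y, spec$z), spec$radius,
                         sim$run$affine, dim(sim$gm_mask))
  expect_equal(sc$score,
               oracle_score(cleaned, roi, sim$gm_mask, cm$retained),
               tolerance = 1e-10)

  # a very spiky run is refused with NA scores, not an error
  sim2 <- simulate_bold_run(grid_shape = c(8, 8, 8), n_volumes = 60,
                            motion_spike_prob = 0.5, rng_seed = 2)
  sc2 <- compute_global_connectivity(sim2$run, sim2$motion, sim2$gm_mask,
                                     sim2$wm_mask, sim2$csf_mask,
                                     seeds = c("LFC", "RFC"))
  expect_true(all(sc2$excluded))
  expect_true(all(is.na(sc2$score)))
  expect_equal(nrow(sc2), 2)
})
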