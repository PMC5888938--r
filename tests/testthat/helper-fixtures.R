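# Shared fixtures: tiny in-memory runs and quiet fitting wrappers.

# A minimal cleaned time x voxel matrix plus masks on a small grid, with a
# known seed signal. Used to exercise global_connectivity directly,
# bypassing the denoising chain.
make_toy_cleaned <- function(grid = c(5, 5, 5), nt = 60, seed = 1) {
  set.seed(seed)
  nvox <- prod(grid)
  M <- matrix(rnorm(nt * nvox), nt, nvox)
  seed_mask <- array(FALSE, grid)
  seed_mask[2:3, 2:3, 2:3] <- TRUE
  gm <- array(TRUE, grid)
  list(M = M, seed_mask = seed_mask, gm = gm, grid = grid, nt = nt)
}

# Brute-force per-voxel connectivity oracle: independent of the package's
# vectorized path.
oracle_score <- function(M, seed_mask, gm, retained = NULL) {
  if (is.null(retained)) retained <- rep(TRUE, nrow(M))
  M <- M[retained, , drop = FALSE]
  sv <- as.vector(seed_mask) & as.vector(gm)
  seed_ts <- rowMeans(M[, sv, drop = FALSE])
  idx <- which(as.vector(gm) & !as.vector(seed_mask))
  zs <- numeric(0)
  for (j in idx) {
    r <- suppressWarnings(stats::cor(seed_ts, M[, j]))
    if (is.na(r)) r <- 0
    r <- min(max(r, -(1 - 1e-7)), 1 - 1e-7)
    if (r > 0) zs <- c(zs, atanh(r))
  }
  if (length(zs)) mean(zs) else 0
}

quiet_reserve <- function(...) suppressWarnings(fit_reserve_interaction(...))
quiet_poly <- function(...) suppressWarnings(select_polynomial_model(...))
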