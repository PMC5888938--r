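# Global hub-connectivity scoring: the mean positive Fisher-z Pearson
# correlation between a seed sphere and every other grey-matter voxel
# (a weighted degree-centrality measure).

FISHER_CLIP <- 1 - 1e-7

#' Global connectivity score of a seed region
#'
#' Drops censored volumes, extracts the mean time series over the seed
#' voxels (restricted to grey matter), correlates it with every grey-matter
#' voxel outside the seed, Fisher z-transforms the correlations (clipped to
#' +/- (1 - 1e-7) before `atanh`), and averages the z values over voxels
#' with r > 0. Voxels with r <= 0 enter neither numerator nor denominator;
#' if no voxel has r > 0 the score is 0 and a warning flag is set.
#'
#' @param cleaned Time x voxel matrix from [denoise_run()] (grid voxels in
#'   array order).
#' @param seed_mask Logical 3D array marking the seed sphere.
#' @param gm_mask Logical 3D array (or [build_group_gm_mask()] result)
#'   marking grey matter.
#' @param censor A [build_censor_mask()] result (its `excluded` flag must be
#'   `FALSE`); `NULL` means all volumes retained.
#' @param subject_id,seed_name Identifiers copied into the result.
#' @return One-row data frame of class `"connectivity_result"`: `subject_id`,
#'   `seed`, `score`, `n_positive_voxels`, `n_gm_voxels`,
#'   `censored_fraction`, `excluded`.
#' @export
global_connectivity <- function(cleaned, seed_mask, gm_mask, censor = NULL,
                                subject_id = "subject", seed_name = "LFC") {
  gm <- as.vector(.as_mask_array(gm_mask))
  seed <- as.vector(.as_mask_array(seed_mask))
  if (length(gm) != ncol(cleaned) || length(seed) != ncol(cleaned))
    stop("mask length does not match the number of voxel columns")

  if (is.null(censor)) {
    retained <- rep(TRUE, nrow(cleaned))
    frac <- 0
  } else {
    stopifnot(inherits(censor, "censor_mask"))
    if (censor$excluded)
      stop("subject '", subject_id, "' is excluded by QC (",
           sprintf("%.1f%%", 100 * censor$censored_fraction),
           " of volumes censored); refusing to compute a score")
    if (length(censor$retained) != nrow(cleaned))
      stop("censor mask length does not match the number of volumes")
    retained <- censor$retained
    frac <- censor$censored_fraction
  }
  if (sum(retained) < 10L)
    stop("fewer than 10 retained volumes; cannot estimate connectivity")

  M <- cleaned[retained, , drop = FALSE]
  seed_vox <- seed & gm
  if (!any(seed_vox)) stop("seed contains no grey-matter voxels")
  seed_ts <- rowMeans(M[, seed_vox, drop = FALSE])
  if (stats::sd(seed_ts) < 1e-12)
    stop("seed time series has zero variance")

  target <- gm & !seed
  n_gm <- sum(target)
  if (n_gm == 0L) stop("no grey-matter voxels outside the seed")

  Tm <- M[, target, drop = FALSE]
  sd_t <- apply(Tm, 2L, stats::sd)
  r <- rep(0, n_gm)
  ok <- sd_t > 1e-12
  if (any(ok)) r[ok] <- as.vector(stats::cor(seed_ts, Tm[, ok, drop = FALSE]))
  r <- pmin(pmax(r, -FISHER_CLIP), FISHER_CLIP)

  pos <- r > 0
  if (any(pos)) {
    score <- mean(atanh(r[pos]))
  } else {
    warning("no positive correlations for subject '", subject_id,
            "', seed ", seed_name, "; score set to 0")
    score <- 0
  }
  structure(data.frame(subject_id = subject_id, seed = seed_name,
                       score = score, n_positive_voxels = sum(pos),
                       n_gm_voxels = n_gm, censored_fraction = frac,
                       excluded = FALSE, stringsAsFactors = FALSE),
            class = c("connectivity_result", "data.frame"))
}

#' Full per-subject connectivity pipeline
#'
#' Runs the preprocessing chain on one subject: spatial smoothing,
#' denoising (detrend, band-pass, motion + WM/CSF regression), framewise
#' displacement scrubbing, then the global connectivity score for each
#' requested seed. An excluded subject (>`exclusion_fraction` censored)
#' yields rows with `NA` scores and `excluded = TRUE`.
#'
#' @param run A [bold_run()].
#' @param motion 6-column motion trace (one row per volume).
#' @param gm_mask,wm_mask,csf_mask Logical 3D arrays on the run grid.
#' @param seeds Seed names among `"LFC"`, `"RFC"`, `"OCC"`, `"M1"`, or
#'   `"all"`.
#' @param subject_id Identifier copied into the result.
#' @param fwhm_mm Smoothing kernel FWHM (default 8 mm; 0 disables).
#' @param band_hz Band-pass edges in Hz (default `c(0.01, 0.08)`).
#' @param fd_threshold_mm,n_pre,n_post,exclusion_fraction Scrubbing
#'   parameters (defaults 0.5 mm, 1, 2, 0.30).
#' @param fd_sphere_radius_mm Rotation-to-mm conversion radius (default 50).
#' @return Data frame with one [global_connectivity()] row per seed.
#' @export
compute_global_connectivity <- function(run, motion, gm_mask, wm_mask, csf_mask,
                                        seeds = "all", subject_id = "subject",
                                        fwhm_mm = 8, band_hz = c(0.01, 0.08),
                                        fd_threshold_mm = 0.5, n_pre = 1, n_post = 2,
                                        exclusion_fraction = 0.30,
                                        fd_sphere_radius_mm = 50) {
  stopifnot(inherits(run, "bold_run"))
  specs <- seed_specs()
  if (identical(seeds, "all")) seeds <- specs$name
  bad <- setdiff(seeds, specs$name)
  if (length(bad)) stop("unknown seed(s): ", paste(bad, collapse = ", "))

  fd <- compute_framewise_displacement(motion, fd_sphere_radius_mm,
                                       n_volumes = dim(run$data)[4])
  censor <- build_censor_mask(fd, fd_threshold_mm, n_pre, n_post,
                              exclusion_fraction)
  if (censor$excluded) {
    return(data.frame(subject_id = subject_id, seed = seeds, score = NA_real_,
                      n_positive_voxels = NA_integer_, n_gm_voxels = NA_integer_,
                      censored_fraction = censor$censored_fraction,
                      excluded = TRUE, stringsAsFactors = FALSE))
  }

  sm <- smooth_volumes(run, fwhm_mm)
  cleaned <- denoise_run(sm, motion, wm_mask, csf_mask, band_hz)
  sp <- dim(run$data)[1:3]
  out <- lapply(seeds, function(s) {
    spec <- specs[specs$name == s, ]
    roi <- make_sphere_roi(c(spec$x, spec$y, spec$z), spec$radius,
                           run$affine, sp, name = s)
    global_connectivity(cleaned, roi, gm_mask, censor,
                        subject_id = subject_id, seed_name = s)
  })
  do.call(rbind, out)
}

#' Write per-subject connectivity scores as TSV
#'
#' @param scores Data frame of [global_connectivity()] rows.
#' @param path Output path (written atomically).
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  .write_tsv_atomic(as.data.frame(scores), path)
}
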