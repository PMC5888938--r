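# Seedable synthetic data: BOLD-like runs with planted seed-coupled voxels
# and motion spikes, and DIAN-like / DELCODE-like cohort tables with planted
# moderation effects, group effect sizes, sigmoid biomarker trajectories
# over disease time, and an education-connectivity correlation. Generators
# are pure functions of their parameters including the RNG seed.

# Unit-variance band-limited (0.01-0.08 Hz) signal.
.bl_signal <- function(n, tr, ncol = 1L) {
  v <- bandpass_butterworth(matrix(stats::rnorm(n * ncol), n, ncol), tr)
  sweep(v, 2L, apply(v, 2L, stats::sd), "/")
}

#' Simulate a BOLD run with planted connectivity structure
#'
#' Builds a 4D run in which the seed-sphere voxels share a band-limited
#' latent signal `s`, a `coupled_fraction` of the remaining grey-matter
#' voxels equals `rho * s + sqrt(1 - rho^2) * noise` (band-limited noise, so
#' the population correlation with the seed survives the pipeline's
#' band-pass), and all other voxels are independent noise. White-matter and
#' CSF corner blocks carry their own shared nuisance signals which also leak
#' (amplitude 0.2) into grey matter, a linear scanner drift is added
#' everywhere, and the motion trace is a slow random walk with Bernoulli
#' displacement spikes.
#'
#' @param grid_shape Length-3 voxel grid (default `c(12, 12, 12)`).
#' @param voxel_size_mm Isotropic voxel size (default 3 mm).
#' @param n_volumes Number of volumes (default 140, the ADAD protocol).
#' @param tr Repetition time in seconds (default 2.23).
#' @param seed_name Which seed sphere to plant (default `"LFC"`); the affine
#'   is chosen so the seed centre falls on the grid centre voxel.
#' @param coupled_fraction Fraction of grey-matter voxels coupled to the
#'   seed (in `[0, 1]`).
#' @param coupling_rho Target population Pearson r of coupled voxels
#'   (`|rho| < 1`).
#' @param noise_sd Amplitude of the voxel signals (Pearson r is scale
#'   invariant; this only sets the raw units).
#' @param motion_spike_prob Per-volume probability of a displacement spike.
#' @param spike_magnitude_mm Size of a spike (default 1 mm, i.e. above the
#'   0.5 mm scrubbing cutoff).
#' @param rng_seed Integer seed; identical seeds give identical output.
#' @return List with `run` (a [bold_run()]), `motion` (n x 6 matrix),
#'   `gm_mask`, `wm_mask`, `csf_mask`, `seed_mask`, and `params`.
#' @export
simulate_bold_run <- function(grid_shape = c(12, 12, 12), voxel_size_mm = 3,
                              n_volumes = 140, tr = 2.23, seed_name = "LFC",
                              coupled_fraction = 0.3, coupling_rho = 0.3,
                              noise_sd = 1, motion_spike_prob = 0.02,
                              spike_magnitude_mm = 1, rng_seed = 1) {
  stopifnot(coupled_fraction >= 0, coupled_fraction <= 1,
            abs(coupling_rho) < 1, n_volumes >= 20, all(grid_shape >= 4))
  set.seed(rng_seed)

  spec <- seed_specs()
  spec <- spec[spec$name == seed_name, ]
  if (nrow(spec) == 0L) stop("unknown seed name: ", seed_name)
  center <- c(spec$x, spec$y, spec$z)
  affine <- diag(c(rep(voxel_size_mm, 3), 1))
  affine[1:3, 4] <- center - voxel_size_mm * floor(grid_shape / 2)

  seed_mask <- make_sphere_roi(center, spec$radius, affine, grid_shape,
                               name = seed_name)

  wm_mask <- array(FALSE, grid_shape)
  wm_mask[1:2, 1:2, 1:2] <- TRUE
  csf_mask <- array(FALSE, grid_shape)
  csf_mask[(grid_shape[1] - 1):grid_shape[1], 1:2, 1:2] <- TRUE
  if (any(seed_mask & (wm_mask | csf_mask)))
    stop("grid too small: seed sphere overlaps the nuisance blocks")
  gm_mask <- !(wm_mask | csf_mask)

  nvox <- prod(grid_shape)
  nt <- n_volumes
  s <- as.vector(.bl_signal(nt, tr))
  w_sig <- as.vector(.bl_signal(nt, tr))
  c_sig <- as.vector(.bl_signal(nt, tr))

  V <- matrix(0, nt, nvox)
  gm_idx <- which(as.vector(gm_mask) & !as.vector(seed_mask))
  seed_idx <- which(as.vector(seed_mask))
  n_coupled <- round(coupled_fraction * length(gm_idx))
  coupled_idx <- if (n_coupled > 0) sample(gm_idx, n_coupled) else integer(0)
  uncoupled_idx <- setdiff(gm_idx, coupled_idx)

  amp <- stats::runif(length(seed_idx), 0.8, 1.2)
  V[, seed_idx] <- outer(s, amp) + 0.05 * matrix(stats::rnorm(nt * length(seed_idx)),
                                                 nt)
  if (length(coupled_idx)) {
    eps <- .bl_signal(nt, tr, length(coupled_idx))
    V[, coupled_idx] <- noise_sd *
      (coupling_rho * s + sqrt(1 - coupling_rho^2) * eps)
  }
  if (length(uncoupled_idx))
    V[, uncoupled_idx] <- noise_sd * .bl_signal(nt, tr, length(uncoupled_idx))

  wm_idx <- which(as.vector(wm_mask))
  csf_idx <- which(as.vector(csf_mask))
  V[, wm_idx] <- w_sig + 0.1 * matrix(stats::rnorm(nt * length(wm_idx)), nt)
  V[, csf_idx] <- c_sig + 0.1 * matrix(stats::rnorm(nt * length(csf_idx)), nt)
  V[, gm_idx] <- V[, gm_idx] + 0.2 * (w_sig + c_sig)

  V <- V + 100 + 0.02 * seq_len(nt)          # baseline + scanner drift

  trans <- apply(matrix(stats::rnorm(nt * 3, 0, 0.02), nt), 2L, cumsum)
  rot <- apply(matrix(stats::rnorm(nt * 3, 0, 2e-4), nt), 2L, cumsum)
  spikes <- which(stats::runif(nt) < motion_spike_prob)
  spikes <- spikes[spikes > 1L]
  for (sp in spikes) {
    ax <- sample(3L, 1L)
    trans[sp, ax] <- trans[sp, ax] + spike_magnitude_mm
  }
  motion <- cbind(trans, rot)
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")

  # V is time x voxel; rearrange to (x, y, z, t)
  vol4d <- array(t(V), c(grid_shape, nt))
  run <- bold_run(vol4d, tr, affine,
                  run_id = sprintf("sim-%s-%d", seed_name, rng_seed))
  list(run = run, motion = motion, gm_mask = gm_mask, wm_mask = wm_mask,
       csf_mask = csf_mask, seed_mask = seed_mask,
       params = list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                     n_volumes = n_volumes, tr = tr, seed_name = seed_name,
                     coupled_fraction = coupled_fraction,
                     coupling_rho = coupling_rho, noise_sd = noise_sd,
                     motion_spike_prob = motion_spike_prob,
                     spike_magnitude_mm = spike_magnitude_mm,
                     rng_seed = rng_seed))
}

# lognormal parameters matching a target mean and SD
.lnorm_params <- function(m, s) {
  if (!is.finite(m) || m <= 0)
    stop("infeasible distribution target: mean ", m, " must be positive")
  s2 <- log(1 + (s / m)^2)
  list(mu = log(m) - s2 / 2, sigma = sqrt(s2))
}

# exp(mu + sigma * z) for a standardized deviate z: lognormal with the
# target mean/SD, monotone in z.
.lnorm_from_z <- function(z, m, s) {
  p <- .lnorm_params(m, s)
  exp(p$mu + p$sigma * z)
}

.rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# Standardize a vector (returns 0s for degenerate input).
.std <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Within-group biomarker deviate: half trajectory (standardized sigmoid of
# EYO), half independent noise, standardized; NULL eyo means pure noise.
.biomarker_deviate <- function(n, eyo = NULL, mid = 0, scale = 5, lambda = 0.5) {
  eta <- stats::rnorm(n)
  if (is.null(eyo)) return(eta)
  zt <- .std(stats::plogis((eyo - mid) / scale))
  sqrt(lambda) * zt + sqrt(1 - lambda) * eta
}

# Standardized cognition latent: linear moderation model with unit total
# variance. severity/conn are standardized deviates.
.cognition_latent <- function(severity, conn, beta_sev, beta_conn, beta_int,
                              female, site, site_sd = 0.15, gender_beta = 0.1,
                              residual_sd = NULL) {
  n <- length(conn)
  sev <- if (is.null(severity)) rep(0, n) else severity
  b_sev <- if (is.null(severity)) 0 else beta_sev
  b_int <- if (is.null(severity)) 0 else beta_int
  u <- stats::rnorm(length(unique(site)), 0, site_sd)
  names(u) <- unique(site)
  expl <- b_sev^2 + beta_conn^2 + b_int^2 + gender_beta^2 * 0.25 + site_sd^2
  if (is.null(residual_sd)) {
    if (expl >= 0.95)
      stop("infeasible effect sizes: planted variance exceeds the unit total")
    residual_sd <- sqrt(1 - expl)
  }
  b_sev * sev + beta_conn * conn + b_int * sev * conn +
    gender_beta * (female - mean(female)) + u[as.character(site)] +
    stats::rnorm(n, 0, residual_sd)
}

# Map a standardized latent to a bounded raw scale.
.to_raw <- function(latent, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, mean + sd * latent))
}

# group mean implied by a Cohen's d target (RMS convention) against a
# reference group
.mean_from_d <- function(ref_mean, d, sd_grp, sd_ref, direction) {
  ref_mean + direction * d * sqrt((sd_grp^2 + sd_ref^2) / 2)
}

#' Simulate a DIAN-like or DELCODE-like cohort table
#'
#' Generates a per-subject phenotype table with planted structure:
#' \itemize{
#'   \item DIAN mode: mutation carriers (MC) and non-carrier siblings (NC)
#'     with EYO ~ truncated normal (mean -9.8, SD 11, range -30..+15),
#'     families of size 1-3, multi-site assignment, gender ~
#'     Bernoulli(0.55 female).
#'   \item Cognition (MMSE, delayed recall; plus ADAS recall in DELCODE)
#'     generated as a standardized linear model
#'     `beta_sev * severity + beta_conn * connectivity +
#'     interaction_beta * severity * connectivity + gender + site + noise`
#'     with unit total variance, mapped affinely to a bounded raw scale
#'     (main-effect betas follow the published moderation models). In the
#'     control stratum (NC / amyloid-negative) no severity effect is
#'     planted.
#'   \item Biomarkers (CSF tau, p-tau181, PiB; amyloid ratio) as
#'     moment-matched lognormals whose carrier-group means are placed to
#'     hit the `group_effect_d` Cohen's d targets (RMS convention), with a
#'     sigmoid (inflection near symptom onset) EYO trajectory inside the
#'     carrier group.
#'   \item Education correlated with the connectivity latent at
#'     `education_connectivity_r`.
#'   \item DELCODE mode: four diagnostic groups (CN, SCD, MCI, ADD) with
#'     amyloid status derived from a simulated CSF A-beta 42/40 ratio and
#'     the 0.1 cutoff; CSF tau is the severity axis.
#' }
#'
#' @param cohort `"DIAN"` or `"DELCODE"`.
#' @param n_per_group Named group sizes. Defaults: DIAN
#'   `c(MC = 74, NC = 55)`; DELCODE `c(CN = 49, SCD = 40, MCI = 14,
#'   ADD = 13)`.
#' @param interaction_beta Planted standardized severity x connectivity
#'   moderation effect on cognition (default 0.269 in DIAN, 0.285 in
#'   DELCODE, the published values).
#' @param education_connectivity_r Correlation between education and the
#'   connectivity latent (default 0.25).
#' @param group_effect_d Named Cohen's d targets (DIAN mode) for
#'   `csf_tau`, `csf_ptau181`, `pib_suvr`, `conn_lfc`, `mmse`,
#'   `lm_delayed`, `education`; defaults are the published baseline
#'   effect sizes.
#' @param n_sites Number of acquisition sites (default 6 DIAN, 8 DELCODE).
#' @param residual_sd Residual SD of the cognition latent; `NULL` (default)
#'   solves it so the latent has unit variance.
#' @param cognition_trajectory `"linear"` (default; the standardized
#'   moderation model above) or `"sigmoid"` (DIAN only): MMSE follows a
#'   logistic decline over EYO whose midpoint is shifted right by
#'   `conn_shift` years per SD of connectivity -- the reserve mechanism
#'   expressed as a trajectory delay, used to validate difference-curve
#'   recovery.
#' @param trajectory_shape Parameters of the sigmoid cognition mode:
#'   `drop` (MMSE points lost, default 4, placing the standardized group
#'   difference near -2 SD at EYO +10 as in the published trajectory
#'   figures), `mid` (midpoint EYO, 0), `tau` (slope scale in years, 5,
#'   a decade-scale decline), `conn_shift` (midpoint shift per SD of
#'   connectivity, 3), `noise_sd` (raw residual SD, 1).
#' @param rng_seed Integer seed; identical seeds give identical tables.
#' @return Data frame with one row per subject (see the package data
#'   dictionary): identifiers, group labels, amyloid status, EYO, age,
#'   gender, education, family and site ids, scanner model, CSF and PET
#'   biomarkers, hippocampal volume, cognition, and per-seed connectivity
#'   scores `conn_lfc`, `conn_rfc`, `conn_occ`, `conn_m1`.
#' @export
simulate_cohort <- function(cohort = c("DIAN", "DELCODE"), n_per_group = NULL,
                            interaction_beta = NULL,
                            education_connectivity_r = 0.25,
                            group_effect_d = NULL, n_sites = NULL,
                            residual_sd = NULL,
                            cognition_trajectory = c("linear", "sigmoid"),
                            trajectory_shape = NULL, rng_seed = 1) {
  cohort <- match.arg(cohort)
  cognition_trajectory <- match.arg(cognition_trajectory)
  set.seed(rng_seed)
  if (cohort == "DIAN") {
    .simulate_dian(n_per_group, interaction_beta, education_connectivity_r,
                   group_effect_d, n_sites, residual_sd,
                   cognition_trajectory, trajectory_shape)
  } else {
    if (cognition_trajectory == "sigmoid")
      stop("the sigmoid cognition trajectory is only implemented for DIAN")
    .simulate_delcode(n_per_group, interaction_beta,
                      education_connectivity_r, n_sites, residual_sd)
  }
}

#' Generating difference curve of the sigmoid cognition mode
#'
#' The population MMSE difference (carriers minus non-carriers, in raw
#' points) implied by the sigmoid generator at given EYO values, averaged
#' over the connectivity distribution (standard normal latent, or a fixed
#' conditioning value). Serves as the ground-truth curve when validating
#' trajectory-model recovery.
#'
#' @param eyo EYO values (years).
#' @param shape Shape list as in [simulate_cohort()] (`NULL` = defaults).
#' @param conn_z Conditioning value(s) of the connectivity latent;
#'   `NULL` (default) integrates over N(0, 1) by quadrature.
#' @return Numeric vector of raw MMSE differences at `eyo`.
#' @export
sigmoid_generating_curve <- function(eyo, shape = NULL, conn_z = NULL) {
  sh <- .sigmoid_shape(shape)
  if (is.null(conn_z)) {
    gh <- seq(-4, 4, length.out = 81)
    w <- stats::dnorm(gh); w <- w / sum(w)
    vapply(eyo, function(x)
      -sh$drop * sum(w * stats::plogis((x - sh$mid - sh$conn_shift * gh) / sh$tau)),
      0)
  } else {
    -sh$drop * stats::plogis((eyo - sh$mid - sh$conn_shift * mean(conn_z)) / sh$tau)
  }
}

.sigmoid_shape <- function(shape) {
  sh <- list(drop = 4, mid = 0, tau = 5, conn_shift = 3, noise_sd = 1)
  if (!is.null(shape)) sh[names(shape)] <- shape
  sh
}

.simulate_dian <- function(n_per_group, interaction_beta, edu_r,
                           group_effect_d, n_sites, residual_sd,
                           cognition_trajectory = "linear",
                           trajectory_shape = NULL) {
  if (is.null(n_per_group)) n_per_group <- c(MC = 74, NC = 55)
  if (is.null(interaction_beta)) interaction_beta <- 0.269
  if (is.null(n_sites)) n_sites <- 6
  stopifnot(all(n_per_group >= 2), n_sites >= 1)
  d_default <- c(csf_tau = 0.84, csf_ptau181 = 1.19, pib_suvr = 1.22,
                 conn_lfc = 0.43, mmse = 0.66, lm_delayed = 0.77,
                 education = 0.38)
  d <- d_default
  if (!is.null(group_effect_d)) d[names(group_effect_d)] <- group_effect_d

  n_mc <- n_per_group[["MC"]]; n_nc <- n_per_group[["NC"]]
  n <- n_mc + n_nc
  group <- c(rep("MC", n_mc), rep("NC", n_nc))
  is_mc <- group == "MC"

  # families of size 1-3 spanning both groups (sibling structure)
  fam_sizes <- integer(0)
  while (sum(fam_sizes) < n)
    fam_sizes <- c(fam_sizes, sample(1:3, 1L, prob = c(0.3, 0.45, 0.25)))
  family_id <- paste0("F", rep(seq_along(fam_sizes), fam_sizes)[seq_len(n)])
  family_id <- sample(family_id)             # decouple family from group order

  site_id <- paste0("site", sample(n_sites, n, replace = TRUE))
  scanners <- c("Verio", "Trio", "Prisma")
  site_scanner <- stats::setNames(scanners[1 + (seq_len(n_sites) - 1) %% 3],
                                  paste0("site", seq_len(n_sites)))
  gender <- ifelse(stats::runif(n) < 0.55, "female", "male")
  female <- as.numeric(gender == "female")

  eyo <- .rtrunc_norm(n, -9.8, 11, -30, 15)
  age <- pmax(20, 37.5 + eyo - mean(eyo) + stats::rnorm(n, 0, 3))

  # connectivity latents: LFC latent reused for education correlation;
  # control seeds share half their variance with it
  zc <- stats::rnorm(n)
  zc_ctrl <- replicate(3, 0.5 * zc + sqrt(0.75) * stats::rnorm(n))

  conn_nc <- c(conn_lfc = 0.30, conn_rfc = 0.28, conn_occ = 0.25, conn_m1 = 0.25)
  conn_sd <- 0.07
  conn <- matrix(NA_real_, n, 4,
                 dimnames = list(NULL, names(conn_nc)))
  conn_mc_mean <- c(.mean_from_d(conn_nc[1], d[["conn_lfc"]], conn_sd, conn_sd, -1),
                    .mean_from_d(conn_nc[2], 0.8 * d[["conn_lfc"]], conn_sd, conn_sd, -1),
                    conn_nc[3], conn_nc[4])  # null seeds: no group effect
  lat <- cbind(zc, zc_ctrl)
  for (j in 1:4) {
    conn[is_mc, j] <- .lnorm_from_z(lat[is_mc, j], conn_mc_mean[j], conn_sd)
    conn[!is_mc, j] <- .lnorm_from_z(lat[!is_mc, j], conn_nc[j], conn_sd)
  }

  edu_lat <- edu_r * zc + sqrt(1 - edu_r^2) * stats::rnorm(n)
  edu_mc_mean <- .mean_from_d(15.51, d[["education"]], 3.2, 2.16, -1)
  education <- numeric(n)
  education[is_mc] <- .to_raw(edu_lat[is_mc], edu_mc_mean, 3.2, 6, 22)
  education[!is_mc] <- .to_raw(edu_lat[!is_mc], 15.51, 2.16, 6, 22)

  # biomarkers: lognormals with sigmoid EYO trajectories inside MC
  bio_ref <- list(csf_tau = c(55.19, 22.2), csf_ptau181 = c(29.77, 9.41),
                  pib_suvr = c(1.04, 0.05))
  bio_sd_mc <- c(csf_tau = 89.48, csf_ptau181 = 35.58, pib_suvr = 1.25)
  bio_mid <- c(csf_tau = -5, csf_ptau181 = -5, pib_suvr = -10)
  bio <- list()
  for (v in names(bio_ref)) {
    m_mc <- .mean_from_d(bio_ref[[v]][1], d[[v]], bio_sd_mc[[v]],
                         bio_ref[[v]][2], +1)
    dev_mc <- .biomarker_deviate(n_mc, eyo[is_mc], mid = bio_mid[[v]])
    dev_nc <- .biomarker_deviate(n_nc)
    out <- numeric(n)
    out[is_mc] <- .lnorm_from_z(dev_mc, m_mc, bio_sd_mc[[v]])
    out[!is_mc] <- .lnorm_from_z(dev_nc, bio_ref[[v]][1], bio_ref[[v]][2])
    bio[[v]] <- out
  }

  abeta <- numeric(n)
  abeta[is_mc] <- pmax(0.01, 0.12 - 0.06 * stats::plogis((eyo[is_mc] + 5) / 4) +
                         stats::rnorm(n_mc, 0, 0.01))
  abeta[!is_mc] <- pmax(0.01, 0.12 + stats::rnorm(n_nc, 0, 0.015))

  hippo <- numeric(n)
  hippo[is_mc] <- 7600 - 900 * stats::plogis(eyo[is_mc] / 5) +
    stats::rnorm(n_mc, 0, 450)
  hippo[!is_mc] <- 7500 + stats::rnorm(n_nc, 0, 450)

  # cognition: moderation model inside MC, null model in NC
  zeyo_mc <- .std(eyo[is_mc])
  zconn_mc <- .std(log(conn[is_mc, "conn_lfc"]))
  zconn_nc <- .std(log(conn[!is_mc, "conn_lfc"]))
  cog_betas <- list(mmse = c(-0.576, 0.216), lm_delayed = c(-0.458, 0.047))
  # bounded-safe raw maps hitting the published d targets (see vignette)
  raw_map <- list(mmse = list(nc = c(27.8, 0.8), sd_mc = 1.5, lim = c(0, 30)),
                  lm_delayed = list(nc = c(13.0, 3.0), sd_mc = 4.0, lim = c(0, 25)))
  cog <- list()
  for (v in names(cog_betas)) {
    b <- cog_betas[[v]]
    lat_mc <- .cognition_latent(zeyo_mc, zconn_mc, b[1], b[2], interaction_beta,
                                female[is_mc], site_id[is_mc],
                                residual_sd = residual_sd)
    lat_nc <- .cognition_latent(NULL, zconn_nc, 0, b[2], 0,
                                female[!is_mc], site_id[!is_mc],
                                residual_sd = residual_sd)
    mp <- raw_map[[v]]
    m_mc <- .mean_from_d(mp$nc[1], d[[v]], mp$sd_mc, mp$nc[2], -1)
    out <- numeric(n)
    out[is_mc] <- .to_raw(lat_mc, m_mc, mp$sd_mc, mp$lim[1], mp$lim[2])
    out[!is_mc] <- .to_raw(lat_nc, mp$nc[1], mp$nc[2], mp$lim[1], mp$lim[2])
    cog[[v]] <- out
  }
  if (cognition_trajectory == "sigmoid") {
    # logistic MMSE decline over EYO, midpoint delayed by conn_shift years
    # per SD of connectivity (reserve as a trajectory shift); non-carriers
    # stay flat
    sh <- .sigmoid_shape(trajectory_shape)
    base <- 29.0
    u <- stats::rnorm(length(unique(site_id)), 0, 0.3)
    names(u) <- unique(site_id)
    mmse_sig <- numeric(n)
    mmse_sig[is_mc] <- base - sh$drop *
      stats::plogis((eyo[is_mc] - sh$mid - sh$conn_shift * zconn_mc) / sh$tau) +
      u[site_id[is_mc]] + stats::rnorm(n_mc, 0, sh$noise_sd)
    mmse_sig[!is_mc] <- base + u[site_id[!is_mc]] + stats::rnorm(n_nc, 0, 0.7)
    cog$mmse <- pmin(30, pmax(0, mmse_sig))
  }

  tab <- data.frame(subject_id = sprintf("DIAN-%03d", seq_len(n)),
                    cohort = "DIAN", group = group,
                    abeta_status = ifelse(abeta < 0.1, "pos", "neg"),
                    eyo = eyo, age = age, gender = gender,
                    education = education, family_id = family_id,
                    site_id = site_id,
                    scanner_model = unname(site_scanner[site_id]),
                    csf_tau = bio$csf_tau, csf_ptau181 = bio$csf_ptau181,
                    csf_abeta_ratio = abeta, pib_suvr = bio$pib_suvr,
                    hippocampal_volume = hippo, mmse = cog$mmse,
                    lm_delayed = cog$lm_delayed, adas_recall = NA_real_,
                    conn_lfc = conn[, "conn_lfc"], conn_rfc = conn[, "conn_rfc"],
                    conn_occ = conn[, "conn_occ"], conn_m1 = conn[, "conn_m1"],
                    stringsAsFactors = FALSE)
  tab
}

.simulate_delcode <- function(n_per_group, interaction_beta, edu_r,
                              n_sites, residual_sd) {
  if (is.null(n_per_group)) n_per_group <- c(CN = 49, SCD = 40, MCI = 14, ADD = 13)
  if (is.null(interaction_beta)) interaction_beta <- 0.285
  if (is.null(n_sites)) n_sites <- 8
  stopifnot(all(n_per_group >= 2), n_sites >= 1)

  groups <- c("CN", "SCD", "MCI", "ADD")
  n_g <- n_per_group[groups]
  n_g[is.na(n_g)] <- 0
  n <- sum(n_g)
  group <- rep(groups, n_g)

  # amyloid-positive fractions per diagnostic group (MCI/ADD all positive)
  p_pos <- c(CN = 25 / 49, SCD = 23 / 40, MCI = 1, ADD = 1)
  pos <- stats::runif(n) < p_pos[group]

  site_id <- paste0("site", sample(n_sites, n, replace = TRUE))
  scanners <- c("Verio", "Trio", "Skyra")
  site_scanner <- stats::setNames(scanners[1 + (seq_len(n_sites) - 1) %% 3],
                                  paste0("site", seq_len(n_sites)))
  gender <- ifelse(stats::runif(n) < 0.55, "female", "male")
  female <- as.numeric(gender == "female")

  age_par <- list(CN = c(67.5, 4.9), SCD = c(71.7, 4.9), MCI = c(74.6, 5.3),
                  ADD = c(71.3, 6.2))
  age <- vapply(seq_len(n), function(i)
    stats::rnorm(1, age_par[[group[i]]][1], age_par[[group[i]]][2]), 0)
  age <- pmax(55, pmin(90, age))

  # CSF amyloid ratio: truncated at the 0.1 cutoff so status is exact
  ratio_pos_par <- list(CN = c(0.08, 0.015), SCD = c(0.08, 0.015),
                        MCI = c(0.06, 0.015), ADD = c(0.04, 0.01))
  abeta <- numeric(n)
  for (i in seq_len(n)) {
    if (pos[i]) {
      p <- ratio_pos_par[[group[i]]]
      abeta[i] <- .rtrunc_norm(1, p[1], p[2], 0.01, 0.0999)
    } else {
      abeta[i] <- .rtrunc_norm(1, 0.12, 0.02, 0.1, 0.2)
    }
  }

  # CSF tau / p-tau: moment-matched lognormals per (group, status)
  tau_par <- list(pos = list(CN = c(357.08, 136.91), SCD = c(395.16, 178.58),
                             MCI = c(534.97, 172.61), ADD = c(818.53, 322.62)),
                  neg = list(CN = c(320.78, 112.02), SCD = c(355.84, 114.32),
                             MCI = c(400, 120), ADD = c(450, 130)))
  ptau_par <- list(pos = list(CN = c(49.08, 17.06), SCD = c(53.96, 25.89),
                              MCI = c(71.99, 21.37), ADD = c(101.6, 45.58)),
                   neg = list(CN = c(51.57, 16.28), SCD = c(50.35, 21.1),
                              MCI = c(55, 18), ADD = c(60, 20)))
  status_key <- ifelse(pos, "pos", "neg")
  ztau <- stats::rnorm(n)
  csf_tau <- vapply(seq_len(n), function(i) {
    p <- tau_par[[status_key[i]]][[group[i]]]
    .lnorm_from_z(ztau[i], p[1], p[2])
  }, 0)
  csf_ptau <- vapply(seq_len(n), function(i) {
    p <- ptau_par[[status_key[i]]][[group[i]]]
    .lnorm_from_z(0.7 * ztau[i] + sqrt(0.51) * stats::rnorm(1), p[1], p[2])
  }, 0)

  conn_par <- list(pos = list(CN = c(0.23, 0.05), SCD = c(0.25, 0.05),
                              MCI = c(0.23, 0.05), ADD = c(0.22, 0.03)),
                   neg = list(CN = c(0.25, 0.06), SCD = c(0.23, 0.04),
                              MCI = c(0.24, 0.05), ADD = c(0.23, 0.05)))
  zc <- stats::rnorm(n)
  zc_ctrl <- replicate(3, 0.5 * zc + sqrt(0.75) * stats::rnorm(n))
  conn <- matrix(NA_real_, n, 4,
                 dimnames = list(NULL, c("conn_lfc", "conn_rfc", "conn_occ",
                                         "conn_m1")))
  lat <- cbind(zc, zc_ctrl)
  ctrl_means <- c(0.26, 0.24, 0.24)
  for (i in seq_len(n)) {
    p <- conn_par[[status_key[i]]][[group[i]]]
    conn[i, 1] <- .lnorm_from_z(lat[i, 1], p[1], p[2])
    for (j in 2:4) conn[i, j] <- .lnorm_from_z(lat[i, j], ctrl_means[j - 1], 0.05)
  }

  education <- .to_raw(edu_r * zc + sqrt(1 - edu_r^2) * stats::rnorm(n),
                       14.6, 3.0, 6, 22)

  hippo_par <- list(CN = c(7400, 500), SCD = c(7300, 500), MCI = c(6800, 550),
                    ADD = c(6300, 600))
  hippo <- vapply(seq_len(n), function(i)
    stats::rnorm(1, hippo_par[[group[i]]][1], hippo_par[[group[i]]][2]), 0)

  # cognition: moderation on z(log tau) inside the amyloid-positive
  # stratum, null model in the negative stratum
  cog_betas <- list(mmse = c(-0.553, 0.159), lm_delayed = c(-0.327, -0.011),
                    adas_recall = c(-0.30, 0.05))
  raw_map <- list(mmse = list(pos = c(26.8, 1.6), neg = c(28.8, 0.6),
                              lim = c(0, 30)),
                  lm_delayed = list(pos = c(11, 4.5), neg = c(14, 4),
                                    lim = c(0, 25)),
                  adas_recall = list(pos = c(5, 2), neg = c(7, 1.5),
                                     lim = c(0, 10)))
  zsev_pos <- .std(log(csf_tau[pos]))
  zconn_pos <- .std(log(conn[pos, "conn_lfc"]))
  zconn_neg <- .std(log(conn[!pos, "conn_lfc"]))
  cog <- list()
  for (v in names(cog_betas)) {
    b <- cog_betas[[v]]
    lat_pos <- .cognition_latent(zsev_pos, zconn_pos, b[1], b[2],
                                 interaction_beta, female[pos], site_id[pos],
                                 residual_sd = residual_sd)
    lat_neg <- .cognition_latent(NULL, zconn_neg, 0, b[2], 0,
                                 female[!pos], site_id[!pos],
                                 residual_sd = residual_sd)
    mp <- raw_map[[v]]
    out <- numeric(n)
    out[pos] <- .to_raw(lat_pos, mp$pos[1], mp$pos[2], mp$lim[1], mp$lim[2])
    out[!pos] <- .to_raw(lat_neg, mp$neg[1], mp$neg[2], mp$lim[1], mp$lim[2])
    cog[[v]] <- out
  }

  data.frame(subject_id = sprintf("DELCODE-%03d", seq_len(n)),
             cohort = "DELCODE", group = group,
             abeta_status = ifelse(abeta < 0.1, "pos", "neg"),
             eyo = NA_real_, age = age, gender = gender,
             education = education,
             family_id = sprintf("F%03d", seq_len(n)),
             site_id = site_id,
             scanner_model = unname(site_scanner[site_id]),
             csf_tau = csf_tau, csf_ptau181 = csf_ptau,
             csf_abeta_ratio = abeta, pib_suvr = NA_real_,
             hippocampal_volume = hippo, mmse = cog$mmse,
             lm_delayed = cog$lm_delayed, adas_recall = cog$adas_recall,
             conn_lfc = conn[, "conn_lfc"], conn_rfc = conn[, "conn_rfc"],
             conn_occ = conn[, "conn_occ"], conn_m1 = conn[, "conn_m1"],
             stringsAsFactors = FALSE)
}
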