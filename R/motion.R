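# Head-motion quantification and volume scrubbing.

#' Framewise displacement from realignment parameters
#'
#' Summarizes head motion between adjacent volumes as the sum of absolute
#' differences of the three translations (mm) plus the sum of absolute
#' differences of the three rotations (radians) converted to arc length on a
#' sphere of radius `sphere_radius_mm`. The first volume has no predecessor
#' and is fixed at 0.
#'
#' @param motion Numeric matrix or data frame with one row per volume and six
#'   columns: `trans_x`, `trans_y`, `trans_z` (mm), `rot_x`, `rot_y`, `rot_z`
#'   (radians). Column order is positional; names are not required.
#' @param sphere_radius_mm Radius used to convert rotations to mm
#'   (default 50, the convention matched to the 0.5 mm scrubbing cutoff).
#' @param n_volumes Optional expected number of volumes (e.g. from the paired
#'   BOLD run); a mismatch is an error.
#' @return Numeric vector of per-volume displacements in mm (`fd[1] = 0`).
#' @examples
#' m <- matrix(0, 10, 6)
#' m[5:10, 1] <- 0.6  # 0.6 mm x-translation step between volumes 4 and 5
#' compute_framewise_displacement(m)
#' @export
compute_framewise_displacement <- function(motion, sphere_radius_mm = 50,
                                           n_volumes = NULL) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop("motion trace must have 6 columns (3 translations, 3 rotations), got ",
         ncol(motion))
  if (nrow(motion) < 2L) stop("motion trace needs at least 2 volumes")
  if (!is.null(n_volumes) && nrow(motion) != n_volumes)
    stop("motion trace has ", nrow(motion), " rows but the run has ",
         n_volumes, " volumes")
  if (any(!is.finite(motion))) stop("motion trace contains non-finite values")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            sphere_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  fd
}

#' Build a volume-censoring (scrubbing) mask from framewise displacement
#'
#' Volumes with displacement strictly above `threshold_mm` are censored
#' together with `n_pre` preceding and `n_post` subsequent volumes
#' (windows are clipped at the run boundaries and overlapping windows are
#' unioned). A subject whose censored fraction strictly exceeds
#' `exclusion_fraction` is flagged for exclusion.
#'
#' @param fd Numeric vector of framewise displacements (mm), `fd[1] = 0`.
#' @param threshold_mm Censoring cutoff (default 0.5 mm, strict `>`).
#' @param n_pre,n_post Volumes censored before/after each supra-threshold
#'   volume (defaults 1 and 2).
#' @param exclusion_fraction Maximum tolerated censored fraction
#'   (default 0.30, strict `>`).
#' @return An object of class `"censor_mask"`: a list with `retained`
#'   (logical per volume), `censored_fraction`, and `excluded`.
#' @examples
#' build_censor_mask(c(0.1, 0.6, 0.1, 0.1, 0.1, 0.1))
#' @export
build_censor_mask <- function(fd, threshold_mm = 0.5, n_pre = 1, n_post = 2,
                              exclusion_fraction = 0.30) {
  if (length(fd) == 0L) stop("fd series is empty")
  if (any(!is.finite(fd)) || any(fd < 0)) stop("fd must be finite and non-negative")
  n <- length(fd)
  spikes <- which(fd > threshold_mm)
  censored <- logical(n)
  for (s in spikes) {
    lo <- max(1L, s - n_pre)
    hi <- min(n, s + n_post)
    censored[lo:hi] <- TRUE
  }
  frac <- mean(censored)
  structure(list(retained = !censored,
                 censored_fraction = frac,
                 excluded = frac > exclusion_fraction),
            class = "censor_mask")
}

#' @export
print.censor_mask <- function(x, ...) {
  n <- length(x$retained)
  cat(sprintf("censor mask: %d/%d volumes retained (%.1f%% censored)%s\n",
              sum(x$retained), n, 100 * x$censored_fraction,
              if (x$excluded) " -- EXCLUDED (>30% censored)" else ""))
  invisible(x)
}

#' Read a 6-column motion trace from TSV
#'
#' Expects columns `trans_x`, `trans_y`, `trans_z` (mm) and `rot_x`, `rot_y`,
#' `rot_z` (radians), one row per volume.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix with the six named columns.
#' @export
read_motion <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  need <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("motion file is missing column(s): ",
                         paste(miss, collapse = ", "))
  as.matrix(tab[, need])
}
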