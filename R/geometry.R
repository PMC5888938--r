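# Seed-sphere and grey-matter-mask geometry. All geometry is computed in
# world millimetres through the image affine (RAS+); voxel indices are
# 0-based internally and never compared across grids.

#' Seed region specifications
#'
#' The four global-connectivity seed regions: the left frontal cortex hub
#' (LFC, Brodmann area 6/44), its right homotope (RFC), and two null regions
#' in the occipital pole (OCC) and primary motor cortex (M1). All are 8 mm
#' radius spheres around fixed MNI coordinates.
#'
#' @return A data frame with columns `name`, `x`, `y`, `z` (MNI mm), `radius`.
#' @export
seed_specs <- function() {
  data.frame(name = c("LFC", "RFC", "OCC", "M1"),
             x = c(-42, 42, -19, -38),
             y = c(6, 6, -102, -22),
             z = c(28, 28, -3, 56),
             radius = 8,
             stringsAsFactors = FALSE)
}

#' Binary sphere region of interest on an image grid
#'
#' A voxel belongs to the sphere iff the Euclidean distance from its
#' world-space centre (via the affine) to `center_mni` is at most `radius`.
#'
#' @param center_mni Length-3 world coordinate of the sphere centre (mm).
#' @param radius Sphere radius in mm (> 0).
#' @param affine 4x4 voxel-to-world matrix of the grid.
#' @param dim Length-3 grid shape.
#' @param name Seed name used in error messages.
#' @return Logical 3D array of the grid shape.
#' @examples
#' aff <- diag(c(2, 2, 2, 1))
#' roi <- make_sphere_roi(c(10, 10, 10), 8, aff, c(11, 11, 11))
#' sum(roi)  # 257 lattice points with i^2+j^2+k^2 <= 16
#' @export
make_sphere_roi <- function(center_mni, radius, affine, dim, name = "seed") {
  stopifnot(length(center_mni) == 3L, length(dim) == 3L)
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  if (abs(det(affine)) < .Machine$double.eps) stop("affine is not invertible")
  ijk <- as.matrix(expand.grid(i = 0:(dim[1] - 1L),
                               j = 0:(dim[2] - 1L),
                               k = 0:(dim[3] - 1L)))
  world <- ijk %*% t(affine[1:3, 1:3]) +
    matrix(affine[1:3, 4], nrow(ijk), 3L, byrow = TRUE)
  d2 <- (world[, 1] - center_mni[1])^2 + (world[, 2] - center_mni[2])^2 +
    (world[, 3] - center_mni[3])^2
  mask <- array(d2 <= radius^2, dim = dim)
  if (!any(mask))
    stop("sphere ROI '", name, "' lies entirely outside the image grid")
  mask
}

#' Group grey-matter mask from probability maps
#'
#' Averages subject grey-matter probability maps voxelwise and binarizes the
#' mean at a strict `> threshold` cutoff.
#'
#' @param gm_probability_maps List of 3D arrays on a common grid, values in
#'   \[0, 1\].
#' @param threshold Probability cutoff (default 0.3; strict inequality, so a
#'   voxel whose mean is exactly 0.3 is excluded).
#' @return A list of class `"gm_mask"` with `mask` (logical 3D array) and
#'   `threshold`.
#' @export
build_group_gm_mask <- function(gm_probability_maps, threshold = 0.3) {
  if (!is.list(gm_probability_maps) || length(gm_probability_maps) == 0L)
    stop("need a non-empty list of grey-matter probability maps")
  dims <- lapply(gm_probability_maps, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("probability maps must be 3D arrays")
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("probability maps have mismatched shapes")
  rng <- range(unlist(lapply(gm_probability_maps, range)))
  if (rng[1] < 0 || rng[2] > 1)
    stop("probability maps must have values in [0, 1]")
  mean_map <- Reduce(`+`, gm_probability_maps) / length(gm_probability_maps)
  mask <- mean_map > threshold
  if (!any(mask)) stop("grey-matter mask is empty at threshold ", threshold)
  structure(list(mask = mask, threshold = threshold), class = "gm_mask")
}

# Accept either a bare logical array or a gm_mask object where a mask is
# expected.
.as_mask_array <- function(mask) {
  if (inherits(mask, "gm_mask")) mask <- mask$mask
  if (is.null(dim(mask)) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  array(as.logical(mask), dim = dim(mask))
}
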