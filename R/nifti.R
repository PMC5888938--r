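# Minimal NIfTI-1 reader/writer.
#
# The installed stack ships no NIfTI package, so the small subset of the
# format this pipeline needs is implemented here: single-file .nii or
# .nii.gz, sform affine (RAS+ world mm), datatypes uint8/int16/int32/
# float32/float64, optional scl_slope/scl_inter scaling. Everything else in
# the 348-byte header is ignored on read and zero-filled on write.

NIFTI_DATATYPES <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L),
  what = c("integer", "integer", "integer", "double", "double"),
  size = c(1L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE)
)

#' Read a NIfTI-1 image
#'
#' Reads a 3D or 4D single-file NIfTI-1 image (`.nii` or `.nii.gz`). The
#' voxel-to-world affine is taken from the sform rows when `sform_code > 0`,
#' otherwise from an axis-aligned affine built from `pixdim`.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list of class `"hub_nifti"` with elements `data` (numeric
#'   array), `affine` (4x4 voxel-to-world matrix, mm), and `tr` (seconds;
#'   `pixdim[4]`, `NA` for 3D images).
#' @seealso [write_nifti()]
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))

  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    if (.swap_int4(sizeof_hdr) != 348L)
      stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  readBin(con, "raw", 36L)                                 # unused fields
  dim8 <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "raw", 14L)                                 # intent fields
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 1L, size = 2L, endian = endian)  # bitpix
  readBin(con, "integer", 1L, size = 2L, endian = endian)  # slice_start
  pixdim <- readBin(con, "numeric", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  # after scl_inter we are at byte offset 120; skip slice_end(2),
  # slice_code(1), xyzt_units(1), cal_max(4), cal_min(4),
  # slice_duration(4), toffset(4), glmax(4), glmin(4) -> offset 148,
  # then descrip(80) and aux_file(24) -> offset 252
  readBin(con, "raw", 28L + 80L + 24L)
  qform_code <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  sform_code <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "numeric", 6L, size = 4L, endian = endian)  # quaternion
  srow <- matrix(readBin(con, "numeric", 12L, size = 4L, endian = endian),
                 nrow = 3L, byrow = TRUE)
  readBin(con, "raw", 16L)
  magic <- rawToChar(readBin(con, "raw", 3L))
  readBin(con, "raw", 1L)
  if (magic != "n+1") stop("unsupported NIfTI magic '", magic, "' in ", path)

  ndim <- dim8[1L]
  if (ndim < 3L || ndim > 4L) stop("expected a 3D or 4D image, got ", ndim, "D: ", path)
  shape <- dim8[2L:(1L + ndim)]
  dt <- NIFTI_DATATYPES[NIFTI_DATATYPES$code == datatype, ]
  if (nrow(dt) == 0L) stop("unsupported NIfTI datatype code ", datatype, " in ", path)

  skip <- vox_offset - 352
  if (skip > 0) readBin(con, "raw", as.integer(skip))
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed, endian = endian)
  if (length(vals) != n) stop("truncated NIfTI data in ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter

  affine <- diag(4)
  if (sform_code > 0L) {
    affine[1:3, ] <- srow
  } else {
    diag(affine)[1:3] <- pixdim[2:4]
  }
  structure(list(data = array(as.double(vals), dim = shape),
                 affine = affine,
                 tr = if (ndim == 4L) pixdim[5L] else NA_real_),
            class = "hub_nifti")
}

#' Write a NIfTI-1 image
#'
#' Writes a 3D or 4D numeric array as a single-file NIfTI-1 image with the
#' given voxel-to-world affine stored in the sform (and matching pixdim).
#' The write is atomic (temp file + rename). Data are stored as float32
#' unless `datatype = "float64"`.
#'
#' @param data Numeric 3D or 4D array.
#' @param affine 4x4 voxel-to-world matrix (mm, RAS+).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param tr Repetition time in seconds (stored in `pixdim[4]`); required
#'   for 4D images.
#' @param datatype `"float32"` (default) or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, affine, path, tr = NA_real_, datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  nd <- length(dim(data))
  if (nd < 3L || nd > 4L) stop("data must be a 3D or 4D array")
  if (nd == 4L && (is.na(tr) || tr <= 0)) stop("a positive tr is required for 4D images")
  if (!is.matrix(affine) || any(dim(affine) != 4L)) stop("affine must be a 4x4 matrix")

  shape <- dim(data)
  dim8 <- integer(8L)
  dim8[1L] <- nd
  dim8[2L:(1L + nd)] <- shape
  dim8[(2L + nd):8L] <- 1L
  voxsize <- sqrt(colSums(affine[1:3, 1:3]^2))
  pixdim <- c(1, voxsize, if (nd == 4L) tr else 0, 0, 0, 0)

  dtcode <- if (datatype == "float32") 16L else 64L
  dtsize <- if (datatype == "float32") 4L else 8L

  tmp <- paste0(path, ".tmp", Sys.getpid())
  con <- if (grepl("\\.gz$", path)) gzfile(tmp, "wb") else file(tmp, "wb")
  ok <- FALSE
  on.exit({
    close(con)
    if (ok) file.rename(tmp, path) else unlink(tmp)
  })

  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  wi(348L, 4L); wraw(36L)
  wi(dim8, 2L); wraw(14L)
  wi(dtcode, 2L); wi(8L * dtsize, 2L); wi(0L, 2L)
  wf(pixdim)
  wf(352); wf(1); wf(0)                     # vox_offset, scl_slope, scl_inter
  wi(0L, 2L); wraw(1L)                      # slice_end, slice_code
  writeBin(as.raw(10L), con)                # xyzt_units: mm | sec
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4L)     # cal/slice_duration/toffset/glmax/glmin
  wraw(80L + 24L)                           # descrip, aux_file
  wi(0L, 2L); wi(1L, 2L)                    # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))                   # quaternion
  wf(t(affine[1:3, ]))                      # srow_x, srow_y, srow_z
  wraw(16L)
  writeChar("n+1", con, nchars = 3L, eos = NULL); wraw(1L)
  writeBin(as.double(data), con, size = dtsize, endian = "little")
  ok <- TRUE
  invisible(path)
}

.swap_int4 <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4L)
  readBin(rev(b), "integer", 1L, size = 4L)
}
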