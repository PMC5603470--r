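# Minimal NIfTI-1 reader/writer (single-file .nii, optionally gzipped).
# No NIfTI package ships with this environment, so the 348-byte header is
# handled directly. Geometry is carried in the sform (srow_x/y/z), which
# round-trips origin, spacing and direction losslessly.
#
# NIfTI uses RAS+ world axes whereas DICOM is LPS+; this package keeps one
# internal convention (the image's own origin/direction as read) and does
# not re-orient — write_nifti stores exactly what the suv_image holds.

.nifti_dtypes <- list(uint8 = list(code = 2L, bitpix = 8L, what = "integer",
                                   size = 1L, signed = FALSE),
                      int16 = list(code = 4L, bitpix = 16L, what = "integer",
                                   size = 2L, signed = TRUE),
                      int32 = list(code = 8L, bitpix = 32L, what = "integer",
                                   size = 4L, signed = TRUE),
                      float32 = list(code = 16L, bitpix = 32L, what = "double",
                                     size = 4L, signed = TRUE),
                      float64 = list(code = 64L, bitpix = 64L, what = "double",
                                     size = 8L, signed = TRUE))

#' Write a volume as NIfTI-1
#'
#' @param x A `suv_image` or `seg_mask`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param datatype `"float64"` (lossless, default for images), `"float32"`,
#'   or `"uint8"` (default for masks).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path,
                        datatype = if (inherits(x, "seg_mask")) "uint8"
                                   else "float64") {
  dt <- .nifti_dtypes[[match.arg(datatype, names(.nifti_dtypes))]]
  arr <- if (inherits(x, "seg_mask")) x$mask * 1L else x$data
  d <- dim(arr)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "little")
  wf <- function(v, size = 4) writeBin(as.double(v), con, size = size,
                                       endian = "little")
  wi(348L, 4)                              # sizeof_hdr
  writeBin(raw(36), con)                   # data_type..dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)          # dim[8]
  wf(rep(0, 3))                            # intent_p1..p3
  wi(0L, 2)                                # intent_code
  wi(dt$code, 2); wi(dt$bitpix, 2)         # datatype, bitpix
  wi(0L, 2)                                # slice_start
  wf(c(1, x$spacing, rep(0, 4)))           # pixdim[8] (qfac=1)
  wf(352)                                  # vox_offset
  wf(c(1, 0))                              # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con)         # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                           # cal_max, cal_min, slice_duration
  wf(0)                                    # toffset
  wi(c(0L, 0L), 4)                         # glmax, glmin
  writeBin(raw(80 + 24), con)              # descrip, aux_file
  wi(0L, 2); wi(1L, 2)                     # qform_code=0, sform_code=1
  wf(rep(0, 6))                            # quatern b,c,d + qoffset x,y,z
  A <- x$direction %*% diag(x$spacing)
  wf(c(A[1, ], x$origin[1]))               # srow_x
  wf(c(A[2, ], x$origin[2]))               # srow_y
  wf(c(A[3, ], x$origin[3]))               # srow_z
  writeBin(charToRaw(sprintf("%-16s", "")), con)  # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)      # magic
  writeBin(raw(4), con)                           # extension flag
  if (dt$what == "integer")
    wi(as.vector(arr), dt$size)
  else
    wf(as.vector(arr), dt$size)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports the subset this package writes plus common scanner exports:
#' single-file little- or big-endian NIfTI-1, datatypes uint8/int16/int32/
#' float32/float64, with scl_slope/scl_inter applied. Geometry is taken
#' from the sform when present, else from pixdim with identity direction.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param as_mask Return a `seg_mask` (nonzero voxels) instead of a
#'   `suv_image`.
#' @return A `suv_image` (or `seg_mask`).
#' @export
read_nifti <- function(path, as_mask = FALSE) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("not a NIfTI-1 file (short header): ", path)
  rd <- function(off, what, n, size, endian)
    readBin(hdr[(off + 1):length(hdr)], what, n = n, size = size,
            endian = endian)
  endian <- "little"
  if (rd(0, "integer", 1, 4, endian) != 348L) {
    endian <- "big"
    if (rd(0, "integer", 1, 4, endian) != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  dims <- rd(40, "integer", 8, 2, endian)
  if (dims[1] < 3 || any(dims[5:8] > 1))
    stop("non-3-D NIfTI input (dim = ",
         paste(dims[2:(max(dims[1], 3) + 1)], collapse = "x"), "): ", path)
  d <- dims[2:4]
  code <- rd(70, "integer", 1, 2, endian)
  dt <- Filter(function(z) z$code == code, .nifti_dtypes)
  if (!length(dt)) stop("unsupported NIfTI datatype code ", code)
  dt <- dt[[1]]
  pixdim <- rd(76, "double", 8, 4, endian)
  vox_offset <- rd(108, "double", 1, 4, endian)
  slope <- rd(112, "double", 1, 4, endian)
  inter <- rd(116, "double", 1, 4, endian)
  sform <- rd(254, "integer", 1, 2, endian)
  srow <- matrix(rd(280, "double", 12, 4, endian), 3, 4, byrow = TRUE)
  # skip to voxel data
  readBin(con, "raw", vox_offset - 348)
  n <- prod(d)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(vals) < n) stop("truncated NIfTI voxel data: ", path)
  if (slope != 0 && !(slope == 1 && inter == 0)) vals <- vals * slope + inter
  arr <- array(as.double(vals), d)
  if (sform > 0) {
    spacing <- sqrt(colSums(srow[, 1:3]^2))
    direction <- srow[, 1:3] %*% diag(1 / spacing)
    origin <- srow[, 4]
  } else {
    spacing <- abs(pixdim[2:4])
    spacing[spacing == 0] <- 1
    direction <- diag(3)
    origin <- c(0, 0, 0)
  }
  img <- suv_image(arr, spacing, origin, direction,
                   provenance = list(source = "nifti", path = path))
  if (as_mask) seg_mask(arr != 0, img, method = "nifti-mask") else img
}
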