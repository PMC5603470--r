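#' Ellipsoidal volume of interest (VOI)
#'
#' The VOI mimics the single ellipsoid a reader draws around the primary
#' tumor on the PET image: every segmentation method operates only on
#' voxels inside it. Specified in world millimetres so the same VOI applies
#' across resampled grids.
#'
#' @param center World-mm center, length 3.
#' @param semiaxes Semi-axis lengths in mm, length 3, all > 0.
#' @param angles Optional Euler angles in degrees, ZYX order (yaw, pitch,
#'   roll), rotating the ellipsoid axes; default no rotation.
#' @return Object of class `ellipsoid_voi` with fields `center`, `semiaxes`,
#'   `rotation` (3x3) and `volume_cm3` (analytic `(4/3)*pi*a*b*c`).
#' @examples
#' v <- ellipsoid_voi(center = c(0, 0, 0), semiaxes = c(25, 25, 25))
#' v$volume_cm3
#' @export
ellipsoid_voi <- function(center, semiaxes, angles = c(0, 0, 0)) {
  center <- as.numeric(center); semiaxes <- as.numeric(semiaxes)
  if (length(center) != 3L) stop("`center` must be length 3 (mm)")
  if (length(semiaxes) != 3L || any(!is.finite(semiaxes)) ||
      any(semiaxes <= 0))
    stop("`semiaxes` must be 3 positive values (mm)")
  structure(list(center = center, semiaxes = semiaxes,
                 rotation = euler_zyx(angles), angles = as.numeric(angles),
                 volume_cm3 = 4 / 3 * pi * prod(semiaxes) / 1000),
            class = "ellipsoid_voi")
}

# ZYX intrinsic Euler rotation, degrees
euler_zyx <- function(angles) {
  a <- as.numeric(angles) * pi / 180
  if (length(a) != 3L) stop("`angles` must be length 3 (degrees, ZYX)")
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

#' @export
print.ellipsoid_voi <- function(x, ...) {
  cat(sprintf("<ellipsoid_voi> center (%s) mm, semiaxes (%s) mm, %.4g cm^3\n",
              paste(signif(x$center, 4), collapse = ", "),
              paste(signif(x$semiaxes, 4), collapse = ", "), x$volume_cm3))
  invisible(x)
}

#' Rasterize an ellipsoidal VOI onto an image grid
#'
#' A voxel belongs to the VOI iff its center satisfies the ellipsoid
#' inequality (the same center-in-region rule used for contour
#' rasterization). Errors when the VOI misses the grid entirely, mirroring
#' the situation where a usable VOI cannot be drawn.
#'
#' @param voi An `ellipsoid_voi`.
#' @param image `suv_image` supplying the grid.
#' @return A `seg_mask` labeled `"voi"`.
#' @export
voi_to_mask <- function(voi, image) {
  d <- dim(image$data)
  g <- as.matrix(expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
                             k = seq_len(d[3]) - 1))
  pts <- index_to_world(image, g)
  rel <- sweep(pts, 2, voi$center) %*% voi$rotation  # into ellipsoid frame
  q <- (rel[, 1] / voi$semiaxes[1])^2 + (rel[, 2] / voi$semiaxes[2])^2 +
       (rel[, 3] / voi$semiaxes[3])^2
  inside <- array(q <= 1, d)
  if (!any(inside))
    stop("VOI does not intersect the image grid: cannot draw a usable VOI")
  seg_mask(inside, image, method = "voi",
           params = list(center = voi$center, semiaxes = voi$semiaxes,
                         angles = voi$angles))
}

#' Read / write a VOI specification as JSON
#'
#' JSON keys: `center`, `semiaxes`, optional `angles` (Euler degrees, ZYX).
#'
#' @param path File path.
#' @return `read_voi_json` returns an `ellipsoid_voi`.
#' @export
read_voi_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ellipsoid_voi(x$center, x$semiaxes,
                if (is.null(x$angles)) c(0, 0, 0) else x$angles)
}

#' @rdname read_voi_json
#' @param voi An `ellipsoid_voi` to serialize.
#' @export
write_voi_json <- function(voi, path) {
  jsonlite::write_json(list(center = voi$center, semiaxes = voi$semiaxes,
                            angles = voi$angles),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
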