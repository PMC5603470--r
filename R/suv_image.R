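#' SUV image container
#'
#' A 3-D scalar PET volume in standardized uptake value (SUV) units together
#' with its voxel geometry. SUV is unitless (tissue activity concentration
#' normalized by injected dose per body weight); the geometry follows the
#' DICOM patient coordinate convention: world position of voxel index
#' `(i, j, k)` (0-based) is `origin + direction %*% (spacing * c(i, j, k))`.
#'
#' @param data 3-D numeric array of SUV values; all finite and >= 0.
#' @param spacing Voxel spacing in mm, positive length-3 vector.
#' @param origin World coordinates (mm) of the center of voxel (0,0,0).
#' @param direction 3x3 direction-cosine matrix (orthonormal columns).
#' @param provenance Free-form list recording source format and SUV
#'   conversion inputs; kept through I/O round trips.
#' @return An object of class `suv_image`.
#' @examples
#' img <- suv_image(array(1, c(4, 4, 4)), spacing = c(2, 2, 2))
#' voxel_volume_cm3(img)
#' @export
suv_image <- function(data, spacing, origin = c(0, 0, 0),
                      direction = diag(3), provenance = list()) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array, got ", length(dim(data)), " dims")
  storage.mode(data) <- "double"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)")
  if (any(!is.finite(data)) || any(data < 0))
    stop("SUV values must be finite and >= 0")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must be length 3 (mm)")
  direction <- matrix(as.numeric(direction), 3, 3)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("`direction` must have orthonormal columns")
  structure(list(data = data, spacing = spacing, origin = origin,
                 direction = direction, provenance = provenance),
            class = "suv_image")
}

#' @export
print.suv_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<suv_image> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  SUV range [%.4g, %.4g], voxel volume %.4g cm^3\n",
              min(x$data), max(x$data), voxel_volume_cm3(x)))
  invisible(x)
}

#' Voxel volume in cubic centimetres
#'
#' @param image A `suv_image` (or `seg_mask`).
#' @return Volume of one voxel in cm^3: `prod(spacing)/1000`.
#' @export
voxel_volume_cm3 <- function(image) {
  prod(image$spacing) / 1000
}

#' @rdname suv_image
#' @param x Object to test.
#' @export
is_suv_image <- function(x) inherits(x, "suv_image")

# world (mm) -> continuous 0-based voxel index; pts is n x 3
world_to_index <- function(image, pts) {
  pts <- matrix(pts, ncol = 3)
  rel <- sweep(pts, 2, image$origin) %*% image$direction  # = t(D) %*% (p - o)
  sweep(rel, 2, image$spacing, "/")
}

# continuous 0-based voxel index -> world (mm)
index_to_world <- function(image, idx) {
  idx <- matrix(idx, ncol = 3)
  sweep(idx, 2, image$spacing, "*") %*% t(image$direction) +
    matrix(image$origin, nrow(idx), 3, byrow = TRUE)
}

# world coordinates of all voxel centers along each axis (identity-direction
# fast path used by rasterizers); returns list(x=, y=, z=) only when the
# direction matrix is axis-aligned, else NULL.
axis_aligned_centers <- function(image) {
  if (max(abs(image$direction - diag(3))) > 1e-9) return(NULL)
  d <- dim(image$data)
  list(x = image$origin[1] + image$spacing[1] * (seq_len(d[1]) - 1),
       y = image$origin[2] + image$spacing[2] * (seq_len(d[2]) - 1),
       z = image$origin[3] + image$spacing[3] * (seq_len(d[3]) - 1))
}

# trilinear interpolation at continuous 0-based indices (n x 3 matrix);
# outside the grid -> `outside` value
interp_trilinear <- function(arr, idx, outside = NA_real_) {
  d <- dim(arr)
  idx <- matrix(idx, ncol = 3)
  i0 <- floor(idx)
  f <- idx - i0
  out <- rep(outside, nrow(idx))
  ok <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
        idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
        idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]; f <- f[ok, , drop = FALSE]
  i1 <- pmin(i0 + 1, matrix(d - 1, nrow(i0), 3, byrow = TRUE))
  at <- function(ix, iy, iz) arr[cbind(ix + 1, iy + 1, iz + 1)]
  v <- at(i0[,1], i0[,2], i0[,3]) * (1-f[,1])*(1-f[,2])*(1-f[,3]) +
       at(i1[,1], i0[,2], i0[,3]) *    f[,1] *(1-f[,2])*(1-f[,3]) +
       at(i0[,1], i1[,2], i0[,3]) * (1-f[,1])*   f[,2] *(1-f[,3]) +
       at(i1[,1], i1[,2], i0[,3]) *    f[,1] *   f[,2] *(1-f[,3]) +
       at(i0[,1], i0[,2], i1[,3]) * (1-f[,1])*(1-f[,2])*   f[,3]  +
       at(i1[,1], i0[,2], i1[,3]) *    f[,1] *(1-f[,2])*   f[,3]  +
       at(i0[,1], i1[,2], i1[,3]) * (1-f[,1])*   f[,2] *   f[,3]  +
       at(i1[,1], i1[,2], i1[,3]) *    f[,1] *   f[,2] *   f[,3]
  out[ok] <- v
  out
}

#' Resample an image onto another grid
#'
#' Convenience helper for bringing volumes onto a common grid before
#' comparison. Values are interpolated at the target voxel centers;
#' positions outside the source extent receive `fill`.
#'
#' @param image Source `suv_image`.
#' @param target `suv_image` (or the geometry of one) defining the output grid.
#' @param method `"trilinear"` for intensity images, `"nearest"` for masks.
#' @param fill Value for target voxels outside the source grid.
#' @return A `suv_image` on the target grid.
#' @export
resample_image <- function(image, target, method = c("trilinear", "nearest"),
                           fill = 0) {
  method <- match.arg(method)
  d <- dim(target$data)
  g <- expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
                   k = seq_len(d[3]) - 1)
  pts <- index_to_world(target, as.matrix(g))
  idx <- world_to_index(image, pts)
  if (method == "nearest") idx <- round(idx)
  v <- interp_trilinear(image$data, idx, outside = fill)
  suv_image(array(v, d), target$spacing, target$origin, target$direction,
            provenance = c(image$provenance, list(resampled = method)))
}
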