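# Segmentation methods: MO-PET (multi-level Otsu inside the VOI) and the
# conventional comparators (absolute SUV, percent SUVmax, generic gradient).
# All operate on the voxels inside an ellipsoidal VOI and return seg_mask
# objects on the full image grid.

# shared entry guard: VOI voxels + their SUVs
.voi_voxels <- function(image, voi) {
  vm <- voi_to_mask(voi, image)   # errors if VOI misses the grid
  idx <- which(vm$mask)
  list(mask = vm$mask, idx = idx, values = image$data[idx])
}

#' MO-PET segmentation: multi-level Otsu inside a VOI
#'
#' Builds the SUV histogram from the voxels inside the ellipsoidal VOI
#' only, finds the `K - 1` Otsu thresholds, and takes the hottest class —
#' voxels with SUV at or above the topmost threshold `T_(K-1)` — as tumor.
#' The mask is then restricted to the 26-connected component containing
#' the VOI's SUVmax voxel, so disjoint hot spots inside the VOI do not
#' inflate the MTV.
#'
#' @param image A `suv_image`.
#' @param voi An `ellipsoid_voi` containing the primary tumor.
#' @param K Number of Otsu classes (2-5). Default 2 (background vs
#'   lesion): with the hottest class taken as tumor, K = 2 places the cut
#'   near the half-maximum of a blurred lesion and recovers volumes
#'   accurately; K = 3 adds a spill-over rim class whose upper threshold
#'   excludes the partial-volume shell and runs ~30-40% low on
#'   phantom spheres — use it for lesions with a genuine intermediate
#'   tissue class.
#' @param n_bins Histogram bins over the in-VOI SUV range (default 128).
#' @param connected Keep only the component of the SUVmax voxel
#'   (default TRUE).
#' @return List of class `mo_pet_result`: `mask` (a `seg_mask` labeled
#'   `"mo-pet"`), `thresholds` (a `threshold_set`), `suv_cut` (the applied
#'   SUV cut `T_(K-1)`).
#' @examples
#' ph <- generate_phantom(phantom_spec(
#'   shape = c(40, 40, 40), spacing = c(2, 2, 2), background_suv = 1,
#'   spheres = data.frame(x = 40, y = 40, z = 40, diameter = 22, lbr = 8),
#'   psf_fwhm = 0, noise_coef = 0, seed = 1))
#' voi <- ellipsoid_voi(c(40, 40, 40), c(21, 21, 21))
#' res <- segment_mo_pet(ph$image, voi, K = 2)
#' mask_volume(res$mask)
#' @export
segment_mo_pet <- function(image, voi, K = 2, n_bins = 128,
                           connected = TRUE) {
  if (K < 2 || K > 5) stop("`K` must be between 2 and 5")
  v <- .voi_voxels(image, voi)
  hist <- build_histogram(v$values, n_bins)   # degenerate VOI errors here
  ts <- multilevel_otsu(hist, K = K)
  cut <- ts$thresholds[K - 1]
  m <- array(FALSE, dim(image$data))
  m[v$idx[v$values >= cut]] <- TRUE
  if (connected && any(m)) {
    seed <- v$idx[which.max(v$values)]
    m <- m & connected_component(m, seed)
  }
  mask <- seg_mask(m, image, method = "mo-pet",
                   params = list(K = K, n_bins = n_bins, suv_cut = cut,
                                 connected = connected))
  structure(list(mask = mask, thresholds = ts, suv_cut = cut),
            class = "mo_pet_result")
}

#' @export
print.mo_pet_result <- function(x, ...) {
  print(x$thresholds); print(x$mask)
  invisible(x)
}

#' Absolute-SUV threshold segmentation
#'
#' Selects the in-VOI voxels with SUV at or above a fixed absolute cut
#' (the clinical convention, e.g. SUV 2.0 / 2.5 / 3.0). Inclusive at the
#' threshold. No connected-component filtering by default, matching how
#' simple thresholding MTVs are reported.
#'
#' @inheritParams segment_mo_pet
#' @param threshold Absolute SUV cut, > 0.
#' @param connected Restrict to the SUVmax voxel's 26-connected component.
#' @return `seg_mask` labeled `"suv-<threshold>"`. An all-below VOI yields
#'   an empty mask with a warning.
#' @export
segment_absolute_suv <- function(image, voi, threshold, connected = FALSE) {
  if (!is.finite(threshold) || threshold <= 0)
    stop("`threshold` must be a positive SUV value")
  v <- .voi_voxels(image, voi)
  m <- array(FALSE, dim(image$data))
  sel <- v$values >= threshold
  if (!any(sel)) warning("no in-VOI voxel reaches SUV ", format(threshold),
                         ": empty mask")
  m[v$idx[sel]] <- TRUE
  if (connected && any(m))
    m <- m & connected_component(m, v$idx[which.max(v$values)])
  seg_mask(m, image, method = sprintf("suv-%.4g", threshold),
           params = list(threshold = threshold, connected = connected))
}

#' Percent-of-SUVmax threshold segmentation
#'
#' Cut = `fraction * max(in-VOI SUV)`; selects in-VOI voxels with SUV at
#' or above the cut (inclusive), e.g. fraction 0.30 for the 30% SUVmax
#' method.
#'
#' @inheritParams segment_absolute_suv
#' @param fraction Fraction of the in-VOI SUVmax, strictly in (0, 1).
#' @return `seg_mask` labeled `"percent-<100*fraction>"`; params record the
#'   realized SUV cut.
#' @export
segment_percent_suvmax <- function(image, voi, fraction, connected = FALSE) {
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
    stop("`fraction` must be strictly between 0 and 1")
  v <- .voi_voxels(image, voi)
  cut <- fraction * max(v$values)
  m <- array(FALSE, dim(image$data))
  m[v$idx[v$values >= cut]] <- TRUE
  if (connected && any(m))
    m <- m & connected_component(m, v$idx[which.max(v$values)])
  seg_mask(m, image, method = sprintf("percent-%g", 100 * fraction),
           params = list(fraction = fraction, suv_cut = cut,
                         connected = connected))
}

#' Gradient-based segmentation (generic)
#'
#' A generic gradient-shell delineation standing in for commercial
#' gradient tools: it is an approximation, labeled `"gradient (generic)"`
#' in all outputs, and makes no claim of equivalence to any proprietary
#' implementation. The in-VOI volume is Gaussian-smoothed, the spatial
#' gradient magnitude is computed, rays are cast from the SUVmax voxel
#' over a deterministic direction set, the boundary radius along each ray
#' is placed at the maximal gradient magnitude, and the enclosed star-shaped
#' voxel set (nearest-ray radius rule) is returned.
#'
#' @inheritParams segment_mo_pet
#' @param smoothing_fwhm Gaussian pre-smoothing FWHM in mm (0 = none).
#' @param n_rays Number of ray directions (Fibonacci sphere lattice).
#' @return `seg_mask` labeled `"gradient (generic)"`.
#' @export
segment_gradient <- function(image, voi, smoothing_fwhm = 0, n_rays = 500) {
  if (smoothing_fwhm < 0) stop("`smoothing_fwhm` must be >= 0")
  v <- .voi_voxels(image, voi)
  if (max(v$values) - min(v$values) <= 0)
    stop("degenerate (flat) region in VOI: no gradient boundary exists")
  sub <- .crop_box(image, v$mask)
  arr <- sub$data
  if (smoothing_fwhm > 0)
    arr <- gaussian_blur(arr, image$spacing, smoothing_fwhm)
  gm <- .gradient_magnitude(arr, image$spacing)

  # seed at the (smoothed) in-VOI SUVmax, in cropped 0-based index coords
  invoi_sub <- v$mask[sub$i, sub$j, sub$k]
  smax <- which(invoi_sub)[which.max(arr[invoi_sub])]
  seed <- arrayInd(smax, dim(arr)) - 1
  sp <- image$spacing
  dirs <- .fibonacci_sphere(n_rays)

  # march each ray in steps of half the min spacing, up to the VOI extent
  step <- min(sp) / 2
  seed_full <- seed + c(sub$i[1], sub$j[1], sub$k[1]) - 1  # 0-based, full grid
  all_in <- arrayInd(which(v$mask), dim(image$data)) - 1
  rmax <- max(sqrt(rowSums(
    (sweep(all_in, 2, seed_full) *
       matrix(sp, nrow(all_in), 3, byrow = TRUE))^2)))
  radii <- seq(step, rmax + step, by = step)
  # gradient magnitude sampled along every ray (n_rays x n_steps)
  boundary_r <- vapply(seq_len(nrow(dirs)), function(q) {
    pts_mm <- outer(radii, dirs[q, ])                 # displacement in mm
    idx <- sweep(pts_mm, 2, sp, "/") +
           matrix(seed, length(radii), 3, byrow = TRUE)
    g <- interp_trilinear(gm, idx, outside = NA_real_)
    if (all(is.na(g))) return(radii[1])
    radii[which.max(g)]
  }, numeric(1))

  # voxel in mask iff closer to seed than the boundary radius of its
  # nearest ray direction
  sub_idx <- which(invoi_sub)
  ai <- arrayInd(sub_idx, dim(arr)) - 1
  disp <- sweep(ai, 2, seed) * matrix(sp, nrow(ai), 3, byrow = TRUE)
  r <- sqrt(rowSums(disp^2))
  keep <- r == 0
  nz <- r > 0
  if (any(nz)) {
    u <- disp[nz, , drop = FALSE] / r[nz]
    near <- max.col(u %*% t(dirs), ties.method = "first")
    keep[nz] <- r[nz] <= boundary_r[near] + 1e-9
  }
  m <- array(FALSE, dim(image$data))
  full_idx <- which(v$mask)[match(sub_idx, which(invoi_sub))]
  m[full_idx[keep]] <- TRUE
  if (any(m)) {
    seed_lin <- v$idx[which.max(v$values)]
    if (m[seed_lin]) m <- m & connected_component(m, seed_lin)
  }
  seg_mask(m, image, method = "gradient (generic)",
           params = list(smoothing_fwhm = smoothing_fwhm, n_rays = n_rays))
}

# crop image data to the bounding box of a logical array; returns data and
# the index ranges used
.crop_box <- function(image, mask) {
  w <- which(mask, arr.ind = TRUE)
  i <- min(w[, 1]):max(w[, 1]); j <- min(w[, 2]):max(w[, 2])
  k <- min(w[, 3]):max(w[, 3])
  list(data = image$data[i, j, k, drop = FALSE], i = i, j = j, k = k)
}

# central-difference gradient magnitude, spacing-aware, replicated edges
.gradient_magnitude <- function(arr, spacing) {
  d <- dim(arr)
  shift <- function(a, ax, by) {
    idx <- lapply(d, seq_len)
    idx[[ax]] <- pmin(pmax(idx[[ax]] + by, 1), d[ax])
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  g2 <- array(0, d)
  for (ax in 1:3) {
    if (d[ax] < 2) next
    g <- (shift(arr, ax, 1L) - shift(arr, ax, -1L)) / (2 * spacing[ax])
    g2 <- g2 + g * g
  }
  sqrt(g2)
}

# deterministic quasi-uniform unit directions
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
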