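# NEMA-image-quality-style synthetic phantom: hot spheres of known
# diameter and lesion-to-background ratio in a warm background, degraded
# by a Gaussian point-spread function and intensity-proportional noise.
# Ground-truth masks come from the unblurred geometry, so every
# segmentation method can be scored against a known volume.

#' Phantom specification
#'
#' @param shape Grid shape (voxels), length 3.
#' @param spacing Voxel spacing in mm, length 3.
#' @param background_suv Warm-background SUV (default 1).
#' @param spheres `data.frame` with columns `x`, `y`, `z` (center, world
#'   mm), `diameter` (mm) and `lbr` (lesion-to-background ratio, > 1).
#'   Defaults to the six NEMA IQ sphere diameters
#'   (10, 13, 17, 22, 28, 37 mm) at LBR 4, laid out on a ring.
#' @param psf_fwhm Isotropic Gaussian PSF FWHM in mm (default 6, typical
#'   clinical PET resolution; 0 disables blurring).
#' @param noise_coef Gaussian noise with sigma = `noise_coef` * local
#'   intensity (default 0.10; 0 disables noise). Values are clamped at 0
#'   to keep SUVs non-negative.
#' @param seed RNG seed; a fixed seed makes the phantom byte-identical.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128, 64), spacing = c(2, 2, 2),
                         background_suv = 1, spheres = nema_spheres(),
                         psf_fwhm = 6, noise_coef = 0.10, seed = 1L) {
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3, all(shape > 0), length(spacing) == 3,
            all(spacing > 0), background_suv > 0, psf_fwhm >= 0,
            noise_coef >= 0)
  spheres <- as.data.frame(spheres)
  need <- c("x", "y", "z", "diameter", "lbr")
  if (nrow(spheres) && !all(need %in% names(spheres)))
    stop("`spheres` needs columns ", paste(need, collapse = ", "))
  if (nrow(spheres)) {
    if (any(spheres$diameter <= 0)) stop("sphere diameters must be > 0")
    if (any(spheres$lbr <= 1)) stop("lesion-to-background ratio must be > 1")
    if (nrow(spheres) > 1) {
      ctr <- as.matrix(spheres[, c("x", "y", "z")])
      dd <- as.matrix(stats::dist(ctr))
      rr <- outer(spheres$diameter, spheres$diameter, "+") / 2
      diag(dd) <- Inf
      if (any(dd < rr)) stop("spheres overlap")
    }
  }
  structure(list(shape = shape, spacing = spacing,
                 background_suv = background_suv, spheres = spheres,
                 psf_fwhm = psf_fwhm, noise_coef = noise_coef,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' NEMA IQ sphere layout
#'
#' The six standard sphere diameters placed on a 57.2 mm-radius ring, all
#' at one lesion-to-background ratio.
#'
#' @param lbr Lesion-to-background ratio applied to all spheres.
#' @param center Ring center (world mm).
#' @param ring_radius Ring radius in mm.
#' @return `data.frame` usable as the `spheres` argument of
#'   [phantom_spec()].
#' @export
nema_spheres <- function(lbr = 4, center = c(128, 128, 64),
                         ring_radius = 57.2) {
  d <- c(10, 13, 17, 22, 28, 37)
  ang <- (seq_along(d) - 1) * 2 * pi / length(d)
  data.frame(x = center[1] + ring_radius * cos(ang),
             y = center[2] + ring_radius * sin(ang),
             z = center[3], diameter = d, lbr = lbr)
}

#' Generate a synthetic phantom
#'
#' Builds the ideal piecewise-constant volume (background SUV; sphere SUV
#' = background x LBR), convolves it with the Gaussian PSF, adds
#' intensity-proportional Gaussian noise, and returns the image together
#' with per-sphere ground-truth masks taken from the unblurred geometry
#' (voxel center inside the sphere). Ground truth is independent of PSF
#' and noise settings by construction.
#'
#' @param spec A [phantom_spec()].
#' @return List of class `phantom`: `image` (`suv_image`), `truth` (list
#'   of `seg_mask`, one per sphere), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  base <- array(spec$background_suv, d)
  geom <- suv_image(base, spec$spacing)
  cx <- axis_aligned_centers(geom)
  truth <- list()
  if (nrow(spec$spheres)) for (s in seq_len(nrow(spec$spheres))) {
    sp <- spec$spheres[s, ]
    r <- sp$diameter / 2
    dx2 <- (cx$x - sp$x)^2; dy2 <- (cx$y - sp$y)^2; dz2 <- (cx$z - sp$z)^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r * r
    base[inside] <- spec$background_suv * sp$lbr
    truth[[s]] <- seg_mask(inside, geom, method = "truth",
                           params = as.list(sp))
  }
  img <- base
  if (spec$psf_fwhm > 0)
    img <- gaussian_blur(img, spec$spacing, spec$psf_fwhm)
  if (spec$noise_coef > 0) {
    set.seed(spec$seed)
    img <- img + stats::rnorm(length(img), 0, spec$noise_coef * img)
    img <- pmax(img, 0)
    dim(img) <- d
  }
  structure(list(image = suv_image(img, spec$spacing,
                                   provenance = list(source = "phantom_sim",
                                                     seed = spec$seed)),
                 truth = truth, spec = spec),
            class = "phantom")
}

#' Separable Gaussian blur of a 3-D array
#'
#' Convolution with an isotropic Gaussian of the given FWHM, applied as
#' three 1-D passes (implemented as banded-matrix products so it is fast
#' in base R). Kernels are truncated at 4 sigma and renormalized, with
#' replicated edge handling via the renormalization.
#'
#' @param arr 3-D numeric array.
#' @param spacing Voxel spacing in mm.
#' @param fwhm Full width at half maximum in mm.
#' @return Blurred array of the same shape.
#' @export
gaussian_blur <- function(arr, spacing, fwhm) {
  if (fwhm <= 0) return(arr)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma / spacing[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(4 * s))
    k <- stats::dnorm(-half:half, sd = s)
    n <- d[ax]
    # banded convolution matrix with kernel renormalized per row (edges)
    K <- matrix(0, n, n)
    for (off in -half:half) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- k[off + half + 1]
    }
    K <- K / rowSums(K)
    arr <- .apply_axis(arr, ax, K)
  }
  arr
}

# multiply matrix K (n_ax x n_ax) along axis `ax` of 3-D array
.apply_axis <- function(arr, ax, K) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  m <- K %*% matrix(a, nrow = d[ax])
  dim(m) <- d[perm]
  aperm(m, order(perm))
}

#' Volume-recovery experiment across lesion sizes and contrasts
#'
#' For every (diameter, LBR, seed) condition, simulates a single-sphere
#' phantom, runs each requested segmentation method inside a VOI drawn
#' with a fixed margin around the sphere, and records the recovered /
#' true volume ratio. A method failure on a condition is recorded as a
#' missing ratio with the error message, never aborts the grid.
#'
#' @param diameters Sphere diameters in mm.
#' @param lbrs Lesion-to-background ratios.
#' @param seeds Integer RNG seeds (one phantom per seed).
#' @param methods Character vector among `"mo-pet"`, `"suv-2.0"`,
#'   `"suv-2.5"`, `"suv-3.0"`, `"percent-30"`, `"percent-40"`,
#'   `"percent-50"`, `"percent-60"`, `"gradient"`.
#' @param spacing,shape Phantom grid (default 2 mm, 64^3: a 128 mm box).
#' @param background_suv Background SUV (default 1).
#' @param psf_fwhm,noise_coef Degradation settings (defaults 6 mm, 0.10).
#' @param voi_margin_mm VOI radius margin beyond the sphere radius
#'   (default 10 mm — a comfortable manual margin).
#' @param K,n_bins MO-PET settings.
#' @return Long `data.frame`: method, diameter, lbr, seed, true_cm3,
#'   recovered_cm3, ratio, error.
#' @export
run_recovery_experiment <- function(diameters = c(17, 22, 28),
                                    lbrs = c(4, 8),
                                    seeds = 1:20,
                                    methods = c("mo-pet", "suv-2.0",
                                                "percent-30", "gradient"),
                                    spacing = c(2, 2, 2),
                                    shape = c(64, 64, 64),
                                    background_suv = 1,
                                    psf_fwhm = 6, noise_coef = 0.10,
                                    voi_margin_mm = 10,
                                    K = 2, n_bins = 128) {
  center <- spacing * (shape - 1) / 2       # grid center, world mm
  grid <- expand.grid(diameter = diameters, lbr = lbrs, seed = seeds,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    dmm <- grid$diameter[g]; lbr <- grid$lbr[g]; sd_ <- grid$seed[g]
    spec <- phantom_spec(shape = shape, spacing = spacing,
                         background_suv = background_suv,
                         spheres = data.frame(x = center[1], y = center[2],
                                              z = center[3],
                                              diameter = dmm, lbr = lbr),
                         psf_fwhm = psf_fwhm, noise_coef = noise_coef,
                         seed = sd_)
    ph <- generate_phantom(spec)
    true_cm3 <- suppressWarnings(mask_volume(ph$truth[[1]]))
    voi <- ellipsoid_voi(center, rep(dmm / 2 + voi_margin_mm, 3))
    for (meth in methods) {
      res <- tryCatch({
        m <- .run_method(ph$image, voi, meth, K = K, n_bins = n_bins,
                         psf_fwhm = psf_fwhm)
        vol <- suppressWarnings(mask_volume(m))
        data.frame(method = meth, diameter = dmm, lbr = lbr, seed = sd_,
                   true_cm3 = true_cm3, recovered_cm3 = vol,
                   ratio = vol / true_cm3, error = NA_character_)
      }, error = function(e)
        data.frame(method = meth, diameter = dmm, lbr = lbr, seed = sd_,
                   true_cm3 = true_cm3, recovered_cm3 = NA_real_,
                   ratio = NA_real_, error = conditionMessage(e)))
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.run_method <- function(image, voi, method, K = 2, n_bins = 128,
                        psf_fwhm = 6) {
  if (method == "mo-pet")
    return(segment_mo_pet(image, voi, K = K, n_bins = n_bins)$mask)
  if (grepl("^suv-", method))
    return(suppressWarnings(
      segment_absolute_suv(image, voi,
                           as.numeric(sub("^suv-", "", method)))))
  if (grepl("^percent-", method))
    return(suppressWarnings(
      segment_percent_suvmax(image, voi,
                             as.numeric(sub("^percent-", "", method)) / 100)))
  if (method == "gradient")
    return(segment_gradient(image, voi, smoothing_fwhm = 0))
  stop("unknown method: ", method)
}

#' Summarize a recovery experiment
#'
#' Mean and SD of the recovered/true volume ratio per method x diameter x
#' LBR condition, plus the number of failed runs.
#'
#' @param tab Output of [run_recovery_experiment()].
#' @return `data.frame` with one row per condition.
#' @export
summarize_recovery <- function(tab) {
  sp <- split(tab, interaction(tab$method, tab$diameter, tab$lbr,
                               drop = TRUE))
  out <- lapply(sp, function(d) {
    ok <- is.finite(d$ratio)
    data.frame(method = d$method[1], diameter = d$diameter[1],
               lbr = d$lbr[1], n = sum(ok), n_failed = sum(!ok),
               ratio_mean = if (any(ok)) mean(d$ratio[ok]) else NA_real_,
               ratio_sd = if (sum(ok) > 1) stats::sd(d$ratio[ok]) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$method, out$lbr, out$diameter), ]
}
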