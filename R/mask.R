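#' Segmentation mask aligned to an SUV image grid
#'
#' A binary voxel mask carrying the parent grid geometry, the method label
#' that produced it and the parameter record. The metabolic tumor volume
#' (MTV) of a mask is its voxel count times the voxel volume, in cm^3.
#'
#' @param mask Logical (or 0/1) 3-D array.
#' @param image Parent `suv_image` supplying the geometry.
#' @param method Method label, e.g. `"mo-pet"`, `"suv-2.0"`, `"percent-30"`,
#'   `"gradient (generic)"`.
#' @param params Named list of parameters that produced the mask.
#' @return Object of class `seg_mask`.
#' @export
seg_mask <- function(mask, image, method = "manual", params = list()) {
  mask <- as.array(mask)
  if (!identical(dim(mask), dim(image$data)))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match image shape ",
         paste(dim(image$data), collapse = "x"))
  storage.mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  structure(list(mask = mask, spacing = image$spacing, origin = image$origin,
                 direction = image$direction, method = method,
                 params = params),
            class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> method '%s': %d voxels, %.4g cm^3\n",
              x$method, sum(x$mask), mask_volume(x)))
  invisible(x)
}

#' Mask volume in cm^3 (MTV)
#'
#' @param mask A `seg_mask`.
#' @return Voxel count times voxel volume, in cm^3. An empty mask returns
#'   0 with a warning.
#' @examples
#' img <- suv_image(array(1, c(10, 10, 10)), spacing = c(2, 2, 2))
#' m <- seg_mask(array(TRUE, c(10, 10, 10)), img)
#' mask_volume(m)  # 1000 voxels * 8 mm^3 = 8 cm^3
#' @export
mask_volume <- function(mask) {
  n <- sum(mask$mask)
  if (n == 0) warning("empty mask: volume is 0 cm^3")
  n * prod(mask$spacing) / 1000
}

# 26-connectivity neighbor offsets as linear-index deltas for a given dim.
# Returns list(delta = integer offsets, guard fn) -- we instead expand
# frontier as (i,j,k) triplets to avoid wrap-around at array faces.
.neigh26 <- local({
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  as.matrix(g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ])
})

# Connected component (26-connectivity) of `mask` containing linear seed
# index `seed`. Pure R frontier expansion; vectorized over the frontier.
connected_component <- function(mask, seed) {
  d <- dim(mask)
  stopifnot(length(seed) == 1L, mask[seed])
  visited <- array(FALSE, d)
  visited[seed] <- TRUE
  ar <- arrayInd(seed, d)
  frontier <- matrix(ar, ncol = 3)
  off <- .neigh26
  while (nrow(frontier) > 0) {
    # all 26 neighbors of every frontier voxel
    n <- nrow(frontier)
    cand <- frontier[rep(seq_len(n), each = nrow(off)), , drop = FALSE] +
            off[rep(seq_len(nrow(off)), times = n), , drop = FALSE]
    keep <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
            cand[, 2] >= 1 & cand[, 2] <= d[2] &
            cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) break
    lin <- cand[, 1] + d[1] * (cand[, 2] - 1) + d[1] * d[2] * (cand[, 3] - 1)
    new <- mask[lin] & !visited[lin]
    if (!any(new)) break
    lin <- unique(lin[new])
    visited[lin] <- TRUE
    frontier <- arrayInd(lin, d)
  }
  visited
}
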