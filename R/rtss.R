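# RT Structure Set contours: reading named planar contours from DICOM
# RTSS, rasterizing them onto an image grid (voxel center-in-polygon,
# even-odd rule), and extracting rectilinear contours back from a mask
# for round-trip checks. Writing RTSS files is out of scope; masks are
# exported as NIfTI.

#' Contour set
#'
#' Named planar closed polygons in world mm, as stored in an RT Structure
#' Set: a list of structures, each structure a list of n x 3 vertex
#' matrices (one per planar contour, vertices not repeated at closure).
#'
#' @param structures Named list of lists of n x 3 numeric matrices.
#' @return Object of class `contour_set`.
#' @export
contour_set <- function(structures) {
  if (is.null(names(structures)) || any(names(structures) == ""))
    stop("structures must be named")
  for (nm in names(structures)) for (p in structures[[nm]]) {
    if (!is.matrix(p) || ncol(p) != 3 || nrow(p) < 3)
      stop("each contour must be an n x 3 matrix with n >= 3 (", nm, ")")
    sv <- svd(sweep(p, 2, colMeans(p)), nu = 0, nv = 0)$d
    if (sv[3] > 1e-6 * max(sv[1], 1))
      stop("contour not planar within tolerance (", nm, ")")
  }
  structure(list(structures = structures), class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  for (nm in names(x$structures))
    cat(sprintf("  %s: %d contour(s)\n", nm, length(x$structures[[nm]])))
  invisible(x)
}

#' Read contours from a DICOM RT Structure Set
#'
#' @param path RTSS DICOM file.
#' @param structures Optional character vector of structure names to keep.
#' @return A [contour_set()].
#' @export
read_rtss <- function(path, structures = NULL) {
  ds <- read_dicom_file(path)
  rois <- ds[["3006,0020"]]
  if (is.null(rois)) stop("no StructureSetROISequence in ", path)
  names_by_number <- stats::setNames(
    vapply(rois, function(r) as.character(r[["3006,0026"]]), ""),
    vapply(rois, function(r) as.character(r[["3006,0022"]]), ""))
  contours <- ds[["3006,0039"]]
  if (is.null(contours)) stop("no ROIContourSequence in ", path)
  out <- list()
  for (rc in contours) {
    num <- as.character(rc[["3006,0084"]])
    nm <- names_by_number[[num]]
    if (is.null(nm) || is.na(nm)) nm <- paste0("ROI-", num)
    polys <- lapply(rc[["3006,0040"]], function(cs) {
      xyz <- cs[["3006,0050"]]
      matrix(xyz, ncol = 3, byrow = TRUE)
    })
    out[[nm]] <- c(out[[nm]], polys)
  }
  if (!is.null(structures)) {
    miss <- setdiff(structures, names(out))
    if (length(miss)) stop("structures not found: ",
                           paste(miss, collapse = ", "))
    out <- out[structures]
  }
  contour_set(out)
}

# even-odd point-in-polygon, vectorized over test points.
# px, py: point coords; vx, vy: polygon vertices (closed implicitly).
# Points exactly on an edge follow the crossing rule (half-open).
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xint <- vx[i] + (py[crosses] - vy[i]) * (vx[j] - vx[i]) /
        (vy[j] - vy[i])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
    j <- i
  }
  inside
}

#' Rasterize planar contours onto an image grid
#'
#' Each polygon is mapped into voxel index space, matched to the nearest
#' grid slice (error beyond half a slice), and filled with the even-odd
#' rule on voxel centers; overlapping polygons on one slice XOR, so holes
#' encoded as inner contours are respected. The union over structures is
#' returned as one mask.
#'
#' @param contours A [contour_set()] (or a bare list of n x 3 matrices).
#' @param image `suv_image` supplying the target grid.
#' @param structures Optional structure names to rasterize (default all).
#' @return `seg_mask` labeled `"rtss"`.
#' @export
rasterize_contours <- function(contours, image, structures = NULL) {
  if (inherits(contours, "contour_set")) {
    polys <- contours$structures
    if (!is.null(structures)) polys <- polys[structures]
    polys <- do.call(c, unname(polys))
  } else polys <- contours
  d <- dim(image$data)
  m <- array(FALSE, d)
  for (p in polys) {
    idx <- world_to_index(image, p)
    k <- idx[, 3]
    k0 <- round(mean(k))
    if (max(abs(k - k0)) > 0.5 + 1e-9)
      stop(sprintf(
        "contour plane (index %.3f) does not match any slice within half a slice",
        mean(k)))
    if (k0 < 0 || k0 > d[3] - 1)
      stop(sprintf("contour plane at slice %d is outside the grid", k0))
    # restrict the center test to the polygon's bounding box
    i_rng <- max(1, floor(min(idx[, 1])) + 1):min(d[1], ceiling(max(idx[, 1])) + 1)
    j_rng <- max(1, floor(min(idx[, 2])) + 1):min(d[2], ceiling(max(idx[, 2])) + 1)
    if (!length(i_rng) || !length(j_rng)) next
    g <- expand.grid(i = i_rng, j = j_rng)
    inside <- point_in_polygon(g$i - 1, g$j - 1, idx[, 1], idx[, 2])
    if (!any(inside)) next
    sel <- cbind(g$i[inside], g$j[inside], k0 + 1)
    m[sel] <- xor(m[sel], TRUE)
  }
  seg_mask(m, image, method = "rtss")
}

#' Extract rectilinear contours from a mask
#'
#' Traces, per slice, the outline of the voxel region (the boundary of the
#' union of voxel squares) as closed polygons in world mm. Rasterizing the
#' result with [rasterize_contours()] reproduces the mask exactly, since
#' every voxel center lies strictly inside or outside the traced outline.
#'
#' @param mask A `seg_mask`.
#' @param name Structure name for the output.
#' @return A [contour_set()] with one structure.
#' @export
contours_from_mask <- function(mask, name = "mask") {
  d <- dim(mask$mask)
  img_geom <- list(spacing = mask$spacing, origin = mask$origin,
                   direction = mask$direction)
  polys <- list()
  for (k in seq_len(d[3])) {
    sl <- mask$mask[, , k]
    if (!any(sl)) next
    loops <- .trace_outlines(sl)
    for (lp in loops) {
      # lp: m x 2 vertices in 0-based index coords; lift to world
      idx3 <- cbind(lp, k - 1)
      w <- sweep(idx3, 2, c(img_geom$spacing), "*") %*%
        t(img_geom$direction) +
        matrix(img_geom$origin, nrow(idx3), 3, byrow = TRUE)
      polys[[length(polys) + 1L]] <- w
    }
  }
  if (!length(polys)) stop("empty mask: nothing to contour")
  contour_set(stats::setNames(list(polys), name))
}

# boundary tracing of a logical matrix: directed edges around in-pixels
# (region kept on the left), chained into closed loops. Vertices are at
# pixel corners, i.e. half-integer offsets from the 0-based centers.
.trace_outlines <- function(sl) {
  d <- dim(sl)
  at <- function(i, j) i >= 1 & i <= d[1] & j >= 1 & j <= d[2] &
    sl[cbind(pmax(pmin(i, d[1]), 1), pmax(pmin(j, d[2]), 1))]
  w <- which(sl, arr.ind = TRUE)
  x <- w[, 1] - 1; y <- w[, 2] - 1       # 0-based centers
  edges <- list()
  add <- function(x0, y0, x1, y1, sel) {
    if (any(sel))
      edges[[length(edges) + 1L]] <<- cbind(x0[sel], y0[sel], x1[sel], y1[sel])
  }
  add(x - 0.5, y - 0.5, x + 0.5, y - 0.5, !at(w[, 1], w[, 2] - 1)) # bottom
  add(x + 0.5, y - 0.5, x + 0.5, y + 0.5, !at(w[, 1] + 1, w[, 2])) # right
  add(x + 0.5, y + 0.5, x - 0.5, y + 0.5, !at(w[, 1], w[, 2] + 1)) # top
  add(x - 0.5, y + 0.5, x - 0.5, y - 0.5, !at(w[, 1] - 1, w[, 2])) # left
  e <- do.call(rbind, edges)
  key <- function(a, b) paste(a, b)
  from <- key(e[, 1], e[, 2])
  lookup <- split(seq_len(nrow(e)), from)
  used <- logical(nrow(e))
  loops <- list()
  for (s in seq_len(nrow(e))) {
    if (used[s]) next
    cur <- s; pts <- list()
    repeat {
      used[cur] <- TRUE
      pts[[length(pts) + 1L]] <- e[cur, 1:2]
      nxt_key <- key(e[cur, 3], e[cur, 4])
      cand <- lookup[[nxt_key]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      cur <- cand[1]
    }
    loop <- do.call(rbind, pts)
    # drop collinear midpoints to shorten the polygon
    if (nrow(loop) >= 3) {
      nn <- nrow(loop)
      prev <- loop[c(nn, 1:(nn - 1)), ]
      nxt <- loop[c(2:nn, 1), ]
      keep <- abs((loop[, 1] - prev[, 1]) * (nxt[, 2] - loop[, 2]) -
                  (loop[, 2] - prev[, 2]) * (nxt[, 1] - loop[, 1])) > 1e-12
      loop <- loop[keep, , drop = FALSE]
    }
    if (nrow(loop) >= 3) loops[[length(loops) + 1L]] <- loop
  }
  loops
}
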