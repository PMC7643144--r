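# Local-maxima spot detection. The 2D detector is prominence-based: a
# maximum is reported when its height above the highest saddle connecting it
# to any higher maximum reaches the noise tolerance (the behavior exposed by
# ImageJ-style "find maxima" noise tolerance). The 3D detector reports
# voxels that are the strict maximum of their ellipsoidal neighborhood.

#' Detection parameters
#'
#' @param noise_tolerance minimum prominence (2D) / minimum value (3D), in
#'   intensity units of the analyzed plane.
#' @param pre_blur_radius Gaussian pre-blur sigma in pixels (0 disables).
#' @param exclude_on_edges drop points on the image border.
#' @param light_background invert intensities before detection.
#' @param color_to_detect palette color name restricting detection to pixels
#'   of that color on RGB renderings, or `NULL`.
#' @param only_inside_outlines palette color name: keep only points inside
#'   outline objects of that color (requires projection metadata), or `NULL`.
#' @param radius_xyz `(rx, ry, rz)` neighborhood radii in pixels (3D only).
#' @return a `detection_params` list.
#' @export
detection_params <- function(noise_tolerance = 10, pre_blur_radius = 0,
                             exclude_on_edges = FALSE, light_background = FALSE,
                             color_to_detect = NULL,
                             only_inside_outlines = NULL,
                             radius_xyz = c(2, 2, 2)) {
  stopifnot(noise_tolerance >= 0, pre_blur_radius >= 0, all(radius_xyz >= 0))
  if (!is.null(color_to_detect)) palette_rgb(color_to_detect)
  if (!is.null(only_inside_outlines)) palette_rgb(only_inside_outlines)
  structure(list(noise_tolerance = noise_tolerance,
                 pre_blur_radius = pre_blur_radius,
                 exclude_on_edges = exclude_on_edges,
                 light_background = light_background,
                 color_to_detect = color_to_detect,
                 only_inside_outlines = only_inside_outlines,
                 radius_xyz = radius_xyz),
            class = "detection_params")
}

# reduce an RGB plane/volume to the scalar intensity of one palette color:
# a pixel with RGB = v * color (v > 0) maps to v, everything else to 0
color_intensity <- function(rgbarr, color_name, tol = 1e-6) {
  col <- palette_rgb(color_name)
  nd <- length(dim(rgbarr))
  ch <- function(k) {
    if (nd == 3) rgbarr[, , k] else rgbarr[, , , k]
  }
  v <- array(0, dim(rgbarr)[-nd])
  for (k in 1:3) if (col[k] > 0) v <- pmax(v, ch(k) / col[k])
  ok <- array(TRUE, dim(v))
  for (k in 1:3) ok <- ok & (abs(ch(k) - v * col[k]) <= tol + 1e-9 * v)
  v * ok
}

as_scalar_plane <- function(plane, params) {
  if (length(dim(plane)) == 3) { # RGB
    if (!is.null(params$color_to_detect)) {
      color_intensity(plane, params$color_to_detect)
    } else {
      pmax(plane[, , 1], plane[, , 2], plane[, , 3])
    }
  } else plane
}

#' Find 2D maxima by prominence
#'
#' Pixels are flooded in order of decreasing intensity; when a peak's basin
#' meets a higher basin at a saddle, the peak is reported iff its height
#' above that saddle is at least the noise tolerance. A connected
#' equal-valued plateau yields one point at its (pixel-rounded) centroid.
#' Constant planes yield no points.
#'
#' @param plane numeric matrix, or RGB array `[y, x, rgb]` (reduced via
#'   `color_to_detect`, else by the per-pixel RGB maximum).
#' @param params a [detection_params()].
#' @param inside optional logical matrix: detected points outside it are
#'   dropped (see [outline_interior_mask()]).
#' @return data.frame of point marks with 0-based columns `x`, `y`, `z`
#'   (`z` is `NA`: plane/projection mode).
#' @export
find_maxima_2d <- function(plane, params = detection_params(), inside = NULL) {
  m <- as_scalar_plane(plane, params)
  stopifnot(length(dim(m)) == 2)
  if (params$light_background) m <- max(m) - m
  if (params$pre_blur_radius > 0) m <- gaussian_blur_2d(m, params$pre_blur_radius)
  pts <- prominence_maxima(m, params$noise_tolerance)
  if (nrow(pts) > 0 && params$exclude_on_edges) {
    ny <- nrow(m); nx <- ncol(m)
    keep <- pts$row > 1 & pts$row < ny & pts$col > 1 & pts$col < nx
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) > 0 && !is.null(inside)) {
    keep <- inside[cbind(pts$row, pts$col)]
    pts <- pts[keep, , drop = FALSE]
  }
  data.frame(x = pts$col - 1, y = pts$row - 1, z = rep(NA_integer_, nrow(pts)))
}

# core of the 2D detector; returns 1-based (row, col) of accepted maxima
prominence_maxima <- function(m, tolerance) {
  ny <- nrow(m); nx <- ncol(m)
  n <- ny * nx
  if (max(m) == min(m)) return(data.frame(row = integer(), col = integer()))
  vals <- as.vector(m)
  rows <- rep(seq_len(ny), nx)
  cols <- rep(seq_len(nx), each = ny)
  raster <- (rows - 1) * nx + cols # smallest y, then x
  ord <- order(-vals, raster)
  parent <- seq_len(n)
  find_root <- function(i) { # union-find with path halving
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  peak <- vals
  # plateau centroid accumulators per root
  psum_r <- as.numeric(rows); psum_c <- as.numeric(cols); pn <- rep(1, n)
  plateau <- logical(n)
  processed <- logical(n)
  emitted_r <- numeric(0); emitted_c <- numeric(0)
  noff <- as.integer(c(-1, 1, -ny, ny, -ny - 1, -ny + 1, ny - 1, ny + 1))
  for (p in ord) {
    v <- vals[p]
    rp <- rows[p]; cp <- cols[p]
    nb <- integer(0)
    for (k in 1:8) {
      q <- p + noff[k]
      dr <- rp + c(-1, 1, 0, 0, -1, 1, -1, 1)[k]
      dc <- cp + c(0, 0, -1, 1, -1, -1, 1, 1)[k]
      if (dr >= 1 && dr <= ny && dc >= 1 && dc <= nx && processed[q]) {
        nb <- c(nb, q)
      }
    }
    processed[p] <- TRUE
    if (length(nb) == 0) {
      plateau[p] <- TRUE
      next
    }
    roots <- unique(vapply(nb, function(q) find_root(q), integer(1)))
    main <- roots[which.max(peak[roots])]
    for (r in roots) {
      if (r == main) next
      if (peak[r] == peak[main] && peak[r] == v) {
        # two plateaus of the same height joining through p: same plateau
        psum_r[main] <- psum_r[main] + psum_r[r]
        psum_c[main] <- psum_c[main] + psum_c[r]
        pn[main] <- pn[main] + pn[r]
      } else if (peak[r] - v >= tolerance) {
        emitted_r <- c(emitted_r, psum_r[r] / pn[r])
        emitted_c <- c(emitted_c, psum_c[r] / pn[r])
      }
      parent[r] <- main
    }
    parent[p] <- main
    if (v == peak[main]) {
      # p extends the main plateau if it touches it
      touches <- any(vapply(nb, function(q) {
        plateau[q] && find_root(q) == main
      }, logical(1)))
      if (touches) {
        plateau[p] <- TRUE
        psum_r[main] <- psum_r[main] + rp
        psum_c[main] <- psum_c[main] + cp
        pn[main] <- pn[main] + 1
      }
    }
  }
  final <- find_root(ord[1])
  emitted_r <- c(emitted_r, psum_r[final] / pn[final])
  emitted_c <- c(emitted_c, psum_c[final] / pn[final])
  data.frame(row = round(emitted_r), col = round(emitted_c))
}

#' Find 3D maxima
#'
#' After the optional per-slice pre-blur, a voxel is reported iff its value
#' is at least the noise tolerance and it is the strict maximum within its
#' `(rx, ry, rz)` ellipsoidal neighborhood; equal-valued ties are resolved
#' deterministically in raster order (smallest z, then y, then x wins).
#'
#' @param volume numeric 3D array `[y, x, z]`, or RGB `[y, x, z, rgb]`.
#' @param params a [detection_params()]; `radius_xyz` sets the neighborhood.
#' @param inside optional logical `[y, x]` mask applied to the XY position.
#' @return data.frame of 0-based point marks `x`, `y`, `z`.
#' @export
find_maxima_3d <- function(volume, params = detection_params(), inside = NULL) {
  if (length(dim(volume)) == 4) {
    v <- if (!is.null(params$color_to_detect)) {
      color_intensity(volume, params$color_to_detect)
    } else {
      pmax(volume[, , , 1], volume[, , , 2], volume[, , , 3])
    }
  } else v <- volume
  stopifnot(length(dim(v)) == 3)
  if (params$light_background) v <- max(v) - v
  if (params$pre_blur_radius > 0) {
    v <- slicewise(v, gaussian_blur_2d, sigma = params$pre_blur_radius)
  }
  r <- params$radius_xyz
  dims <- dim(v)
  keep <- v >= params$noise_tolerance
  offs <- ellipsoid_offsets(r[1], r[2], r[3])
  for (i in seq_len(nrow(offs))) {
    off <- c(offs$dy[i], offs$dx[i], offs$dz[i])
    shifted <- shift_pad_3d(v, off, pad = -Inf)
    # the neighbor at +off is later in raster (z, y, x) order than the voxel
    later <- offs$dz[i] > 0 ||
      (offs$dz[i] == 0 && (offs$dy[i] > 0 ||
                           (offs$dy[i] == 0 && offs$dx[i] > 0)))
    keep <- keep & (v > shifted | (v == shifted & later))
    if (!any(keep)) break
  }
  idx <- which(keep)
  zi <- (idx - 1L) %/% (dims[1] * dims[2])
  rest <- (idx - 1L) %% (dims[1] * dims[2])
  xi <- rest %/% dims[1]
  yi <- rest %% dims[1]
  pts <- data.frame(x = xi, y = yi, z = zi)
  if (nrow(pts) > 0 && params$exclude_on_edges) {
    pts <- pts[pts$x > 0 & pts$x < dims[2] - 1 &
               pts$y > 0 & pts$y < dims[1] - 1, , drop = FALSE]
  }
  if (nrow(pts) > 0 && !is.null(inside)) {
    pts <- pts[inside[cbind(pts$y + 1, pts$x + 1)], , drop = FALSE]
  }
  pts[order(pts$z, pts$y, pts$x), , drop = FALSE]
}

ellipsoid_offsets <- function(rx, ry, rz) {
  sx <- floor(max(rx, 0)); sy <- floor(max(ry, 0)); sz <- floor(max(rz, 0))
  g <- expand.grid(dy = -sy:sy, dx = -sx:sx, dz = -sz:sz)
  num <- (g$dx / max(rx, .Machine$double.eps))^2 +
         (g$dy / max(ry, .Machine$double.eps))^2 +
         (g$dz / max(rz, .Machine$double.eps))^2
  g <- g[num <= 1 & !(g$dx == 0 & g$dy == 0 & g$dz == 0), , drop = FALSE]
  g
}

shift_pad_3d <- function(v, off, pad = -Inf) {
  dims <- dim(v)
  out <- array(pad, dims)
  pr <- shift_pairs(dims, off)
  if (is.null(pr)) return(out)
  out[pr$src] <- v[pr$dst]
  out
}
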