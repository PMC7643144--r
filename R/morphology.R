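# Low-level raster utilities: connected-component labeling, rank filters,
# hole filling, Gaussian blur. Conventions follow ImageJ: 8-connectivity in
# 2D, 26-connectivity in 3D, rank-filter discs contain the offsets with
# dx^2 + dy^2 <= r^2 + 1, filter edges are replicate-padded.

# forward half-space neighbor offsets for a given connectivity
neighbor_offsets <- function(ndim, connectivity) {
  if (ndim == 2) {
    if (connectivity == 4) {
      list(c(1, 0), c(0, 1))
    } else {
      list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))
    }
  } else {
    offs <- list()
    for (dz in 0:1) for (dx in -1:1) for (dy in -1:1) {
      key <- c(dz, dx, dy) # lexicographic forwardness: z, then x, then y
      if (all(key == 0)) next
      first_nz <- key[which(key != 0)[1]]
      if (first_nz < 0) next
      if (connectivity == 6 && sum(abs(c(dy, dx, dz))) != 1) next
      offs[[length(offs) + 1]] <- c(dy, dx, dz)
    }
    offs
  }
}

# linear indices of all (src, dst = src + off) in-bound pairs
shift_pairs <- function(dims, off) {
  rng <- vector("list", length(dims))
  for (k in seq_along(dims)) {
    lo <- 1 + max(0, -off[k])
    hi <- dims[k] - max(0, off[k])
    if (hi < lo) return(NULL)
    rng[[k]] <- lo:hi
  }
  if (length(dims) == 2) {
    src <- as.vector(outer(rng[[1]], (rng[[2]] - 1) * dims[1], "+"))
    dst <- as.vector(outer(rng[[1]] + off[1],
                           (rng[[2]] + off[2] - 1) * dims[1], "+"))
  } else {
    nyx <- dims[1] * dims[2]
    b1 <- as.vector(outer(rng[[1]], (rng[[2]] - 1) * dims[1], "+"))
    src <- as.vector(outer(b1, (rng[[3]] - 1) * nyx, "+"))
    b2 <- as.vector(outer(rng[[1]] + off[1],
                          (rng[[2]] + off[2] - 1) * dims[1], "+"))
    dst <- as.vector(outer(b2, (rng[[3]] + off[3] - 1) * nyx, "+"))
  }
  list(src = src, dst = dst)
}

#' Label connected components of a binary mask
#'
#' 2D masks use 8-connectivity, 3D masks 26-connectivity (set `connectivity`
#' to 4 or 6 for the face-connected variants). Component ids are positive
#' integers; background is 0.
#'
#' @param mask logical matrix or 3D logical array.
#' @param connectivity 4/8 (2D) or 6/26 (3D); default is the full diagonal
#'   connectivity.
#' @return integer array of the same shape with component labels.
#' @export
label_components <- function(mask, connectivity = NULL) {
  dims <- dim(mask)
  ndim <- length(dims)
  stopifnot(ndim %in% c(2L, 3L))
  if (is.null(connectivity)) connectivity <- if (ndim == 2) 8 else 26
  lab <- array(0L, dims)
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  rank <- integer(prod(dims))
  rank[idx] <- seq_along(idx)
  edges <- list()
  for (off in neighbor_offsets(ndim, connectivity)) {
    pr <- shift_pairs(dims, off)
    if (is.null(pr)) next
    sel <- mask[pr$src] & mask[pr$dst]
    if (any(sel)) {
      edges[[length(edges) + 1]] <- rbind(rank[pr$src[sel]], rank[pr$dst[sel]])
    }
  }
  if (length(edges) > 0) {
    em <- do.call(cbind, edges)
    g <- igraph::make_graph(as.vector(em), n = length(idx), directed = FALSE)
  } else {
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  }
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

# offsets (dy, dx) of the ImageJ rank-filter disc of radius r (center included)
disc_offsets <- function(radius) {
  r <- max(0, radius)
  s <- floor(r + 1)
  g <- expand.grid(dy = -s:s, dx = -s:s)
  g <- g[g$dy^2 + g$dx^2 <= r^2 + 1, , drop = FALSE]
  g
}

# shift a matrix by (dy, dx) with replicate padding
shift_replicate <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  m[clamp(seq_len(ny) + dy, 1, ny), clamp(seq_len(nx) + dx, 1, nx), drop = FALSE]
}

# 2D rank filters over the disc footprint (min = erosion, max = dilation)
rank_filter_2d <- function(m, radius, fun = pmin) {
  if (radius <= 0) return(m)
  offs <- disc_offsets(radius)
  out <- m
  for (i in seq_len(nrow(offs))) {
    if (offs$dy[i] == 0 && offs$dx[i] == 0) next
    out <- fun(out, shift_replicate(m, offs$dy[i], offs$dx[i]))
  }
  out
}

erode_mask_2d <- function(mask, radius) {
  rank_filter_2d(mask * 1, radius, pmin) > 0.5
}

dilate_mask_2d <- function(mask, radius) {
  rank_filter_2d(mask * 1, radius, pmax) > 0.5
}

# fill 2D holes: background components (4-conn) not touching the border
fill_holes_2d <- function(mask) {
  lab <- label_components(!mask, connectivity = 4)
  if (max(lab) == 0) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  mask | (lab > 0 & !(lab %in% border))
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

conv1d_replicate <- function(v, kern) {
  r <- (length(kern) - 1L) %/% 2L
  pad <- c(rep(v[1], r), v, rep(v[length(v)], r))
  out <- stats::filter(pad, kern, sides = 2)
  as.numeric(out[(r + 1):(r + length(v))])
}

# separable 2D Gaussian blur, replicate edges; sigma in pixels
gaussian_blur_2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel(sigma)
  out <- apply(m, 2, conv1d_replicate, kern = k)          # along y
  out <- t(apply(out, 1, conv1d_replicate, kern = k))     # along x
  dim(out) <- dim(m)
  out
}

# per-slice 2D blur plus 1D blur along z (separable 3D Gaussian)
gaussian_blur_3d <- function(vol, sigma, sigma_z = sigma) {
  if (sigma <= 0 && sigma_z <= 0) return(vol)
  dims <- dim(vol)
  out <- vol
  if (sigma > 0) {
    for (z in seq_len(dims[3])) out[, , z] <- gaussian_blur_2d(out[, , z], sigma)
  }
  if (sigma_z > 0 && dims[3] > 1) {
    k <- gaussian_kernel(sigma_z)
    r <- (length(k) - 1L) %/% 2L
    nz <- dims[3]
    zout <- array(0, dims)
    for (j in seq_along(k)) { # replicate-padded shift along z, vectorized
      src <- clamp(seq_len(nz) + (j - r - 1L), 1, nz)
      zout <- zout + k[j] * out[, , src, drop = FALSE]
    }
    out <- zout
  }
  out
}

# maximum projection of a [y, x, z] volume onto [y, x]
max_project <- function(vol) {
  if (length(dim(vol)) == 2) return(vol)
  nz <- dim(vol)[3]
  Reduce(pmax, lapply(seq_len(nz), function(z) vol[, , z]))
}

# apply a function slice-wise to a [y, x, z] volume (or a bare matrix)
slicewise <- function(vol, f, ...) {
  if (length(dim(vol)) == 2) return(f(vol, ...))
  out <- vol
  for (z in seq_len(dim(vol)[3])) out[, , z] <- f(vol[, , z], ...)
  out
}
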