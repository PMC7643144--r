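# Independent brute-force oracles. These are deliberately written as plain
# nested loops / floodfills, sharing no code with the package internals.

oracle_label <- function(mask, connectivity = NULL) {
  dims <- dim(mask)
  nd <- length(dims)
  if (is.null(connectivity)) connectivity <- if (nd == 2) 8 else 26
  lab <- array(0L, dims)
  cur <- 0L
  if (nd == 2) dims <- c(dims, 1L)
  m <- array(mask, dims)
  lab <- array(0L, dims)
  for (z0 in seq_len(dims[3])) for (x0 in seq_len(dims[2])) for (y0 in seq_len(dims[1])) {
    if (!m[y0, x0, z0] || lab[y0, x0, z0] > 0) next
    cur <- cur + 1L
    queue <- list(c(y0, x0, z0))
    lab[y0, x0, z0] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dz in -1:1) for (dx in -1:1) for (dy in -1:1) {
        if (dy == 0 && dx == 0 && dz == 0) next
        if (connectivity %in% c(4, 6) && sum(abs(c(dy, dx, dz))) != 1) next
        if (nd == 2 && dz != 0) next
        q <- p + c(dy, dx, dz)
        if (any(q < 1) || any(q > dims)) next
        if (m[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0) {
          lab[q[1], q[2], q[3]] <- cur
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  array(lab, dim(mask))
}

oracle_erode <- function(mask, radius) {
  ny <- nrow(mask); nx <- ncol(mask)
  out <- mask
  for (y in 1:ny) for (x in 1:nx) {
    keep <- TRUE
    for (dy in -(radius + 1):(radius + 1)) for (dx in -(radius + 1):(radius + 1)) {
      if (dy^2 + dx^2 > radius^2 + 1) next
      yy <- min(max(y + dy, 1), ny); xx <- min(max(x + dx, 1), nx)
      if (!mask[yy, xx]) keep <- FALSE
    }
    out[y, x] <- keep
  }
  out
}

oracle_fill_holes <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  outside <- matrix(FALSE, ny, nx)
  queue <- list()
  for (y in 1:ny) for (x in 1:nx) {
    if ((y == 1 || y == ny || x == 1 || x == nx) && !mask[y, x]) {
      outside[y, x] <- TRUE
      queue[[length(queue) + 1]] <- c(y, x)
    }
  }
  while (length(queue) > 0) {
    p <- queue[[1]]; queue <- queue[-1]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      q <- p + d
      if (q[1] < 1 || q[1] > ny || q[2] < 1 || q[2] > nx) next
      if (!mask[q[1], q[2]] && !outside[q[1], q[2]]) {
        outside[q[1], q[2]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  mask | !outside
}

# prominence of every local maximum by thresholded connectivity (assumes no
# equal-valued ties except deliberate plateaus; use continuous random data)
oracle_prominence_maxima <- function(m, tolerance) {
  ny <- nrow(m); nx <- ncol(m)
  peaks <- list()
  for (y in 1:ny) for (x in 1:nx) {
    v <- m[y, x]
    is_max <- TRUE
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      yy <- y + dy; xx <- x + dx
      if (yy < 1 || yy > ny || xx < 1 || xx > nx) next
      if (m[yy, xx] > v) is_max <- FALSE
    }
    if (is_max) peaks[[length(peaks) + 1]] <- c(y, x)
  }
  global_v <- max(m)
  keep <- list()
  for (p in peaks) {
    v0 <- m[p[1], p[2]]
    if (v0 == global_v) {
      keep[[length(keep) + 1]] <- p
      next
    }
    # highest threshold at which p's component contains a higher pixel
    levels <- sort(unique(as.vector(m[m <= v0])), decreasing = TRUE)
    saddle <- -Inf
    for (t in levels) {
      comp <- oracle_label(m >= t, 8)
      cid <- comp[p[1], p[2]]
      if (any(m[comp == cid] > v0)) {
        saddle <- t
        break
      }
    }
    if (v0 - saddle >= tolerance) keep[[length(keep) + 1]] <- p
  }
  if (length(keep) == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  df <- data.frame(x = vapply(keep, function(p) p[2] - 1, numeric(1)),
                   y = vapply(keep, function(p) p[1] - 1, numeric(1)))
  df[order(df$y, df$x), , drop = FALSE]
}

oracle_maxima_3d <- function(v, tolerance, rx, ry, rz) {
  dims <- dim(v)
  out <- list()
  for (z in 1:dims[3]) for (x in 1:dims[2]) for (y in 1:dims[1]) {
    val <- v[y, x, z]
    if (val < tolerance) next
    ok <- TRUE
    for (dz in -floor(rz):floor(rz)) for (dx in -floor(rx):floor(rx)) for (dy in -floor(ry):floor(ry)) {
      if (dy == 0 && dx == 0 && dz == 0) next
      if ((dx / max(rx, 1e-12))^2 + (dy / max(ry, 1e-12))^2 +
          (dz / max(rz, 1e-12))^2 > 1) next
      yy <- y + dy; xx <- x + dx; zz <- z + dz
      if (yy < 1 || yy > dims[1] || xx < 1 || xx > dims[2] ||
          zz < 1 || zz > dims[3]) next
      w <- v[yy, xx, zz]
      if (w > val) ok <- FALSE
      if (w == val) {
        # raster tie-break: the earlier voxel (z, then y, then x) wins
        later <- dz > 0 || (dz == 0 && (dy > 0 || (dy == 0 && dx > 0)))
        if (!later) ok <- FALSE
      }
    }
    if (ok) out[[length(out) + 1]] <- c(x - 1, y - 1, z - 1)
  }
  if (length(out) == 0) return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0)))
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("x", "y", "z")
  df[order(df$z, df$y, df$x), , drop = FALSE]
}

# voxel-wise mixing-rule oracle: gray additive then binary by priority
oracle_compose <- function(elements, priority) {
  dims <- colocbox:::element_dims(elements[[1]])
  out <- array(0, c(dims, 3))
  for (z in 1:dims[3]) for (x in 1:dims[2]) for (y in 1:dims[1]) {
    px <- c(0, 0, 0)
    for (el in elements) {
      if (el$kind == "grayscale") px <- px + el$scalar[y, x, z] * el$color
    }
    px <- pmin(px, 1)
    best <- Inf
    for (el in elements) {
      if (el$kind == "binary" && el$mask[y, x, z]) {
        r <- match(el$color_name, priority)
        if (r < best) {
          best <- r
          px <- el$color
        }
      }
    }
    out[y, x, z, ] <- px
  }
  out
}
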