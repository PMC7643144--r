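#' Voxel geometry
#'
#' Physical calibration of a stack: micrometres per pixel in XY and
#' micrometres per Z-step.
#'
#' @param xy_um_per_px micrometres per pixel in X and Y (> 0).
#' @param z_step_um micrometres per Z slice (> 0).
#' @return an object of class `voxel_geometry`.
#' @export
#' @examples
#' voxel_geometry(0.21, 0.48)
voxel_geometry <- function(xy_um_per_px = 1, z_step_um = 1) {
  stopifnot(is.numeric(xy_um_per_px), xy_um_per_px > 0,
            is.numeric(z_step_um), z_step_um > 0)
  structure(list(xy_um_per_px = xy_um_per_px, z_step_um = z_step_um),
            class = "voxel_geometry")
}

#' Multichannel intensity stack
#'
#' The raw input container: a list of per-channel 3D intensity volumes
#' (indexed `[y, x, z]`), all of identical shape, with a bit depth and voxel
#' geometry. `nz = 1` denotes single-plane mode.
#'
#' @param channels list of numeric 3D arrays (or matrices, promoted to
#'   single-slice volumes), intensities in `[0, 2^bit_depth - 1]`.
#' @param bit_depth 8 or 16.
#' @param voxel a [voxel_geometry()].
#' @param name image name used in CSV outputs.
#' @return an object of class `intensity_stack`.
#' @export
intensity_stack <- function(channels, bit_depth = 16,
                            voxel = voxel_geometry(), name = "stack") {
  if (!is.list(channels) || length(channels) == 0) {
    stop("'channels' must be a non-empty list of volumes", call. = FALSE)
  }
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) dim(ch) <- c(dim(ch), 1L)
    stopifnot(length(dim(ch)) == 3)
    ch
  })
  dims <- dim(channels[[1]])
  for (ch in channels) {
    if (!identical(dim(ch), dims)) {
      stop("all channels must share identical (nz, ny, nx) dimensions",
           call. = FALSE)
    }
  }
  stopifnot(bit_depth %in% c(8, 16))
  bit_depth <- as.integer(bit_depth)
  maxval <- 2^bit_depth - 1
  rng <- range(vapply(channels, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > maxval) {
    stop("intensities must lie within the bit-depth range [0, ", maxval, "]",
         call. = FALSE)
  }
  stopifnot(inherits(voxel, "voxel_geometry"))
  structure(list(channels = channels, bit_depth = bit_depth, voxel = voxel,
                 name = name),
            class = "intensity_stack")
}

#' @export
print.intensity_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<intensity_stack '%s': %d channel(s), %dx%d px, %d slice(s), %d-bit, %.3g um/px, %.3g um/slice>\n",
              x$name, length(x$channels), d[2], d[1], d[3], x$bit_depth,
              x$voxel$xy_um_per_px, x$voxel$z_step_um))
  invisible(x)
}

stack_dims <- function(stack) dim(stack$channels[[1]])

sidecar_path <- function(path) paste0(path, ".meta.json")

#' Write a stack or rendered output to TIFF
#'
#' Planes are written channel-major, then by slice; for rendered outputs the
#' Z-projection (when present) is written as the leading plane of each output
#' channel. Because the installed TIFF writer cannot embed custom tags,
#' channel count, bit depth and voxel geometry are stored in a JSON sidecar
#' `<path>.meta.json` next to the image.
#'
#' @param stack an [intensity_stack()] or a `rendered_output`.
#' @param path output TIFF path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  }
  if (inherits(stack, "rendered_output")) {
    return(write_rendered(stack, path))
  }
  stopifnot(inherits(stack, "intensity_stack"))
  maxval <- 2^stack$bit_depth - 1
  planes <- list()
  for (ch in stack$channels) {
    for (z in seq_len(dim(ch)[3])) {
      planes[[length(planes) + 1]] <- ch[, , z] / maxval
    }
  }
  tiff::writeTIFF(planes, path, bits.per.sample = stack$bit_depth,
                  compression = "none")
  meta <- list(type = "intensity", n_channels = length(stack$channels),
               nz = dim(stack$channels[[1]])[3], bit_depth = stack$bit_depth,
               name = stack$name,
               xy_um_per_px = stack$voxel$xy_um_per_px,
               z_step_um = stack$voxel$z_step_um)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multichannel TIFF stack
#'
#' Reads the JSON sidecar written by [write_stack()] when present; otherwise
#' the file is treated as a single-channel stack with default voxel geometry
#' (1 um/px, 1 um/slice) and a warning. Plane order is channel-major, then z
#' (ImageJ hyperstack order for a single channel is accepted trivially).
#'
#' @param path TIFF file path.
#' @param n_channels optional override of the channel count for files without
#'   a sidecar.
#' @return an [intensity_stack()].
#' @export
read_stack <- function(path, n_channels = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  planes <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  if (any(vapply(planes, function(p) length(dim(p)) == 3, logical(1)))) {
    stop("file contains RGB planes; use read_rendered()", call. = FALSE)
  }
  d1 <- dim(planes[[1]])
  if (!all(vapply(planes, function(p) identical(dim(p), d1), logical(1)))) {
    stop("mixed per-plane dimensions; not a regular stack", call. = FALSE)
  }
  bits <- attr(planes[[1]], "bits.per.sample") %||% 16L
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  if (is.null(meta)) {
    if (is.null(n_channels)) {
      warning("no metadata sidecar found for '", path,
              "': assuming 1 channel and default voxel geometry (1 um)")
      n_channels <- 1L
    }
    voxel <- voxel_geometry()
    bit_depth <- if (bits >= 16) 16 else 8
    name <- sub("\\.tiff?$", "", basename(path), ignore.case = TRUE)
  } else {
    n_channels <- n_channels %||% meta$n_channels
    voxel <- voxel_geometry(meta$xy_um_per_px, meta$z_step_um)
    bit_depth <- meta$bit_depth
    name <- meta$name
  }
  if (length(planes) %% n_channels != 0) {
    stop("plane count ", length(planes), " is not divisible by ",
         n_channels, " channels", call. = FALSE)
  }
  nz <- length(planes) %/% n_channels
  maxval <- 2^bit_depth - 1
  channels <- vector("list", n_channels)
  for (c_i in seq_len(n_channels)) {
    vol <- array(0, c(d1[1], d1[2], nz))
    for (z in seq_len(nz)) {
      vol[, , z] <- round(planes[[(c_i - 1) * nz + z]] * maxval)
    }
    channels[[c_i]] <- vol
  }
  intensity_stack(channels, bit_depth = bit_depth, voxel = voxel, name = name)
}

write_rendered <- function(out, path) {
  planes <- list()
  for (ch in out$channels) {
    if (!is.null(ch$projection)) {
      planes[[length(planes) + 1]] <- ch$projection
    }
    nz <- dim(ch$rgb)[3]
    for (z in seq_len(nz)) {
      planes[[length(planes) + 1]] <- ch$rgb[, , z, ]
    }
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 8, compression = "none")
  meta <- list(type = "rendered", n_channels = length(out$channels),
               nz = dim(out$channels[[1]]$rgb)[3],
               has_projection = !is.null(out$channels[[1]]$projection),
               name = out$name,
               xy_um_per_px = out$voxel$xy_um_per_px,
               z_step_um = out$voxel$z_step_um)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a rendered RGB output file
#'
#' @param path TIFF written by [write_stack()] from a `rendered_output`.
#' @return list with per-channel `$rgb` (`[y, x, z, rgb]`) and `$projection`
#'   (`[y, x, rgb]` or `NULL`), plus `$voxel` and `$name`.
#' @export
read_rendered <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  stopifnot(identical(meta$type, "rendered"))
  planes <- tiff::readTIFF(path, all = TRUE)
  per <- meta$nz + as.integer(meta$has_projection)
  channels <- vector("list", meta$n_channels)
  for (c_i in seq_len(meta$n_channels)) {
    block <- planes[((c_i - 1) * per + 1):(c_i * per)]
    proj <- NULL
    if (meta$has_projection) {
      proj <- block[[1]]
      block <- block[-1]
    }
    d <- dim(block[[1]])
    rgb <- array(0, c(d[1], d[2], meta$nz, 3))
    for (z in seq_len(meta$nz)) rgb[, , z, ] <- block[[z]]
    channels[[c_i]] <- list(rgb = rgb, projection = proj)
  }
  list(channels = channels, name = meta$name,
       voxel = voxel_geometry(meta$xy_um_per_px, meta$z_step_um))
}
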