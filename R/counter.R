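# Point-based object bookkeeping: circular overlays with category strings,
# the three counting modes (add / set / delete), point filtering relative to
# overlays, and the Counts/ CSV persistence layer with its operation log.

#' Create an empty overlay table
#'
#' Overlays represent counted objects: a center point, a radius and a
#' colocalization category string. `z` is the 0-based slice of the overlay
#' or `NA` for projection mode ("all slices").
#'
#' @return zero-row data.frame with columns `id`, `x`, `y`, `z`,
#'   `radius_px`, `category`.
#' @export
empty_overlays <- function() {
  data.frame(id = integer(), x = numeric(), y = numeric(), z = integer(),
             radius_px = numeric(), category = character(),
             stringsAsFactors = FALSE)
}

# is point (x, y, z) inside overlay row o? closed disc, z must match unless
# either side is the all-slices sentinel (NA)
point_in_overlay <- function(px, py, pz, ox, oy, oz, radius) {
  d2 <- (px - ox)^2 + (py - oy)^2
  zok <- is.na(pz) | is.na(oz) | (pz == oz)
  d2 <= radius^2 & zok
}

#' Convert multipoints to overlays (counting modes)
#'
#' A point is "inside" an overlay iff its Euclidean XY distance to the
#' center is at most the overlay radius and the slices match (the `NA`
#' all-slices sentinel matches any z). Modes:
#' \describe{
#'   \item{add}{inside: the active digit is inserted into that overlay's
#'     category (set-insert, kept sorted); outside: a new overlay is created
#'     with the active digit as category.}
#'   \item{set}{inside: the category is replaced by the single active
#'     digit; outside: a new overlay is created.}
#'   \item{delete}{overlays containing at least one point are removed;
#'     points outside any overlay are ignored.}
#' }
#' Points hitting several overlapping overlays affect the nearest center
#' (ties: smaller id). Points are consumed by the conversion.
#'
#' @param points data.frame with 0-based `x`, `y`, `z` (NA = all slices).
#' @param overlays overlay data.frame (see [empty_overlays()]).
#' @param mode `"add"`, `"set"` or `"delete"`.
#' @param active_category digit 1..8 (ignored for delete).
#' @param radius_px radius of newly created overlays (default 8 px).
#' @param counts_dir optional Counts/ directory for operation logging.
#' @return updated overlay data.frame.
#' @export
convert_multipoints <- function(points, overlays, mode = c("add", "set", "delete"),
                                active_category = 1, radius_px = 8,
                                counts_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(points), is.data.frame(overlays))
  if (mode != "delete") {
    stopifnot(length(active_category) == 1, active_category %in% 1:8)
  }
  stopifnot(radius_px > 0)
  if (mode == "delete") {
    if (nrow(points) == 0 || nrow(overlays) == 0) return(overlays)
    hit <- logical(nrow(overlays))
    for (i in seq_len(nrow(points))) {
      hit <- hit | point_in_overlay(points$x[i], points$y[i], points$z[i],
                                    overlays$x, overlays$y, overlays$z,
                                    overlays$radius_px)
    }
    out <- overlays[!hit, , drop = FALSE]
    if (!is.null(counts_dir)) {
      counting_log(counts_dir, "convert_multipoints mode=delete points=%d removed=%d",
                   nrow(points), sum(hit))
    }
    return(out)
  }
  next_id <- if (nrow(overlays) == 0) 1L else max(overlays$id) + 1L
  for (i in seq_len(nrow(points))) {
    if (nrow(overlays) > 0) {
      inside <- point_in_overlay(points$x[i], points$y[i], points$z[i],
                                 overlays$x, overlays$y, overlays$z,
                                 overlays$radius_px)
    } else inside <- logical(0)
    if (any(inside)) {
      d2 <- (points$x[i] - overlays$x)^2 + (points$y[i] - overlays$y)^2
      d2[!inside] <- Inf
      j <- order(d2, overlays$id)[1]
      overlays$category[j] <- if (mode == "add") {
        category_add(overlays$category[j], active_category)
      } else {
        category_string(active_category)
      }
    } else {
      overlays <- rbind(overlays, data.frame(
        id = next_id, x = points$x[i], y = points$y[i], z = points$z[i],
        radius_px = radius_px, category = category_string(active_category),
        stringsAsFactors = FALSE))
      next_id <- next_id + 1L
    }
  }
  if (!is.null(counts_dir)) {
    counting_log(counts_dir, "convert_multipoints mode=%s category=%s points=%d overlays=%d",
                 mode, category_string(active_category), nrow(points),
                 nrow(overlays))
  }
  overlays
}

#' Filter points relative to overlays
#'
#' @param points point data.frame (`x`, `y`, `z`).
#' @param overlays overlay data.frame.
#' @param mode `"inside"` keeps points within at least one overlay,
#'   `"outside"` keeps the complement, `"all"` is the identity.
#' @return filtered point data.frame.
#' @export
toggle_point_filter <- function(points, overlays, mode = c("inside", "outside", "all")) {
  mode <- match.arg(mode)
  if (mode == "all" || nrow(points) == 0) return(points)
  if (nrow(overlays) == 0) {
    return(if (mode == "inside") points[0, , drop = FALSE] else points)
  }
  inside <- vapply(seq_len(nrow(points)), function(i) {
    any(point_in_overlay(points$x[i], points$y[i], points$z[i],
                         overlays$x, overlays$y, overlays$z,
                         overlays$radius_px))
  }, logical(1))
  if (mode == "inside") points[inside, , drop = FALSE]
  else points[!inside, , drop = FALSE]
}

counts_dir_for <- function(image_dir) file.path(image_dir, "Counts")

#' Save / load object counts
#'
#' Counts are written as CSV under `<image_dir>/Counts/` with columns
#' `image`, `id`, `x_px`, `y_px`, `z_slice`, `category`, `radius_px`
#' (category strings are preserved verbatim as text; `z_slice` is empty for
#' projection-mode overlays). Every save is appended to
#' `Counts/Counting_log.txt`.
#'
#' @param overlays overlay data.frame.
#' @param image_name image file name recorded in the CSV.
#' @param image_dir directory of the image; the `Counts` subfolder is
#'   created beneath it.
#' @return `save_counts()` returns the CSV path; `load_counts()` the
#'   overlay data.frame (plus the image name in column `image`).
#' @export
save_counts <- function(overlays, image_name, image_dir) {
  cdir <- counts_dir_for(image_dir)
  dir.create(cdir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(image = rep(image_name, nrow(overlays)),
                   id = overlays$id, x_px = overlays$x, y_px = overlays$y,
                   z_slice = overlays$z, category = overlays$category,
                   radius_px = overlays$radius_px, stringsAsFactors = FALSE)
  path <- file.path(cdir, paste0(image_name, "_counts.csv"))
  write.csv(df, path, row.names = FALSE, na = "")
  counting_log(cdir, "save_counts image=%s overlays=%d", image_name, nrow(overlays))
  invisible(path)
}

#' @rdname save_counts
#' @param path CSV path to load.
#' @export
load_counts <- function(path) {
  if (!file.exists(path)) stop("cannot read counts file: ", path, call. = FALSE)
  df <- tryCatch(
    read.csv(path, colClasses = c(image = "character", id = "integer",
                                  x_px = "numeric", y_px = "numeric",
                                  z_slice = "integer", category = "character",
                                  radius_px = "numeric")),
    error = function(e) stop("malformed counts CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  need <- c("image", "id", "x_px", "y_px", "z_slice", "category", "radius_px")
  if (!all(need %in% names(df))) {
    stop("counts CSV is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  data.frame(image = df$image, id = df$id, x = df$x_px, y = df$y_px,
             z = df$z_slice, radius_px = df$radius_px,
             category = df$category, stringsAsFactors = FALSE)
}

#' Record the image origin and north direction
#'
#' The origin/north pair anchors a section in the shared series frame: the
#' origin becomes `(0, 0)` and the north vector is rotated onto screen-up
#' `(0, -1)` by [transform_xy()]. An unnormalized north vector is normalized
#' with a warning.
#'
#' @param origin numeric `(x0, y0)` in pixels.
#' @param north numeric direction vector in image coordinates.
#' @param image_name image file name.
#' @param image_dir image directory (CSV goes to its `Counts` subfolder).
#' @return path of the written CSV, invisibly.
#' @export
record_origin_north <- function(origin, north, image_name, image_dir) {
  stopifnot(length(origin) == 2, length(north) == 2)
  nrm <- sqrt(sum(north^2))
  if (nrm == 0) stop("north vector must be nonzero", call. = FALSE)
  if (abs(nrm - 1) > 1e-9) {
    warning("north vector is not unit length; normalizing")
    north <- north / nrm
  }
  cdir <- counts_dir_for(image_dir)
  dir.create(cdir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(image = image_name, x0 = origin[1], y0 = origin[2],
                   north_x = north[1], north_y = north[2])
  path <- file.path(cdir, paste0(image_name, "_origin.csv"))
  write.csv(df, path, row.names = FALSE)
  counting_log(cdir, "record_origin_north image=%s origin=(%g,%g) north=(%g,%g)",
               image_name, origin[1], origin[2], north[1], north[2])
  invisible(path)
}

#' @rdname record_origin_north
#' @param path origin CSV path.
#' @export
load_origin_north <- function(path) {
  df <- read.csv(path)
  list(origin = c(df$x0[1], df$y0[1]), north = c(df$north_x[1], df$north_y[1]),
       image = df$image[1])
}

#' Record tissue contours
#'
#' @param contours named list of contour matrices/data.frames with columns
#'   `x`, `y` (>= 3 vertices each; closed polylines).
#' @param image_name image file name.
#' @param image_dir image directory.
#' @return path of the written CSV, invisibly.
#' @export
record_contours <- function(contours, image_name, image_dir) {
  stopifnot(is.list(contours), length(contours) > 0)
  if (is.null(names(contours)) || any(names(contours) == "")) {
    names(contours) <- paste0("contour", seq_along(contours))
  }
  rows <- list()
  for (nm in names(contours)) {
    cm <- as.data.frame(contours[[nm]])
    if (nrow(cm) < 3) stop("contour '", nm, "' needs >= 3 vertices", call. = FALSE)
    rows[[nm]] <- data.frame(image = image_name, contour = nm,
                             vertex = seq_len(nrow(cm)),
                             x = cm$x, y = cm$y, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  cdir <- counts_dir_for(image_dir)
  dir.create(cdir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(cdir, paste0(image_name, "_contours.csv"))
  write.csv(df, path, row.names = FALSE)
  counting_log(cdir, "record_contours image=%s contours=%d vertices=%d",
               image_name, length(contours), nrow(df))
  invisible(path)
}

#' @rdname record_contours
#' @param path contour CSV path.
#' @export
load_contours <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  split_df <- split(df[, c("x", "y")], df$contour)
  lapply(split_df, function(d) {
    rownames(d) <- NULL
    d
  })
}

#' Interior mask of projected outline objects
#'
#' Union of the XY footprints of the accepted outline objects of a given
#' color in a channel projection; used for the "only inside outlines"
#' detection restriction.
#'
#' @param projection result of [project_channel()] (or the
#'   `projection_meta` of a [render_output()] channel: a list of accepted
#'   objects).
#' @param color palette color name of the outline elements.
#' @param dims `(ny, nx)`; required when `projection` is a bare object list.
#' @return logical `[y, x]` mask.
#' @export
outline_interior_mask <- function(projection, color, dims = NULL) {
  objects <- if (!is.null(projection$objects)) projection$objects else projection
  if (is.null(dims)) {
    if (is.null(projection$rgb)) stop("supply dims for a bare object list", call. = FALSE)
    dims <- dim(projection$rgb)[1:2]
  }
  mask <- matrix(FALSE, dims[1], dims[2])
  for (o in objects) {
    if (o$outline != "none" && o$color_name == color) mask <- mask | o$footprint
  }
  mask
}
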