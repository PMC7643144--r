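# Declarative element specifications and the JSON settings descriptor.
# The settings file is a versioned JSON dialect ("schema_version": 1);
# unknown keys are rejected so that descriptors round-trip losslessly.

FILTER_KINDS <- c("gaussian_blur", "median", "minimum", "maximum", "fill_holes")

#' Filter operation
#'
#' One step of the optional filtering stage of an image element. `minimum`
#' and `maximum` are rank filters (erosion/dilation on binary masks) with an
#' ImageJ-style disc footprint; `fill_holes` fills 2D holes per slice and
#' takes no radius.
#'
#' @param kind one of `"gaussian_blur"`, `"median"`, `"minimum"`,
#'   `"maximum"`, `"fill_holes"`.
#' @param radius radius in pixels (>= 0); omitted for `fill_holes`.
#' @return a `filter_op`.
#' @export
filter_op <- function(kind, radius = NULL) {
  if (length(kind) != 1 || !kind %in% FILTER_KINDS) {
    stop("unknown filter kind: '", kind, "'", call. = FALSE)
  }
  if (kind == "fill_holes") {
    if (!is.null(radius)) stop("'fill_holes' takes no radius", call. = FALSE)
    return(structure(list(kind = kind), class = "filter_op"))
  }
  if (is.null(radius) || !is.numeric(radius) || radius < 0) {
    stop("filter '", kind, "' needs a radius >= 0", call. = FALSE)
  }
  structure(list(kind = kind, radius = radius), class = "filter_op")
}

check_filters <- function(filters) {
  lapply(filters, function(f) {
    if (inherits(f, "filter_op")) return(f)
    do.call(filter_op, f)
  })
}

#' Grayscale element specification
#'
#' A brightness-adjusted, pseudo-colored, optionally filtered rendition of
#' one (or, discouraged, several) input channels. Multiple input channels
#' are mixed additively, which risks projection artifacts, so such specs are
#' flagged and rendering logs a warning.
#'
#' @param input_channels input channel indices (1-based, >= 1 entry).
#' @param display_range `(min, max)` intensities mapped linearly to `[0, 1]`
#'   (clamped).
#' @param color palette color name or RGB triple in `[0, 1]`.
#' @param filters list of [filter_op()]s, applied in order.
#' @param output_channel output channel index (>= 1).
#' @return a `grayscale_element`.
#' @export
grayscale_element <- function(input_channels, display_range,
                              color = "white", filters = list(),
                              output_channel = 1) {
  stopifnot(length(input_channels) >= 1, all(input_channels >= 1))
  if (length(display_range) != 2 || display_range[1] >= display_range[2]) {
    stop("display_range must be (min, max) with min < max", call. = FALSE)
  }
  if (is.character(color)) color <- palette_rgb(color)
  stopifnot(length(color) == 3, all(color >= 0 & color <= 1))
  stopifnot(output_channel >= 1)
  structure(list(type = "grayscale",
                 input_channels = as.integer(input_channels),
                 display_range = as.numeric(display_range),
                 color = as.numeric(color),
                 filters = check_filters(filters),
                 output_channel = as.integer(output_channel),
                 discouraged = length(input_channels) > 1),
            class = c("grayscale_element", "element_spec"))
}

#' Binary element specification
#'
#' Channels are thresholded, AND-combined, optionally NOT-subtracted,
#' filtered, cleaned of small particles and of 3D objects touching the stack
#' faces, optionally reduced to outlines, and colorized with one of the seven
#' palette colors.
#'
#' @param and_channels channel indices combined with Boolean AND (>= 1).
#' @param not_channels channel indices whose binarized signal is subtracted
#'   (disjoint from `and_channels`).
#' @param thresholds `"auto"` (applied to every channel), a single manual
#'   level, or a named list/vector mapping channel index to `"auto"` or a
#'   manual level.
#' @param filters list of [filter_op()]s.
#' @param min_particle_area_um2 per-slice 2D particles smaller than this
#'   area are removed (0 disables).
#' @param exclude_edge_objects_3d drop 3D objects touching any XYZ stack face.
#' @param outline `"none"`, `"thin"` (1 px) or `"thick"` (2 px) border.
#' @param color palette color name.
#' @param output_channel output channel index (>= 1).
#' @return a `binary_element`.
#' @export
binary_element <- function(and_channels, not_channels = integer(),
                           thresholds = "auto", filters = list(),
                           min_particle_area_um2 = 0,
                           exclude_edge_objects_3d = FALSE,
                           outline = c("none", "thin", "thick"),
                           color = "green", output_channel = 1) {
  stopifnot(length(and_channels) >= 1, all(and_channels >= 1))
  if (length(intersect(and_channels, not_channels)) > 0) {
    stop("and_channels and not_channels must be disjoint", call. = FALSE)
  }
  outline <- match.arg(outline)
  stopifnot(is.finite(min_particle_area_um2), min_particle_area_um2 >= 0)
  if (is.null(color)) stop("binary element is missing 'color'", call. = FALSE)
  palette_rgb(color) # validates the name
  stopifnot(output_channel >= 1)
  structure(list(type = "binary",
                 and_channels = as.integer(and_channels),
                 not_channels = as.integer(not_channels),
                 thresholds = thresholds,
                 filters = check_filters(filters),
                 min_particle_area_um2 = as.numeric(min_particle_area_um2),
                 exclude_edge_objects_3d = isTRUE(exclude_edge_objects_3d),
                 outline = outline,
                 color = color,
                 output_channel = as.integer(output_channel)),
            class = c("binary_element", "element_spec"))
}

# resolve the threshold setting for one channel index
threshold_for <- function(thresholds, channel) {
  if (is.list(thresholds) || (length(thresholds) > 1 && !is.null(names(thresholds)))) {
    th <- thresholds[[as.character(channel)]]
    if (is.null(th)) "auto" else th
  } else {
    thresholds
  }
}

#' Settings descriptor
#'
#' An ordered list of element specifications plus the color priority table
#' and the Z-projection policy; serializable to JSON with [save_settings()].
#'
#' @param elements list of [grayscale_element()] / [binary_element()] specs.
#' @param color_priority permutation of the seven palette color names,
#'   highest priority first.
#' @param projection_policy `"top"` or `"bottom"`: which of several
#'   Z-stacked objects survives in the Z-projection.
#' @return a `settings_descriptor`.
#' @export
settings_descriptor <- function(elements,
                                color_priority = default_color_priority(),
                                projection_policy = c("top", "bottom")) {
  stopifnot(is.list(elements))
  lapply(elements, function(e) stopifnot(inherits(e, "element_spec")))
  validate_color_priority(color_priority)
  projection_policy <- match.arg(projection_policy)
  structure(list(schema_version = 1L, elements = elements,
                 color_priority = color_priority,
                 projection_policy = projection_policy),
            class = "settings_descriptor")
}

color_to_json <- function(color) {
  pal <- palette_colors()
  for (nm in names(pal)) if (all(pal[[nm]] == color)) return(nm)
  color
}

element_to_json <- function(e) {
  filters <- lapply(e$filters, function(f) {
    out <- list(kind = f$kind)
    if (!is.null(f$radius)) out$radius <- f$radius
    out
  })
  if (e$type == "grayscale") {
    list(type = "grayscale", input_channels = e$input_channels,
         display_range = e$display_range, color = color_to_json(e$color),
         filters = filters, output_channel = e$output_channel)
  } else {
    th <- e$thresholds
    if (is.list(th)) th <- lapply(th, identity)
    list(type = "binary", and_channels = e$and_channels,
         not_channels = e$not_channels, thresholds = th,
         filters = filters, min_particle_area_um2 = e$min_particle_area_um2,
         exclude_edge_objects_3d = e$exclude_edge_objects_3d,
         outline = e$outline, color = e$color,
         output_channel = e$output_channel)
  }
}

check_keys <- function(x, allowed, required, what) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0) {
    stop("unknown key(s) in ", what, ": ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop(what, " is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

element_from_json <- function(x, i) {
  what <- paste0("element ", i)
  if (is.null(x$type)) stop(what, " is missing required key(s): type", call. = FALSE)
  filters <- lapply(x$filters %||% list(), function(f) {
    check_keys(f, c("kind", "radius"), "kind", "filter")
    filter_op(f$kind, f$radius)
  })
  if (x$type == "grayscale") {
    check_keys(x, c("type", "input_channels", "display_range", "color",
                    "filters", "output_channel"),
               c("type", "input_channels", "display_range", "color",
                 "output_channel"), what)
    grayscale_element(unlist(x$input_channels),
                      unlist(x$display_range),
                      if (is.character(x$color)) x$color else unlist(x$color),
                      filters, x$output_channel)
  } else if (x$type == "binary") {
    check_keys(x, c("type", "and_channels", "not_channels", "thresholds",
                    "filters", "min_particle_area_um2",
                    "exclude_edge_objects_3d", "outline", "color",
                    "output_channel"),
               c("type", "and_channels", "color", "output_channel"), what)
    binary_element(unlist(x$and_channels),
                   unlist(x$not_channels %||% integer()),
                   x$thresholds %||% "auto",
                   filters,
                   x$min_particle_area_um2 %||% 0,
                   x$exclude_edge_objects_3d %||% FALSE,
                   x$outline %||% "none",
                   x$color,
                   x$output_channel)
  } else {
    stop(what, ": unknown element type '", x$type, "'", call. = FALSE)
  }
}

#' Save / load a settings descriptor as JSON
#'
#' `save_settings()` followed by `load_settings()` is the identity on the
#' descriptor; unknown keys in the file are rejected with an error naming
#' the offending key.
#'
#' @param sd a [settings_descriptor()].
#' @param path JSON file path.
#' @return `load_settings()` returns the descriptor.
#' @export
save_settings <- function(sd, path) {
  stopifnot(inherits(sd, "settings_descriptor"))
  out <- list(schema_version = sd$schema_version,
              projection_policy = sd$projection_policy,
              color_priority = sd$color_priority,
              elements = lapply(sd$elements, element_to_json))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_settings
#' @export
load_settings <- function(path) {
  if (!file.exists(path)) stop("cannot read settings file: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  check_keys(x, c("schema_version", "projection_policy", "color_priority",
                  "elements"),
             c("schema_version", "elements"), "settings file")
  elements <- mapply(element_from_json, x$elements,
                     seq_along(x$elements), SIMPLIFY = FALSE)
  settings_descriptor(elements,
                      unlist(x$color_priority %||% default_color_priority()),
                      x$projection_policy %||% "top")
}
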