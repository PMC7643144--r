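# The image-element processing engine: stage operations and the grayscale /
# binary rendering pipelines.

#' Global intensity thresholding
#'
#' Binarizes a volume with a global threshold: voxels are TRUE where
#' intensity >= level. `"auto"` computes the level once over the whole
#' volume with the iterative intermeans (IsoData-style) rule: starting from
#' the overall mean, the level is repeatedly replaced by the mean of the
#' below- and above-level class means until it stabilizes.
#'
#' @param volume numeric matrix or 3D array.
#' @param threshold `"auto"` or a manual level (inclusive, >=).
#' @return logical array of the same shape. The computed level is attached
#'   as attribute `"level"`.
#' @export
binarize <- function(volume, threshold = "auto") {
  if (identical(threshold, "auto")) {
    v <- as.numeric(volume)
    if (max(v) == min(v)) {
      warning("auto threshold on a constant volume; returning all-false")
      out <- array(FALSE, dim(volume))
      attr(out, "level") <- Inf
      return(out)
    }
    level <- mean(v)
    repeat {
      lo <- v[v < level]
      hi <- v[v >= level]
      new <- (mean(lo) + mean(hi)) / 2
      if (!is.finite(new) || abs(new - level) < 1e-9) break
      level <- new
    }
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1)
    level <- threshold
  }
  out <- volume >= level
  attr(out, "level") <- level
  out
}

#' Boolean AND of binary masks
#'
#' @param masks non-empty list of logical arrays of identical shape.
#' @return voxel-wise conjunction.
#' @export
combine_and <- function(masks) {
  if (!is.list(masks) || length(masks) == 0) {
    stop("combine_and() needs a non-empty list of masks", call. = FALSE)
  }
  dims <- dim(masks[[1]])
  for (m in masks) stopifnot(identical(dim(m), dims))
  out <- Reduce(`&`, masks)
  attributes(out) <- list(dim = dims)
  out
}

#' Boolean NOT subtraction
#'
#' Removes from `mask` every voxel present in any of `not_masks`.
#'
#' @param mask logical array.
#' @param not_masks list of logical arrays (may be empty).
#' @return logical array: `mask & !union(not_masks)`.
#' @export
subtract_not <- function(mask, not_masks = list()) {
  if (length(not_masks) == 0) return(mask)
  for (m in not_masks) stopifnot(identical(dim(m), dim(mask)))
  mask & !Reduce(`|`, not_masks)
}

apply_one_filter <- function(x, f, is_mask) {
  switch(f$kind,
    gaussian_blur = {
      if (is_mask) slicewise(x * 1, gaussian_blur_2d, sigma = f$radius) >= 0.5
      else slicewise(x, gaussian_blur_2d, sigma = f$radius)
    },
    minimum = {
      out <- slicewise(x * 1, rank_filter_2d, radius = f$radius, fun = pmin)
      if (is_mask) out > 0.5 else out
    },
    maximum = {
      out <- slicewise(x * 1, rank_filter_2d, radius = f$radius, fun = pmax)
      if (is_mask) out > 0.5 else out
    },
    median = {
      out <- slicewise(x * 1, median_filter_2d, radius = f$radius)
      if (is_mask) out > 0.5 else out
    },
    fill_holes = {
      if (!is_mask) stop("'fill_holes' applies to binary masks only", call. = FALSE)
      slicewise(x, fill_holes_2d)
    },
    stop("unknown filter kind: '", f$kind, "'", call. = FALSE)
  )
}

# disc-footprint 2D median (used by the 'median' filter op)
median_filter_2d <- function(m, radius) {
  if (radius <= 0) return(m)
  offs <- disc_offsets(radius)
  stacks <- lapply(seq_len(nrow(offs)), function(i) {
    as.vector(shift_replicate(m, offs$dy[i], offs$dx[i]))
  })
  vals <- do.call(cbind, stacks)
  out <- apply(vals, 1, stats::median)
  dim(out) <- dim(m)
  out
}

#' Apply an ordered list of filters
#'
#' Filters operate per slice. On binary masks, `minimum`/`maximum` act as
#' erosion/dilation with the disc footprint of the given radius and
#' `gaussian_blur` re-binarizes at 0.5.
#'
#' @param x numeric volume or logical mask (matrix or 3D array).
#' @param filters list of [filter_op()]s applied in order.
#' @return same type as `x`.
#' @export
apply_filters <- function(x, filters) {
  filters <- check_filters(filters)
  is_mask <- is.logical(x)
  for (f in filters) x <- apply_one_filter(x, f, is_mask)
  x
}

#' Remove small 2D particles
#'
#' Per-slice 8-connected particles with physical area
#' `n_pixels * xy_um_per_px^2 < min_area_um2` are removed.
#'
#' @param mask logical matrix or 3D array.
#' @param min_area_um2 minimum retained area in square micrometres (0
#'   disables).
#' @param voxel a [voxel_geometry()].
#' @return filtered mask.
#' @export
remove_small_particles <- function(mask, min_area_um2, voxel = voxel_geometry()) {
  stopifnot(min_area_um2 >= 0)
  if (min_area_um2 == 0) return(mask)
  px_area <- voxel$xy_um_per_px^2
  drop_small <- function(slice) {
    lab <- label_components(slice, connectivity = 8)
    if (max(lab) == 0) return(slice)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes * px_area >= min_area_um2)
    slice & (lab %in% keep & lab > 0)
  }
  out <- slicewise(mask, function(s) {
    r <- drop_small(s)
    dim(r) <- dim(s)
    r
  })
  out
}

#' Remove 3D objects touching the stack faces
#'
#' 26-connected 3D components having any voxel on an X, Y or Z face of the
#' stack are removed entirely.
#'
#' @param mask 3D logical array.
#' @return filtered mask.
#' @export
filter_3d_edge_objects <- function(mask) {
  stopifnot(length(dim(mask)) == 3)
  lab <- label_components(mask, connectivity = 26)
  if (max(lab) == 0) return(mask)
  d <- dim(mask)
  edge_labels <- unique(c(lab[1, , ], lab[d[1], , ],
                          lab[, 1, ], lab[, d[2], ],
                          lab[, , 1], lab[, , d[3]]))
  edge_labels <- edge_labels[edge_labels > 0]
  mask & !(lab %in% edge_labels & lab > 0)
}

#' Convert a mask to its outline
#'
#' Per slice, `thin` keeps a 1-px border (mask minus its erosion by radius
#' 1), `thick` a 2-px border (erosion by radius 2); the interior becomes
#' FALSE.
#'
#' @param mask logical matrix or 3D array.
#' @param mode `"thin"` or `"thick"`.
#' @return outline mask.
#' @export
to_outline <- function(mask, mode = c("thin", "thick")) {
  mode <- match.arg(mode)
  r <- if (mode == "thin") 1 else 2
  slicewise(mask, function(s) s & !erode_mask_2d(s, r))
}

rescale_display <- function(channel, display_range) {
  clamp((channel - display_range[1]) / (display_range[2] - display_range[1]))
}

#' Render a grayscale element
#'
#' Each input channel is linearly rescaled from the display range to
#' `[0, 1]` (clamped), filtered, and the channels are summed with a clamp at
#' 1; the element color scales the result per RGB component. Multi-input
#' specs log a discouragement warning (additive grayscale mixing invites
#' projection artifacts).
#'
#' @param spec a [grayscale_element()].
#' @param stack an [intensity_stack()].
#' @return a `rendered_element` with fields `kind`, `scalar` (`[y, x, z]`
#'   in `[0, 1]`), `color`, `output_channel`, `spec`.
#' @export
render_grayscale_element <- function(spec, stack) {
  stopifnot(inherits(spec, "grayscale_element"), inherits(stack, "intensity_stack"))
  if (any(spec$input_channels > length(stack$channels))) {
    stop("input channel out of range", call. = FALSE)
  }
  if (spec$discouraged) {
    coloc_log("grayscale element mixes %d input channels; mixing multiple grayscale channels is discouraged",
              length(spec$input_channels), level = "WARN")
    warning("mixing multiple grayscale input channels is discouraged")
  }
  acc <- NULL
  for (ci in spec$input_channels) {
    v <- rescale_display(stack$channels[[ci]], spec$display_range)
    v <- apply_filters(v, spec$filters)
    acc <- if (is.null(acc)) v else acc + v
  }
  structure(list(kind = "grayscale", scalar = clamp(acc), color = spec$color,
                 color_name = NA_character_, outline = "none",
                 output_channel = spec$output_channel, spec = spec),
            class = "rendered_element")
}

#' Render a binary element
#'
#' Pipeline order: binarize each AND channel, Boolean AND, subtract the
#' binarized NOT channels, apply filters, remove small particles, drop 3D
#' edge objects (if enabled), convert to outline (if enabled), colorize.
#'
#' @param spec a [binary_element()].
#' @param stack an [intensity_stack()].
#' @param voxel voxel geometry used by the particle-area filter; defaults to
#'   the stack's.
#' @return a `rendered_element` with fields `mask` (final, post-outline),
#'   `solid_mask` (pre-outline), `color`, `color_name`, `outline`,
#'   `output_channel`, `spec`.
#' @export
render_binary_element <- function(spec, stack, voxel = NULL) {
  stopifnot(inherits(spec, "binary_element"), inherits(stack, "intensity_stack"))
  voxel <- voxel %||% stack$voxel
  if (any(c(spec$and_channels, spec$not_channels) > length(stack$channels))) {
    stop("input channel out of range", call. = FALSE)
  }
  masks <- lapply(spec$and_channels, function(ci) {
    binarize(stack$channels[[ci]], threshold_for(spec$thresholds, ci))
  })
  m <- combine_and(masks)
  if (length(spec$not_channels) > 0) {
    nots <- lapply(spec$not_channels, function(ci) {
      binarize(stack$channels[[ci]], threshold_for(spec$thresholds, ci))
    })
    m <- subtract_not(m, nots)
  }
  m <- apply_filters(m, spec$filters)
  m <- remove_small_particles(m, spec$min_particle_area_um2, voxel)
  if (spec$exclude_edge_objects_3d) m <- filter_3d_edge_objects(m)
  solid <- m
  if (spec$outline != "none") m <- to_outline(m, spec$outline)
  structure(list(kind = "binary", mask = m, solid_mask = solid,
                 color = palette_rgb(spec$color), color_name = spec$color,
                 outline = spec$outline,
                 output_channel = spec$output_channel, spec = spec),
            class = "rendered_element")
}

render_element <- function(spec, stack) {
  if (inherits(spec, "grayscale_element")) render_grayscale_element(spec, stack)
  else render_binary_element(spec, stack)
}
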