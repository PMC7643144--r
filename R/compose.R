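# Output-channel composition under the element mixing rules: grayscale
# elements mix additively, binary elements never blend -- they are drawn in
# ascending color priority so the highest-priority color wins on overlaps,
# and outline elements overwrite only their outline voxels.

element_dims <- function(el) {
  if (el$kind == "binary") dim(el$mask) else dim(el$scalar)
}

#' Compose rendered elements into an RGB Z-stack
#'
#' Step 1 sums grayscale elements additively (clamped at 1). Step 2 draws
#' binary elements lowest-priority first, each overwriting prior content on
#' its nonzero voxels; outline elements carry only their outline ring, so
#' underlying content remains visible inside them.
#'
#' @param elements list of `rendered_element`s sharing one output channel.
#' @param priority color priority table (highest first).
#' @return RGB array `[y, x, z, rgb]` with values in `[0, 1]`.
#' @export
compose_channel <- function(elements, priority = default_color_priority()) {
  stopifnot(length(elements) >= 1)
  validate_color_priority(priority)
  dims <- element_dims(elements[[1]])
  for (el in elements) stopifnot(identical(element_dims(el), dims))
  out <- array(0, c(dims, 3))
  nvox <- prod(dims)
  gray <- Filter(function(e) e$kind == "grayscale", elements)
  bins <- Filter(function(e) e$kind == "binary", elements)
  for (el in gray) {
    for (k in 1:3) {
      out[seq_len(nvox) + (k - 1) * nvox] <-
        out[seq_len(nvox) + (k - 1) * nvox] + el$scalar * el$color[k]
    }
  }
  out <- clamp(out)
  if (length(bins) > 0) {
    ranks <- vapply(bins, function(e) color_rank(e$color_name, priority), numeric(1))
    if (anyDuplicated(ranks)) {
      coloc_log("output channel holds multiple binary elements of one color; they are indistinguishable by construction",
                level = "WARN")
    }
    for (el in bins[order(-ranks)]) { # lowest priority first
      vox <- which(el$mask)
      for (k in 1:3) out[vox + (k - 1) * nvox] <- el$color[k]
    }
  }
  out
}

#' Render a full output image from a settings descriptor
#'
#' Renders every element of the descriptor against the stack, composes each
#' output channel, and (for Z-stacks) computes the artifact-suppressing
#' Z-projection of each channel.
#'
#' @param stack an [intensity_stack()].
#' @param settings a [settings_descriptor()].
#' @param project compute Z-projections (default TRUE).
#' @return a `rendered_output`: list of per-channel lists with `$rgb`
#'   (`[y, x, z, rgb]`), `$projection` (`[y, x, rgb]` or NULL),
#'   `$projection_meta` (accepted objects), `$elements`; plus `$settings`,
#'   `$voxel`, `$name`.
#' @export
render_output <- function(stack, settings, project = TRUE) {
  stopifnot(inherits(stack, "intensity_stack"),
            inherits(settings, "settings_descriptor"))
  rendered <- lapply(settings$elements, render_element, stack = stack)
  out_idx <- vapply(rendered, function(e) e$output_channel, integer(1))
  channels <- vector("list", max(out_idx))
  for (ch in seq_len(max(out_idx))) {
    els <- rendered[out_idx == ch]
    if (length(els) == 0) {
      channels[[ch]] <- NULL
      next
    }
    rgb <- compose_channel(els, settings$color_priority)
    proj <- NULL
    meta <- NULL
    if (project) {
      pr <- project_channel(els, settings$projection_policy,
                            settings$color_priority)
      proj <- pr$rgb
      meta <- pr$objects
    }
    channels[[ch]] <- list(rgb = rgb, projection = proj,
                           projection_meta = meta, elements = els)
  }
  structure(list(channels = channels, settings = settings,
                 voxel = stack$voxel, name = stack$name),
            class = "rendered_output")
}
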