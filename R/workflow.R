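# The semi-automatic counting workflow formalized: detect target objects
# inside outline elements on the Z-projection, convert to overlays, then
# annotate further markers by detecting inside the existing overlays with
# ascending category digits -- the worked large-image procedure of the
# toolbox, minus the interactive verification step.

#' Semi-automatic colocalization counting on a rendered output
#'
#' Step 1 detects target objects (the first entry of `steps`) on the
#' Z-projection of its output channel, restricted to the interiors of
#' outline objects of `outline_color`, and converts every point to a new
#' overlay carrying the step's category digit. Each later step detects
#' again (typically a grayscale marker signal in another output channel),
#' keeps only points inside existing overlays, and adds its digit to the
#' hit overlays' category strings.
#'
#' @param rendered a [render_output()] result with projections.
#' @param steps list of steps, each `list(category = digit, channel =
#'   output channel index, params = detection_params())`.
#' @param outline_color palette color of the outline elements that restrict
#'   detection.
#' @param radius_px overlay radius for newly created overlays.
#' @param counts_dir optional Counts/ directory for operation logging.
#' @return overlay data.frame with accumulated category strings.
#' @export
count_colocalization <- function(rendered, steps, outline_color = "magenta",
                                 radius_px = 6, counts_dir = NULL) {
  stopifnot(inherits(rendered, "rendered_output"), length(steps) >= 1)
  overlays <- empty_overlays()
  first <- TRUE
  for (s in steps) {
    ch <- rendered$channels[[s$channel]]
    if (is.null(ch$projection)) {
      stop("output channel ", s$channel, " has no Z-projection", call. = FALSE)
    }
    mask <- outline_interior_mask(
      list(objects = ch$projection_meta, rgb = ch$projection), outline_color)
    pts <- find_maxima_2d(ch$projection, s$params, inside = mask)
    if (!first) pts <- toggle_point_filter(pts, overlays, "inside")
    overlays <- convert_multipoints(pts, overlays, "add", s$category,
                                    radius_px = radius_px,
                                    counts_dir = counts_dir)
    first <- FALSE
  }
  overlays
}
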