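#' The seven-color binary element palette
#'
#' Binary image elements are displayed in one of seven pure saturated colors.
#' Conflicts between overlapping binary elements are resolved by a color
#' priority table; the default order runs from brightest to faintest color.
#'
#' @return `palette_colors()` returns a named list mapping color name to an
#'   RGB triple in `[0, 1]`. `default_color_priority()` returns the default
#'   priority order (highest first).
#' @export
#' @examples
#' palette_colors()$magenta
#' default_color_priority()
palette_colors <- function() {
  list(
    white   = c(1, 1, 1),
    yellow  = c(1, 1, 0),
    cyan    = c(0, 1, 1),
    magenta = c(1, 0, 1),
    green   = c(0, 1, 0),
    red     = c(1, 0, 0),
    blue    = c(0, 0, 1)
  )
}

#' @rdname palette_colors
#' @export
default_color_priority <- function() {
  c("white", "yellow", "cyan", "magenta", "green", "red", "blue")
}

palette_rgb <- function(name) {
  pal <- palette_colors()
  if (!name %in% names(pal)) {
    stop("unknown palette color: '", name, "'", call. = FALSE)
  }
  pal[[name]]
}

# rank of a color in a priority table: 1 = highest priority
color_rank <- function(name, priority = default_color_priority()) {
  r <- match(name, priority)
  if (is.na(r)) stop("color '", name, "' missing from priority table", call. = FALSE)
  r
}

#' Validate a color priority table
#'
#' @param priority character vector of the seven palette color names,
#'   highest priority first.
#' @return the validated table, invisibly usable as-is.
#' @export
validate_color_priority <- function(priority) {
  want <- sort(default_color_priority())
  if (!identical(sort(priority), want)) {
    stop("color priority table must be a permutation of: ",
         paste(want, collapse = ", "), call. = FALSE)
  }
  priority
}
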