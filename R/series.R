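# Serial-section organization: assign Z levels to section images, rotate /
# translate XY coordinates into the shared series frame, jitter Z so objects
# do not line up strictly with section planes, summarize category counts,
# and score predictions against ground truth.

#' Series layout
#'
#' Physical layout of a serial-section series. The Z spacing in pixels is
#' derived as `round(section_interval * section_thickness_um / xy_um_per_px)`
#' so that Z uses the same unit as X and Y. Analyzing every 6th section of
#' 20 um at 0.21 um/px gives 120 um between sections, i.e. 571 px.
#'
#' @param section_interval every k-th section is analyzed.
#' @param section_thickness_um physical section thickness.
#' @param xy_um_per_px XY calibration of the images.
#' @param jitter_amplitude_px Z jitter amplitude; default
#'   [default_jitter()] of the spacing.
#' @param seed RNG seed for the jitter.
#' @return a `series_layout`.
#' @export
#' @examples
#' derive_z_spacing(series_layout(6, 20, 0.21)) # 571
series_layout <- function(section_interval, section_thickness_um, xy_um_per_px,
                          jitter_amplitude_px = NULL, seed = 1L) {
  stopifnot(section_interval > 0, section_thickness_um > 0, xy_um_per_px > 0)
  l <- structure(list(section_interval = section_interval,
                      section_thickness_um = section_thickness_um,
                      xy_um_per_px = xy_um_per_px,
                      seed = seed),
                 class = "series_layout")
  l$z_spacing_px <- derive_z_spacing(l)
  l$jitter_amplitude_px <- jitter_amplitude_px %||% default_jitter(l$z_spacing_px)
  l
}

#' Derive the Z spacing between sections in pixels
#'
#' @param layout a [series_layout()].
#' @return integer pixels: `round(interval * thickness / xy_um_per_px)`.
#' @export
derive_z_spacing <- function(layout) {
  if (layout$xy_um_per_px <= 0) stop("pixel size must be positive", call. = FALSE)
  as.integer(round(layout$section_interval * layout$section_thickness_um /
                     layout$xy_um_per_px))
}

#' Default Z jitter amplitude
#'
#' One third of the section spacing (floored), e.g. 571 px -> 190 px.
#'
#' @param z_spacing_px section spacing in pixels (> 0).
#' @return integer pixels.
#' @export
default_jitter <- function(z_spacing_px) {
  stopifnot(z_spacing_px > 0)
  as.integer(floor(z_spacing_px / 3))
}

#' Assign Z levels to counts across a section series
#'
#' @param counts_by_image named list of overlay/count data.frames (as from
#'   [load_counts()]), one per image.
#' @param image_order character vector giving the series order of the image
#'   names; every name in `counts_by_image` must appear here.
#' @param layout a [series_layout()].
#' @return a `series records` data.frame: `image`, `id`, `x`, `y`, `z`
#'   (pixels: series index * spacing), `category`.
#' @export
assign_z_levels <- function(counts_by_image, image_order, layout) {
  unknown <- setdiff(names(counts_by_image), image_order)
  if (length(unknown) > 0) {
    stop("image(s) not in the ordered list: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  spacing <- derive_z_spacing(layout)
  out <- lapply(names(counts_by_image), function(nm) {
    df <- counts_by_image[[nm]]
    lvl <- (match(nm, image_order) - 1L) * spacing
    data.frame(image = nm, id = df$id, x = df$x, y = df$y,
               z = rep(as.numeric(lvl), nrow(df)),
               category = as.character(df$category),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Translate and rotate section coordinates into the series frame
#'
#' Per image, coordinates are translated so that the recorded origin maps
#' to `(0, 0)`, then rotated so that the image's north vector maps to
#' screen-up `(0, -1)`. The transform is an isometry: pairwise distances
#' within an image are preserved.
#'
#' @param records series records (from [assign_z_levels()]).
#' @param origin_north named list per image: `list(origin = c(x0, y0),
#'   north = c(nx, ny))`.
#' @return records with transformed `x`, `y`.
#' @export
transform_xy <- function(records, origin_north) {
  for (nm in unique(records$image)) {
    on <- origin_north[[nm]]
    if (is.null(on)) {
      stop("missing origin/north for image '", nm, "'", call. = FALSE)
    }
    north <- on$north / sqrt(sum(on$north^2))
    # rotate current north angle onto -pi/2 (screen-up)
    delta <- -pi / 2 - atan2(north[2], north[1])
    R <- matrix(c(cos(delta), sin(delta), -sin(delta), cos(delta)), 2, 2)
    sel <- records$image == nm
    xy <- cbind(records$x[sel] - on$origin[1], records$y[sel] - on$origin[2])
    xy <- xy %*% t(R)
    records$x[sel] <- xy[, 1]
    records$y[sel] <- xy[, 2]
  }
  records
}

#' Add uniform Z jitter to series records
#'
#' Adds independent `Uniform[-amplitude/2, +amplitude/2]` noise to each
#' record's z so objects do not line up strictly with the section planes.
#' Reproducible given `seed`.
#'
#' @param records series records.
#' @param amplitude_px jitter amplitude in pixels (>= 0).
#' @param seed RNG seed.
#' @return records with jittered `z`.
#' @export
apply_z_jitter <- function(records, amplitude_px, seed = 1L) {
  stopifnot(amplitude_px >= 0)
  if (amplitude_px == 0 || nrow(records) == 0) return(records)
  u <- with_seed(seed, runif(nrow(records), -amplitude_px / 2, amplitude_px / 2))
  records$z <- records$z + u
  records
}

#' Summarize category counts
#'
#' @param records series records.
#' @return a `summary_table`: `$totals` (named per-category totals),
#'   `$per_image` (category x image count matrix), `$n` (grand total).
#' @export
summarize_records <- function(records) {
  if (nrow(records) == 0) {
    return(structure(list(totals = integer(0),
                          per_image = matrix(0L, 0, 0), n = 0L),
                     class = "summary_table"))
  }
  tab <- table(records$category, records$image)
  totals <- rowSums(tab)
  structure(list(totals = totals, per_image = unclass(tab),
                 n = nrow(records)),
            class = "summary_table")
}

#' @export
print.summary_table <- function(x, ...) {
  cat("Object count summary:", x$n, "objects\n")
  if (length(x$totals) > 0) {
    df <- data.frame(category = names(x$totals), total = as.integer(x$totals))
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Benchmark result arithmetic
#'
#' Accuracy is the percentage of correct assignments among all assignments
#' made (`correct + incorrect_markers + false_target`); omission is the
#' percentage of ground-truth target cells without a correct or
#' incorrect-marker assignment (`omitted / truth_total`). Percentages are
#' rounded half-up to one decimal.
#'
#' @param correct predictions matching a truth object with identical
#'   category.
#' @param incorrect_markers predictions matching a truth object with a
#'   different category.
#' @param false_target predictions not matching any truth object.
#' @param truth_total number of ground-truth target objects.
#' @return a `benchmark_result` with fields `correct`, `incorrect_markers`,
#'   `false_target`, `omitted`, `truth_total`, `pct_accurate`,
#'   `pct_omitted`.
#' @export
#' @examples
#' benchmark_result(223, 48, 8, 284)$pct_accurate # 79.9
benchmark_result <- function(correct, incorrect_markers, false_target,
                             truth_total) {
  omitted <- truth_total - correct - incorrect_markers
  assigned <- correct + incorrect_markers + false_target
  structure(list(correct = correct, incorrect_markers = incorrect_markers,
                 false_target = false_target, omitted = omitted,
                 truth_total = truth_total,
                 pct_accurate = round_half_up(100 * correct / assigned, 1),
                 pct_omitted = round_half_up(100 * omitted / truth_total, 1)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark: %d correct, %d incorrect markers, %d false targets, %d omitted of %d\n",
              x$correct, x$incorrect_markers, x$false_target, x$omitted,
              x$truth_total))
  cat(sprintf("  %% accurate assignments: %.1f\n  %% omitted: %.1f\n",
              x$pct_accurate, x$pct_omitted))
  invisible(x)
}

#' Score predicted overlays against ground truth
#'
#' Greedy nearest-neighbor matching in XY: candidate (prediction, truth)
#' pairs within `match_radius_px` are taken in order of ascending distance,
#' each prediction and each truth object matched at most once. A match with
#' identical category counts as correct, with differing category as an
#' incorrect-marker assignment; unmatched predictions are false targets and
#' unmatched truth objects omissions.
#'
#' @param predicted overlay data.frame (`x`, `y`, `category`).
#' @param truth truth overlay data.frame (`x`, `y`, `category`), e.g. from
#'   [truth_to_counts()].
#' @param match_radius_px maximum center distance for a match (> 0).
#' @return a [benchmark_result()].
#' @export
score_vs_truth <- function(predicted, truth, match_radius_px = 8) {
  stopifnot(match_radius_px > 0)
  np <- nrow(predicted); nt <- nrow(truth)
  if (np == 0) return(benchmark_result(0, 0, 0, nt))
  if (nt == 0) return(benchmark_result(0, 0, np, 0))
  d <- outer(predicted$x, truth$x, "-")^2 + outer(predicted$y, truth$y, "-")^2
  cand <- which(d <= match_radius_px^2, arr.ind = TRUE)
  ord <- order(d[cand])
  cand <- cand[ord, , drop = FALSE]
  p_used <- logical(np); t_used <- logical(nt)
  correct <- 0L; incorrect <- 0L
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, 1]; t <- cand[i, 2]
    if (p_used[p] || t_used[t]) next
    p_used[p] <- TRUE; t_used[t] <- TRUE
    if (identical(as.character(predicted$category[p]),
                  as.character(truth$category[t]))) {
      correct <- correct + 1L
    } else {
      incorrect <- incorrect + 1L
    }
  }
  benchmark_result(correct, incorrect, sum(!p_used), nt)
}

#' Export combined series data for 3D reconstruction
#'
#' Writes `objects.csv` (`image`, `id`, `x`, `y`, `z`, `category`) and
#' `contours.csv` (`image`, `contour`, `vertex`, `x`, `y`, `z`) into
#' `<out_dir>/Counts/Export/`.
#'
#' @param records transformed series records.
#' @param contours data.frame of contour vertices with columns `image`,
#'   `contour`, `vertex`, `x`, `y`, `z` (may have zero rows).
#' @param out_dir series directory.
#' @return named character vector of written paths, invisibly.
#' @export
export_combined <- function(records, contours, out_dir) {
  edir <- file.path(out_dir, "Counts", "Export")
  dir.create(edir, showWarnings = FALSE, recursive = TRUE)
  op <- file.path(edir, "objects.csv")
  cp <- file.path(edir, "contours.csv")
  write.csv(records[, c("image", "id", "x", "y", "z", "category")], op,
            row.names = FALSE)
  if (is.null(contours) || nrow(contours) == 0) {
    contours <- data.frame(image = character(), contour = character(),
                           vertex = integer(), x = numeric(), y = numeric(),
                           z = numeric())
  }
  write.csv(contours, cp, row.names = FALSE)
  invisible(c(objects = op, contours = cp))
}
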