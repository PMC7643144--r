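# Synthetic labeled-tissue generator. Emulates 4-channel neural tissue:
# channel 1 a nuclear stain present in every cell, channels 2 and 3 two
# cytoplasmic labels (A, B) in overlapping subsets of cells, channel 4 a
# nucleus-restricted marker (M) whose probability is conditional on A.
# Cells are spherical nuclei inside ellipsoidal somata; designated cells are
# transected at the stack faces, and designated pairs coincide in XY while
# being separated in Z (the classic source of Z-projection artifacts).

#' Parameters of the synthetic tissue generator
#'
#' Defaults describe a moderately packed embryonic-tissue-like field: 60
#' cells in a 128 x 128 x 16 voxel stack at 1 um/px, nuclei of 2-2.5 um
#' inside somata of 4-5 um (z semi-axis 60% of the XY radius), cytoplasmic
#' label A in 40% and B in 60% of cells (independently), nuclear marker M in
#' 85% of A-positive and 25% of A-negative cells, 10% of cells transected at
#' a Z face, labels at half the 16-bit dynamic range, 5% background, and
#' Gaussian noise of 2% of the range after a 1 px PSF blur. Cytoplasmic
#' labels bleed 1 px into the nuclear rim (small tracers cross the nuclear
#' envelope), which is also what makes nucleus-AND-label binarization
#' well-posed.
#'
#' @param nz,ny,nx stack shape in voxels.
#' @param voxel a [voxel_geometry()].
#' @param n_cells number of cells (including stacked pairs and transected
#'   cells).
#' @param nucleus_r_um,soma_r_um radius ranges (uniformly sampled).
#' @param soma_z_ratio z semi-axis of the soma relative to its XY radius.
#' @param p_A,p_B membership probabilities of the two cytoplasmic labels.
#' @param p_M_given_A,p_M_given_notA conditional probabilities of the
#'   nuclear marker.
#' @param fraction_edge_transected fraction of cells cut by a Z face.
#' @param n_stacked_pairs number of XY-coincident, Z-separated cell pairs
#'   (first member carries label A, second label B; at most `n_cells / 2`).
#' @param background background level as a fraction of the dynamic range.
#' @param noise_sd Gaussian noise sigma as a fraction of the dynamic range.
#' @param psf_blur_px Gaussian PSF sigma in pixels.
#' @param label_level label intensity as a fraction of the dynamic range.
#' @param nuclear_bleed_px cytoplasmic label bleed into the nuclear rim.
#' @param bit_depth 8 or 16.
#' @param seed RNG seed; generation is fully reproducible given the seed.
#' @return a `synth_params` list.
#' @export
synth_params <- function(nz = 16, ny = 128, nx = 128,
                         voxel = voxel_geometry(1, 1),
                         n_cells = 60,
                         nucleus_r_um = c(2, 2.5), soma_r_um = c(4, 5),
                         soma_z_ratio = 0.6,
                         p_A = 0.4, p_B = 0.6,
                         p_M_given_A = 0.85, p_M_given_notA = 0.25,
                         fraction_edge_transected = 0.1,
                         n_stacked_pairs = 0,
                         background = 0.05, noise_sd = 0.02,
                         psf_blur_px = 1, label_level = 0.5,
                         nuclear_bleed_px = 1,
                         bit_depth = 16, seed = 1L) {
  stopifnot(all(c(p_A, p_B, p_M_given_A, p_M_given_notA,
                  fraction_edge_transected) >= 0),
            all(c(p_A, p_B, p_M_given_A, p_M_given_notA,
                  fraction_edge_transected) <= 1),
            all(nucleus_r_um > 0), all(soma_r_um > 0),
            max(nucleus_r_um) < min(soma_r_um),
            n_stacked_pairs <= n_cells / 2,
            bit_depth %in% c(8, 16))
  structure(as.list(environment()), class = "synth_params")
}

# voxels of an ellipsoid (semi-axes in px) within the stack; returns linear
# indices into a [ny, nx, nz] array
ellipsoid_voxels <- function(cx, cy, cz, rx, ry, rz, dims) {
  ylo <- max(1, floor(cy + 1 - ry)); yhi <- min(dims[1], ceiling(cy + 1 + ry))
  xlo <- max(1, floor(cx + 1 - rx)); xhi <- min(dims[2], ceiling(cx + 1 + rx))
  zlo <- max(1, floor(cz + 1 - rz)); zhi <- min(dims[3], ceiling(cz + 1 + rz))
  if (ylo > yhi || xlo > xhi || zlo > zhi) return(integer(0))
  g <- expand.grid(y = ylo:yhi, x = xlo:xhi, z = zlo:zhi)
  d <- ((g$x - 1 - cx) / rx)^2 + ((g$y - 1 - cy) / ry)^2 +
    ((g$z - 1 - cz) / rz)^2
  sel <- d <= 1
  (g$y[sel]) + (g$x[sel] - 1) * dims[1] + (g$z[sel] - 1) * dims[1] * dims[2]
}

#' Generate a synthetic labeled tissue stack with ground truth
#'
#' @param params a [synth_params()].
#' @return list with `$stack` (an [intensity_stack()] of 4 channels:
#'   nuclei, label A, label B, marker M) and `$truth` (data.frame: `id`,
#'   `x`, `y`, `z` in 0-based pixels, `nucleus_r_px`, `soma_r_px`,
#'   `labels` (semicolon-joined subset of `A;B;M`), `fully_included`,
#'   `stacked_pair`).
#' @export
generate_stack <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  dims <- c(p$ny, p$nx, p$nz)
  with_seed(p$seed, {
    xyppx <- p$voxel$xy_um_per_px
    zppx <- p$voxel$z_step_um
    cells <- list()
    placed <- NULL # matrix: cx, cy, cz, rxy, rz (px)
    n_trans <- round(p$fraction_edge_transected *
                       (p$n_cells - 2 * p$n_stacked_pairs))
    n_regular <- p$n_cells - 2 * p$n_stacked_pairs - n_trans
    sample_radii <- function() {
      rn <- runif(1, p$nucleus_r_um[1], p$nucleus_r_um[2])
      rs <- runif(1, p$soma_r_um[1], p$soma_r_um[2])
      c(rn_xy = rn / xyppx, rn_z = rn / zppx,
        rs_xy = rs / xyppx, rs_z = rs * p$soma_z_ratio / zppx)
    }
    overlaps <- function(cx, cy, cz, rxy, rz) {
      if (is.null(placed)) return(FALSE)
      dxy2 <- (placed[, 1] - cx)^2 + (placed[, 2] - cy)^2
      dz <- abs(placed[, 3] - cz)
      any(dxy2 / (placed[, 4] + rxy)^2 + dz^2 / (placed[, 5] + rz)^2 < 1)
    }
    place <- function(kind) {
      r <- sample_radii()
      for (try in 1:2000) {
        cx <- runif(1, r["rs_xy"] + 1, p$nx - r["rs_xy"] - 2)
        cy <- runif(1, r["rs_xy"] + 1, p$ny - r["rs_xy"] - 2)
        if (kind == "interior") {
          if (p$nz == 1) {
            cz <- 0
          } else {
            lo <- r["rs_z"]; hi <- p$nz - 1 - r["rs_z"]
            if (hi < lo) stop("stack too shallow for fully included somata",
                              call. = FALSE)
            cz <- runif(1, lo, hi)
          }
        } else { # transected at a Z face
          top <- runif(1) < 0.5
          cz <- if (top) runif(1, 0, r["rs_z"] / 2)
                else runif(1, p$nz - 1 - r["rs_z"] / 2, p$nz - 1)
        }
        if (!overlaps(cx, cy, cz, r["rs_xy"], r["rs_z"])) {
          placed <<- rbind(placed, c(cx, cy, cz, r["rs_xy"], r["rs_z"]))
          return(c(cx = cx, cy = cy, cz = cz, r))
        }
      }
      stop("could not place cell after bounded retries; reduce n_cells",
           call. = FALSE)
    }
    sample_labels <- function(forced = NULL) {
      if (!is.null(forced)) return(forced)
      labs <- character(0)
      a <- runif(1) < p$p_A
      if (a) labs <- c(labs, "A")
      if (runif(1) < p$p_B) labs <- c(labs, "B")
      pm <- if (a) p$p_M_given_A else p$p_M_given_notA
      if (runif(1) < pm) labs <- c(labs, "M")
      labs
    }
    id <- 0L
    add_cell <- function(pos, labels, fully, pair) {
      id <<- id + 1L
      cells[[id]] <<- list(id = id, cx = pos["cx"], cy = pos["cy"],
                           cz = pos["cz"],
                           rn_xy = pos["rn_xy"], rn_z = pos["rn_z"],
                           rs_xy = pos["rs_xy"], rs_z = pos["rs_z"],
                           labels = labels, fully = fully, pair = pair)
    }
    for (i in seq_len(n_regular)) add_cell(place("interior"), sample_labels(),
                                           TRUE, NA_integer_)
    for (i in seq_len(n_trans)) add_cell(place("edge"), sample_labels(),
                                         FALSE, NA_integer_)
    for (k in seq_len(p$n_stacked_pairs)) {
      # two cells sharing XY, separated in Z: first near top with label A,
      # second near bottom with label B
      r1 <- sample_radii(); r2 <- sample_radii()
      ok <- FALSE
      for (try in 1:2000) {
        rxy <- max(r1["rs_xy"], r2["rs_xy"])
        cx <- runif(1, rxy + 1, p$nx - rxy - 2)
        cy <- runif(1, rxy + 1, p$ny - rxy - 2)
        z1 <- r1["rs_z"]
        z2 <- p$nz - 1 - r2["rs_z"]
        if (z2 - z1 <= r1["rs_z"] + r2["rs_z"]) {
          stop("stack too shallow for stacked pairs", call. = FALSE)
        }
        if (!overlaps(cx, cy, z1, r1["rs_xy"], r1["rs_z"]) &&
            !overlaps(cx, cy, z2, r2["rs_xy"], r2["rs_z"])) {
          placed <<- rbind(placed, c(cx, cy, z1, r1["rs_xy"], r1["rs_z"]),
                           c(cx, cy, z2, r2["rs_xy"], r2["rs_z"]))
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place stacked pair; reduce n_cells", call. = FALSE)
      add_cell(c(cx = unname(cx), cy = unname(cy), cz = unname(z1), r1),
               "A", TRUE, k)
      add_cell(c(cx = unname(cx), cy = unname(cy), cz = unname(z2), r2),
               "B", TRUE, k)
    }
    # paint channels
    chans <- lapply(1:4, function(i) array(0, dims))
    bleed <- p$nuclear_bleed_px
    for (cl in cells) {
      nuc <- ellipsoid_voxels(cl$cx, cl$cy, cl$cz, cl$rn_xy, cl$rn_xy,
                              cl$rn_z, dims)
      chans[[1]][nuc] <- 1
      if (any(c("A", "B") %in% cl$labels)) {
        soma <- ellipsoid_voxels(cl$cx, cl$cy, cl$cz, cl$rs_xy, cl$rs_xy,
                                 cl$rs_z, dims)
        core <- ellipsoid_voxels(cl$cx, cl$cy, cl$cz,
                                 max(cl$rn_xy - bleed, 0.5),
                                 max(cl$rn_xy - bleed, 0.5),
                                 max(cl$rn_z - bleed, 0.5), dims)
        shell <- setdiff(soma, core)
        if ("A" %in% cl$labels) chans[[2]][shell] <- 1
        if ("B" %in% cl$labels) chans[[3]][shell] <- 1
      }
      if ("M" %in% cl$labels) chans[[4]][nuc] <- 1
    }
    maxval <- 2^p$bit_depth - 1
    chans <- lapply(chans, function(v) {
      if (p$psf_blur_px > 0) v <- gaussian_blur_3d(v, p$psf_blur_px)
      v <- v * p$label_level + p$background
      if (p$noise_sd > 0) v <- v + rnorm(length(v), 0, p$noise_sd)
      round(clamp(v) * maxval)
    })
    truth <- data.frame(
      id = vapply(cells, function(cl) cl$id, integer(1)),
      x = vapply(cells, function(cl) unname(cl$cx), numeric(1)),
      y = vapply(cells, function(cl) unname(cl$cy), numeric(1)),
      z = vapply(cells, function(cl) unname(cl$cz), numeric(1)),
      nucleus_r_px = vapply(cells, function(cl) unname(cl$rn_xy), numeric(1)),
      soma_r_px = vapply(cells, function(cl) unname(cl$rs_xy), numeric(1)),
      labels = vapply(cells, function(cl) paste(cl$labels, collapse = ";"),
                      character(1)),
      fully_included = vapply(cells, function(cl) cl$fully, logical(1)),
      stacked_pair = vapply(cells, function(cl) cl$pair, integer(1)),
      stringsAsFactors = FALSE)
    list(stack = intensity_stack(chans, bit_depth = p$bit_depth,
                                 voxel = p$voxel, name = "synthetic"),
         truth = truth)
  })
}

#' Generate a synthetic serial-section series
#'
#' Writes one stack per section (TIFF + metadata sidecar), a tissue contour
#' polygon, origin/north CSVs, and the merged ground truth with a section
#' index. Sections share the series coordinate frame: origin at the image
#' center, north screen-up.
#'
#' @param params a [synth_params()] (per-section cell count etc.); section
#'   `k` is generated with seed `params$seed + k`.
#' @param n_sections number of sections (>= 1).
#' @param out_dir output directory (created).
#' @param contour_vertices vertex count of the elliptical tissue contour.
#' @return list with `$stacks` (in-memory), `$truth` (merged, with
#'   `section` and `image` columns), `$images` (section image names),
#'   `$dir`.
#' @export
generate_series <- function(params = synth_params(), n_sections = 3,
                            out_dir = tempfile("series"),
                            contour_vertices = 24) {
  stopifnot(n_sections >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stacks <- list()
  truths <- list()
  images <- character(n_sections)
  for (k in seq_len(n_sections)) {
    pk <- params
    pk$seed <- params$seed + k
    gen <- generate_stack(pk)
    nm <- sprintf("section_%02d", k)
    images[k] <- nm
    gen$stack$name <- nm
    write_stack(gen$stack, file.path(out_dir, paste0(nm, ".tif")))
    # elliptical tissue contour inscribed in the field
    th <- seq(0, 2 * pi, length.out = contour_vertices + 1)[-(contour_vertices + 1)]
    contour <- data.frame(x = params$nx / 2 + 0.45 * params$nx * cos(th),
                          y = params$ny / 2 + 0.45 * params$ny * sin(th))
    record_contours(list(tissue = contour), nm, out_dir)
    record_origin_north(c(params$nx / 2, params$ny / 2), c(0, -1), nm, out_dir)
    gen$truth$section <- k
    gen$truth$image <- nm
    stacks[[nm]] <- gen$stack
    truths[[nm]] <- gen$truth
  }
  truth <- do.call(rbind, truths)
  rownames(truth) <- NULL
  write.csv(truth, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  list(stacks = stacks, truth = truth, images = images, dir = out_dir)
}

#' Convert ground truth to expert count overlays
#'
#' One overlay per fully included cell; the category is the sorted digit
#' string of the cell's label memberships under `category_map`. Used as the
#' expert side of [score_vs_truth()].
#'
#' @param truth ground-truth data.frame from [generate_stack()].
#' @param category_map named vector mapping label names to digits, e.g.
#'   `c(B = 1, A = 2, M = 3)`.
#' @param radius_px overlay radius.
#' @return overlay data.frame (`id`, `x`, `y`, `z`, `radius_px`,
#'   `category`).
#' @export
truth_to_counts <- function(truth, category_map = c(B = 1, A = 2, M = 3),
                            radius_px = 8) {
  keep <- truth$fully_included
  tf <- truth[keep, , drop = FALSE]
  cats <- vapply(seq_len(nrow(tf)), function(i) {
    labs <- strsplit(tf$labels[i], ";")[[1]]
    labs <- labs[nzchar(labs)]
    unmapped <- setdiff(labs, names(category_map))
    if (length(unmapped) > 0) {
      stop("unmapped label(s): ", paste(unmapped, collapse = ", "),
           call. = FALSE)
    }
    if (length(labs) == 0) return(NA_character_)
    category_string(category_map[labs])
  }, character(1))
  out <- data.frame(id = tf$id, x = tf$x, y = tf$y, z = tf$z,
                    radius_px = radius_px, category = cats,
                    stringsAsFactors = FALSE)
  out[!is.na(out$category), , drop = FALSE]
}
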