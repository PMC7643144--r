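# The artifact-suppressing Z-projection. Binary objects stacked in Z at the
# same XY location are the classic source of false colocalization in maximum
# projections; here whole 3D objects are greedily accepted in order of stack
# position so that accepted footprints never overlap.

#' Label the 3D binary objects of a channel's elements
#'
#' Each binary element's solid (pre-outline) mask is decomposed into
#' 26-connected components. Every nonzero binary voxel belongs to exactly
#' one object.
#'
#' @param elements list of `rendered_element`s of one output channel.
#' @return list of `binary_object3d`: fields `id`, `element` (index),
#'   `voxels` (linear indices into the volume), `footprint` (logical
#'   `[y, x]`), `zmin`, `zmax`, `color`, `color_name`, `outline`.
#' @export
label_binary_objects <- function(elements) {
  objs <- list()
  id <- 0L
  for (ei in seq_along(elements)) {
    el <- elements[[ei]]
    if (el$kind != "binary") next
    lab <- label_components(el$solid_mask, connectivity = 26)
    n <- max(lab)
    if (n == 0) next
    dims <- dim(el$solid_mask)
    vox <- which(lab > 0)
    labs <- lab[vox]
    zidx <- (vox - 1L) %/% (dims[1] * dims[2]) + 1L
    rest <- (vox - 1L) %% (dims[1] * dims[2]) + 1L
    for (k in seq_len(n)) {
      sel <- labs == k
      fp <- matrix(FALSE, dims[1], dims[2])
      fp[rest[sel]] <- TRUE
      id <- id + 1L
      objs[[id]] <- structure(
        list(id = id, element = ei, voxels = vox[sel], footprint = fp,
             zmin = min(zidx[sel]), zmax = max(zidx[sel]),
             color = el$color, color_name = el$color_name,
             outline = el$outline),
        class = "binary_object3d")
    }
  }
  objs
}

#' Select the objects drawn in the Z-projection
#'
#' Objects are sorted by their representative slice (minimum z under the
#' `top` policy, maximum z under `bottom`), ties broken by color priority
#' (higher first) then by smaller object id, and accepted greedily; an
#' object is rejected entirely if its XY footprint intersects any already
#' accepted footprint. Accepted footprints are therefore pairwise disjoint.
#'
#' @param objects list from [label_binary_objects()].
#' @param policy `"top"` or `"bottom"`.
#' @param priority color priority table.
#' @return list with `$accepted` and `$rejected` object lists.
#' @export
select_projection_objects <- function(objects, policy = c("top", "bottom"),
                                      priority = default_color_priority()) {
  policy <- match.arg(policy)
  if (length(objects) == 0) return(list(accepted = list(), rejected = list()))
  zrep <- vapply(objects, function(o) {
    if (policy == "top") o$zmin else -o$zmax
  }, numeric(1))
  ranks <- vapply(objects, function(o) color_rank(o$color_name, priority),
                  numeric(1))
  ids <- vapply(objects, function(o) o$id, integer(1))
  ord <- order(zrep, ranks, ids)
  taken <- NULL
  accepted <- list()
  rejected <- list()
  for (i in ord) {
    o <- objects[[i]]
    if (is.null(taken)) {
      taken <- o$footprint
      accepted[[length(accepted) + 1]] <- o
    } else if (any(taken & o$footprint)) {
      rejected[[length(rejected) + 1]] <- o
    } else {
      taken <- taken | o$footprint
      accepted[[length(accepted) + 1]] <- o
    }
  }
  list(accepted = accepted, rejected = rejected)
}

# z-column map of a voxel set: for each footprint pixel, which z indices
voxel_columns <- function(voxels, dims) {
  zidx <- (voxels - 1L) %/% (dims[1] * dims[2]) + 1L
  pix <- (voxels - 1L) %% (dims[1] * dims[2]) + 1L
  list(pix = pix, z = zidx)
}

#' Artifact-suppressing Z-projection of one output channel
#'
#' Accepted non-outline binary objects are painted solid on their
#' footprints. Accepted outline objects are painted as the projected outline
#' of their footprint; the interior is filled only from content overlapping
#' the object's own voxel set in XYZ -- a binary fill picks, per pixel, the
#' overlapping binary object nearest the policy end (ties by color
#' priority), and a grayscale fill max-projects each grayscale element over
#' the outline object's voxel set. Outside all accepted footprints,
#' grayscale elements are max-projected over the full stack and additively
#' mixed. Single-plane stacks project to [compose_channel()] of the slice.
#'
#' @param elements list of `rendered_element`s of one output channel.
#' @param policy `"top"` or `"bottom"`.
#' @param priority color priority table.
#' @return list with `$rgb` (`[y, x, rgb]`) and `$objects` (the accepted
#'   `binary_object3d`s, with `$rejected` attached as an attribute).
#' @export
project_channel <- function(elements, policy = c("top", "bottom"),
                            priority = default_color_priority()) {
  policy <- match.arg(policy)
  dims <- element_dims(elements[[1]])
  if (dims[3] == 1) {
    rgb <- compose_channel(elements, priority)
    return(list(rgb = array(rgb, c(dims[1], dims[2], 3)), objects = list()))
  }
  gray <- Filter(function(e) e$kind == "grayscale", elements)
  objs <- label_binary_objects(elements)
  sel <- select_projection_objects(objs, policy, priority)
  npix <- dims[1] * dims[2]
  out <- array(0, c(dims[1], dims[2], 3))
  # background: full-stack grayscale max projection, additive
  for (el in gray) {
    m <- max_project(el$scalar)
    for (k in 1:3) out[, , k] <- out[, , k] + m * el$color[k]
  }
  out <- clamp(out)
  # accepted binary footprints replace background content entirely
  for (o in sel$accepted) {
    pix <- which(o$footprint)
    for (k in 1:3) out[pix + (k - 1) * npix] <- 0
  }
  for (o in sel$accepted) {
    if (o$outline == "none") {
      pix <- which(o$footprint)
      for (k in 1:3) out[pix + (k - 1) * npix] <- o$color[k]
    } else {
      r <- if (o$outline == "thin") 1 else 2
      ring <- o$footprint & !erode_mask_2d(o$footprint, r)
      interior <- o$footprint & !ring
      int_pix <- which(interior)
      if (length(int_pix) > 0) {
        fill <- project_outline_interior(o, objs, gray, dims, int_pix,
                                         policy, priority)
        for (k in 1:3) out[int_pix + (k - 1) * npix] <- fill[, k]
      }
      ring_pix <- which(ring)
      for (k in 1:3) out[ring_pix + (k - 1) * npix] <- o$color[k]
    }
  }
  attr(sel$accepted, "rejected") <- sel$rejected
  list(rgb = out, objects = sel$accepted)
}

# fill values for the interior pixels of one accepted outline object
project_outline_interior <- function(o, all_objs, gray, dims, int_pix,
                                     policy, priority) {
  npix <- dims[1] * dims[2]
  fill <- matrix(0, length(int_pix), 3)
  pos <- integer(npix) # interior pixel -> row of `fill`
  pos[int_pix] <- seq_along(int_pix)
  best_key <- rep(Inf, length(int_pix))
  best_rank <- rep(Inf, length(int_pix))
  best_obj <- rep(NA_integer_, length(int_pix))
  filled <- logical(length(int_pix))
  for (bi in seq_along(all_objs)) {
    b <- all_objs[[bi]]
    if (b$id == o$id) next
    common <- intersect(b$voxels, o$voxels)
    if (length(common) == 0) next
    cc <- voxel_columns(common, dims)
    keep <- pos[cc$pix] > 0
    if (!any(keep)) next
    rows <- pos[cc$pix[keep]]
    zkey <- if (policy == "top") cc$z[keep] else -cc$z[keep]
    # per interior pixel, the policy-nearest z of the overlap column
    kz <- tapply(zkey, rows, min)
    rws <- as.integer(names(kz))
    rank_b <- color_rank(b$color_name, priority)
    better <- (kz < best_key[rws]) |
      (kz == best_key[rws] & rank_b < best_rank[rws])
    rws <- rws[better]
    if (length(rws) > 0) {
      best_key[rws] <- kz[better]
      best_rank[rws] <- rank_b
      best_obj[rws] <- bi
      filled[rws] <- TRUE
    }
  }
  for (bi in unique(best_obj[!is.na(best_obj)])) {
    rws <- which(!is.na(best_obj) & best_obj == bi)
    fill[rws, ] <- matrix(all_objs[[bi]]$color, length(rws), 3, byrow = TRUE)
  }
  # grayscale fill where no binary fill: max over z within o's voxel set
  open <- which(!filled)
  if (length(open) > 0 && length(gray) > 0) {
    oc <- voxel_columns(o$voxels, dims)
    acc <- matrix(0, length(int_pix), 3)
    for (el in gray) {
      g <- numeric(length(int_pix))
      vals <- el$scalar[o$voxels]
      rows <- pos[oc$pix]
      ok <- rows > 0
      if (any(ok)) {
        mx <- tapply(vals[ok], rows[ok], max)
        g[as.integer(names(mx))] <- mx
      }
      for (k in 1:3) acc[, k] <- acc[, k] + g * el$color[k]
    }
    acc <- clamp(acc)
    fill[open, ] <- acc[open, ]
  }
  fill
}
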