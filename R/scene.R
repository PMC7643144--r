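# 3D reconstruction scene: category-colored point cloud plus an alpha-shape
# tissue surface built from contour vertices. The alpha complex keeps the
# Delaunay tetrahedra whose circumradius is at most alpha; its volume and
# boundary triangles are derived from that set. The tetrahedralization is a
# Bowyer-Watson incremental construction; input points receive a tiny
# deterministic perturbation (~1e-8 of the bounding box) so that cospherical
# degeneracies (e.g. the corners of a box) are resolved consistently.

circumsphere <- function(p) {
  a <- p[1, ]
  M <- 2 * sweep(p[2:4, , drop = FALSE], 2, a)
  b <- rowSums(p[2:4, , drop = FALSE]^2) - sum(a^2)
  det_m <- det(M)
  if (!is.finite(det_m) || abs(det_m) < 1e-12) {
    return(list(center = a, r2 = Inf))
  }
  center <- solve(M, b)
  list(center = center, r2 = sum((a - center)^2))
}

tet_faces <- function(tet) {
  list(sort(tet[c(1, 2, 3)]), sort(tet[c(1, 2, 4)]),
       sort(tet[c(1, 3, 4)]), sort(tet[c(2, 3, 4)]))
}

#' Delaunay tetrahedralization of a 3D point set
#'
#' @param pts numeric matrix `n x 3`.
#' @return integer matrix `m x 4` of point indices, one row per tetrahedron.
#' @export
delaunay3d <- function(pts) {
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 3)
  n <- nrow(pts)
  if (n < 4) return(matrix(integer(0), 0, 4))
  scale <- max(apply(pts, 2, function(v) diff(range(v))), 1)
  # deterministic symbolic-style perturbation against cospherical input
  pert <- outer(seq_len(n), 1:3, function(i, j) {
    sin(i * 12.9898 + j * 78.233) * 43758.5453
  })
  pert <- (pert - floor(pert) - 0.5) * 2e-8 * scale
  P <- pts + pert
  ctr <- colMeans(P)
  R <- max(sqrt(rowSums(sweep(P, 2, ctr)^2))) * 50 + scale
  super <- rbind(ctr + c(0, 0, 3 * R),
                 ctr + c(-2 * R, -R, -R),
                 ctr + c(2 * R, -R, -R),
                 ctr + c(0, 2 * R, -R))
  P <- rbind(P, super)
  sup_idx <- n + 1:4
  tets <- list(list(v = sup_idx, cs = circumsphere(P[sup_idx, ])))
  for (i in seq_len(n)) {
    p <- P[i, ]
    bad <- vapply(tets, function(t) {
      sum((p - t$cs$center)^2) <= t$cs$r2
    }, logical(1))
    if (!any(bad)) { # numerically lost point: attach to nearest tet
      d <- vapply(tets, function(t) sum((p - t$cs$center)^2) - t$cs$r2,
                  numeric(1))
      bad[which.min(d)] <- TRUE
    }
    boundary <- list()
    seen <- new.env(parent = emptyenv())
    for (t in tets[bad]) {
      for (f in tet_faces(t$v)) {
        key <- paste(f, collapse = "-")
        if (is.null(seen[[key]])) {
          seen[[key]] <- f
        } else {
          seen[[key]] <- NA # interior face, appears twice
        }
      }
    }
    for (key in ls(seen)) {
      f <- seen[[key]]
      if (!anyNA(f)) boundary[[length(boundary) + 1]] <- f
    }
    tets <- tets[!bad]
    for (f in boundary) {
      v <- c(f, i)
      tets[[length(tets) + 1]] <- list(v = v, cs = circumsphere(P[v, ]))
    }
  }
  keep <- vapply(tets, function(t) all(t$v <= n), logical(1))
  out <- t(vapply(tets[keep], function(t) sort(t$v), integer(4)))
  if (length(out) == 0) out <- matrix(integer(0), 0, 4)
  out
}

tet_volume <- function(pts, tet) {
  a <- pts[tet[1], ]; b <- pts[tet[2], ]; c_ <- pts[tet[3], ]; d <- pts[tet[4], ]
  abs(det(rbind(b - a, c_ - a, d - a))) / 6
}

#' Alpha shape of a 3D point set
#'
#' Keeps the Delaunay tetrahedra with circumradius <= `alpha`; for large
#' alpha this converges to the convex hull.
#'
#' @param pts numeric matrix `n x 3`.
#' @param alpha alpha radius, in the coordinate units of `pts` (> 0).
#' @return list with `$tetrahedra` (index matrix), `$volume`, `$faces`
#'   (boundary triangle index matrix), `$alpha`.
#' @export
alpha_shape3d <- function(pts, alpha) {
  stopifnot(alpha > 0)
  pts <- as.matrix(pts)
  tets <- delaunay3d(pts)
  if (nrow(tets) == 0) {
    return(list(tetrahedra = tets, volume = 0,
                faces = matrix(integer(0), 0, 3), alpha = alpha))
  }
  keep <- vapply(seq_len(nrow(tets)), function(i) {
    cs <- circumsphere(pts[tets[i, ], ])
    sqrt(cs$r2) <= alpha
  }, logical(1))
  tets <- tets[keep, , drop = FALSE]
  vol <- sum(vapply(seq_len(nrow(tets)), function(i) tet_volume(pts, tets[i, ]),
                    numeric(1)))
  face_tab <- list()
  for (i in seq_len(nrow(tets))) {
    for (f in tet_faces(tets[i, ])) {
      key <- paste(f, collapse = "-")
      face_tab[[key]] <- c(face_tab[[key]], i)
    }
  }
  bnd <- names(face_tab)[vapply(face_tab, length, integer(1)) == 1]
  faces <- if (length(bnd) > 0) {
    do.call(rbind, lapply(strsplit(bnd, "-"), as.integer))
  } else matrix(integer(0), 0, 3)
  list(tetrahedra = tets, volume = vol, faces = faces, alpha = alpha)
}

# fixed, documented category -> display color cycle
category_palette <- function(categories) {
  base <- c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00",
            "#A65628", "#F781BF", "#17BECF", "#BCBD22", "#999999")
  setNames(base[(seq_along(categories) - 1) %% length(base) + 1], categories)
}

#' Build a 3D reconstruction scene
#'
#' One scatter point per object record, colored by colocalization category
#' via a fixed palette cycle, plus an alpha-shape surface built jointly from
#' all contour vertices (per-section contours lofted by their z).
#'
#' @param objects data.frame with `x`, `y`, `z`, `category` (e.g.
#'   `Counts/Export/objects.csv`), or a path to such a CSV.
#' @param contours data.frame with `x`, `y`, `z` vertices (or CSV path);
#'   `NULL` or zero rows gives a points-only scene (logged).
#' @param point_size scatter point size recorded in the scene.
#' @param alpha alpha-shape radius in pixels.
#' @return a `scene3d`: `$points`, `$colors` (category -> color map),
#'   `$shape` (or `NULL`), `$point_size`, `$alpha`.
#' @export
build_scene <- function(objects, contours = NULL, point_size = 30, alpha = 1200) {
  if (is.character(objects)) {
    objects <- read.csv(objects, colClasses = c(category = "character"))
  }
  stopifnot(all(c("x", "y", "z", "category") %in% names(objects)))
  if (is.character(contours)) contours <- read.csv(contours)
  cats <- sort(unique(as.character(objects$category)))
  colors <- category_palette(cats)
  shape <- NULL
  if (is.null(contours) || nrow(contours) == 0) {
    coloc_log("build_scene: no contour rows; points-only scene")
  } else {
    cpts <- as.matrix(contours[, c("x", "y", "z")])
    shape <- alpha_shape3d(cpts, alpha)
    attr(shape, "pts") <- cpts
  }
  structure(list(points = objects, colors = colors, shape = shape,
                 point_size = point_size, alpha = alpha),
            class = "scene3d")
}

#' @export
print.scene3d <- function(x, ...) {
  cat(sprintf("<scene3d: %d points, %d categories, %s, point_size=%g, alpha=%g>\n",
              nrow(x$points), length(x$colors),
              if (is.null(x$shape)) "no surface"
              else sprintf("surface volume %.4g", x$shape$volume),
              x$point_size, x$alpha))
  invisible(x)
}

# orthographic projection used by the renderer
scene_project <- function(xyz, theta = -35, phi = 25) {
  t1 <- theta * pi / 180; t2 <- phi * pi / 180
  Rz <- matrix(c(cos(t1), sin(t1), 0, -sin(t1), cos(t1), 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(t2), sin(t2), 0, -sin(t2), cos(t2)), 3, 3)
  out <- xyz %*% t(Rz) %*% t(Rx)
  list(u = out[, 1], v = out[, 3], depth = out[, 2])
}

#' Render a scene to PNG or standalone HTML
#'
#' PNG output draws an orthographic view with base graphics (depth-sorted
#' translucent surface triangles, category-colored points, legend). HTML
#' output embeds the same PNG as a base64 image in a minimal standalone
#' page.
#'
#' @param scene a [build_scene()] scene.
#' @param path output path ending in `.png` or `.html`.
#' @param width,height device size in pixels.
#' @return `path`, invisibly.
#' @export
render_scene <- function(scene, path, width = 900, height = 700) {
  stopifnot(inherits(scene, "scene3d"))
  ext <- tolower(tools::file_ext(path))
  png_path <- if (ext == "png") path else tempfile(fileext = ".png")
  grDevices::png(png_path, width = width, height = height)
  ok <- FALSE
  on.exit(if (!ok) grDevices::dev.off(), add = TRUE)
  op <- par(mar = c(2, 2, 3, 8), xpd = NA)
  pts <- as.matrix(scene$points[, c("x", "y", "z")])
  pr <- scene_project(pts)
  xl <- range(pr$u); yl <- range(pr$v)
  plot(NA, xlim = xl, ylim = yl, asp = 1, axes = FALSE, xlab = "", ylab = "")
  title("3D reconstruction")
  if (!is.null(scene$shape) && nrow(scene$shape$faces) > 0 &&
      !is.null(attr(scene$shape, "pts"))) {
    sp <- attr(scene$shape, "pts")
    fpr <- scene_project(sp)
    depth <- vapply(seq_len(nrow(scene$shape$faces)), function(i) {
      mean(fpr$depth[scene$shape$faces[i, ]])
    }, numeric(1))
    for (i in order(-depth)) {
      f <- scene$shape$faces[i, ]
      polygon(fpr$u[f], fpr$v[f], col = grDevices::rgb(0.7, 0.7, 0.75, 0.25),
              border = grDevices::rgb(0.5, 0.5, 0.55, 0.35))
    }
  }
  cols <- scene$colors[as.character(scene$points$category)]
  points(pr$u, pr$v, pch = 19, col = cols,
         cex = sqrt(scene$point_size) / 3)
  legend("topright", inset = c(-0.12, 0), legend = names(scene$colors),
         col = scene$colors, pch = 19, title = "category", bty = "n")
  par(op)
  grDevices::dev.off()
  ok <- TRUE
  if (ext == "html") {
    b64 <- jsonlite::base64_enc(readBin(png_path, "raw",
                                        file.info(png_path)$size))
    html <- paste0("<!DOCTYPE html><html><head><title>3D reconstruction</title>",
                   "</head><body><img alt='3D reconstruction scene' src=",
                   "'data:image/png;base64,", gsub("\n", "", b64),
                   "'/></body></html>")
    writeLines(html, path)
    unlink(png_path)
  }
  invisible(path)
}
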