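# Maxima detection against brute-force oracles, the three counting modes,
# point filtering, and the Counts/ persistence layer.

test_that("2D detection handles blobs, plateaus and constant planes", {
  expect_equal(nrow(find_maxima_2d(matrix(5, 16, 16),
                                   detection_params(noise_tolerance = 1))), 0)
  # two well-separated Gaussian blobs of amplitude 100
  m <- matrix(0, 40, 40)
  for (y in 1:40) for (x in 1:40) {
    m[y, x] <- 100 * exp(-((y - 10)^2 + (x - 10)^2) / 8) +
      100 * exp(-((y - 30)^2 + (x - 28)^2) / 8)
  }
  pts <- find_maxima_2d(m, detection_params(noise_tolerance = 50))
  expect_equal(nrow(pts), 2)
  pts <- pts[order(pts$y), ]
  expect_lte(max(abs(pts$x - c(9, 27))), 1)
  expect_lte(max(abs(pts$y - c(9, 29))), 1)
  # twin peaks 100/100 with saddle 80
  tp <- matrix(0, 9, 21)
  tp[5, 5] <- 100; tp[5, 17] <- 100; tp[5, 6:16] <- 80
  expect_equal(nrow(find_maxima_2d(tp, detection_params(noise_tolerance = 10))), 2)
  expect_equal(nrow(find_maxima_2d(tp, detection_params(noise_tolerance = 30))), 1)
  # a flat-topped plateau yields a single centroid point
  pl <- matrix(0, 11, 11); pl[4:8, 4:8] <- 10
  p <- find_maxima_2d(pl, detection_params(noise_tolerance = 5))
  expect_equal(nrow(p), 1)
  expect_equal(c(p$x, p$y), c(5, 5))
})

test_that("2D detection matches the brute-force prominence oracle", {
  set.seed(71)
  for (i in 1:25) {
    ny <- sample(8:20, 1); nx <- sample(8:20, 1)
    m <- matrix(runif(ny * nx), ny, nx)
    m <- colocbox:::gaussian_blur_2d(m, 0.8) # smooth; continuous values
    tol <- runif(1, 0.01, 0.2)
    got <- find_maxima_2d(m, detection_params(noise_tolerance = tol))
    got <- got[order(got$y, got$x), c("x", "y")]
    want <- oracle_prominence_maxima(m, tol)
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  }
})

test_that("light background and edge exclusion act before/after detection", {
  m <- matrix(100, 15, 15)
  m[8, 8] <- 0 # dark blob on light background
  pts <- find_maxima_2d(m, detection_params(noise_tolerance = 50,
                                            light_background = TRUE))
  expect_equal(c(pts$x, pts$y), c(7, 7))
  e <- matrix(0, 10, 10); e[1, 5] <- 50; e[6, 6] <- 40
  pe <- find_maxima_2d(e, detection_params(noise_tolerance = 5,
                                           exclude_on_edges = TRUE))
  expect_equal(nrow(pe), 1)
  expect_equal(c(pe$x, pe$y), c(5, 5))
})

test_that("3D detection matches the sliding-neighborhood oracle", {
  # single bright voxel
  v <- array(0, c(6, 6, 6)); v[3, 4, 2] <- 7
  p <- find_maxima_3d(v, detection_params(noise_tolerance = 5))
  expect_equal(unname(unlist(p)), c(3, 2, 1)) # 0-based x, y, z
  # two blobs separated by more than the radius
  v2 <- array(0, c(12, 12, 8)); v2[3, 3, 2] <- 5; v2[10, 10, 6] <- 6
  p2 <- find_maxima_3d(v2, detection_params(noise_tolerance = 1,
                                            radius_xyz = c(2, 2, 2)))
  expect_equal(nrow(p2), 2)
  # equal-valued grid closer than the radius: raster-order tie-break
  v3 <- array(0, c(8, 8, 4))
  v3[c(3, 5), c(3, 5), 2] <- 4
  p3 <- find_maxima_3d(v3, detection_params(noise_tolerance = 1,
                                            radius_xyz = c(3, 3, 2)))
  expect_equal(nrow(p3), 1)
  expect_equal(unname(unlist(p3)), c(2, 2, 1))
  set.seed(73)
  for (i in 1:12) {
    dims <- c(sample(6:12, 1), sample(6:12, 1), sample(4:8, 1))
    v <- array(sample(0:9, prod(dims), replace = TRUE), dims)
    r <- c(sample(1:3, 1), sample(1:3, 1), sample(1:2, 1))
    tol <- sample(2:6, 1)
    got <- find_maxima_3d(v, detection_params(noise_tolerance = tol,
                                              radius_xyz = r))
    want <- oracle_maxima_3d(v, tol, r[1], r[2], r[3])
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  }
})

test_that("category strings assemble via repeated add conversions", {
  ov <- empty_overlays()
  pt <- data.frame(x = 10, y = 10, z = NA_integer_)
  ov <- convert_multipoints(pt, ov, "add", 3, radius_px = 6)
  ov <- convert_multipoints(pt, ov, "add", 5)
  ov <- convert_multipoints(pt, ov, "add", 8)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$category, "358")
  # adding an existing digit is idempotent
  ov <- convert_multipoints(pt, ov, "add", 5)
  expect_equal(ov$category, "358")
  # set mode is last-writer-wins
  ov <- convert_multipoints(pt, ov, "set", 2)
  expect_equal(ov$category, "2")
  # outside points create new overlays with fresh ids
  far <- data.frame(x = 40, y = 40, z = NA_integer_)
  ov <- convert_multipoints(far, ov, "add", 1, radius_px = 6)
  expect_equal(nrow(ov), 2)
  expect_equal(ov$id, c(1L, 2L))
})

test_that("delete mode removes exactly the marked overlays", {
  ov <- empty_overlays()
  for (i in 1:3) {
    ov <- convert_multipoints(data.frame(x = 20 * i, y = 10, z = NA_integer_),
                              ov, "add", 1, radius_px = 5)
  }
  ov2 <- convert_multipoints(data.frame(x = 40, y = 10, z = NA_integer_),
                             ov, "delete")
  expect_equal(ov2$id, c(1L, 3L))
  # a point outside all overlays deletes nothing
  ov3 <- convert_multipoints(data.frame(x = 90, y = 90, z = NA_integer_),
                             ov, "delete")
  expect_equal(nrow(ov3), 3)
})

test_that("z-specific points only hit overlays on their slice", {
  ov <- convert_multipoints(data.frame(x = 10, y = 10, z = 3L),
                            empty_overlays(), "add", 1, radius_px = 5)
  # same XY, different slice: new overlay
  ov <- convert_multipoints(data.frame(x = 10, y = 10, z = 5L), ov, "add", 2,
                            radius_px = 5)
  expect_equal(nrow(ov), 2)
  # all-slices point hits both... nearest center wins; same center, so id 1
  ov2 <- convert_multipoints(data.frame(x = 10, y = 10, z = NA_integer_),
                             ov, "add", 4)
  expect_equal(ov2$category, c("14", "2"))
})

test_that("toggle_point_filter partitions points", {
  expect_equal(nrow(toggle_point_filter(empty_overlays()[, 2:4],
                                        empty_overlays(), "inside")), 0)
  set.seed(79)
  pts <- data.frame(x = runif(40, 0, 50), y = runif(40, 0, 50),
                    z = NA_integer_)
  ov <- convert_multipoints(data.frame(x = c(10, 30), y = c(10, 30),
                                       z = NA_integer_),
                            empty_overlays(), "add", 1, radius_px = 12)
  expect_identical(toggle_point_filter(pts, ov, "all"), pts)
  ins <- toggle_point_filter(pts, ov, "inside")
  outs <- toggle_point_filter(pts, ov, "outside")
  expect_equal(nrow(ins) + nrow(outs), nrow(pts))
  expect_length(intersect(rownames(ins), rownames(outs)), 0)
  # exhaustive membership check
  for (i in seq_len(nrow(pts))) {
    inside <- any((pts$x[i] - ov$x)^2 + (pts$y[i] - ov$y)^2 <= 12^2)
    expect_equal(inside, rownames(pts)[i] %in% rownames(ins))
  }
})

test_that("counts round-trip through the Counts/ CSV layer", {
  dir <- withr::local_tempdir()
  ov <- empty_overlays()
  expect_equal(nrow(ov), 0)
  p <- save_counts(ov, "img1", dir)
  expect_true(file.exists(p))
  expect_equal(nrow(load_counts(p)), 0) # header-only CSV
  set.seed(83)
  n <- 284
  ov <- data.frame(id = 1:n, x = runif(n, 0, 500), y = runif(n, 0, 500),
                   z = NA_integer_, radius_px = 8,
                   category = sample(c("1", "12", "13", "123"), n, TRUE),
                   stringsAsFactors = FALSE)
  p <- save_counts(ov, "img2", dir)
  back <- load_counts(p)
  expect_equal(nrow(back), n)
  expect_equal(back$x, ov$x)
  expect_equal(back$category, ov$category) # "13" stays text, not 13
  expect_type(back$category, "character")
  expect_true(file.exists(file.path(dir, "Counts", "Counting_log.txt")))
  log <- readLines(file.path(dir, "Counts", "Counting_log.txt"))
  expect_true(any(grepl("save_counts image=img2", log)))
})

test_that("origin/north and contours round-trip; north is normalized", {
  dir <- withr::local_tempdir()
  p <- record_origin_north(c(100, 120), c(0, -1), "imgA", dir)
  on <- load_origin_north(p)
  expect_equal(on$origin, c(100, 120))
  expect_equal(on$north, c(0, -1))
  expect_warning(p2 <- record_origin_north(c(0, 0), c(3, 4), "imgB", dir),
                 "normaliz")
  on2 <- load_origin_north(p2)
  expect_equal(sqrt(sum(on2$north^2)), 1)
  expect_equal(on2$north, c(0.6, 0.8))
  sq <- data.frame(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  tri <- data.frame(x = c(2, 8, 5), y = c(2, 2, 9))
  cp <- record_contours(list(outer = sq, inner = tri), "imgA", dir)
  got <- load_contours(cp)
  expect_equal(nrow(got$outer), 4)
  expect_equal(got$outer$x, sq$x)
  expect_equal(got$inner, tri, ignore_attr = TRUE)
  expect_error(record_contours(list(bad = sq[1:2, ]), "imgA", dir), ">= 3")
})

test_that("automatic detection inside outlines recovers nearly all targets", {
  # projection-mode detection restricted to the outlines of nucleus-AND-B
  # objects recovers >= 95% of non-abutting targets with no duplicates
  g <- generate_stack(synth_params(n_cells = 30, ny = 128, nx = 128, nz = 12,
                                   seed = 29))
  sdsc <- settings_descriptor(list(
    binary_element(c(1, 3), thresholds = 0.25 * 65535, outline = "thick",
                   color = "magenta", output_channel = 1)))
  out <- render_output(g$stack, sdsc)
  ch <- out$channels[[1]]
  mask <- outline_interior_mask(list(objects = ch$projection_meta,
                                     rgb = ch$projection), "magenta")
  pts <- find_maxima_2d(ch$projection,
                        detection_params(noise_tolerance = 0.05,
                                         pre_blur_radius = 2,
                                         color_to_detect = "magenta"),
                        inside = mask)
  truth <- g$truth[grepl("B", g$truth$labels), ]
  expected <- length(ch$projection_meta) # accepted target objects
  expect_gte(nrow(pts), ceiling(0.95 * expected))
  expect_lte(nrow(pts), expected) # zero duplicates
  # every point sits within a truth nucleus footprint
  d2 <- outer(pts$x, truth$x, "-")^2 + outer(pts$y, truth$y, "-")^2
  expect_true(all(apply(d2, 1, min) <= (truth$soma_r_px[1] + 2)^2))
})
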