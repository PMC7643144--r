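# Stage operations of the element engine against brute-force oracles, and
# the composition / mixing rules.

test_that("manual thresholding is an inclusive per-voxel comparison", {
  expect_false(any(binarize(matrix(0, 4, 4), 1)))
  pl <- matrix(c(0, 10, 20, 30, 40, 50, 60, 70, 80), 3, 3, byrow = TRUE)
  expect_equal(sum(binarize(pl, 40)), 5)
  expect_equal(unname(which(binarize(pl, 40))), which(as.vector(pl) >= 40))
})

test_that("auto threshold matches the iterative-intermeans fixpoint oracle", {
  set.seed(7)
  for (i in 1:10) {
    v <- c(rnorm(300, 20, 4), rnorm(120, 200, 12))
    v <- pmin(pmax(round(v), 0), 255)
    vol <- array(v, c(21, 10, 2))
    got <- binarize(vol, "auto")
    # oracle: iterate the intermeans update to its fixpoint
    t_or <- mean(v)
    repeat {
      t_new <- (mean(v[v < t_or]) + mean(v[v >= t_or])) / 2
      if (abs(t_new - t_or) < 1e-9) break
      t_or <- t_new
    }
    expect_true(attr(got, "level") > 20 && attr(got, "level") < 200)
    expect_equal(as.vector(got), as.vector(vol >= t_or))
    # mask equals the manual mask at the computed level
    expect_equal(as.vector(got), as.vector(binarize(vol, attr(got, "level"))))
  }
  expect_warning(out <- binarize(array(5, c(3, 3, 1)), "auto"), "constant")
  expect_false(any(out))
})

test_that("combine_and and subtract_not equal per-voxel brute force", {
  set.seed(11)
  a <- array(runif(4 * 5 * 3) < 0.5, c(4, 5, 3))
  b <- array(runif(4 * 5 * 3) < 0.5, c(4, 5, 3))
  expect_equal(combine_and(list(a, a)), a, ignore_attr = TRUE)
  expect_equal(as.vector(combine_and(list(a, b))), as.vector(a) & as.vector(b))
  d1 <- array(FALSE, c(4, 4, 1)); d1[1:2, 1:2, 1] <- TRUE
  d2 <- array(FALSE, c(4, 4, 1)); d2[3:4, 3:4, 1] <- TRUE
  expect_false(any(combine_and(list(d1, d2))))
  expect_error(combine_and(list()), "non-empty")
  expect_identical(subtract_not(a, list()), a)
  expect_false(any(subtract_not(a, list(a | b))))
  expect_equal(as.vector(subtract_not(a, list(b))),
               as.vector(a) & !as.vector(b))
})

test_that("filters match morphological oracles", {
  sq <- matrix(FALSE, 9, 9); sq[3:7, 3:7] <- TRUE
  expect_identical(apply_filters(sq, list()), sq)
  er <- apply_filters(sq, list(filter_op("minimum", 1)))
  expect_equal(sum(er), 9) # 5x5 square erodes to 3x3
  ring <- matrix(FALSE, 11, 11); ring[3:9, 3:9] <- TRUE; ring[5:7, 5:7] <- FALSE
  expect_equal(apply_filters(ring, list(filter_op("fill_holes"))),
               oracle_fill_holes(ring))
  set.seed(23)
  for (i in 1:8) {
    m <- random_mask2d(c(16, 16), 0.55)
    for (r in 1:2) {
      expect_equal(apply_filters(m, list(filter_op("minimum", r))),
                   oracle_erode(m, r))
    }
    expect_equal(apply_filters(m, list(filter_op("fill_holes"))),
                 oracle_fill_holes(m))
  }
  expect_error(apply_filters(sq, list(list(kind = "sharpen", radius = 1))),
               "sharpen")
})

test_that("small-particle removal applies the physical area rule", {
  m <- matrix(FALSE, 12, 12)
  m[2, 2] <- TRUE; m[5, 5] <- TRUE # single-pixel particles
  m[8:11, 8:11] <- TRUE # 16 px
  vox <- voxel_geometry(1, 1)
  expect_identical(remove_small_particles(m, 0, vox), m)
  out <- remove_small_particles(m, 2, vox) # below 2 um^2 = 2 px removed
  expect_equal(sum(out), 16)
  # the worked calibration: at 0.21 um/px, 20 um^2 = 453.5 px
  vox2 <- voxel_geometry(0.21, 1)
  big <- matrix(FALSE, 40, 40); big[1:20, 1:25] <- TRUE # 500 px kept
  small <- matrix(FALSE, 30, 30)
  small[cbind(rep(1:21, each = 21), rep(1:21, 21))[1:441, ]] <- TRUE
  expect_equal(sum(remove_small_particles(big, 20, vox2)), 500)
  expect_equal(sum(remove_small_particles(small, 20, vox2)), 0) # 441 < 454
  # threshold pixel count: ceil(20 / 0.21^2) = 454 is kept
  just <- matrix(FALSE, 40, 40)
  just[cbind(rep(1:22, each = 22), rep(1:22, 22))[1:454, ]] <- TRUE
  expect_equal(sum(remove_small_particles(just, 20, vox2)), 454)
  # oracle check on random scenes
  set.seed(31)
  for (i in 1:6) {
    m <- random_mask2d(c(20, 20), 0.3)
    lab <- oracle_label(m, 8)
    keep_or <- m
    for (k in seq_len(max(lab))) {
      if (sum(lab == k) < 5) keep_or[lab == k] <- FALSE
    }
    expect_equal(remove_small_particles(m, 5, vox), keep_or)
  }
})

test_that("3D edge-object filter drops exactly the face-touching components", {
  a <- array(FALSE, c(6, 6, 6)); a[3, 3, 3] <- TRUE
  expect_identical(filter_3d_edge_objects(a), a) # interior voxel kept
  b <- array(FALSE, c(6, 6, 6)); b[2:3, 2:3, 1:2] <- TRUE # touches z = 0 face
  expect_false(any(filter_3d_edge_objects(b)))
  set.seed(37)
  for (i in 1:8) {
    m <- random_mask3d(c(10, 10, 6), n_seeds = 5, radius = 2)
    got <- filter_3d_edge_objects(m)
    lab <- oracle_label(m, 26)
    d <- dim(m)
    expect_true(all(got <= m)) # monotone: never adds voxels
    surv <- 0L
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k, arr.ind = TRUE)
      touches <- any(idx[, 1] %in% c(1, d[1])) || any(idx[, 2] %in% c(1, d[2])) ||
        any(idx[, 3] %in% c(1, d[3]))
      if (!touches) surv <- surv + 1L
      expect_equal(any(got[idx]), !touches)
    }
    expect_equal(max(oracle_label(got, 26)), surv)
  }
})

test_that("outline conversion equals the erosion-difference oracle", {
  expect_false(any(to_outline(matrix(FALSE, 6, 6), "thin")))
  sq <- matrix(FALSE, 9, 9); sq[3:7, 3:7] <- TRUE
  expect_equal(sum(to_outline(sq, "thin")), 16)
  expect_equal(sum(to_outline(sq, "thick")), 24)
  set.seed(43)
  for (i in 1:6) {
    m <- random_mask2d(c(18, 18), 0.5)
    expect_equal(to_outline(m, "thin"), m & !oracle_erode(m, 1))
    expect_equal(to_outline(m, "thick"), m & !oracle_erode(m, 2))
  }
})

test_that("grayscale rendering rescales, colors and mixes additively", {
  chans <- list(array(c(0, 50, 100, 200), c(2, 2, 1)),
                array(100, c(2, 2, 1)),
                array(100, c(2, 2, 1)))
  st <- intensity_stack(chans, bit_depth = 8, name = "g")
  # one channel, full range, white: a normalized copy
  el <- render_grayscale_element(grayscale_element(1, c(0, 200), "white"), st)
  expect_equal(as.vector(el$scalar), c(0, 0.25, 0.5, 1))
  # values below display min clamp to zero
  el2 <- render_grayscale_element(grayscale_element(1, c(60, 200), "white"), st)
  expect_equal(el2$scalar[1, 1, 1], 0)
  expect_equal(el2$scalar[2, 1, 1], 0)
  # two half-intensity channels colored red + blue give half magenta
  sdsc <- settings_descriptor(list(
    grayscale_element(2, c(0, 200), "red"),
    grayscale_element(3, c(0, 200), "blue")
  ))
  out <- render_output(st, sdsc, project = FALSE)
  px <- out$channels[[1]]$rgb[1, 1, 1, ]
  expect_equal(px, c(0.5, 0, 0.5))
  # multi-input mixing is discouraged and warns
  expect_warning(
    render_grayscale_element(grayscale_element(c(2, 3), c(0, 200)), st),
    "discouraged")
  expect_error(grayscale_element(1, c(10, 10)), "min < max")
})

test_that("binary rendering equals the hand-sequenced stage composition", {
  set.seed(47)
  for (i in 1:5) {
    g <- generate_stack(small_synth(8, ny = 40, nx = 40, noise_sd = 0, seed = 100 + i))
    st <- g$stack
    lev <- 0.25 * 65535
    spec <- binary_element(c(1, 3), not_channels = 4, thresholds = lev,
                           filters = list(filter_op("minimum", 1),
                                          filter_op("fill_holes")),
                           min_particle_area_um2 = 2,
                           exclude_edge_objects_3d = TRUE,
                           color = "green")
    el <- render_binary_element(spec, st)
    manual <- combine_and(list(binarize(st$channels[[1]], lev),
                               binarize(st$channels[[3]], lev)))
    manual <- subtract_not(manual, list(binarize(st$channels[[4]], lev)))
    manual <- apply_filters(manual, spec$filters)
    manual <- remove_small_particles(manual, 2, st$voxel)
    manual <- filter_3d_edge_objects(manual)
    expect_equal(as.vector(el$mask), as.vector(manual))
    # trivial reduction: all options off = colorized binarization
    sp0 <- binary_element(1, thresholds = lev, color = "red")
    el0 <- render_binary_element(sp0, st)
    expect_equal(as.vector(el0$mask), as.vector(binarize(st$channels[[1]], lev)))
    expect_equal(el0$color, c(1, 0, 0))
  }
})

test_that("channel composition obeys the priority rules (oracle)", {
  # white over green on overlap
  m1 <- array(FALSE, c(6, 6, 2)); m1[2:4, 2:4, 1] <- TRUE
  m2 <- array(FALSE, c(6, 6, 2)); m2[3:5, 3:5, 1] <- TRUE
  els <- list(mock_binary_el(m1, "green"), mock_binary_el(m2, "white"))
  rgb <- compose_channel(els)
  expect_equal(rgb[3, 3, 1, ], c(1, 1, 1)) # white wins the overlap
  expect_equal(rgb[2, 2, 1, ], c(0, 1, 0))
  # single grayscale element passes through
  sc <- array(runif(6 * 6 * 2), c(6, 6, 2))
  gel <- mock_gray_el(sc, "white")
  rgbg <- compose_channel(list(gel))
  expect_equal(rgbg[, , , 1], sc)
  # random scenes: 3 binaries + 1 grayscale vs voxel-wise oracle
  set.seed(53)
  for (i in 1:6) {
    dims <- c(7, 7, 3)
    els <- list(
      mock_binary_el(array(runif(prod(dims)) < 0.3, dims), "red"),
      mock_binary_el(array(runif(prod(dims)) < 0.3, dims), "cyan"),
      mock_binary_el(array(runif(prod(dims)) < 0.3, dims), "yellow",
                     outline = "thin"),
      mock_gray_el(array(runif(prod(dims)), dims), "magenta"))
    pri <- sample(default_color_priority())
    got <- compose_channel(els, pri)
    expect_equal(got, oracle_compose(els, pri))
  }
})

test_that("binary colors never blend where any binary mask is true", {
  set.seed(59)
  pal <- palette_colors()
  dims <- c(8, 8, 2)
  els <- list(
    mock_binary_el(array(runif(prod(dims)) < 0.4, dims), "green"),
    mock_binary_el(array(runif(prod(dims)) < 0.4, dims), "red"),
    mock_gray_el(array(runif(prod(dims)), dims), "white"))
  rgb <- compose_channel(els)
  anybin <- els[[1]]$mask | els[[2]]$mask
  for (v in which(anybin)) {
    z <- (v - 1) %/% 64 + 1; rest <- (v - 1) %% 64
    x <- rest %/% 8 + 1; y <- rest %% 8 + 1
    px <- rgb[y, x, z, ]
    expect_true(any(vapply(pal, function(p) all(p == px), logical(1))))
  }
})

test_that("a verification channel reproduces the rescaled input exactly", {
  g <- generate_stack(small_synth(6, nz = 6, seed = 9))
  sdsc <- settings_descriptor(list(
    grayscale_element(3, c(0, 65535), "white", output_channel = 1)))
  out <- render_output(g$stack, sdsc, project = FALSE)
  expect_equal(out$channels[[1]]$rgb[, , , 2],
               g$stack$channels[[3]] / 65535)
})
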