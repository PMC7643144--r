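# Fixture builders: mock rendered elements and small random scenes, all
# generated in code under fixed seeds.

mock_binary_el <- function(mask, color = "green", outline = "none") {
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1L)
  final <- if (outline == "none") mask else to_outline(mask, outline)
  structure(list(kind = "binary", mask = final, solid_mask = mask,
                 color = palette_colors()[[color]], color_name = color,
                 outline = outline, output_channel = 1L, spec = NULL),
            class = "rendered_element")
}

mock_gray_el <- function(scalar, color = "white") {
  if (is.matrix(scalar)) dim(scalar) <- c(dim(scalar), 1L)
  col <- if (is.character(color)) palette_colors()[[color]] else color
  structure(list(kind = "grayscale", scalar = scalar, color = col,
                 color_name = NA_character_, outline = "none",
                 output_channel = 1L, spec = NULL),
            class = "rendered_element")
}

# synthetic params scaled for small test stacks (shallow stacks need
# flatter somata so fully included cells still fit)
small_synth <- function(n_cells, ny = 32, nx = 32, nz = 8, seed = 1, ...) {
  synth_params(n_cells = n_cells, ny = ny, nx = nx, nz = nz,
               nucleus_r_um = c(1.6, 2), soma_r_um = c(3, 3.8),
               seed = seed, ...)
}

# random 3D mask with a few blobby seeds, for oracle-equivalence loops
random_mask3d <- function(dims, n_seeds = 6, radius = 2) {
  m <- array(FALSE, dims)
  for (i in seq_len(n_seeds)) {
    c0 <- c(sample(dims[1], 1), sample(dims[2], 1), sample(dims[3], 1))
    for (dz in -radius:radius) for (dx in -radius:radius) for (dy in -radius:radius) {
      if (dy^2 + dx^2 + dz^2 > radius^2) next
      p <- c0 + c(dy, dx, dz)
      if (all(p >= 1) && all(p <= dims)) m[p[1], p[2], p[3]] <- TRUE
    }
  }
  m
}

random_mask2d <- function(dims, p = 0.35) {
  matrix(runif(prod(dims)) < p, dims[1], dims[2])
}

# place a solid box object into a 3D mask, 1-based inclusive ranges
add_box <- function(mask, ys, xs, zs) {
  mask[ys, xs, zs] <- TRUE
  mask
}

# a small stack whose two label channels carry disc objects at given spots
disc_plane <- function(ny, nx, cx, cy, r) {
  m <- matrix(FALSE, ny, nx)
  for (y in 1:ny) for (x in 1:nx) {
    if ((x - cx)^2 + (y - cy)^2 <= r^2) m[y, x] <- TRUE
  }
  m
}
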