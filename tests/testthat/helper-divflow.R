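# Fixture builders and independent loop oracles used across the suite.

rand_grid <- function(ny = 8, nx = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(ny * nx), ny, nx)
}

const_slice <- function(v = c(1, 2, 3), ny = 8, nx = 8, z = 0) {
  v <- rep_len(v, 3)
  velocity_slice(matrix(v[1], ny, nx), matrix(v[2], ny, nx),
                 matrix(v[3], ny, nx), z = z)
}

rand_slice <- function(ny = 8, nx = 8, z = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  velocity_slice(rand_grid(ny, nx), rand_grid(ny, nx), rand_grid(ny, nx),
                 z = z)
}

# field linear in z: recovered exactly by the linear baseline
linear_z_volume <- function(ny = 10, nx = 10, nz = 5) {
  slices <- lapply(seq_len(nz), function(k) {
    z <- k - 1
    velocity_slice(matrix(1 + 2 * z, ny, nx),
                   matrix(-3 + 0.5 * z, ny, nx),
                   matrix(z, ny, nx), z = z)
  })
  velocity_volume(slices, dx = 1, dy = 1, dz = 1)
}

# replicate-boundary clamped index
clamp_idx <- function(i, n) pmin(pmax(i, 1L), n)

# explicit double-loop central difference (replicate boundary)
loop_d1 <- function(g, axis) {
  out <- g * 0
  ny <- nrow(g); nx <- ncol(g)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    if (axis == "x")
      out[i, j] <- (g[i, clamp_idx(j + 1L, nx)] -
                      g[i, clamp_idx(j - 1L, nx)]) / 2
    else
      out[i, j] <- (g[clamp_idx(i + 1L, ny), j] -
                      g[clamp_idx(i - 1L, ny), j]) / 2
  }
  out
}

# explicit 3x3 Horn-Schunck neighbourhood convolution (replicate boundary)
loop_navg <- function(g) {
  out <- g * 0
  ny <- nrow(g); nx <- ncol(g)
  w4 <- 1 / 6; wd <- 1 / 12
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    gi <- function(di, dj) g[clamp_idx(i + di, ny), clamp_idx(j + dj, nx)]
    out[i, j] <- w4 * (gi(-1, 0) + gi(1, 0) + gi(0, -1) + gi(0, 1)) +
      wd * (gi(-1, -1) + gi(-1, 1) + gi(1, -1) + gi(1, 1))
  }
  out
}

# per-pixel 2x2 normal-equations minimiser of the constrained quadratic
oracle_minimizer <- function(Hx, Hy, Hz, Dx, Dy, Dz, abar, bbar,
                             gamma, lambda) {
  g2 <- gamma^2; l2 <- lambda^2
  A <- matrix(c(Hx^2 + g2 * Dx^2 + l2, Hx * Hy + g2 * Dx * Dy,
                Hx * Hy + g2 * Dx * Dy, Hy^2 + g2 * Dy^2 + l2), 2, 2)
  rhs <- c(l2 * abar - Hx * Hz - g2 * Dx * Dz,
           l2 * bbar - Hy * Hz - g2 * Dy * Dz)
  solve(A, rhs)
}

# coordinate matrices in the package's grid convention (row = y, col = x)
coord_mats <- function(ny, nx) {
  list(x = matrix(seq_len(nx) - 1, ny, nx, byrow = TRUE),
       y = matrix(seq_len(ny) - 1, ny, nx))
}

interior <- function(g, m = 1L) {
  g[(1L + m):(nrow(g) - m), (1L + m):(ncol(g) - m)]
}
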