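## Finite-difference stencils shared by the solvers and the divergence
## metric.  Axis convention: "x" runs along columns, "y" along rows.
## All stencils use unit (pixel) spacing; physical spacings are applied
## only in the divergence metric.

#' Shift a grid with boundary handling
#'
#' Returns the grid sampled at `(row + dr, col + dc)`; out-of-range
#' indices are clamped to the edge (`"replicate"`) or mirrored about the
#' edge pixel (`"reflect"`).
#'
#' @param grid Numeric matrix.
#' @param dr,dc Integer row/column offsets.
#' @param boundary `"replicate"` or `"reflect"`.
#' @return Shifted matrix of the same shape.
#' @keywords internal
shift_grid <- function(grid, dr = 0L, dc = 0L,
                       boundary = c("replicate", "reflect")) {
  boundary <- match.arg(boundary)
  idx <- function(n, d) {
    i <- seq_len(n) + d
    if (boundary == "replicate") pmin(pmax(i, 1L), n)
    else {                       # reflect about the edge pixel
      i <- ifelse(i < 1L, 2L - i, i)
      ifelse(i > n, 2L * n - i, i)
    }
  }
  grid[idx(nrow(grid), dr), idx(ncol(grid), dc), drop = FALSE]
}

axis_offsets <- function(axis) {
  switch(axis,
         x = function(d) c(0L, d),
         y = function(d) c(d, 0L),
         stop_divflow("'axis' must be \"x\" or \"y\""))
}

#' First derivative (central difference)
#'
#' `(f[i+1] - f[i-1]) / 2` along the chosen axis, exact for fields linear
#' and quadratic in that coordinate.  Boundary rows/columns follow the
#' boundary mode of [shift_grid()].
#'
#' @param grid Numeric matrix (at least 3 wide along `axis`).
#' @param axis `"x"` (columns) or `"y"` (rows).
#' @param boundary Boundary mode.
#' @return Matrix of the same shape.
#' @export
d1 <- function(grid, axis = c("x", "y"),
               boundary = c("replicate", "reflect")) {
  axis <- match.arg(axis); boundary <- match.arg(boundary)
  check_grid(grid)
  if (dim(grid)[if (axis == "x") 2L else 1L] < 3L)
    stop_divflow("grid must be at least 3 wide along the derivative axis")
  off <- axis_offsets(axis)
  p <- off(1L); m <- off(-1L)
  (shift_grid(grid, p[1], p[2], boundary) -
     shift_grid(grid, m[1], m[2], boundary)) / 2
}

#' Second derivative
#'
#' `f[i+1] - 2 f[i] + f[i-1]` along the chosen axis (unit spacing), exact
#' for quadratics.
#'
#' @inheritParams d1
#' @return Matrix of the same shape.
#' @export
d2 <- function(grid, axis = c("x", "y"),
               boundary = c("replicate", "reflect")) {
  axis <- match.arg(axis); boundary <- match.arg(boundary)
  check_grid(grid)
  if (dim(grid)[if (axis == "x") 2L else 1L] < 3L)
    stop_divflow("grid must be at least 3 wide along the derivative axis")
  off <- axis_offsets(axis)
  p <- off(1L); m <- off(-1L)
  shift_grid(grid, p[1], p[2], boundary) - 2 * grid +
    shift_grid(grid, m[1], m[2], boundary)
}

#' Mixed second derivative
#'
#' Central `d/dx` composed with central `d/dy`; the two orders commute
#' exactly in the interior.
#'
#' @inheritParams d1
#' @return Matrix of the same shape.
#' @export
dxy <- function(grid, boundary = c("replicate", "reflect")) {
  boundary <- match.arg(boundary)
  check_grid(grid)
  if (nrow(grid) < 3L || ncol(grid) < 3L)
    stop_divflow("grid must be at least 3x3")
  d1(d1(grid, "x", boundary), "y", boundary)
}

#' Horn-Schunck brightness gradients for a frame pair
#'
#' The classical Horn-Schunck estimates: `Ix` and `Iy` are forward
#' differences averaged over the 2x2x2 cube spanning both frames, and
#' `It` is the forward temporal difference averaged over the four pixels
#' of the 2x2 spatial face.  Replicate handling at the last row/column.
#'
#' @param I_prev,I_next Equal-shape numeric matrices (scalar images).
#' @return List with matrices `Ix`, `Iy`, `It`.
#' @export
hs_gradients <- function(I_prev, I_next) {
  check_grid(I_prev); check_grid(I_next)
  check_same_shape(I_prev, I_next, "frames")
  fx <- function(g)            # forward x-difference averaged over rows i, i+1
    (shift_grid(g, 0L, 1L) - g + shift_grid(g, 1L, 1L) -
       shift_grid(g, 1L, 0L)) / 4
  fy <- function(g)
    (shift_grid(g, 1L, 0L) - g + shift_grid(g, 1L, 1L) -
       shift_grid(g, 0L, 1L)) / 4
  face <- function(g)
    (g + shift_grid(g, 1L, 0L) + shift_grid(g, 0L, 1L) +
       shift_grid(g, 1L, 1L)) / 4
  list(Ix = fx(I_prev) + fx(I_next),
       Iy = fy(I_prev) + fy(I_next),
       It = face(I_next) - face(I_prev))
}
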