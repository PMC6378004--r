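#' divflow: divergence-constrained optical-flow slice interpolation
#'
#' Reconstructs intermediate velocity slices in anisotropic velocimetry
#' volumes by symmetric variational optical flow between the two bracketing
#' slices.  The flow energy combines the classical brightness-constancy and
#' smoothness terms with a divergence term derived from the incompressible
#' continuity equation, so reconstructed slices have low error and low
#' divergence.  See `vignette("divflow-methods")` for the model.
#'
#' @section Grid convention:
#' A single convention is used throughout: grids are numeric matrices with
#' the row index running along y and the column index along x, pixel-centred.
#' Solvers operate in pixel/slice-index units; the physical spacings
#' `dx, dy, dz` stored in a [velocity_volume] enter only the divergence
#' metric ([slice_divergence()]) and the file header.
#'
#' @name divflow-package
#' @keywords internal
"_PACKAGE"

## ---- validation helpers -------------------------------------------------

stop_divflow <- function(...) stop(..., call. = FALSE)

check_grid <- function(g, name = deparse(substitute(g))) {
  if (!is.matrix(g) || !is.numeric(g))
    stop_divflow(sprintf("'%s' must be a numeric matrix", name))
  if (!all(is.finite(g)))
    stop_divflow(sprintf("'%s' contains non-finite values", name))
  invisible(g)
}

check_same_shape <- function(a, b, what = "grids") {
  if (!identical(dim(a), dim(b)))
    stop_divflow(sprintf("%s must share one shape (got %s vs %s)",
                         what, paste(dim(a), collapse = "x"),
                         paste(dim(b), collapse = "x")))
  invisible(NULL)
}

## ---- VelocitySlice ------------------------------------------------------

#' Construct a velocity slice
#'
#' A velocity slice is one z-plane of a velocimetry volume: three
#' co-registered scalar grids holding the `Vx`, `Vy`, `Vz` components at
#' each pixel, plus the z-coordinate of the plane.
#'
#' @param vx,vy,vz Numeric matrices of identical shape (rows = y,
#'   columns = x), velocity components in consistent (arbitrary) units.
#' @param z z-coordinate of the plane (physical units).
#' @return An object of class `velocity_slice`.
#' @examples
#' s <- velocity_slice(matrix(3, 4, 4), matrix(4, 4, 4), matrix(0, 4, 4), z = 0)
#' magnitude(s)[1, 1]  # 5
#' @export
velocity_slice <- function(vx, vy, vz, z = 0) {
  check_grid(vx); check_grid(vy); check_grid(vz)
  check_same_shape(vx, vy, "vx and vy")
  check_same_shape(vx, vz, "vx and vz")
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z))
    stop_divflow("'z' must be a single finite number")
  structure(list(vx = vx, vy = vy, vz = vz, z = as.numeric(z)),
            class = "velocity_slice")
}

#' @export
print.velocity_slice <- function(x, ...) {
  cat(sprintf("<velocity_slice> %d x %d at z = %g\n",
              nrow(x$vx), ncol(x$vx), x$z))
  m <- magnitude(x)
  cat(sprintf("  |V|: min %.4g, mean %.4g, max %.4g\n",
              min(m), mean(m), max(m)))
  invisible(x)
}

#' @export
dim.velocity_slice <- function(x) dim(x$vx)

#' Velocity magnitude image of a slice
#'
#' The per-pixel Euclidean norm `sqrt(vx^2 + vy^2 + vz^2)`.  This scalar
#' image is the brightness signal the optical-flow solvers operate on.
#'
#' @param slice A [velocity_slice].
#' @return Numeric matrix of the slice's shape, elementwise `>= 0`.
#' @export
magnitude <- function(slice) {
  if (!inherits(slice, "velocity_slice"))
    stop_divflow("'slice' must be a velocity_slice")
  sqrt(slice$vx^2 + slice$vy^2 + slice$vz^2)
}

## ---- VelocityVolume -----------------------------------------------------

#' Construct a velocity volume
#'
#' An ordered stack of [velocity_slice] objects with strictly increasing
#' z-coordinates, plus the grid spacings.  `dz` is the nominal out-of-plane
#' spacing; in typical stereo-PIV stacks it is much larger than the
#' in-plane spacings `dx`, `dy`, which is the anisotropy this package's
#' interpolators address.
#'
#' @param slices List of [velocity_slice] objects, one shape, increasing z.
#' @param dx,dy In-plane grid spacings (physical units per pixel).
#' @param dz Nominal out-of-plane spacing (physical units per slice step).
#' @return An object of class `velocity_volume`.
#' @export
velocity_volume <- function(slices, dx = 1, dy = 1, dz = 1) {
  if (!is.list(slices) || length(slices) == 0L ||
      !all(vapply(slices, inherits, logical(1), "velocity_slice")))
    stop_divflow("'slices' must be a non-empty list of velocity_slice objects")
  shp <- dim(slices[[1L]])
  for (s in slices) check_same_shape(slices[[1L]]$vx, s$vx, "all slices")
  zs <- vapply(slices, function(s) s$z, numeric(1))
  if (any(diff(zs) <= 0))
    stop_divflow("slice z-coordinates must be strictly increasing")
  for (sp in c(dx, dy, dz))
    if (!is.finite(sp) || sp <= 0)
      stop_divflow("spacings dx, dy, dz must be positive and finite")
  structure(list(slices = slices, dx = dx, dy = dy, dz = dz),
            class = "velocity_volume")
}

#' @export
print.velocity_volume <- function(x, ...) {
  zs <- slice_z(x)
  cat(sprintf("<velocity_volume> %d slices of %d x %d\n",
              length(x$slices), nrow(x$slices[[1]]$vx),
              ncol(x$slices[[1]]$vx)))
  cat(sprintf("  spacings dx = %g, dy = %g, dz = %g\n", x$dx, x$dy, x$dz))
  cat("  z:", paste(signif(zs, 6), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.velocity_volume <- function(x) length(x$slices)

#' z-coordinates of a volume's slices
#' @param volume A [velocity_volume].
#' @return Numeric vector of slice z-coordinates.
#' @export
slice_z <- function(volume) {
  vapply(volume$slices, function(s) s$z, numeric(1))
}

## ---- FlowField ----------------------------------------------------------

#' Construct a flow field
#'
#' Per-pixel in-plane displacement components `(alpha, beta)` in pixel
#' units.  Under the symmetric convention, a mid-slice pixel at `(x, y)`
#' maps forward to `(x + alpha, y + beta)` in the upper slice and backward
#' to `(x - alpha, y - beta)` in the lower slice, so `alpha`/`beta` are
#' *half*-displacements across the slice gap.
#'
#' @param alpha,beta Numeric matrices, same shape, finite.
#' @return An object of class `flow_field`.
#' @export
flow_field <- function(alpha, beta) {
  check_grid(alpha); check_grid(beta)
  check_same_shape(alpha, beta, "alpha and beta")
  structure(list(alpha = alpha, beta = beta), class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %d x %d; |alpha| max %.4g, |beta| max %.4g\n",
              nrow(x$alpha), ncol(x$alpha),
              max(abs(x$alpha)), max(abs(x$beta))))
  invisible(x)
}

## ---- SolverConfig -------------------------------------------------------

#' Solver configuration
#'
#' Bundles the tunable parameters of the flow solvers and the evaluation.
#' Defaults follow the reference evaluation protocol: divergence weight
#' `gamma = 150`, smoothness weight `lambda = 1`, `iterations = 2000`,
#' slice half-offset `delta = 1`, replicate boundary handling and a
#' 110x110 centred evaluation region.  `gamma` and `lambda` are stored
#' unsquared; they enter the energy functional squared.
#'
#' @param gamma Divergence-term weight, `>= 0`.  `gamma = 0` reduces the
#'   solver to pure (symmetric) Horn-Schunck.
#' @param lambda Smoothness weight, `> 0` (guarantees the update
#'   denominator `gamma^2*D1 + lambda^2*D2 >= lambda^4 > 0`).
#' @param iterations Number of Jacobi sweeps (positive integer).
#' @param delta Slice half-offset in slice-index units: the outer slices
#'   sit `delta` stack positions below and above the target.
#' @param boundary Boundary mode for stencils, `"replicate"` or `"reflect"`.
#' @param region Side length of the centred square evaluation window.
#' @param tol Optional early-stop threshold on the max absolute flow
#'   update per sweep; `NULL` (default) runs all `iterations` sweeps.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(gamma = 150, lambda = 1, iterations = 2000,
                          delta = 1, boundary = c("replicate", "reflect"),
                          region = 110, tol = NULL) {
  boundary <- match.arg(boundary)
  if (!is.finite(gamma) || gamma < 0) stop_divflow("'gamma' must be >= 0")
  if (!is.finite(lambda) || lambda <= 0) stop_divflow("'lambda' must be > 0")
  if (!is.finite(iterations) || iterations < 1 ||
      iterations != round(iterations))
    stop_divflow("'iterations' must be a positive integer")
  if (!is.finite(delta) || delta <= 0)
    stop_divflow("'delta' must be a positive number of slice steps")
  if (!is.finite(region) || region < 1) stop_divflow("'region' must be >= 1")
  if (!is.null(tol) && (!is.finite(tol) || tol <= 0))
    stop_divflow("'tol' must be NULL or > 0")
  structure(list(gamma = gamma, lambda = lambda,
                 iterations = as.integer(iterations), delta = delta,
                 boundary = boundary, region = as.integer(region), tol = tol),
            class = "solver_config")
}

#' @export
print.solver_config <- function(x, ...) {
  cat(sprintf(paste0("<solver_config> gamma = %g, lambda = %g, ",
                     "iterations = %d, delta = %g\n"),
              x$gamma, x$lambda, x$iterations, x$delta)); cat(sprintf(
    "  boundary = %s, region = %d, tol = %s\n", x$boundary, x$region,
    if (is.null(x$tol)) "none" else format(x$tol)))
  invisible(x)
}

## ---- padding ------------------------------------------------------------

#' Centre a grid in a target frame (crop then zero-pad per dimension)
#'
#' Per dimension, the input is centre-cropped if it is larger than the
#' target and centre-zero-padded if smaller (crop precedes pad per
#' dimension).  This mirrors the common preprocessing that brings e.g.
#' 154x121 PIV vector fields to a 128x128 frame.  The placement offsets
#' are recorded in the `"pad_info"` attribute so the retained region can
#' be mapped back with [crop_back()].
#'
#' @param grid Numeric matrix.
#' @param target_ny,target_nx Target number of rows / columns.
#' @return Matrix of shape `target_ny x target_nx` with attribute
#'   `"pad_info"` (list with `row_off`, `col_off`, `src_rows`, `src_cols`,
#'   the retained source index ranges and placement offsets).
#' @export
pad_to <- function(grid, target_ny, target_nx) {
  check_grid(grid)
  if (target_ny < 1 || target_nx < 1)
    stop_divflow("target dimensions must be positive")
  place <- function(n, target) {
    if (n > target) {           # centre crop
      off <- (n - target) %/% 2L
      list(src = seq.int(off + 1L, off + target), dst = seq_len(target))
    } else {                    # centre pad
      off <- (target - n) %/% 2L
      list(src = seq_len(n), dst = seq.int(off + 1L, off + n))
    }
  }
  pr <- place(nrow(grid), target_ny)
  pc <- place(ncol(grid), target_nx)
  out <- matrix(0, target_ny, target_nx)
  out[pr$dst, pc$dst] <- grid[pr$src, pc$src]
  attr(out, "pad_info") <- list(row_off = pr$dst[1L] - 1L,
                                col_off = pc$dst[1L] - 1L,
                                src_rows = range(pr$src),
                                src_cols = range(pc$src),
                                orig_dim = dim(grid))
  out
}

#' Recover the retained region placed by [pad_to()]
#'
#' @param padded Matrix produced by [pad_to()] (must carry `"pad_info"`).
#' @return The retained region, i.e. the sub-matrix of the original grid
#'   that survived cropping.
#' @export
crop_back <- function(padded) {
  info <- attr(padded, "pad_info")
  if (is.null(info)) stop_divflow("'padded' lacks a \"pad_info\" attribute")
  nr <- diff(info$src_rows) + 1L
  nc <- diff(info$src_cols) + 1L
  padded[info$row_off + seq_len(nr), info$col_off + seq_len(nc),
         drop = FALSE]
}

#' Index range of a centred square window
#'
#' @param ny,nx Grid dimensions.
#' @param side Window side length (must fit in both dimensions).
#' @return List with integer index vectors `rows` and `cols`.
#' @keywords internal
centered_window <- function(ny, nx, side) {
  if (side > ny || side > nx)
    stop_divflow(sprintf("evaluation region %d exceeds grid %dx%d",
                         side, ny, nx))
  r0 <- (ny - side) %/% 2L
  c0 <- (nx - side) %/% 2L
  list(rows = r0 + seq_len(side), cols = c0 + seq_len(side))
}
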