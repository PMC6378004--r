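## Synthetic velocimetry inputs: the analytical divergence-free
## benchmark field, a calibrated Gaussian noise model, random solenoidal
## fields built as curls of smooth vector potentials, and translation
## phantoms for optical-flow validation.  Fields are defined as R
## expressions so their divergence can be checked by symbolic
## differentiation (stats::D), not only discretely.

#' Sampling grid specification
#'
#' Regular grid over a box, by default `[-1, 1]^3`.  Velocimetry stacks
#' are anisotropic: with the default ranges the out-of-plane spacing
#' `dz` greatly exceeds `dx`, `dy` whenever `nz << nx`.
#'
#' @param nx,ny Number of in-plane samples (columns / rows), `>= 3`.
#' @param nz Number of slices, `>= 3`.
#' @param xlim,ylim,zlim Coordinate ranges (non-degenerate).
#' @return An object of class `grid_spec` with the coordinate vectors
#'   and derived spacings `dx`, `dy`, `dz`.
#' @export
grid_spec <- function(nx = 128, ny = 128, nz = 7,
                      xlim = c(-1, 1), ylim = c(-1, 1), zlim = c(-1, 1)) {
  if (nx < 3 || ny < 3 || nz < 3)
    stop_divflow("nx, ny, nz must all be >= 3")
  for (l in list(xlim, ylim, zlim))
    if (length(l) != 2L || !all(is.finite(l)) || diff(l) <= 0)
      stop_divflow("coordinate ranges must be finite and increasing")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 nz = as.integer(nz),
                 x = seq(xlim[1], xlim[2], length.out = nx),
                 y = seq(ylim[1], ylim[2], length.out = ny),
                 z = seq(zlim[1], zlim[2], length.out = nz),
                 dx = diff(xlim) / (nx - 1), dy = diff(ylim) / (ny - 1),
                 dz = diff(zlim) / (nz - 1)),
            class = "grid_spec")
}

## Evaluate a component expression on one z-plane of a grid_spec.
eval_on_plane <- function(expr, grid, z) {
  xm <- matrix(grid$x, grid$ny, grid$nx, byrow = TRUE)
  ym <- matrix(grid$y, grid$ny, grid$nx)
  v <- eval(expr, list(x = xm, y = ym, z = z))
  if (length(v) == 1L) v <- matrix(v, grid$ny, grid$nx)
  v
}

## Sample a named list of component expressions into a velocity_volume.
sample_expressions <- function(exprs, grid) {
  slices <- lapply(grid$z, function(zk)
    velocity_slice(eval_on_plane(exprs$vx, grid, zk),
                   eval_on_plane(exprs$vy, grid, zk),
                   eval_on_plane(exprs$vz, grid, zk), z = zk))
  vol <- velocity_volume(slices, dx = grid$dx, dy = grid$dy, dz = grid$dz)
  attr(vol, "expressions") <- exprs
  vol
}

#' Component expressions of the analytical benchmark field
#'
#' The divergence-free polynomial benchmark:
#' `Vx = 0.3 y^2 + 0.15 x^2`,
#' `Vy = 0.3 (1 - x^2) y - 1 - 0.3 x y`,
#' `Vz = -0.3 (1 - x^2) z`,
#' whose analytic divergence is identically zero
#' (`0.3 x + 0.3(1 - x^2) - 0.3 x - 0.3(1 - x^2)`).  Alternative
#' readings of the `Vy` formula, whose typography admits other
#' groupings, are exposed for inspection: `"literal_inner"` is *not*
#' divergence-free; `"literal_grouped"` differs from the default only
#' by an x-dependent offset in `Vy` (so it is also solenoidal but a
#' different field).
#'
#' @param vy_parse `"divergence_free"` (default) or one of the literal
#'   alternative groupings `"literal_inner"`
#'   (`0.3 (1 - x^2 y) - 1 - 0.3 x y`) and `"literal_grouped"`
#'   (`0.3 (1 - x^2) (y - 1) - 0.3 x y`).
#' @return Named list of expressions `vx`, `vy`, `vz` in variables
#'   `x`, `y`, `z`.
#' @export
analytical_expressions <- function(vy_parse = c("divergence_free",
                                                "literal_inner",
                                                "literal_grouped")) {
  vy_parse <- match.arg(vy_parse)
  list(vx = quote(0.3 * y^2 + 0.15 * x^2),
       vy = switch(vy_parse,
                   divergence_free = quote(0.3 * (1 - x^2) * y - 1 -
                                             0.3 * x * y),
                   literal_inner = quote(0.3 * (1 - x^2 * y) - 1 -
                                           0.3 * x * y),
                   literal_grouped = quote(0.3 * (1 - x^2) * (y - 1) -
                                             0.3 * x * y)),
       vz = quote(-0.3 * (1 - x^2) * z))
}

#' Sample the analytical benchmark field on a grid
#'
#' @param grid A [grid_spec].
#' @inheritParams analytical_expressions
#' @return A [velocity_volume]; the component expressions are attached
#'   as attribute `"expressions"` for symbolic checks.
#' @examples
#' vol <- analytical_field(grid_spec(16, 16, 3))
#' max(abs(symbolic_divergence_grid(vol, grid_spec(16, 16, 3))))  # 0
#' @export
analytical_field <- function(grid, vy_parse = "divergence_free") {
  if (!inherits(grid, "grid_spec")) stop_divflow("'grid' must be a grid_spec")
  sample_expressions(analytical_expressions(vy_parse), grid)
}

#' Symbolic divergence of an expression-defined field
#'
#' Differentiates the component expressions symbolically
#' (`stats::D`) and returns the divergence expression
#' `dVx/dx + dVy/dy + dVz/dz`.
#'
#' @param exprs Named list of expressions `vx`, `vy`, `vz`, or a
#'   [velocity_volume] carrying an `"expressions"` attribute.
#' @return An R expression in `x`, `y`, `z`.
#' @export
symbolic_divergence <- function(exprs) {
  if (inherits(exprs, "velocity_volume"))
    exprs <- attr(exprs, "expressions")
  if (is.null(exprs$vx)) stop_divflow("no component expressions available")
  call("+", call("+", stats::D(exprs$vx, "x"), stats::D(exprs$vy, "y")),
       stats::D(exprs$vz, "z"))
}

#' Evaluate the symbolic divergence on every grid point
#'
#' @param exprs As in [symbolic_divergence()].
#' @param grid A [grid_spec].
#' @return Numeric array `ny x nx x nz` of divergence values.
#' @export
symbolic_divergence_grid <- function(exprs, grid) {
  dv <- symbolic_divergence(exprs)
  out <- array(0, c(grid$ny, grid$nx, grid$nz))
  for (k in seq_len(grid$nz))
    out[, , k] <- eval_on_plane(dv, grid, grid$z[k])
  out
}

#' Add calibrated Gaussian noise to a volume
#'
#' Independent zero-mean Gaussian noise is added to every component
#' grid.  The standard deviation is `fraction` times the maximum
#' absolute value of that component over the whole volume
#' (`scale = "component"`, default) or of all components
#' (`scale = "global"`).  `fraction = 0.1` reproduces the usual
#' robustness protocol: noise sd equal to 10% of the field maximum.
#'
#' @param volume A [velocity_volume].
#' @param fraction Noise level as a fraction of the field maximum, `>= 0`.
#' @param seed Integer seed (required; the generator is reproducible).
#' @param scale `"component"` or `"global"` reference maximum.
#' @return A [velocity_volume] with perturbed components.
#' @export
add_gaussian_noise <- function(volume, fraction = 0.1, seed,
                               scale = c("component", "global")) {
  scale <- match.arg(scale)
  if (!inherits(volume, "velocity_volume"))
    stop_divflow("'volume' must be a velocity_volume")
  if (!is.finite(fraction) || fraction < 0)
    stop_divflow("'fraction' must be >= 0")
  if (missing(seed)) stop_divflow("'seed' is required for reproducibility")
  if (fraction == 0) return(volume)
  comp_max <- sapply(c("vx", "vy", "vz"), function(cm)
    max(vapply(volume$slices, function(s) max(abs(s[[cm]])), numeric(1))))
  if (scale == "global") comp_max[] <- max(comp_max)
  sds <- fraction * comp_max
  set.seed(as.integer(seed))
  slices <- lapply(volume$slices, function(s) {
    ny <- nrow(s$vx); nx <- ncol(s$vx)
    velocity_slice(s$vx + matrix(stats::rnorm(ny * nx, 0, sds[["vx"]]), ny),
                   s$vy + matrix(stats::rnorm(ny * nx, 0, sds[["vy"]]), ny),
                   s$vz + matrix(stats::rnorm(ny * nx, 0, sds[["vz"]]), ny),
                   z = s$z)
  })
  out <- velocity_volume(slices, volume$dx, volume$dy, volume$dz)
  attr(out, "noise_sd") <- sds
  out
}

#' Random smooth solenoidal field
#'
#' Draws a smooth random vector potential `A` (sums of low-frequency
#' sinusoidal modes with seeded coefficients) and returns `V = curl A`,
#' so the analytic divergence is identically zero (`div curl = 0`).
#' The discrete central-difference divergence is `O(h^2)`.
#'
#' @param grid A [grid_spec].
#' @param smoothness Positive scalar; larger values concentrate energy
#'   in lower spatial frequencies (mode amplitudes decay as
#'   `|k|^-smoothness`).
#' @param seed Integer seed.
#' @param n_modes Number of random modes per potential component.
#' @return A [velocity_volume] with the curl expressions attached as
#'   attribute `"expressions"`.
#' @export
solenoidal_random_field <- function(grid, smoothness = 2, seed,
                                    n_modes = 3) {
  if (!inherits(grid, "grid_spec")) stop_divflow("'grid' must be a grid_spec")
  if (missing(seed)) stop_divflow("'seed' is required for reproducibility")
  if (!is.finite(smoothness) || smoothness <= 0)
    stop_divflow("'smoothness' must be > 0")
  set.seed(as.integer(seed))
  rand_potential <- function() {
    terms <- lapply(seq_len(n_modes), function(i) {
      k <- sample(1:3, 3, replace = TRUE)         # integer frequencies
      amp <- stats::rnorm(1) / sqrt(sum(k^2))^smoothness
      ph <- stats::runif(3, 0, 2 * pi)
      bquote(.(amp) * sin(.(k[1]) * x + .(ph[1])) *
               sin(.(k[2]) * y + .(ph[2])) * sin(.(k[3]) * z + .(ph[3])))
    })
    Reduce(function(a, b) bquote(.(a) + .(b)), terms)
  }
  A1 <- rand_potential(); A2 <- rand_potential(); A3 <- rand_potential()
  exprs <- list(
    vx = call("-", stats::D(A3, "y"), stats::D(A2, "z")),
    vy = call("-", stats::D(A1, "z"), stats::D(A3, "x")),
    vz = call("-", stats::D(A2, "x"), stats::D(A1, "y")))
  sample_expressions(exprs, grid)
}

#' Gaussian-blob translation phantom
#'
#' A smooth Gaussian blob and its copy shifted by a (possibly
#' subpixel) displacement, both evaluated analytically (no resampling),
#' for validating optical-flow recovery of a known shift.
#'
#' @param shape `c(ny, nx)` of the images.
#' @param shift `c(dx, dy)` displacement in pixels applied to the second
#'   image (positive `dx` moves the blob towards larger column index);
#'   each component must not exceed a quarter of the image size.
#' @param blob_width Gaussian sigma in pixels.
#' @param seed Integer seed jittering the blob centre (subpixel).
#' @param amplitude Peak brightness.  The default 255 puts the blob on
#'   the usual 8-bit image scale so brightness gradients dominate the
#'   smoothness weight at the conventional `lambda = 1`.
#' @return List with matrices `I_prev`, `I_next`, the `shift`, the blob
#'   `center` (row, col) and `sigma`.
#' @export
translation_phantom <- function(shape = c(64, 64), shift = c(1, 0),
                                blob_width = 6, seed = 1,
                                amplitude = 255) {
  ny <- shape[1]; nx <- shape[2]
  if (any(abs(shift) > c(nx, ny) / 4))
    stop_divflow("'shift' must not exceed a quarter of the image size")
  set.seed(as.integer(seed))
  cr <- (ny + 1) / 2 + stats::runif(1, -0.5, 0.5)
  cc <- (nx + 1) / 2 + stats::runif(1, -0.5, 0.5)
  blob <- function(crow, ccol) {
    r <- matrix(seq_len(ny), ny, nx)
    c <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    amplitude * exp(-((r - crow)^2 + (c - ccol)^2) / (2 * blob_width^2))
  }
  list(I_prev = blob(cr, cc),
       I_next = blob(cr + shift[2], cc + shift[1]),
       shift = shift, center = c(cr, cc), sigma = blob_width)
}
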