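## Baseline Horn-Schunck optical-flow solver.  Serves two roles: the
## classical full-displacement flow between two frames, and (with
## gradients = "symmetric") the gamma = 0 comparator of the
## divergence-constrained solver, sharing its brightness terms and
## half-displacement convention.

#' Horn-Schunck neighbourhood average
#'
#' 3x3 weighted local mean with weight 1/6 for the 4-neighbours and 1/12
#' for the diagonal neighbours (the classical kernel; weights sum to 1,
#' centre excluded), replicate boundary.
#'
#' @param grid Numeric matrix, at least 3x3.
#' @param boundary Boundary mode, see [shift_grid()].
#' @return Matrix of the same shape.
#' @export
neighborhood_average <- function(grid,
                                 boundary = c("replicate", "reflect")) {
  boundary <- match.arg(boundary)
  if (nrow(grid) < 3L || ncol(grid) < 3L)
    stop_divflow("grid must be at least 3x3")
  (shift_grid(grid, -1L, 0L, boundary) + shift_grid(grid, 1L, 0L, boundary) +
     shift_grid(grid, 0L, -1L, boundary) + shift_grid(grid, 0L, 1L, boundary)) / 6 +
    (shift_grid(grid, -1L, -1L, boundary) + shift_grid(grid, -1L, 1L, boundary) +
       shift_grid(grid, 1L, -1L, boundary) + shift_grid(grid, 1L, 1L, boundary)) / 12
}

#' One Horn-Schunck Jacobi update
#'
#' Elementwise update
#' `alpha' = abar - Ix (Ix abar + Iy bbar + It) / (lambda^2 + Ix^2 + Iy^2)`
#' and analogously for `beta`.  This is the per-pixel minimiser of the
#' local quadratic `(Ix a + Iy b + It)^2 +
#' lambda^2 [(a - abar)^2 + (b - bbar)^2]`.
#'
#' @param alpha_bar,beta_bar Neighbourhood-averaged flow components.
#' @param Ix,Iy,It Brightness gradients (equal shapes).
#' @param lambda Smoothness weight, `> 0`.
#' @return List with matrices `alpha`, `beta`.
#' @export
hs_update <- function(alpha_bar, beta_bar, Ix, Iy, It, lambda = 1) {
  if (!is.finite(lambda) || lambda <= 0) stop_divflow("'lambda' must be > 0")
  check_same_shape(alpha_bar, beta_bar, "alpha_bar and beta_bar")
  check_same_shape(alpha_bar, Ix, "flow and gradient grids")
  resid <- (Ix * alpha_bar + Iy * beta_bar + It) /
    (lambda^2 + Ix^2 + Iy^2)
  list(alpha = alpha_bar - Ix * resid,
       beta  = beta_bar - Iy * resid)
}

#' Discrete Horn-Schunck energy
#'
#' Monitors the discretised energy: sum of squared brightness residuals
#' plus `lambda^2` times the summed squared flow gradients (central
#' differences).  Useful for checking that the iteration descends.
#'
#' @param flow A [flow_field].
#' @param Ix,Iy,It Brightness gradients.
#' @param lambda Smoothness weight.
#' @param boundary Boundary mode for the flow gradients.
#' @return Single non-negative number.
#' @export
hs_energy <- function(flow, Ix, Iy, It, lambda = 1,
                      boundary = "replicate") {
  a <- flow$alpha; b <- flow$beta
  data_term <- sum((Ix * a + Iy * b + It)^2)
  smooth <- sum(d1(a, "x", boundary)^2 + d1(a, "y", boundary)^2 +
                  d1(b, "x", boundary)^2 + d1(b, "y", boundary)^2)
  data_term + lambda^2 * smooth
}

#' Horn-Schunck optical flow between two scalar images
#'
#' Iterates [neighborhood_average()] + [hs_update()] from zero flow for
#' `config$iterations` sweeps (deterministic).  Two gradient schemes are
#' available:
#'
#' * `"classic"` (default): the cube-averaged kernels of
#'   [hs_gradients()]; `(alpha, beta)` is the full displacement carrying
#'   `I_prev` onto `I_next`.
#' * `"symmetric"`: the two-slice symmetric terms of
#'   [brightness_terms()], i.e. `Ix = dI_next/dx + dI_prev/dx` and
#'   `It = I_next - I_prev`; `(alpha, beta)` is then the
#'   *half*-displacement of the mid-plane convention, and the solver
#'   coincides with [divof_solve()] at `gamma = 0`.  This scheme is used
#'   as the Horn-Schunck comparator inside [interpolate_volume()] so
#'   that method differences isolate the divergence term.
#'
#' @param I_prev,I_next Equal-shape numeric matrices (for velocimetry
#'   use, velocity-magnitude images of the lower and upper slices).
#' @param config A [solver_config] (`gamma` is ignored here).
#' @param gradients Gradient scheme, `"classic"` or `"symmetric"`.
#' @return A [flow_field].  Attribute `"iterations_run"` records the
#'   number of sweeps performed (less than `config$iterations` only when
#'   `config$tol` triggers early stopping).
#' @export
hs_solve <- function(I_prev, I_next, config = solver_config(),
                     gradients = c("classic", "symmetric")) {
  gradients <- match.arg(gradients)
  check_grid(I_prev); check_grid(I_next)
  check_same_shape(I_prev, I_next, "images")
  if (!inherits(config, "solver_config"))
    stop_divflow("'config' must be a solver_config")
  g <- if (gradients == "classic") hs_gradients(I_prev, I_next)
  else {
    h <- brightness_terms(I_prev, I_next, boundary = config$boundary)
    list(Ix = h$Hx, Iy = h$Hy, It = h$Hz)
  }
  a <- matrix(0, nrow(I_prev), ncol(I_prev))
  b <- a
  iters_run <- 0L
  for (it in seq_len(config$iterations)) {
    upd <- hs_update(neighborhood_average(a, config$boundary),
                     neighborhood_average(b, config$boundary),
                     g$Ix, g$Iy, g$It, config$lambda)
    step <- max(abs(upd$alpha - a), abs(upd$beta - b))
    a <- upd$alpha; b <- upd$beta
    iters_run <- it
    if (!is.null(config$tol) && step < config$tol) break
  }
  out <- flow_field(a, b)
  attr(out, "iterations_run") <- iters_run
  out
}
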