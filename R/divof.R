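## The divergence-constrained symmetric optical-flow solver.  The flow
## between the two outer slices minimises
##
##   E = integral (Hx a + Hy b + Hz)^2                    brightness
##       + gamma^2 (Dx a + Dy b + Dz)^2                   divergence
##       + lambda^2 (|grad a|^2 + |grad b|^2) dx dy       smoothness
##
## where the H-terms couple the magnitude images of the two slices
## symmetrically and the D-terms linearise the mid-plane divergence of
## the incompressible field.  All six constraint grids depend only on
## the input slices, so they are computed once before iterating.

#' Symmetric brightness-constraint terms
#'
#' For magnitude images of the slices at `z - delta` and `z + delta`:
#' `Hx = dI_up/dx + dI_lo/dx`, `Hy = dI_up/dy + dI_lo/dy`,
#' `Hz = I_up - I_lo`.  A mid-plane flow `(alpha, beta)` satisfying the
#' symmetric brightness-constancy relation obeys
#' `Hx alpha + Hy beta + Hz = 0` to first order.
#'
#' @param mag_lower,mag_upper Equal-shape magnitude images.
#' @param boundary Boundary mode for the derivatives.
#' @return List with matrices `Hx`, `Hy`, `Hz`.
#' @export
brightness_terms <- function(mag_lower, mag_upper,
                             boundary = "replicate") {
  check_grid(mag_lower); check_grid(mag_upper)
  check_same_shape(mag_lower, mag_upper, "magnitude images")
  list(Hx = d1(mag_upper, "x", boundary) + d1(mag_lower, "x", boundary),
       Hy = d1(mag_upper, "y", boundary) + d1(mag_lower, "y", boundary),
       Hz = mag_upper - mag_lower)
}

#' Symmetric divergence-constraint terms
#'
#' Linearisation of the mid-plane divergence using only the two outer
#' slices:
#' * `Dx = d2x(Vx_up) - d2x(Vx_lo) + dxy(Vy_up) - dxy(Vy_lo)`
#' * `Dy = dxy(Vx_up) - dxy(Vx_lo) + d2y(Vy_up) - d2y(Vy_lo)`
#' * `Dz = d1x(Vx_up) + d1x(Vx_lo) + d1y(Vy_up) + d1y(Vy_lo)
#'        + (Vz_up - Vz_lo) / delta`
#'
#' The last term is the two-slice estimate of `2 dVz/dz` at the
#' mid-plane (twice the central difference over the `2 delta` gap),
#' `delta` in slice-index units.  A flow minimising the divergence of
#' the reconstructed mid-slice obeys `Dx alpha + Dy beta + Dz = 0` to
#' first order.
#'
#' @param lower,upper [velocity_slice] objects at `z - delta`, `z + delta`.
#' @param delta Slice half-offset (slice-index units), `> 0`.
#' @param boundary Boundary mode.
#' @return List with matrices `Dx`, `Dy`, `Dz`.
#' @export
divergence_terms <- function(lower, upper, delta = 1,
                             boundary = "replicate") {
  if (!inherits(lower, "velocity_slice") || !inherits(upper, "velocity_slice"))
    stop_divflow("'lower' and 'upper' must be velocity_slice objects")
  check_same_shape(lower$vx, upper$vx, "slices")
  if (!is.finite(delta) || delta <= 0) stop_divflow("'delta' must be > 0")
  Dx <- d2(upper$vx, "x", boundary) - d2(lower$vx, "x", boundary) +
    dxy(upper$vy, boundary) - dxy(lower$vy, boundary)
  Dy <- dxy(upper$vx, boundary) - dxy(lower$vx, boundary) +
    d2(upper$vy, "y", boundary) - d2(lower$vy, "y", boundary)
  Dz <- d1(upper$vx, "x", boundary) + d1(lower$vx, "x", boundary) +
    d1(upper$vy, "y", boundary) + d1(lower$vy, "y", boundary) +
    (upper$vz - lower$vz) / delta
  list(Dx = Dx, Dy = Dy, Dz = Dz)
}

#' Update coefficients of the constrained solver
#'
#' The twelve coefficient grids of the Jacobi update, computed from the
#' constraint terms with `g2 = gamma^2`, `l2 = lambda^2` and
#' `S = (Hx Dy - Hy Dx)^2`:
#'
#' * `A1 = g2 S + l2 (Hx^2 + g2 Dx^2)`
#' * `B1 = l2 (Hx Hy + g2 Dx Dy)` (= `A2`)
#' * `C1 = Hx Hz Dy^2 + Hy^2 Dx Dz - Hy Hz Dx Dy - Hx Hy Dy Dz`
#' * `C2 = Hx Hz + g2 Dx Dz`
#' * `D1 = S`, `D2 = Hx^2 + Hy^2 + l2 + g2 (Dx^2 + Dy^2)`
#' * `B2 = g2 S + l2 (Hy^2 + g2 Dy^2)`
#' * `C3 = Hy Hz Dx^2 + Hx^2 Dy Dz - Hx Hz Dx Dy - Hx Hy Dx Dz`
#' * `C4 = Hy Hz + g2 Dy Dz`, `D3 = D1`, `D4 = D2`
#'
#' The shared update denominator `g2 D1 + l2 D2` equals the determinant
#' of the per-pixel normal equations and is bounded below by
#' `lambda^4 > 0`.  At `gamma = 0` the coefficients collapse to the
#' Horn-Schunck structure.
#'
#' @param terms List with `Hx, Hy, Hz, Dx, Dy, Dz` (from
#'   [brightness_terms()] and [divergence_terms()]).
#' @param gamma Divergence weight, `>= 0`.
#' @param lambda Smoothness weight, `> 0`.
#' @return List of the twelve coefficient grids.
#' @export
divof_coefficients <- function(terms, gamma = 150, lambda = 1) {
  if (!is.finite(gamma) || gamma < 0) stop_divflow("'gamma' must be >= 0")
  if (!is.finite(lambda) || lambda <= 0) stop_divflow("'lambda' must be > 0")
  for (nm in c("Hx", "Hy", "Hz", "Dx", "Dy", "Dz"))
    if (is.null(terms[[nm]]))
      stop_divflow(sprintf("constraint terms lack '%s'", nm))
  Hx <- terms$Hx; Hy <- terms$Hy; Hz <- terms$Hz
  Dx <- terms$Dx; Dy <- terms$Dy; Dz <- terms$Dz
  g2 <- gamma^2; l2 <- lambda^2
  S <- (Hx * Dy - Hy * Dx)^2
  B1 <- l2 * (Hx * Hy + g2 * Dx * Dy)
  D1 <- S
  D2 <- Hx^2 + Hy^2 + l2 + g2 * (Dx^2 + Dy^2)
  list(A1 = g2 * S + l2 * (Hx^2 + g2 * Dx^2),
       B1 = B1,
       C1 = Hx * Hz * Dy^2 + Hy^2 * Dx * Dz -
         Hy * Hz * Dx * Dy - Hx * Hy * Dy * Dz,
       C2 = Hx * Hz + g2 * Dx * Dz,
       D1 = D1, D2 = D2,
       A2 = B1,
       B2 = g2 * S + l2 * (Hy^2 + g2 * Dy^2),
       C3 = Hy * Hz * Dx^2 + Hx^2 * Dy * Dz -
         Hx * Hz * Dx * Dy - Hx * Hy * Dx * Dz,
       C4 = Hy * Hz + g2 * Dy * Dz,
       D3 = D1, D4 = D2)
}

#' One Jacobi update of the constrained solver
#'
#' `alpha' = abar - (A1 abar + B1 bbar + g2 C1 + l2 C2) / (g2 D1 + l2 D2)`
#' and analogously for `beta` with `A2, B2, C3, C4, D3, D4`.  The result
#' is the exact per-pixel minimiser over `(alpha, beta)` of
#' `(Hx a + Hy b + Hz)^2 + gamma^2 (Dx a + Dy b + Dz)^2 +
#'  lambda^2 [(a - abar)^2 + (b - bbar)^2]`.
#'
#' @param alpha_bar,beta_bar Neighbourhood-averaged flow components.
#' @param coeffs Coefficient grids from [divof_coefficients()].
#' @param gamma,lambda Weights (must match those used for `coeffs`).
#' @return List with matrices `alpha`, `beta`.
#' @export
divof_update <- function(alpha_bar, beta_bar, coeffs,
                         gamma = 150, lambda = 1) {
  if (!is.finite(lambda) || lambda <= 0) stop_divflow("'lambda' must be > 0")
  check_same_shape(alpha_bar, beta_bar, "alpha_bar and beta_bar")
  g2 <- gamma^2; l2 <- lambda^2
  den <- g2 * coeffs$D1 + l2 * coeffs$D2
  list(alpha = alpha_bar -
         (coeffs$A1 * alpha_bar + coeffs$B1 * beta_bar +
            g2 * coeffs$C1 + l2 * coeffs$C2) / den,
       beta = beta_bar -
         (coeffs$A2 * alpha_bar + coeffs$B2 * beta_bar +
            g2 * coeffs$C3 + l2 * coeffs$C4) / den)
}

#' Divergence-constrained symmetric optical flow between two slices
#'
#' Computes the magnitude images, constraint terms and update
#' coefficients once, then iterates [neighborhood_average()] +
#' [divof_update()] from zero flow for `config$iterations` sweeps.
#' Deterministic for fixed inputs.  At `config$gamma = 0` the result
#' equals `hs_solve(..., gradients = "symmetric")` iteration by
#' iteration.
#'
#' @param lower,upper [velocity_slice] objects bracketing the target
#'   plane at `z - delta` and `z + delta`.
#' @param config A [solver_config]; `gamma`, `lambda`, `iterations`,
#'   `delta` and `boundary` are used.
#' @return A [flow_field] in the half-displacement convention (see
#'   [flow_field()]), with attribute `"iterations_run"`.
#' @export
divof_solve <- function(lower, upper, config = solver_config()) {
  if (!inherits(config, "solver_config"))
    stop_divflow("'config' must be a solver_config")
  h <- brightness_terms(magnitude(lower), magnitude(upper),
                        boundary = config$boundary)
  d <- divergence_terms(lower, upper, delta = config$delta,
                        boundary = config$boundary)
  co <- divof_coefficients(c(h, d), gamma = config$gamma, lambda = config$lambda)
  den_min <- min(config$gamma^2 * co$D1 + config$lambda^2 * co$D2)
  # denominator >= lambda^4 by construction; guards against NaN inputs
  if (!(den_min >= config$lambda^4 * (1 - 1e-12)))
    stop_divflow("update denominator lost positivity (non-finite inputs?)")
  a <- matrix(0, nrow(lower$vx), ncol(lower$vx))
  b <- a
  iters_run <- 0L
  for (it in seq_len(config$iterations)) {
    upd <- divof_update(neighborhood_average(a, config$boundary),
                        neighborhood_average(b, config$boundary),
                        co, config$gamma, config$lambda)
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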