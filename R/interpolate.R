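## Mid-slice reconstruction: motion-compensated symmetric averaging plus
## the linear and truncated-sinc baselines.

#' Bilinear sampling of a grid at fractional coordinates
#'
#' @param grid Numeric matrix.
#' @param rows,cols Matrices/vectors of fractional row/column positions
#'   (1-based); out-of-bounds coordinates are clamped to the edge.
#' @return Sampled values with the shape of `rows`.
#' @keywords internal
bilinear_sample <- function(grid, rows, cols) {
  ny <- nrow(grid); nx <- ncol(grid)
  r <- pmin(pmax(rows, 1), ny)
  c <- pmin(pmax(cols, 1), nx)
  r0 <- pmin(floor(r), ny - 1L); c0 <- pmin(floor(c), nx - 1L)
  fr <- r - r0; fc <- c - c0
  v00 <- grid[cbind(as.vector(r0),     as.vector(c0))]
  v01 <- grid[cbind(as.vector(r0),     as.vector(c0) + 1L)]
  v10 <- grid[cbind(as.vector(r0) + 1L, as.vector(c0))]
  v11 <- grid[cbind(as.vector(r0) + 1L, as.vector(c0) + 1L)]
  out <- (1 - as.vector(fr)) * ((1 - as.vector(fc)) * v00 + as.vector(fc) * v01) +
    as.vector(fr) * ((1 - as.vector(fc)) * v10 + as.vector(fc) * v11)
  matrix(out, nrow(rows), ncol(rows))
}

#' Motion-compensated mid-slice reconstruction
#'
#' For each component `C` of the velocity field,
#' `C_mid(x, y) = (C_upper(x + alpha, y + beta) +
#'                 C_lower(x - alpha, y - beta)) / 2`
#' with bilinear sampling and replicate handling of out-of-bounds
#' coordinates; the slice z is set to the midpoint.  Zero flow reduces
#' exactly to [linear_midslice()].
#'
#' @param lower,upper [velocity_slice] objects bracketing the target.
#' @param flow A [flow_field] in the half-displacement convention.
#' @return A [velocity_slice] at the midpoint z.
#' @export
warp_midslice <- function(lower, upper, flow) {
  check_same_shape(lower$vx, upper$vx, "slices")
  check_same_shape(lower$vx, flow$alpha, "slices and flow")
  ny <- nrow(lower$vx); nx <- ncol(lower$vx)
  rows <- matrix(seq_len(ny), ny, nx)
  cols <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  warp1 <- function(g_up, g_lo)
    (bilinear_sample(g_up, rows + flow$beta, cols + flow$alpha) +
       bilinear_sample(g_lo, rows - flow$beta, cols - flow$alpha)) / 2
  velocity_slice(warp1(upper$vx, lower$vx),
                 warp1(upper$vy, lower$vy),
                 warp1(upper$vz, lower$vz),
                 z = (lower$z + upper$z) / 2)
}

#' Linear (elementwise-average) mid-slice baseline
#'
#' @param lower,upper [velocity_slice] objects.
#' @return A [velocity_slice] at the midpoint z; exact for fields linear
#'   in z.
#' @export
linear_midslice <- function(lower, upper) {
  check_same_shape(lower$vx, upper$vx, "slices")
  velocity_slice((lower$vx + upper$vx) / 2,
                 (lower$vy + upper$vy) / 2,
                 (lower$vz + upper$vz) / 2,
                 z = (lower$z + upper$z) / 2)
}

#' Truncated-sinc mid-slice baseline
#'
#' Per component, a weighted sum over the `taps` slices nearest to
#' `z_target` with weights `sinc((z_target - z_k) / dz)` renormalised to
#' sum 1.  With `taps = 2` at the midpoint this equals the linear
#' baseline; at an existing slice z it returns that slice exactly.
#'
#' @param volume A [velocity_volume] with at least `taps` slices.
#' @param z_target Target plane, strictly inside the z range.
#' @param taps Number of neighbouring slices used (`>= 2`).
#' @return A [velocity_slice] at `z_target`.
#' @export
sinc_midslice <- function(volume, z_target, taps = 6) {
  if (!inherits(volume, "velocity_volume"))
    stop_divflow("'volume' must be a velocity_volume")
  if (taps < 2) stop_divflow("'taps' must be >= 2")
  zs <- slice_z(volume)
  if (taps > length(zs))
    stop_divflow("'taps' exceeds the number of slices")
  if (z_target < min(zs) || z_target > max(zs))
    stop_divflow("'z_target' must lie inside the volume's z range")
  sel <- order(abs(zs - z_target))[seq_len(taps)]
  t <- (z_target - zs[sel]) / volume$dz
  w <- ifelse(t == 0, 1, sin(pi * t) / (pi * t))
  w <- w / sum(w)
  acc <- function(comp) {
    out <- 0
    for (i in seq_along(sel))
      out <- out + w[i] * volume$slices[[sel[i]]][[comp]]
    out
  }
  velocity_slice(acc("vx"), acc("vy"), acc("vz"), z = z_target)
}

#' Reconstruct interior slices of a volume
#'
#' For the flow methods (`"divof"`, `"hs"`, `"linear"`) each target
#' slice `k` is reconstructed from the outer slices at stack positions
#' `k - delta` and `k + delta`; `"sinc"` uses the `taps` nearest slices
#' of the whole stack.  The Horn-Schunck comparator uses
#' `hs_solve(gradients = "symmetric")` and the identical reconstruction
#' path as `"divof"`, so the two methods differ only in the divergence
#' term.
#'
#' @param volume A [velocity_volume].
#' @param method `"divof"`, `"hs"`, `"linear"` or `"sinc"`.
#' @param config A [solver_config]; `delta` selects the outer-slice
#'   offset.
#' @param targets Integer vector of 1-based slice positions to
#'   reconstruct; default: every position with both outer slices
#'   available.
#' @param taps Tap count for `method = "sinc"`.
#' @return A [velocity_volume] of the reconstructed slices (same
#'   spacings), with attributes `"targets"` (the stack positions) and,
#'   for the flow methods, `"flows"` (list of [flow_field]s).
#' @export
interpolate_volume <- function(volume,
                               method = c("divof", "hs", "linear", "sinc"),
                               config = solver_config(),
                               targets = NULL, taps = 6) {
  method <- match.arg(method)
  if (!inherits(volume, "velocity_volume"))
    stop_divflow("'volume' must be a velocity_volume")
  n <- length(volume$slices)
  delta <- as.integer(round(config$delta))
  if (is.null(targets))
    targets <- seq_len(n)[seq_len(n) > delta & seq_len(n) <= n - delta]
  if (length(targets) == 0L) stop_divflow("no reconstructable target slices")
  if (any(targets - delta < 1L) || any(targets + delta > n))
    stop_divflow("outer slices k - delta, k + delta missing for some target")
  zs <- slice_z(volume)
  flows <- list()
  recon <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    k <- targets[i]
    lo <- volume$slices[[k - delta]]
    up <- volume$slices[[k + delta]]
    recon[[i]] <- switch(method,
      linear = linear_midslice(lo, up),
      sinc = sinc_midslice(volume, zs[k], taps),
      hs = {
        fl <- hs_solve(magnitude(lo), magnitude(up), config,
                       gradients = "symmetric")
        flows[[as.character(k)]] <- fl
        warp_midslice(lo, up, fl)
      },
      divof = {
        fl <- divof_solve(lo, up, config)
        flows[[as.character(k)]] <- fl
        warp_midslice(lo, up, fl)
      })
    # the reconstruction targets the acquired plane's z
    recon[[i]]$z <- zs[k]
  }
  out <- velocity_volume(recon, dx = volume$dx, dy = volume$dy,
                         dz = volume$dz)
  attr(out, "targets") <- as.integer(targets)
  attr(out, "method") <- method
  if (length(flows)) attr(out, "flows") <- flows
  out
}
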