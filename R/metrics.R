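## Evaluation metrics: regional MSE of the velocity magnitude, the
## mid-plane divergence of a reconstructed slice, per-volume reports and
## the (gamma, lambda) sweep harness.

#' Regional mean squared error between two slices
#'
#' Mean squared difference of the velocity magnitude over a centred
#' `region_side x region_side` window (the headline statistic), with
#' per-component MSEs reported alongside.
#'
#' @param estimate,truth [velocity_slice] objects of one shape.
#' @param region_side Side of the centred square window (must fit).
#' @return List with `magnitude` (headline MSE), `vx`, `vy`, `vz`.
#' @export
mse_region <- function(estimate, truth, region_side = 110) {
  check_same_shape(estimate$vx, truth$vx, "slices")
  w <- centered_window(nrow(truth$vx), ncol(truth$vx), region_side)
  msew <- function(a, b) mean((a[w$rows, w$cols] - b[w$rows, w$cols])^2)
  list(magnitude = msew(magnitude(estimate), magnitude(truth)),
       vx = msew(estimate$vx, truth$vx),
       vy = msew(estimate$vy, truth$vy),
       vz = msew(estimate$vz, truth$vz))
}

#' Divergence of a reconstructed mid-slice
#'
#' Discrete incompressibility residual at the mid-plane,
#' `D = d(vx_mid)/dx / dx_phys + d(vy_mid)/dy / dy_phys +
#'     (vz_upper - vz_lower) / (2 dz_phys)`,
#' with central in-plane differences and the two bracketing slices
#' supplying the out-of-plane derivative.  The outer slices should come
#' from the reference data so the metric isolates the reconstruction
#' under test.  For incompressible flow D is zero up to discretisation
#' and measurement error.
#'
#' @param mid [velocity_slice] under test.
#' @param lower,upper Bracketing [velocity_slice]s (reference data).
#' @param spacings Numeric `c(dx, dy, dz)`; `dz` is the physical
#'   distance from the mid-plane to each outer slice (half the gap).
#' @param region_side Centred window for the summary statistics.
#' @param boundary Boundary mode for the in-plane derivatives.
#' @return List with `field` (full divergence grid), `mean_abs` and
#'   `sum_sq` (summaries over the centred window).
#' @export
slice_divergence <- function(mid, lower, upper, spacings = c(1, 1, 1),
                             region_side = 110, boundary = "replicate") {
  check_same_shape(mid$vx, lower$vx, "slices")
  check_same_shape(mid$vx, upper$vx, "slices")
  if (length(spacings) != 3L || any(!is.finite(spacings)) ||
      any(spacings <= 0))
    stop_divflow("'spacings' must be three positive numbers c(dx, dy, dz)")
  D <- d1(mid$vx, "x", boundary) / spacings[1] +
    d1(mid$vy, "y", boundary) / spacings[2] +
    (upper$vz - lower$vz) / (2 * spacings[3])
  w <- centered_window(nrow(D), ncol(D), region_side)
  Dw <- D[w$rows, w$cols]
  list(field = D, mean_abs = mean(abs(Dw)), sum_sq = sum(Dw^2))
}

#' Evaluate reconstructed slices against a reference volume
#'
#' For each reconstructed slice, computes the regional magnitude MSE
#' against the reference slice at the same stack position and the
#' mid-plane divergence using the reference volume's outer slices at
#' `k - delta`, `k + delta`.  Physical spacings from the reference
#' volume enter the divergence; the MSE is unitless in velocity^2.
#'
#' @param truth_volume Reference [velocity_volume] (for measured data,
#'   the acquired stack itself).
#' @param reconstructed_volume Output of [interpolate_volume()] (must
#'   carry the `"targets"` attribute) or a volume plus `targets`.
#' @param config A [solver_config]; `region` and `delta` are used.
#' @param targets Stack positions of the reconstructed slices; default
#'   taken from the `"targets"` attribute.
#' @return An `eval_report`: data frame with one row per slice
#'   (`slice`, `z`, `mse`, `mse_vx`, `mse_vy`, `mse_vz`,
#'   `div_mean_abs`, `div_ss`) plus attributes `"aggregate"` (named
#'   means across slices) and `"method"`.
#' @export
evaluate <- function(truth_volume, reconstructed_volume,
                     config = solver_config(), targets = NULL) {
  if (is.null(targets))
    targets <- attr(reconstructed_volume, "targets")
  if (is.null(targets) || length(targets) == 0L)
    stop_divflow("no target slices to evaluate")
  if (length(targets) != length(reconstructed_volume$slices))
    stop_divflow("targets and reconstructed slices differ in number")
  delta <- as.integer(round(config$delta))
  n <- length(truth_volume$slices)
  if (any(targets - delta < 1L) || any(targets + delta > n))
    stop_divflow("reference outer slices missing for some target")
  dz_half <- truth_volume$dz * delta
  rows <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    k <- targets[i]
    est <- reconstructed_volume$slices[[i]]
    tru <- truth_volume$slices[[k]]
    m <- mse_region(est, tru, config$region)
    dv <- slice_divergence(est, truth_volume$slices[[k - delta]],
                           truth_volume$slices[[k + delta]],
                           spacings = c(truth_volume$dx, truth_volume$dy,
                                        dz_half),
                           region_side = config$region,
                           boundary = config$boundary)
    rows[[i]] <- data.frame(slice = k, z = tru$z, mse = m$magnitude,
                            mse_vx = m$vx, mse_vy = m$vy, mse_vz = m$vz,
                            div_mean_abs = dv$mean_abs, div_ss = dv$sum_sq)
  }
  rep <- do.call(rbind, rows)
  class(rep) <- c("eval_report", "data.frame")
  attr(rep, "aggregate") <- c(mse = mean(rep$mse),
                              div_mean_abs = mean(rep$div_mean_abs),
                              div_ss = mean(rep$div_ss))
  attr(rep, "method") <- attr(reconstructed_volume, "method") %||% "unknown"
  rep
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> method = %s\n", attr(x, "method")))
  print.data.frame(x, row.names = FALSE, digits = 5)
  agg <- attr(x, "aggregate")
  cat(sprintf("aggregate: mse = %.5g, div_mean_abs = %.5g, div_ss = %.5g\n",
              agg["mse"], agg["div_mean_abs"], agg["div_ss"]))
  invisible(x)
}

#' Sweep the divergence and smoothness weights
#'
#' Runs `interpolate_volume(method = "divof")` and [evaluate()] once per
#' `(gamma, lambda)` pair on the same inputs and collects the aggregate
#' statistics, rows ordered by `(gamma, lambda)`.  `gamma = 0` rows
#' coincide with the symmetric Horn-Schunck comparator.
#'
#' @param volume Input [velocity_volume] (e.g. the noisy stack).
#' @param truth_volume Reference volume for [evaluate()]; defaults to
#'   `volume` (the measured-data protocol, where the held-out acquired
#'   slice is the reference).
#' @param gammas,lambdas Non-empty numeric vectors of weights.
#' @param config Base [solver_config]; its `gamma`/`lambda` are
#'   overridden pairwise.
#' @param targets Passed to [interpolate_volume()].
#' @return Data frame with columns `gamma`, `lambda`, `mse`,
#'   `div_mean_abs`, `div_ss`.
#' @export
sweep_weights <- function(volume, truth_volume = volume,
                          gammas, lambdas = 1,
                          config = solver_config(), targets = NULL) {
  if (length(gammas) == 0L || length(lambdas) == 0L)
    stop_divflow("'gammas' and 'lambdas' must be non-empty")
  grid <- expand.grid(lambda = sort(lambdas), gamma = sort(gammas))
  grid <- grid[order(grid$gamma, grid$lambda), , drop = FALSE]
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$gamma <- grid$gamma[i]
    cfg$lambda <- grid$lambda[i]
    rec <- interpolate_volume(volume, "divof", cfg, targets = targets)
    agg <- attr(evaluate(truth_volume, rec, cfg), "aggregate")
    out[[i]] <- data.frame(gamma = grid$gamma[i], lambda = grid$lambda[i],
                           mse = agg[["mse"]],
                           div_mean_abs = agg[["div_mean_abs"]],
                           div_ss = agg[["div_ss"]])
  }
  do.call(rbind, out)
}
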