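test_that("warp with zero flow equals the linear baseline exactly", {
  set.seed(51)
  lo <- rand_slice(10, 10, z = 0)
  up <- rand_slice(10, 10, z = 2)
  zf <- flow_field(matrix(0, 10, 10), matrix(0, 10, 10))
  w <- warp_midslice(lo, up, zf)
  l <- linear_midslice(lo, up)
  for (cm in c("vx", "vy", "vz")) expect_identical(w[[cm]], l[[cm]])
  expect_equal(w$z, 1)
})

test_that("identical outer slices are recovered exactly by every method", {
  set.seed(52)
  s <- rand_slice(10, 10, z = 0)
  s2 <- velocity_slice(s$vx, s$vy, s$vz, z = 2)
  zf <- flow_field(matrix(0, 10, 10), matrix(0, 10, 10))
  expect_equal(warp_midslice(s, s2, zf)$vx, s$vx)
  expect_equal(linear_midslice(s, s2)$vy, s$vy)
})

test_that("warp_midslice moves a translated blob to the half-way position", {
  ph <- translation_phantom(c(64, 64), shift = c(1, 0), blob_width = 6,
                            seed = 2)
  mk <- function(m, z) velocity_slice(m, 0 * m, 0 * m, z = z)
  half_flow <- flow_field(matrix(0.5, 64, 64), matrix(0, 64, 64))
  mid <- warp_midslice(mk(ph$I_prev, -1), mk(ph$I_next, 1), half_flow)
  ph_half <- translation_phantom(c(64, 64), shift = c(0.5, 0),
                                 blob_width = 6, seed = 2)
  # error bounded by bilinear interpolation error, well under 1% of peak
  expect_lt(max(abs(mid$vx - ph_half$I_next)) / max(ph$I_prev), 0.01)
})

test_that("linear baseline is exact for fields linear in z", {
  vol <- linear_z_volume(nz = 5)
  l <- linear_midslice(vol$slices[[2]], vol$slices[[4]])
  for (cm in c("vx", "vy", "vz"))
    expect_equal(l[[cm]], vol$slices[[3]][[cm]])
  expect_equal(linear_midslice(const_slice(1, 4, 4, 0),
                               const_slice(3, 4, 4, 2))$vx,
               matrix(2, 4, 4))
})

test_that("sinc baseline has the interpolation property and beats linear near Nyquist", {
  g <- grid_spec(12, 12, 12, zlim = c(-1, 1.75))
  exprs <- list(vx = quote(cos(8 * z + 0 * x)), vy = quote(0 * x),
                vz = quote(0 * x))
  vol <- divflow:::sample_expressions(exprs, g)

  # taps = 2 at the midpoint reduces to the linear baseline
  zt <- (g$z[6] + g$z[7]) / 2
  s2 <- sinc_midslice(vol, zt, taps = 2)
  lin <- linear_midslice(vol$slices[[6]], vol$slices[[7]])
  expect_equal(s2$vx, lin$vx, tolerance = 1e-12)

  # an existing slice is returned exactly
  s0 <- sinc_midslice(vol, g$z[4], taps = 6)
  expect_equal(s0$vx, vol$slices[[4]]$vx, tolerance = 1e-12)

  # oscillatory (near-Nyquist) signal: 6-tap sinc beats linear
  truth <- cos(8 * zt)
  expect_lt(max(abs(sinc_midslice(vol, zt, 6)$vx - truth)),
            max(abs(lin$vx - truth)))

  expect_error(sinc_midslice(vol, zt, taps = 1), "taps")
  expect_error(sinc_midslice(vol, 99, taps = 4), "z range")
})

test_that("interpolate_volume wires outer slices correctly for each delta", {
  vol <- add_gaussian_noise(analytical_field(grid_spec(16, 16, 7)), 0.05,
                            seed = 53)
  cfg <- solver_config(gamma = 10, lambda = 1, iterations = 15, delta = 1)
  rec <- interpolate_volume(vol, "divof", cfg, targets = 3:5)
  expect_equal(attr(rec, "targets"), 3:5)
  expect_equal(slice_z(rec), slice_z(vol)[3:5])
  # target 3 must equal the direct two-slice reconstruction from 2 and 4
  direct <- warp_midslice(vol$slices[[2]], vol$slices[[4]],
                          divof_solve(vol$slices[[2]], vol$slices[[4]], cfg))
  expect_equal(rec$slices[[1]]$vx, direct$vx, tolerance = 1e-12)

  # delta = 2: slice 3 from slices 1 and 5
  cfg2 <- solver_config(gamma = 10, lambda = 1, iterations = 15, delta = 2)
  rec2 <- interpolate_volume(vol, "linear", cfg2, targets = 3)
  direct2 <- linear_midslice(vol$slices[[1]], vol$slices[[5]])
  expect_equal(rec2$slices[[1]]$vx, direct2$vx)

  expect_error(interpolate_volume(vol, "divof", cfg, targets = c(1, 4)),
               "outer slices")
  expect_error(interpolate_volume(vol, "wavelet", cfg), "arg")
})

test_that("a constant volume is reproduced by every method", {
  slices <- lapply(0:4, function(z) const_slice(c(2, -1, 0.5), 12, 12, z))
  vol <- velocity_volume(slices, dz = 1)
  cfg <- solver_config(gamma = 150, lambda = 1, iterations = 10, delta = 1)
  for (m in c("divof", "hs", "linear", "sinc")) {
    rec <- interpolate_volume(vol, m, cfg, targets = 3, taps = 4)
    expect_equal(rec$slices[[1]]$vx, matrix(2, 12, 12), tolerance = 1e-12)
    expect_equal(rec$slices[[1]]$vy, matrix(-1, 12, 12), tolerance = 1e-12)
  }
})

test_that("reconstructions of finite inputs are finite", {
  vol <- add_gaussian_noise(analytical_field(grid_spec(16, 16, 5)), 0.1,
                            seed = 54)
  cfg <- solver_config(gamma = 150, lambda = 1, iterations = 25, delta = 1)
  for (m in c("divof", "hs", "linear", "sinc")) {
    rec <- interpolate_volume(vol, m, cfg, targets = 3, taps = 4)
    for (cm in c("vx", "vy", "vz"))
      expect_true(all(is.finite(rec$slices[[1]][[cm]])))
  }
})
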