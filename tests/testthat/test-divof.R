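test_that("brightness_terms are symmetric in the expected way", {
  set.seed(41)
  g <- rand_grid(8, 8)
  same <- brightness_terms(g, g)
  expect_equal(same$Hz, matrix(0, 8, 8))
  expect_equal(same$Hx, 2 * d1(g, "x"))

  const <- matrix(3, 8, 8)
  bc <- brightness_terms(const, const)
  expect_equal(bc$Hx, matrix(0, 8, 8))
  expect_equal(bc$Hy, matrix(0, 8, 8))
  expect_equal(bc$Hz, matrix(0, 8, 8))

  # adding a constant to the upper slice shifts only Hz
  up <- brightness_terms(g, g + 0.7)
  expect_equal(up$Hz, matrix(0.7, 8, 8))
  expect_equal(up$Hx, same$Hx, tolerance = 1e-14)
  expect_equal(up$Hy, same$Hy, tolerance = 1e-14)
})

test_that("divergence_terms vanish where antisymmetry demands", {
  c1 <- const_slice(c(1, 2, 3), 8, 8, z = 0)
  c2 <- const_slice(c(1, 2, 3), 8, 8, z = 2)
  dt <- divergence_terms(c1, c2, delta = 1)
  expect_equal(dt$Dx, matrix(0, 8, 8))
  expect_equal(dt$Dy, matrix(0, 8, 8))
  expect_equal(dt$Dz, matrix(0, 8, 8))

  # identical (arbitrary) slices: Dx, Dy are differences of identical
  # derivatives, hence exactly zero; Dz need not vanish
  set.seed(42)
  s <- rand_slice(8, 8, z = 0)
  s2 <- velocity_slice(s$vx, s$vy, s$vz, z = 2)
  dt2 <- divergence_terms(s, s2, delta = 1)
  expect_equal(dt2$Dx, matrix(0, 8, 8))
  expect_equal(dt2$Dy, matrix(0, 8, 8))
  expect_error(divergence_terms(s, s2, delta = 0), "delta")
})

test_that("coefficients reduce to Horn-Schunck structure at gamma = 0", {
  set.seed(43)
  t <- list(Hx = rand_grid(4, 4), Hy = rand_grid(4, 4), Hz = rand_grid(4, 4),
            Dx = rand_grid(4, 4), Dy = rand_grid(4, 4), Dz = rand_grid(4, 4))
  lam <- 1.7
  co <- divof_coefficients(t, gamma = 0, lambda = lam)
  expect_equal(co$A1, lam^2 * t$Hx^2)
  expect_equal(co$B1, lam^2 * t$Hx * t$Hy)
  expect_equal(co$C2, t$Hx * t$Hz)
  expect_equal(co$D1, (t$Hx * t$Dy - t$Hy * t$Dx)^2)
  expect_equal(co$D2, t$Hx^2 + t$Hy^2 + lam^2)
})

test_that("coefficients match direct substitution and degenerate cases", {
  m <- function(v) matrix(v, 2, 2)
  h <- 0.4
  t <- list(Hx = m(1), Hy = m(0), Hz = m(h), Dx = m(0), Dy = m(0), Dz = m(0))
  co <- divof_coefficients(t, gamma = 5, lambda = 1)
  expect_equal(co$A1, m(1))
  expect_equal(co$B1, m(0))
  expect_equal(co$C1, m(0))
  expect_equal(co$C2, m(h))
  expect_equal(co$D1, m(0))
  expect_equal(co$D2, m(2))
  expect_identical(co$D3, co$D1)
  expect_identical(co$D4, co$D2)
  expect_identical(co$A2, co$B1)

  zero <- lapply(t, function(x) m(0))
  co0 <- divof_coefficients(zero, gamma = 150, lambda = 2)
  for (nm in c("A1", "B1", "C1", "C2", "D1", "A2", "B2", "C3", "C4"))
    expect_equal(co0[[nm]], m(0))
  expect_equal(co0$D2, m(4))
  expect_equal(co0$D4, m(4))
})

test_that("divof_update equals the per-pixel normal-equations minimiser", {
  set.seed(44)
  worst <- 0
  for (i in 1:1000) {
    v <- rnorm(6); ab <- rnorm(1); bb <- rnorm(1)
    gam <- runif(1, 0, 300); lam <- runif(1, 0.2, 3)
    m <- function(x) matrix(x, 1, 1)
    t <- list(Hx = m(v[1]), Hy = m(v[2]), Hz = m(v[3]),
              Dx = m(v[4]), Dy = m(v[5]), Dz = m(v[6]))
    co <- divof_coefficients(t, gam, lam)
    up <- divof_update(m(ab), m(bb), co, gam, lam)
    sol <- oracle_minimizer(v[1], v[2], v[3], v[4], v[5], v[6], ab, bb,
                            gam, lam)
    worst <- max(worst, abs(c(up$alpha, up$beta) - sol) /
                   pmax(abs(sol), 1e-8))
  }
  expect_lt(worst, 1e-8)
})

test_that("update denominator is bounded below by lambda^4", {
  set.seed(45)
  for (i in 1:50) {
    t <- list(Hx = rand_grid(5, 5), Hy = rand_grid(5, 5),
              Hz = rand_grid(5, 5), Dx = rand_grid(5, 5),
              Dy = rand_grid(5, 5), Dz = rand_grid(5, 5))
    gam <- runif(1, 0, 500); lam <- runif(1, 0.1, 2)
    co <- divof_coefficients(t, gam, lam)
    expect_gte(min(gam^2 * co$D1 + lam^2 * co$D2), lam^4)
  }
})

test_that("all-zero constraint terms leave the averages unchanged", {
  m <- matrix(0, 4, 4)
  t <- list(Hx = m, Hy = m, Hz = m, Dx = m, Dy = m, Dz = m)
  co <- divof_coefficients(t, gamma = 150, lambda = 1)
  up <- divof_update(m + 0.3, m - 0.2, co, 150, 1)
  expect_equal(up$alpha, m + 0.3)
  expect_equal(up$beta, m - 0.2)
})

test_that("gamma = 0 solve reduces to symmetric Horn-Schunck per iteration", {
  vol <- add_gaussian_noise(analytical_field(grid_spec(24, 24, 3)), 0.1,
                            seed = 46)
  lo <- vol$slices[[1]]; up <- vol$slices[[3]]
  for (n in c(1, 10, 60)) {
    cfg <- solver_config(gamma = 0, lambda = 1, iterations = n, delta = 1)
    f1 <- divof_solve(lo, up, cfg)
    f2 <- hs_solve(magnitude(lo), magnitude(up), cfg,
                   gradients = "symmetric")
    expect_lt(max(abs(f1$alpha - f2$alpha), abs(f1$beta - f2$beta)), 1e-10)
  }
})

test_that("divof_solve is deterministic and computes terms only once", {
  vol <- add_gaussian_noise(analytical_field(grid_spec(16, 16, 3)), 0.1,
                            seed = 47)
  cfg <- solver_config(gamma = 150, lambda = 1, iterations = 40, delta = 1)
  f1 <- divof_solve(vol$slices[[1]], vol$slices[[3]], cfg)
  f2 <- divof_solve(vol$slices[[1]], vol$slices[[3]], cfg)
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$beta, f2$beta)

  calls <- list(brightness = 0L, divergence = 0L, coefficients = 0L)
  orig_bt <- brightness_terms
  orig_dt <- divergence_terms
  orig_co <- divof_coefficients
  local_mocked_bindings(
    brightness_terms = function(...) {
      calls$brightness <<- calls$brightness + 1L
      orig_bt(...)
    },
    divergence_terms = function(...) {
      calls$divergence <<- calls$divergence + 1L
      orig_dt(...)
    },
    divof_coefficients = function(...) {
      calls$coefficients <<- calls$coefficients + 1L
      orig_co(...)
    },
    .package = "divflow"
  )
  invisible(divof_solve(vol$slices[[1]], vol$slices[[3]], cfg))
  expect_identical(calls, list(brightness = 1L, divergence = 1L,
                               coefficients = 1L))
})

test_that("constant identical slices give zero flow", {
  c1 <- const_slice(c(1, 2, 3), 10, 10, z = 0)
  c2 <- const_slice(c(1, 2, 3), 10, 10, z = 2)
  fl <- divof_solve(c1, c2, solver_config(iterations = 20, delta = 1))
  expect_equal(fl$alpha, matrix(0, 10, 10))
  expect_equal(fl$beta, matrix(0, 10, 10))
})
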