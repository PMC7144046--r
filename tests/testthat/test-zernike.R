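test_that("single Zernike terms match their analytic values", {
  expect_equal(zernike_term(0, 0, 0.3, 2.1), 1.0)
  expect_equal(zernike_term(1, 1, 1.0, 0.0), 2.0)
  expect_equal(zernike_term(2, 0, 1.0, 0.7), sqrt(3))
  # sin branch and radial polynomial spot checks
  expect_equal(zernike_term(2, -2, 1, pi / 4), sqrt(6) * sin(pi / 2))
  expect_equal(zernike_term(4, 0, 0.5, 0),
               sqrt(5) * (6 * 0.5^4 - 6 * 0.5^2 + 1))
})

test_that("invalid index pairs are rejected", {
  expect_error(zernike_term(2, 1, 0.5, 0), "parity|invalid")
  expect_error(zernike_term(3, -4, 0.5, 0), "invalid")
  expect_error(zernike_term(1, 1, 1.5, 0), "rho")
})

test_that("ANSI ordering and term counts are consistent", {
  idx <- zernike_index_table(7)
  expect_equal(nrow(idx), 36L)
  expect_equal(zernike_n_terms(7), 36)
  expect_equal(idx$j, 0:35)
  expect_equal(idx$j, (idx$n * (idx$n + 2) + idx$m) / 2)
  expect_error(zernike_coef(numeric(35), 7, 8), "requires 36")
})

test_that("basis is orthonormal under disk quadrature", {
  q <- disk_quadrature(256)
  A <- zernike_basis(q$rho, q$theta, 5)
  G <- crossprod(A * q$w, A) / sum(q$w)
  expect_lt(max(abs(G - diag(ncol(A)))), 1e-3)
})

test_that("fitting a pure basis-term surface recovers its coefficient", {
  m <- single_term_map(3, -1, amplitude = 1.5)
  cf <- fit_elevation(m, 8, 7)
  expect_equal(unname(cf["Z3.-1"]), 1.5, tolerance = 1e-6)
  expect_lt(max(abs(cf[names(cf) != "Z3.-1"])), 1e-6)
  expect_lt(attr(cf, "residual_rms_um"), 1e-8)
})

test_that("all-zero maps fit to all-zero coefficients", {
  m <- single_term_map(2, 0, amplitude = 0)
  expect_equal(max(abs(fit_elevation(m, 8, 7))), 0, tolerance = 1e-12)
})

test_that("fit-reconstruct round trip is exact within the span", {
  for (seed in 1:3) {
    cf <- random_coef(seed)
    m <- coef_map(cf)
    refit <- fit_elevation(m, 8, 7)
    expect_lt(max(abs(as.numeric(refit) - as.numeric(cf))), 1e-8)
  }
})

test_that("Parseval: surface RMS equals coefficient norm (piston/tilt removed)", {
  cf <- random_coef(11, scale = 0.3)
  v <- as.numeric(cf); v[1:3] <- 0
  cf <- zernike_coef(v, 7, 8)
  q <- disk_quadrature(512)
  A <- zernike_basis(q$rho, q$theta, 7)
  z <- as.numeric(A %*% v)
  grid_rms <- sqrt(sum(q$w * z^2) / sum(q$w))
  expect_equal(grid_rms, sqrt(sum(v^2)), tolerance = 2e-3)
})

test_that("under-sampled fits fail loudly", {
  xs <- seq(-4, 4, length.out = 7)
  m <- elevation_map(xs, xs, matrix(0, 7, 7), diameter_mm = 8)
  expect_error(fit_elevation(m, 8, 7), "in-aperture samples")
})

test_that("excessive missing data inside the aperture is refused", {
  m <- single_term_map(2, 0)
  z <- m$z
  g <- expand.grid(x = m$xs, y = m$ys)
  inside <- sqrt(g$x^2 + g$y^2) <= 4
  kill <- which(inside)[seq_len(floor(0.3 * sum(inside)))]
  z[kill] <- NA
  m$z <- z
  expect_error(fit_elevation(m, 8, 7), "missing")
})

test_that("pupil rescaling matches analytic defocus scaling", {
  v <- numeric(36); v[5] <- 2
  c0 <- zernike_coef(v, 7, 8)
  c1 <- rescale_pupil(c0, 6)
  s2 <- (6 / 8)^2
  expect_equal(unname(c1["Z2.0"]), 2 * s2, tolerance = 1e-12)
  expect_equal(unname(c1["Z0.0"]), sqrt(3) * (s2 - 1) * 2, tolerance = 1e-12)
})

test_that("pupil rescaling equals a dense-grid refit", {
  cf <- random_coef(5)
  c6 <- rescale_pupil(cf, 6)
  xs <- seq(-3, 3, length.out = 91)
  g <- expand.grid(x = xs, y = xs)
  z <- reconstruct_surface(cf, g$x, g$y)
  m <- elevation_map(xs, xs, matrix(z, 91, 91), diameter_mm = 6)
  refit <- fit_elevation(m, 6, 7)
  expect_lt(max(abs(as.numeric(refit) - as.numeric(c6))), 1e-8)
})

test_that("pupil rescaling is idempotent at ratio 1 and composes", {
  cf <- random_coef(9)
  expect_equal(as.numeric(rescale_pupil(cf, 8)), as.numeric(cf))
  a <- rescale_pupil(rescale_pupil(cf, 7), 5)
  b <- rescale_pupil(cf, 5)
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-10)
  expect_error(rescale_pupil(b, 8), "extrapolation")
})

test_that("elevation to wavefront is the refractive-index scalar multiply", {
  cf <- random_coef(3)
  w <- elevation_to_wavefront(cf)
  expect_equal(as.numeric(w), as.numeric(cf) * 0.376)
  v1 <- random_coef(4); v2 <- random_coef(6)
  sum_first <- elevation_to_wavefront(
    zernike_coef(as.numeric(v1) + as.numeric(v2), 7, 8))
  expect_equal(as.numeric(sum_first),
               as.numeric(elevation_to_wavefront(v1)) +
                 as.numeric(elevation_to_wavefront(v2)))
  one <- numeric(36); one[5] <- 1
  expect_equal(unname(elevation_to_wavefront(zernike_coef(one, 7, 8))["Z2.0"]),
               0.376)
})

test_that("RMS groups partition the spectrum as documented", {
  v <- numeric(36); v[8] <- 2   # (3,-1) coma
  g <- rms_groups(zernike_coef(v, 7, 6), 6)
  expect_equal(g$coma_like, 2)
  expect_equal(g$hoa, 2)
  expect_equal(g$spherical_like, 0)
  expect_equal(g$astigmatism, 0)

  v2 <- numeric(36); v2[6] <- 3; v2[13] <- 4   # (2,2) and (4,0)
  g2 <- rms_groups(zernike_coef(v2, 7, 6), 6)
  expect_equal(g2$total, 5)
  expect_equal(g2$astigmatism, 3)
  expect_equal(g2$spherical_like, 4)

  g0 <- rms_groups(zernike_coef(numeric(36), 7, 6), 6)
  expect_true(all(unlist(g0[c("total", "hoa", "astigmatism", "coma_like",
                              "spherical_like")]) == 0))
})

test_that("rotationally grouped RMS metrics are rotation invariant", {
  cf <- random_coef(21, scale = 0.4, pupil = 6)
  g0 <- rms_groups(cf, 6)
  # rotate the surface by rotating each (n, |m|) pair
  idx <- zernike_index_table(7)
  phi <- 0.7
  v <- as.numeric(cf); vr <- v
  for (n in unique(idx$n)) for (m in unique(abs(idx$m[idx$n == n]))) {
    if (m == 0) next
    ic <- which(idx$n == n & idx$m == m)
    is <- which(idx$n == n & idx$m == -m)
    vr[ic] <- cos(m * phi) * v[ic] + sin(m * phi) * v[is]
    vr[is] <- -sin(m * phi) * v[ic] + cos(m * phi) * v[is]
  }
  g1 <- rms_groups(zernike_coef(vr, 7, 6), 6)
  for (f in c("total", "hoa", "spherical_like", "coma_like", "astigmatism")) {
    expect_equal(g1[[f]], g0[[f]], tolerance = 1e-10)
  }
})

test_that("RMS groups refuse a pupil larger than the fitted aperture", {
  expect_error(rms_groups(random_coef(2, pupil = 6), 8), "valid up to")
})
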