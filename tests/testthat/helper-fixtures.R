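# programmatic fixtures shared across the suite

# elevation map sampling exactly one Zernike basis term on an 8 mm aperture
single_term_map <- function(n, m, amplitude = 1.5, grid_n = 61,
                            diameter_mm = 8) {
  xs <- seq(-diameter_mm / 2 - 0.5, diameter_mm / 2 + 0.5,
            length.out = grid_n)
  g <- expand.grid(x = xs, y = xs)
  r <- sqrt(g$x^2 + g$y^2)
  rho <- r / (diameter_mm / 2)
  z <- ifelse(rho <= 1, amplitude *
                zernike_term(n, m, pmin(rho, 1), atan2(g$y, g$x)), 0)
  elevation_map(xs, xs, matrix(z, grid_n, grid_n), diameter_mm = diameter_mm)
}

# map sampled from an arbitrary coefficient vector (zero outside aperture)
coef_map <- function(coef, grid_n = 81) {
  d <- attr(coef, "pupil_diameter_mm")
  xs <- seq(-d / 2, d / 2, length.out = grid_n)
  g <- expand.grid(x = xs, y = xs)
  z <- reconstruct_surface(coef, g$x, g$y)
  z[is.na(z)] <- 0
  elevation_map(xs, xs, matrix(z, grid_n, grid_n), diameter_mm = d)
}

random_coef <- function(seed, scale = 0.5, pupil = 8) {
  set.seed(seed)
  zernike_coef(rnorm(36, 0, scale), max_order = 7, pupil_diameter_mm = pupil)
}

# a small always-successful synthetic case record with prescribed deltas
toy_case <- function(preop = random_coef(1),
                     postop = random_coef(2),
                     udva = c(0.2, 0.4), cdva = c(0.5, 0.7),
                     se = c(-5, -4), hoa = c(3, 2.5), coma = c(2.5, 2)) {
  mk_rms <- function(h, cm) {
    structure(list(total = h + 1, hoa = h, astigmatism = 1,
                   coma_like = cm, spherical_like = 0.5,
                   residual_hoa = sqrt(max(h^2 - cm^2 - 0.25, 0)),
                   pupil_diameter_mm = 6),
              class = "rms_groups")
  }
  case_record(preop, postop,
              preop_udva = udva[1], postop_udva = udva[2],
              preop_cdva = cdva[1], postop_cdva = cdva[2],
              preop_se = se[1], postop_se = se[2],
              preop_rms = mk_rms(hoa[1], coma[1]),
              postop_rms = mk_rms(hoa[2], coma[2]),
              implant = list(segment_spec("SI6", 150, 250, 90)))
}

# disk quadrature with fractional edge weights for orthonormality checks
disk_quadrature <- function(grid_n) {
  u <- (seq_len(grid_n) - 0.5) / (grid_n / 2) - 1
  g <- expand.grid(x = u, y = u)
  r <- sqrt(g$x^2 + g$y^2)
  h <- 2 / grid_n
  w <- pmin(pmax((1 - r) / h + 0.5, 0), 1)   # pixel coverage of the disk
  keep <- w > 0
  list(rho = pmin(r[keep], 1), theta = atan2(g$y[keep], g$x[keep]),
       w = w[keep])
}
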