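#' Zernike index table in ANSI/OSA ordering
#'
#' Enumerates the double indices (n, m) of the Zernike polynomials up to a
#' maximum radial order in the ANSI/OSA single-index order: radial order n
#' ascending, and within each order the azimuthal frequency m running from
#' -n to n in steps of 2. The single index is j = (n(n+2)+m)/2.
#'
#' @param max_order maximum radial order N (>= 0).
#' @return data.frame with columns `j` (0-based single index), `n`, `m`.
#' @export
#' @examples
#' zernike_index_table(2)
zernike_index_table <- function(max_order) {
  stopifnot(is.numeric(max_order), length(max_order) == 1L, max_order >= 0)
  max_order <- as.integer(max_order)
  n <- rep.int(0:max_order, 0:max_order + 1L)
  m <- unlist(lapply(0:max_order, function(k) seq(-k, k, by = 2L)), use.names = FALSE)
  data.frame(j = (n * (n + 2L) + m) %/% 2L, n = n, m = m)
}

#' Number of Zernike terms up to a radial order
#' @param max_order maximum radial order N.
#' @return (N+1)(N+2)/2.
#' @export
zernike_n_terms <- function(max_order) {
  (max_order + 1L) * (max_order + 2L) / 2L
}

# radial polynomial coefficients of R_n^{|m|}: named by monomial power of rho
zernike_radial_coefs <- function(n, m) {
  m <- abs(m)
  kmax <- (n - m) / 2
  k <- 0:kmax
  coefs <- (-1)^k * factorial(n - k) /
    (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k))
  powers <- n - 2 * k
  list(powers = powers, coefs = coefs)
}

#' Evaluate a single Zernike term
#'
#' Evaluates the RMS-normalized (unit-variance over the unit disk) Zernike
#' polynomial of radial order `n` and azimuthal frequency `m` at normalized
#' radius `rho` and azimuth `theta`. The normalization constant is
#' sqrt(2(n+1)) for m != 0 and sqrt(n+1) for m = 0, so that the mean square
#' of each term over the unit disk is 1 and the RMS of a surface equals the
#' Euclidean norm of its coefficient vector.
#'
#' @param n radial order (integer >= 0).
#' @param m azimuthal frequency; |m| <= n and n - |m| even. Positive m pairs
#'   with cos(m theta), negative with sin(|m| theta).
#' @param rho normalized radius in \[0, 1\] (vectorized).
#' @param theta azimuth in radians (vectorized, recycled against `rho`).
#' @return numeric vector of term values.
#' @export
#' @examples
#' zernike_term(2, 0, 1, 0)       # sqrt(3)*(2*1 - 1)
#' zernike_term(1, 1, 1, 0)       # 2
zernike_term <- function(n, m, rho, theta) {
  stopifnot(length(n) == 1L, length(m) == 1L)
  if (n < 0 || abs(m) > n || (n - abs(m)) %% 2L != 0L) {
    stop("invalid Zernike indices (n = ", n, ", m = ", m,
         "): need |m| <= n and n - |m| even", call. = FALSE)
  }
  if (any(rho < -1e-12 | rho > 1 + 1e-12, na.rm = TRUE)) {
    stop("rho must lie in [0, 1]", call. = FALSE)
  }
  rc <- zernike_radial_coefs(n, m)
  radial <- rep(0, length(rho))
  for (i in seq_along(rc$powers)) {
    radial <- radial + rc$coefs[i] * rho^rc$powers[i]
  }
  norm <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
  ang <- if (m > 0) cos(m * theta) else if (m < 0) sin(-m * theta) else 1
  norm * radial * ang
}

#' Zernike design matrix
#'
#' Evaluates all terms up to `max_order` at the given polar coordinates.
#'
#' @param rho,theta polar coordinates (equal length).
#' @param max_order maximum radial order.
#' @return matrix of dim length(rho) x zernike_n_terms(max_order), columns in
#'   ANSI/OSA order.
#' @export
zernike_basis <- function(rho, theta, max_order) {
  idx <- zernike_index_table(max_order)
  out <- matrix(0, nrow = length(rho), ncol = nrow(idx))
  for (k in seq_len(nrow(idx))) {
    out[, k] <- zernike_term(idx$n[k], idx$m[k], rho, theta)
  }
  colnames(out) <- sprintf("Z%d.%d", idx$n, idx$m)
  out
}

#' Construct a Zernike coefficient vector
#'
#' @param coeffs numeric vector of length (max_order+1)(max_order+2)/2 in
#'   ANSI/OSA ordering, unit-variance normalization.
#' @param max_order maximum radial order (default 7, giving 36 terms).
#' @param pupil_diameter_mm aperture over which the expansion is valid.
#' @param units coefficient units, `"um"` for elevation/OPD in micrometres.
#' @return object of class `zernike_coef` (a named numeric vector with
#'   attributes `max_order`, `pupil_diameter_mm`, `units`).
#' @export
zernike_coef <- function(coeffs, max_order = 7, pupil_diameter_mm, units = "um") {
  nt <- zernike_n_terms(max_order)
  if (length(coeffs) != nt) {
    stop("coefficient vector has length ", length(coeffs),
         " but order ", max_order, " requires ", nt, call. = FALSE)
  }
  stopifnot(pupil_diameter_mm > 0)
  idx <- zernike_index_table(max_order)
  x <- as.numeric(coeffs)
  names(x) <- sprintf("Z%d.%d", idx$n, idx$m)
  structure(x,
            max_order = as.integer(max_order),
            pupil_diameter_mm = as.numeric(pupil_diameter_mm),
            units = units,
            class = "zernike_coef")
}

#' @export
print.zernike_coef <- function(x, ...) {
  cat("Zernike coefficients (ANSI/OSA, unit-variance normalization)\n")
  cat("  max radial order:", attr(x, "max_order"),
      " terms:", length(x), "\n")
  cat("  pupil diameter :", attr(x, "pupil_diameter_mm"), "mm   units:",
      attr(x, "units"), "\n")
  nz <- which(abs(x) > 1e-12)
  if (length(nz)) {
    show <- utils::head(nz[order(-abs(x[nz]))], 8L)
    cat("  largest terms  :\n")
    for (k in show) cat(sprintf("    %-8s %+.4f\n", names(x)[k], x[k]))
  } else {
    cat("  all coefficients are zero\n")
  }
  invisible(x)
}

# selector helper: keep class/attrs after arithmetic on plain vector
replace_coeffs <- function(template, values) {
  zernike_coef(values,
               max_order = attr(template, "max_order"),
               pupil_diameter_mm = attr(template, "pupil_diameter_mm"),
               units = attr(template, "units"))
}

#' Least-squares Zernike fit of an elevation map
#'
#' Fits a Zernike expansion to the in-aperture samples of a gridded
#' elevation map by QR-based linear least squares (no normal equations).
#' Grid points inside the aperture circle that carry missing heights are
#' excluded; if more than 20% of in-aperture points are missing the fit is
#' refused.
#'
#' @param map an [elevation_map].
#' @param diameter_mm analysis aperture diameter (default the map's own).
#' @param max_order maximum radial order (default 7).
#' @param basis optional precomputed design, as returned by
#'   [zernike_fit_design()], to amortize the decomposition across repeated
#'   fits on the same grid geometry.
#' @return a [zernike_coef] with attribute `residual_rms_um` (root mean
#'   square of fit residuals over the in-aperture samples).
#' @export
fit_elevation <- function(map, diameter_mm = NULL, max_order = 7, basis = NULL) {
  stopifnot(inherits(map, "elevation_map"))
  if (is.null(diameter_mm)) diameter_mm <- map$diameter_mm
  stopifnot(diameter_mm > 0)
  if (is.null(basis)) basis <- zernike_fit_design(map, diameter_mm, max_order)
  z <- map$z[basis$inside]
  ok <- !is.na(z)
  frac_missing <- 1 - mean(ok)
  if (frac_missing > 0.20) {
    stop(sprintf("%.0f%% of in-aperture grid points are missing (limit 20%%)",
                 100 * frac_missing), call. = FALSE)
  }
  nt <- zernike_n_terms(max_order)
  if (sum(ok) < 3L * nt) {
    stop("need at least ", 3L * nt, " in-aperture samples to fit ", nt,
         " coefficients; have ", sum(ok), call. = FALSE)
  }
  if (all(ok) && !is.null(basis$qr)) {
    qrd <- basis$qr
  } else {
    qrd <- qr(basis$A[ok, , drop = FALSE])
  }
  if (qrd$rank < nt) {
    stop("rank-deficient Zernike design (rank ", qrd$rank, " < ", nt,
         "): sampling too sparse for order ", max_order, call. = FALSE)
  }
  beta <- qr.coef(qrd, z[ok])
  resid <- z[ok] - basis$A[ok, , drop = FALSE] %*% beta
  out <- zernike_coef(beta, max_order = max_order,
                      pupil_diameter_mm = diameter_mm, units = "um")
  attr(out, "residual_rms_um") <- sqrt(mean(resid^2))
  out
}

#' Precompute the Zernike fit design for a grid geometry
#'
#' @inheritParams fit_elevation
#' @return list with the design matrix `A`, logical index `inside` of
#'   in-aperture grid points, and the QR decomposition `qr` of `A`.
#' @export
zernike_fit_design <- function(map, diameter_mm = NULL, max_order = 7) {
  stopifnot(inherits(map, "elevation_map"))
  if (is.null(diameter_mm)) diameter_mm <- map$diameter_mm
  g <- expand.grid(x = map$xs, y = map$ys)
  r <- sqrt(g$x^2 + g$y^2)
  inside <- r <= diameter_mm / 2 + 1e-12
  rho <- pmin(r[inside] / (diameter_mm / 2), 1)
  theta <- atan2(g$y[inside], g$x[inside])
  A <- zernike_basis(rho, theta, max_order)
  list(A = A, inside = inside, qr = qr(A), diameter_mm = diameter_mm,
       max_order = max_order)
}

#' Reconstruct a surface from Zernike coefficients
#'
#' @param c a [zernike_coef].
#' @param x,y Cartesian coordinates in mm (vectorized). Points outside the
#'   coefficient aperture give NA.
#' @return numeric vector of heights in the coefficient units.
#' @export
reconstruct_surface <- function(c, x, y) {
  stopifnot(inherits(c, "zernike_coef"))
  a <- attr(c, "pupil_diameter_mm") / 2
  r <- sqrt(x^2 + y^2)
  out <- rep(NA_real_, length(r))
  inside <- r <= a + 1e-12
  rho <- pmin(r[inside] / a, 1)
  A <- zernike_basis(rho, atan2(y[inside], x[inside]), attr(c, "max_order"))
  out[inside] <- as.numeric(A %*% as.numeric(c))
  out
}

# per-m-block monomial scaling matrix: maps coefficients on the old aperture
# to coefficients of the same physical surface on aperture ratio s <= 1.
# Within the block of fixed |m| and sign, the radial functions are linearly
# independent polynomials in rho with powers {m, m+2, ...}; restriction to a
# concentric sub-aperture multiplies the rho^p monomial by s^p.
rescale_block_matrix <- function(ns, m, s) {
  powers <- seq(abs(m), max(ns), by = 2)
  P <- matrix(0, nrow = length(powers), ncol = length(ns))
  for (k in seq_along(ns)) {
    n <- ns[k]
    rc <- zernike_radial_coefs(n, m)
    norm <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
    P[match(rc$powers, powers), k] <- norm * rc$coefs
  }
  solve(P, diag(s^powers, nrow = length(powers)) %*% P)
}

#' Rescale Zernike coefficients to a smaller pupil
#'
#' Returns the coefficients of the same physical surface restricted to a
#' smaller concentric aperture. The transform is computed analytically per
#' azimuthal-frequency block via the monomial representation of the radial
#' polynomials, and is exact (it coincides with refitting the reconstructed
#' surface on the smaller aperture). Upscaling would extrapolate beyond the
#' fitted data and is refused.
#'
#' @param c a [zernike_coef].
#' @param new_diameter_mm target aperture, 0 < new <= old.
#' @return a [zernike_coef] on the new aperture.
#' @export
rescale_pupil <- function(c, new_diameter_mm) {
  stopifnot(inherits(c, "zernike_coef"))
  old <- attr(c, "pupil_diameter_mm")
  if (new_diameter_mm <= 0) stop("new diameter must be positive", call. = FALSE)
  if (new_diameter_mm > old + 1e-9) {
    stop("cannot rescale from ", old, " mm up to ", new_diameter_mm,
         " mm: extrapolation outside the fitted aperture", call. = FALSE)
  }
  s <- new_diameter_mm / old
  idx <- zernike_index_table(attr(c, "max_order"))
  out <- as.numeric(c)
  if (abs(s - 1) > 1e-15) {
    for (m in unique(idx$m)) {
      sel <- which(idx$m == m)
      M <- rescale_block_matrix(idx$n[sel], m, s)
      out[sel] <- as.numeric(M %*% out[sel])
    }
  }
  zernike_coef(out, max_order = attr(c, "max_order"),
               pupil_diameter_mm = new_diameter_mm, units = attr(c, "units"))
}

#' Convert elevation coefficients to wavefront (optical path difference)
#'
#' First-surface approximation: a height difference of the anterior cornea
#' changes the optical path by the refractive index step between air and
#' stroma, so each elevation coefficient is multiplied by `delta_n`
#' (default 0.376, n_cornea 1.376 - n_air 1).
#'
#' @param c elevation [zernike_coef] in micrometres.
#' @param delta_n refractive index step (default 0.376).
#' @return OPD [zernike_coef] in micrometres.
#' @export
elevation_to_wavefront <- function(c, delta_n = 0.376) {
  stopifnot(inherits(c, "zernike_coef"), is.numeric(delta_n), length(delta_n) == 1L)
  out <- replace_coeffs(c, as.numeric(c) * delta_n)
  attr(out, "units") <- "um (OPD)"
  out
}

#' RMS aberration groups
#'
#' Computes the root-mean-square amplitudes of the standard corneal
#' aberration groups for a given pupil. Under unit-variance normalization
#' each group RMS is the Euclidean norm of its coefficients. Piston and
#' tilt (orders 0-1) are excluded from every metric.
#'
#' Groups: `total` = orders 2-N; `astigmatism` = (2, +/-2); `hoa` = orders
#' 3-N; `coma_like` = all odd radial orders (3, 5, 7); `spherical_like` =
#' rotationally symmetric higher-order terms (4,0) and (6,0).
#'
#' @param c a [zernike_coef].
#' @param pupil_diameter_mm pupil at which to evaluate (default 6); the
#'   coefficients are rescaled down if fitted on a larger aperture.
#' @return object of class `rms_groups`: list with `total`, `hoa`,
#'   `astigmatism`, `coma_like`, `spherical_like`, `residual_hoa`,
#'   `pupil_diameter_mm`, all in the coefficient units.
#' @export
rms_groups <- function(c, pupil_diameter_mm = 6) {
  stopifnot(inherits(c, "zernike_coef"))
  have <- attr(c, "pupil_diameter_mm")
  if (pupil_diameter_mm > have + 1e-9) {
    stop("coefficients are only valid up to ", have, " mm; cannot report a ",
         pupil_diameter_mm, " mm pupil", call. = FALSE)
  }
  if (abs(pupil_diameter_mm - have) > 1e-12) {
    c <- rescale_pupil(c, pupil_diameter_mm)
  }
  idx <- zernike_index_table(attr(c, "max_order"))
  v <- as.numeric(c)
  rms <- function(sel) sqrt(sum(v[sel]^2))
  total <- rms(idx$n >= 2)
  hoa <- rms(idx$n >= 3)
  astig <- rms(idx$n == 2 & abs(idx$m) == 2)
  coma <- rms(idx$n >= 3 & idx$n %% 2 == 1)
  sph <- rms(idx$n >= 4 & idx$n %% 2 == 0 & idx$m == 0)
  structure(list(total = total, hoa = hoa, astigmatism = astig,
                 coma_like = coma, spherical_like = sph,
                 residual_hoa = sqrt(max(hoa^2 - coma^2 - sph^2, 0)),
                 pupil_diameter_mm = pupil_diameter_mm),
            class = "rms_groups")
}

#' @export
print.rms_groups <- function(x, ...) {
  cat(sprintf("RMS aberrations (%g mm pupil, um):\n", x$pupil_diameter_mm))
  cat(sprintf("  total %.3f | HOA %.3f | astig %.3f | coma-like %.3f | spherical-like %.3f\n",
              x$total, x$hoa, x$astigmatism, x$coma_like, x$spherical_like))
  invisible(x)
}
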