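#' Complex pupil function from a wavefront
#'
#' Samples the generalized pupil function P = A * exp(i * 2*pi * W / lambda)
#' on a square grid: unit amplitude inside the aperture, zero outside, with
#' the wavefront W reconstructed from OPD Zernike coefficients. The pupil
#' spans `grid_n` samples across its diameter and is embedded in an array
#' `grid_n * pad_factor` on a side so the discrete Fourier transform is
#' adequately sampled.
#'
#' @param w OPD [zernike_coef] in micrometres.
#' @param wavelength_nm light wavelength (default 550, photopic peak).
#' @param grid_n samples across the pupil diameter (>= 64).
#' @param pad_factor zero-padding multiple (>= 2).
#' @return object of class `pupil_field`: list with the complex `field`
#'   matrix, logical aperture `mask`, and the sampling metadata.
#' @export
# memoized pupil-grid geometry + Zernike basis, keyed by grid_n/max_order:
# the same pupil sampling is reused thousands of times during planning
.pupil_cache <- new.env(parent = emptyenv())

pupil_grid_basis <- function(grid_n, max_order) {
  key <- paste(grid_n, max_order, sep = "|")
  hit <- .pupil_cache[[key]]
  if (!is.null(hit)) return(hit)
  u <- (seq_len(grid_n) - (grid_n + 1) / 2) / (grid_n / 2)
  g <- expand.grid(x = u, y = u)
  r <- sqrt(g$x^2 + g$y^2)
  inside <- r <= 1
  A <- zernike_basis(r[inside], atan2(g$y[inside], g$x[inside]), max_order)
  out <- list(inside = inside, A = A)
  .pupil_cache[[key]] <- out
  out
}

pupil_function <- function(w, wavelength_nm = 550, grid_n = 256, pad_factor = 4) {
  stopifnot(inherits(w, "zernike_coef"))
  if (wavelength_nm <= 0) stop("wavelength must be positive", call. = FALSE)
  if (grid_n < 64) stop("grid_n must be at least 64", call. = FALSE)
  if (pad_factor < 2) stop("pad_factor must be at least 2", call. = FALSE)
  n_tot <- as.integer(grid_n * pad_factor)
  gb <- pupil_grid_basis(grid_n, attr(w, "max_order"))
  inside <- gb$inside
  lambda_um <- wavelength_nm / 1000
  phase <- numeric(sum(inside))
  v <- as.numeric(w)
  if (any(v != 0)) {
    phase <- 2 * pi * as.numeric(gb$A %*% v) / lambda_um
  }
  tile <- matrix(0 + 0i, grid_n, grid_n)
  tile[inside] <- exp(1i * phase)
  field <- matrix(0 + 0i, n_tot, n_tot)
  o <- (n_tot - grid_n) %/% 2
  field[o + seq_len(grid_n), o + seq_len(grid_n)] <- tile
  mask <- matrix(FALSE, n_tot, n_tot)
  tm <- matrix(FALSE, grid_n, grid_n); tm[inside] <- TRUE
  mask[o + seq_len(grid_n), o + seq_len(grid_n)] <- tm
  structure(list(field = field, mask = mask,
                 wavelength_nm = wavelength_nm, grid_n = grid_n,
                 pad_factor = pad_factor,
                 pupil_diameter_mm = attr(w, "pupil_diameter_mm")),
            class = "pupil_field")
}

fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((n1 %/% 2 + 1):n1, 1:(n1 %/% 2)), c((n2 %/% 2 + 1):n2, 1:(n2 %/% 2))]
}

#' Point-spread function and Strehl ratio of a pupil field
#'
#' Far-field PSF by discrete Fourier transform: intensity is the squared
#' modulus of the transform of the pupil field, centered on the optical
#' axis. The Strehl ratio is the peak intensity relative to the peak of the
#' diffraction-limited PSF of the same aperture geometry (for which the
#' on-axis amplitude is the number of in-aperture samples), so an
#' unaberrated pupil scores exactly 1 and any pure image translation (tilt)
#' leaves the score unchanged.
#'
#' @param pf a `pupil_field` from [pupil_function()].
#' @return object of class `psf_result`: list with the normalized
#'   `intensity` grid (peak of the diffraction-limited reference = 1),
#'   `strehl`, and sampling metadata.
#' @export
# sub-pixel peak estimate: separable 3-point parabolic interpolation at the
# discrete maximum (exact at the DC bin for an unaberrated pupil)
peak_interp <- function(I) {
  k <- arrayInd(which.max(I), dim(I))
  i <- k[1]; j <- k[2]
  peak <- I[i, j]
  refine1 <- function(a, b, c) {
    den <- a - 2 * b + c
    if (den >= 0) return(b)   # not concave: keep the sample
    b - (a - c)^2 / (8 * den)
  }
  if (i > 1 && i < nrow(I)) peak <- refine1(I[i - 1, j], peak, I[i + 1, j])
  if (j > 1 && j < ncol(I)) {
    peak <- peak + (refine1(I[i, j - 1], I[i, j], I[i, j + 1]) - I[i, j])
  }
  peak
}

compute_psf <- function(pf) {
  stopifnot(inherits(pf, "pupil_field"))
  F <- stats::fft(pf$field)
  I <- fftshift2(Re(F)^2 + Im(F)^2)
  peak_ref <- sum(pf$mask)^2
  I <- I / peak_ref
  structure(list(intensity = I, strehl = min(peak_interp(I), 1),
                 wavelength_nm = pf$wavelength_nm,
                 pupil_diameter_mm = pf$pupil_diameter_mm,
                 grid_n = pf$grid_n, pad_factor = pf$pad_factor),
            class = "psf_result")
}

#' @export
print.psf_result <- function(x, ...) {
  cat(sprintf(
    "PSF (%g mm pupil, %g nm, grid %d x pad %d): Strehl ratio %.4g\n",
    x$pupil_diameter_mm, x$wavelength_nm, x$grid_n, x$pad_factor, x$strehl))
  invisible(x)
}

#' @export
plot.psf_result <- function(x, zoom = 8, log_scale = TRUE,
                            main = "Point-spread function", ...) {
  n <- nrow(x$intensity)
  half <- max(8L, n %/% (2L * zoom))
  sel <- (n %/% 2 - half):(n %/% 2 + half)
  I <- x$intensity[sel, sel]
  if (log_scale) I <- log10(pmax(I, max(I) * 1e-6))
  graphics::image(I, asp = 1, axes = FALSE, main = main, ...)
  invisible(x)
}

#' Strehl ratio of a wavefront
#'
#' Optical-quality scalar: the PSF peak relative to the diffraction-limited
#' peak. Piston and tilt coefficients are removed first -- they shift the
#' image without degrading it -- so the metric is exactly invariant to
#' orders 0 and 1.
#'
#' @inheritParams pupil_function
#' @return Strehl ratio in (0, 1].
#' @export
strehl_ratio <- function(w, wavelength_nm = 550, grid_n = 256, pad_factor = 4) {
  idx <- zernike_index_table(attr(w, "max_order"))
  v <- as.numeric(w)
  v[idx$n <= 1] <- 0
  w <- replace_coeffs(w, v)
  compute_psf(pupil_function(w, wavelength_nm, grid_n, pad_factor))$strehl
}

#' Second-order toggle
#'
#' The planner can rank candidate surgeries for uncorrected vision (UDVA),
#' in which case the full wavefront including defocus and astigmatism is
#' scored, or for spectacle-corrected vision (CDVA), in which case the
#' second-order terms -- the part spectacles can correct -- are removed
#' before scoring.
#'
#' @param w a [zernike_coef].
#' @param include_second_order if `FALSE`, zero all radial-order-2 terms
#'   (defocus and both astigmatisms).
#' @return a [zernike_coef].
#' @export
apply_second_order_toggle <- function(w, include_second_order = TRUE) {
  stopifnot(inherits(w, "zernike_coef"))
  if (include_second_order) return(w)
  idx <- zernike_index_table(attr(w, "max_order"))
  v <- as.numeric(w)
  v[idx$n == 2] <- 0
  replace_coeffs(w, v)
}
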