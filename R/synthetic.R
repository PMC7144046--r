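#' Synthetic cornea parameters
#'
#' Parameter set of the synthetic keratoconic anterior surface: a conicoid
#' base (apical radius + asphericity) with a localized Gaussian cone bump,
#' a toric component, and measurement noise.
#'
#' @param apical_radius_mm apical radius of the conicoid base, in \[6, 9\].
#' @param asphericity_q conic constant Q (0 = sphere; keratoconic corneas
#'   are typically prolate, Q < 0).
#' @param cone_amplitude_um peak additional sag of the cone (>= 0).
#' @param cone_sigma_mm Gaussian radius of the cone.
#' @param cone_center_mm length-2 (x, y) cone apex position.
#' @param astigmatism_d corneal toricity, dioptres of K difference between
#'   principal meridians.
#' @param astigmatism_axis_deg steep meridian axis.
#' @param noise_sd_um per-point Gaussian elevation noise (>= 0).
#' @param seed RNG seed for the noise.
#' @return list of class `cornea_params`.
#' @export
cornea_params <- function(apical_radius_mm = 7.1, asphericity_q = -0.3,
                          cone_amplitude_um = 35, cone_sigma_mm = 1.2,
                          cone_center_mm = c(0.8, -0.6),
                          astigmatism_d = 2, astigmatism_axis_deg = 90,
                          noise_sd_um = 0.5, seed = 1) {
  stopifnot(apical_radius_mm >= 6, apical_radius_mm <= 9,
            cone_amplitude_um >= 0, noise_sd_um >= 0, cone_sigma_mm > 0)
  structure(list(apical_radius_mm = apical_radius_mm,
                 asphericity_q = asphericity_q,
                 cone_amplitude_um = cone_amplitude_um,
                 cone_sigma_mm = cone_sigma_mm,
                 cone_center_mm = cone_center_mm,
                 astigmatism_d = astigmatism_d,
                 astigmatism_axis_deg = astigmatism_axis_deg,
                 noise_sd_um = noise_sd_um, seed = seed),
            class = "cornea_params")
}

#' Generate a synthetic keratoconic elevation map
#'
#' Anterior surface sag (height, micrometres, increasing posteriorly) on a
#' uniform grid: conicoid base
#' `z = r^2 / (R (1 + sqrt(1 - (1+Q) r^2 / R^2)))`, plus a Gaussian cone
#' bump, plus a toric sag term realizing the requested keratometric
#' astigmatism, plus seeded Gaussian noise. The grid covers at least the
#' 8 mm analysis aperture.
#'
#' @param p a [cornea_params].
#' @param grid_n grid points per side (default 121).
#' @param width_mm grid width (default 9, covering the 8 mm aperture).
#' @return an [elevation_map] with `corneal_vertex` at the origin and
#'   geometric-center / pupil-center reference offsets in the metadata.
#' @export
generate_cornea <- function(p, grid_n = 121, width_mm = 9) {
  stopifnot(inherits(p, "cornea_params"))
  xs <- seq(-width_mm / 2, width_mm / 2, length.out = grid_n)
  g <- expand.grid(x = xs, y = xs)
  r2 <- g$x^2 + g$y^2
  R <- p$apical_radius_mm
  disc <- 1 - (1 + p$asphericity_q) * r2 / R^2
  if (any(disc <= 0 & r2 <= 16)) {
    stop("conicoid undefined inside the 8 mm aperture; reduce asphericity",
         call. = FALSE)
  }
  # grid corners beyond the aperture may fall outside the conicoid's
  # domain for steep corneas; flag them missing
  bad <- disc <= 0
  disc[bad] <- 1
  z_mm <- r2 / (R * (1 + sqrt(disc)))
  z_mm[bad] <- NA_real_
  # toric sag: +/- half the curvature split on the steep/flat meridians
  ax <- p$astigmatism_axis_deg * pi / 180
  theta <- atan2(g$y, g$x)
  dcurv <- p$astigmatism_d / 337.5   # 1/mm of curvature difference
  z_mm <- z_mm + (r2 / 2) * (dcurv / 2) * cos(2 * (theta - ax))
  z <- z_mm * 1000
  dx <- g$x - p$cone_center_mm[1]; dy <- g$y - p$cone_center_mm[2]
  z <- z + p$cone_amplitude_um *
    exp(-(dx^2 + dy^2) / (2 * p$cone_sigma_mm^2))
  if (p$noise_sd_um > 0) {
    z <- z + with_seed(p$seed, stats::rnorm(length(z), 0, p$noise_sd_um))
  }
  elevation_map(xs, xs, matrix(z, grid_n, grid_n),
                center = "corneal_vertex", diameter_mm = 8,
                ref_points = list(
                  corneal_vertex = c(0, 0),
                  geometric_center = c(0, 0),
                  pupil_center = c(0.2, 0.1)))
}

#' Mechanistic ring-effect parameters
#'
#' The deterministic stand-in for the morphological effect of an implanted
#' arc segment: a smooth flattening field (sag reduction) concentric with
#' the segment track, scaled linearly by thickness and arc coverage, and
#' weighted toward the segment's side of the cornea so a segment bisecting
#' the cone meridian attenuates the cone's asymmetry.
#'
#' @param amplitude_um peak sag reduction of the track component for a
#'   reference-thickness, full-ring implant.
#' @param sigma_mm radial width of the flattening field around the segment
#'   track.
#' @param inner_fraction amplitude of the inner (cone-attenuating)
#'   component relative to the track component.
#' @param inner_radius_mm,inner_sigma_mm radial center and width of the
#'   inner component (mid-periphery, where cone apices sit).
#' @param angular_floor fraction of the track effect applied on all
#'   meridians (the rest is confined to the arc window).
#' @param taper_deg angular half-taper beyond the arc ends.
#' @param thickness_ref_um thickness at which the amplitude is nominal.
#' @return list of class `ring_effect_params`.
#' @export
ring_effect_params <- function(amplitude_um = 35, sigma_mm = 1.2,
                               inner_fraction = 0.6,
                               inner_radius_mm = 1.1,
                               inner_sigma_mm = 1.0,
                               angular_floor = 0.25, taper_deg = 30,
                               thickness_ref_um = 300) {
  structure(list(amplitude_um = amplitude_um, sigma_mm = sigma_mm,
                 inner_fraction = inner_fraction,
                 inner_radius_mm = inner_radius_mm,
                 inner_sigma_mm = inner_sigma_mm,
                 angular_floor = angular_floor, taper_deg = taper_deg,
                 thickness_ref_um = thickness_ref_um),
            class = "ring_effect_params")
}

#' Apply the mechanistic ring effect to an elevation map
#'
#' Each segment subtracts a deterministic, closed-form sag field scaled
#' linearly by thickness and arc coverage,
#' `A * (thickness/ref) * (arc/360)`, with two radial components: a track
#' component `exp(-(r - r0)^2 / (2 sigma^2))` centered on the segment track
#' radius `r0` (model diameter / 2) and weighted by an arc window (1 inside
#' the arc, cosine taper to a floor outside), and an inner component at the
#' mid-periphery weighted by `max(cos(theta - bisect), 0)`, i.e. acting
#' only on the segment's side of the cornea. Reducing peripheral sag
#' relative to the apex flattens the central keratometry; the one-sided
#' inner component attenuates the cone bump when the bisecting line points
#' at the cone meridian, which is what drives the coma-like reduction.
#'
#' @param map an [elevation_map].
#' @param segments list of 1-2 [segment_spec] (a single spec is accepted).
#' @param effect a [ring_effect_params].
#' @return the modified [elevation_map].
#' @export
apply_ring_effect <- function(map, segments, effect = ring_effect_params()) {
  stopifnot(inherits(map, "elevation_map"), inherits(effect, "ring_effect_params"))
  if (inherits(segments, "segment_spec")) segments <- list(segments)
  stopifnot(length(segments) %in% 1:2,
            all(vapply(segments, inherits, TRUE, "segment_spec")))
  g <- expand.grid(x = map$xs, y = map$ys)
  r <- sqrt(g$x^2 + g$y^2)
  theta <- atan2(g$y, g$x)
  theta_deg <- (theta * 180 / pi) %% 360
  dz <- numeric(nrow(g))
  for (s in segments) {
    r0 <- s$diameter_mm / 2
    amp <- effect$amplitude_um * (s$thickness_um / effect$thickness_ref_um) *
      (s$arc_deg / 360)
    d <- angle_dist(theta_deg, s$bisecting_line_deg)
    half <- s$arc_deg / 2
    ramp <- clamp((d - half) / effect$taper_deg, 0, 1)
    W <- effect$angular_floor +
      (1 - effect$angular_floor) * 0.5 * (1 + cos(pi * ramp))
    track <- exp(-(r - r0)^2 / (2 * effect$sigma_mm^2)) * W
    side <- pmax(cos(theta - s$bisecting_line_deg * pi / 180), 0)
    inner <- effect$inner_fraction *
      exp(-(r - effect$inner_radius_mm)^2 / (2 * effect$inner_sigma_mm^2)) *
      side
    dz <- dz + amp * (track + inner)
  }
  map$z <- map$z - matrix(dz, length(map$xs), length(map$ys))
  map
}

#' Visual-acuity proxy from the Strehl ratio
#'
#' Synthetic-cohort stand-in mapping optical quality to visual acuity:
#' LogMAR is a monotone decreasing function of log10 Strehl,
#' `logmar = clamp(intercept + slope * (-log10 S), 0, 1.3)`, optionally
#' with additive Gaussian noise (clamped again). A diffraction-limited eye
#' scores LogMAR 0; heavily aberrated corneas approach the 1.3 floor
#' acuity. This is a modelling device for generating plausible cohorts, not
#' a clinically validated acuity model.
#'
#' @param strehl Strehl ratio(s) in (0, 1\].
#' @param intercept,slope shape parameters of the monotone map.
#' @param noise_sd LogMAR noise standard deviation (0 = deterministic).
#' @return decimal visual acuity value(s).
#' @export
va_from_strehl <- function(strehl, intercept = -0.25, slope = 0.22,
                           noise_sd = 0) {
  stopifnot(all(strehl > 0))
  lm <- clamp(intercept + slope * (-log10(strehl)), 0, 1.3)
  if (noise_sd > 0) lm <- clamp(lm + stats::rnorm(length(lm), 0, noise_sd), 0, 1.3)
  logmar_to_decimal(lm)
}

# reference-cornea wavefront defocus coefficient over a pupil (um OPD):
# exact sphere sag projected on the (2,0) Zernike term by radial quadrature
reference_defocus_c20 <- function(pupil_diameter_mm = 6,
                                  reference_radius_mm = 7.5,
                                  delta_n = 0.376) {
  a <- pupil_diameter_mm / 2
  rho <- (seq_len(2048) - 0.5) / 2048
  sag_um <- 1000 * (a * rho)^2 /
    (reference_radius_mm * (1 + sqrt(1 - (a * rho)^2 / reference_radius_mm^2)))
  # mean over the disk of z * Z20: integral of z(rho)*sqrt3(2rho^2-1)*2rho drho
  sum(sag_um * sqrt(3) * (2 * rho^2 - 1) * 2 * rho) / 2048 * delta_n
}

#' Spherical-equivalent proxy from wavefront defocus
#'
#' Paraxial relation `SE = -4 sqrt(3) c20 / r^2` (c20 in um, pupil radius r
#' in mm) applied to the corneal-wavefront defocus in excess of an
#' emmetropic reference cornea. The raw corneal defocus encodes the
#' cornea's entire refractive power, so the defocus of a reference sphere
#' (default 7.5 mm radius, 45 D) is subtracted first: a cornea
#' steeper than the reference comes out myopic (negative SE), matching the
#' sign convention of clinical tables.
#'
#' @param wavefront OPD [zernike_coef] (um), valid at the requested pupil.
#' @param pupil_diameter_mm pupil for the paraxial relation (default 6).
#' @param reference_radius_mm emmetropic reference radius (default 7.5).
#' @return spherical equivalent in dioptres.
#' @export
se_from_defocus <- function(wavefront, pupil_diameter_mm = 6,
                            reference_radius_mm = 7.5) {
  stopifnot(inherits(wavefront, "zernike_coef"))
  w <- if (abs(attr(wavefront, "pupil_diameter_mm") - pupil_diameter_mm) > 1e-12)
    rescale_pupil(wavefront, pupil_diameter_mm) else wavefront
  idx <- zernike_index_table(attr(w, "max_order"))
  c20 <- as.numeric(w)[idx$n == 2 & idx$m == 0]
  c20_ref <- reference_defocus_c20(pupil_diameter_mm, reference_radius_mm)
  r <- pupil_diameter_mm / 2
  -4 * sqrt(3) * (c20 - c20_ref) / r^2
}

#' Cohort sampling distributions
#'
#' Settings of the synthetic-cohort sampler. Corneas are parameterized by
#' a target mean Sim-K (sampled normally and hit by a one-step curvature
#' calibration), cone amplitude/width/position, toricity and noise; segment
#' choices emulate clinical practice by aiming the bisecting line near the
#' cone meridian.
#'
#' @param target_simk_mean_d,target_simk_sd_d preoperative mean Sim-K
#'   distribution (default 47.56 +/- 3.8 D, an advanced-keratoconus regime).
#' @param cone_amplitude_range_um,cone_sigma_range_mm,cone_radius_range_mm
#'   uniform ranges for the cone bump.
#' @param astigmatism_range_d uniform range of corneal toricity.
#' @param asphericity_range_q uniform range of the conic constant.
#' @param noise_sd_um elevation noise.
#' @param p_two_segments probability a case receives two segments.
#' @param axis_jitter_deg SD of the bisecting-line deviation from the cone
#'   meridian; `Inf` (the default) draws axes uniformly over the circle so
#'   the implant effect is identifiable independently of the cornea.
#' @param axis_grid_deg surgical axes are specified on this grid (degrees),
#'   as on a clinical protractor.
#' @param thickness_set candidate thicknesses (um).
#' @return list of class `cohort_distributions`.
#' @export
cohort_distributions <- function(target_simk_mean_d = 47.56,
                                 target_simk_sd_d = 3.8,
                                 cone_amplitude_range_um = c(15, 60),
                                 cone_sigma_range_mm = c(0.9, 1.6),
                                 cone_radius_range_mm = c(0.4, 1.5),
                                 astigmatism_range_d = c(0.5, 4),
                                 asphericity_range_q = c(-0.6, -0.1),
                                 noise_sd_um = 0.5,
                                 p_two_segments = 0.4,
                                 axis_jitter_deg = Inf,
                                 axis_grid_deg = 5,
                                 thickness_set = default_thickness_set()) {
  structure(as.list(environment()), class = "cohort_distributions")
}

#' Sample one synthetic cornea from the cohort distributions
#'
#' Draws cornea parameters, builds the surface, then applies a one-step
#' curvature correction so the measured mean Sim-K hits the drawn target
#' (the clinical parameterization is keratometric, not radius-based).
#'
#' @param dist a [cohort_distributions].
#' @param seed RNG seed for this draw.
#' @return list with `params` ([cornea_params]), `map` ([elevation_map]),
#'   `cone_meridian_deg`, and the drawn `target_simk_d`.
#' @export
sample_cornea_params <- function(dist, seed) {
  with_seed(seed, {
    k_target <- stats::rnorm(1, dist$target_simk_mean_d, dist$target_simk_sd_d)
    k_target <- clamp(k_target, 41, 58)
    runifr <- function(r) stats::runif(1, r[1], r[2])
    cone_angle <- stats::runif(1, 0, 360)
    cone_r <- runifr(dist$cone_radius_range_mm)
    p <- cornea_params(
      apical_radius_mm = clamp(337.5 / k_target, 6, 9),
      asphericity_q = runifr(dist$asphericity_range_q),
      cone_amplitude_um = runifr(dist$cone_amplitude_range_um),
      cone_sigma_mm = runifr(dist$cone_sigma_range_mm),
      cone_center_mm = cone_r * c(cos(cone_angle * pi / 180),
                                  sin(cone_angle * pi / 180)),
      astigmatism_d = runifr(dist$astigmatism_range_d),
      astigmatism_axis_deg = stats::runif(1, 0, 180),
      noise_sd_um = 0, seed = seed)
    map0 <- generate_cornea(p)
    k0 <- simulated_keratometry(map0, n_meridians = 24)$mean_simk
    inv_r_new <- 1 / p$apical_radius_mm + (k_target - k0) / 337.5
    p$apical_radius_mm <- clamp(1 / inv_r_new, 6, 9)
    p$noise_sd_um <- dist$noise_sd_um
    p$seed <- seed + 1L
    list(params = p, map = generate_cornea(p),
         cone_meridian_deg = cone_angle, target_simk_d = k_target)
  })
}

# segment choice: bisecting lines drawn uniformly over the protractor grid
# (with an optional pull toward the cone meridian), second segment roughly
# opposite the first. Keeping substantial axis spread independent of the
# cone is essential: if implanted axes always tracked the cone, the
# training set would carry no information to separate the implant's effect
# from the cornea it was implanted in.
sample_segments <- function(dist, cone_meridian_deg, seed) {
  with_seed(seed, {
    cat <- keraring_catalog()
    two <- stats::runif(1) < dist$p_two_segments
    pick <- function(axis) {
      k <- sample.int(nrow(cat), 1L)
      axis <- (round(axis / dist$axis_grid_deg) * dist$axis_grid_deg) %% 360
      segment_spec(cat$model[k], cat$arc_deg[k],
                   sample(dist$thickness_set, 1L), axis)
    }
    a1 <- if (is.finite(dist$axis_jitter_deg)) {
      cone_meridian_deg + stats::rnorm(1, 0, dist$axis_jitter_deg)
    } else {
      stats::runif(1, 0, 360)
    }
    segs <- list(pick(a1))
    if (two) {
      a2 <- a1 + 180 + stats::rnorm(1, 0, 20)
      s2 <- pick(a2)
      # keep drawing arcs until the pair does not overlap
      tries <- 0L
      while (angle_dist(segs[[1]]$bisecting_line_deg, s2$bisecting_line_deg) <
             (segs[[1]]$arc_deg + s2$arc_deg) / 2 && tries < 20L) {
        s2 <- pick(a2); tries <- tries + 1L
      }
      if (angle_dist(segs[[1]]$bisecting_line_deg, s2$bisecting_line_deg) >=
          (segs[[1]]$arc_deg + s2$arc_deg) / 2) {
        segs <- c(segs, list(s2))
      }
    }
    segs
  })
}

# full clinical metric set for one cornea state; RMS groups are reported on
# the corneal wavefront (clinical convention: elevation converted to OPD)
eye_metrics <- function(coef8, psf_grid_n = 64, psf_pad = 2,
                        wavelength_nm = 550) {
  c6 <- rescale_pupil(coef8, 6)
  w6 <- elevation_to_wavefront(c6)
  s_full <- strehl_ratio(w6, wavelength_nm, psf_grid_n, psf_pad)
  s_hoa <- strehl_ratio(apply_second_order_toggle(w6, FALSE),
                        wavelength_nm, psf_grid_n, psf_pad)
  list(rms = rms_groups(w6, 6),
       strehl_full = s_full, strehl_hoa = s_hoa,
       se = se_from_defocus(w6))
}

#' Generate a success-filtered synthetic training cohort
#'
#' Rejection-samples synthetic surgeries until `n_target` cases passing the
#' surgical success filter are collected: sample a keratoconic cornea and a
#' clinically plausible segment configuration, apply the mechanistic ring
#' effect, compute pre/post Zernike fits (8 mm), RMS groups (6 mm), Strehl
#' ratios, the visual-acuity proxy and the spherical-equivalent proxy, and
#' keep the case if it meets any success criterion.
#'
#' @param n_target number of successful cases to return (default 75).
#' @param dist a [cohort_distributions].
#' @param effect a [ring_effect_params].
#' @param seed cohort seed; every random draw descends from it.
#' @param va_noise_sd LogMAR noise of the acuity proxy (default 0.05).
#' @param max_attempts bound on sampled surgeries before giving up.
#' @return list of [case_record] objects, length `n_target`, with the
#'   acceptance rate and the generating seed in attributes `accept_rate`
#'   and `seed`.
#' @export
generate_training_cohort <- function(n_target = 75,
                                     dist = cohort_distributions(),
                                     effect = ring_effect_params(),
                                     seed = 1,
                                     va_noise_sd = 0.05,
                                     max_attempts = 50 * n_target) {
  stopifnot(n_target >= 1)
  cases <- vector("list", n_target)
  got <- 0L
  attempts <- 0L
  design <- NULL
  while (got < n_target) {
    attempts <- attempts + 1L
    if (attempts > max_attempts ||
        (attempts >= 300L && got / attempts < 0.01)) {
      stop("cohort acceptance rate too low (", got, "/", attempts,
           "); revise the cohort distributions or the ring-effect parameters",
           call. = FALSE)
    }
    # per-attempt sub-seed, kept below 2^31 (R RNG seeds are 32-bit)
    case_seed <- (as.numeric(seed) * 100003 + attempts * 7) %% 2147483647
    cs <- sample_cornea_params(dist, case_seed)
    segs <- sample_segments(dist, cs$cone_meridian_deg, case_seed + 3L)
    post_map <- apply_ring_effect(cs$map, segs, effect)
    if (is.null(design)) design <- zernike_fit_design(cs$map, 8, 7)
    pre8 <- fit_elevation(cs$map, 8, 7, basis = design)
    post8 <- fit_elevation(post_map, 8, 7, basis = design)
    pre <- eye_metrics(pre8)
    post <- eye_metrics(post8)
    va <- with_seed(case_seed + 5L, list(
      pre_ud = va_from_strehl(pre$strehl_full, noise_sd = va_noise_sd),
      pre_cd = va_from_strehl(pre$strehl_hoa, noise_sd = va_noise_sd),
      post_ud = va_from_strehl(post$strehl_full, noise_sd = va_noise_sd),
      post_cd = va_from_strehl(post$strehl_hoa, noise_sd = va_noise_sd)))
    cs_rec <- case_record(
      preop_zernike = pre8, postop_zernike = post8,
      preop_udva = va$pre_ud, postop_udva = va$post_ud,
      preop_cdva = va$pre_cd, postop_cdva = va$post_cd,
      preop_se = pre$se, postop_se = post$se,
      preop_rms = pre$rms, postop_rms = post$rms,
      implant = segs, months_followup = 6)
    if (success_filter(cs_rec)$is_success) {
      got <- got + 1L
      attr(cs_rec, "target_simk_d") <- cs$target_simk_d
      cases[[got]] <- cs_rec
    }
  }
  attr(cases, "accept_rate") <- got / attempts
  attr(cases, "seed") <- seed
  cases
}
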