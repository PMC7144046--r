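#' Convert decimal visual acuity to LogMAR
#'
#' LogMAR = -log10(decimal acuity), reported to two decimals with R's
#' round-half-even policy, matching the convention of clinical tables that
#' print the decimal acuity with the LogMAR value in brackets.
#'
#' @param v decimal acuity in (0, 2\].
#' @param digits rounding digits (default 2; use `Inf` for no rounding).
#' @return LogMAR value(s).
#' @export
#' @examples
#' decimal_to_logmar(0.60)  # 0.22
#' decimal_to_logmar(0.20)  # 0.70
decimal_to_logmar <- function(v, digits = 2) {
  if (any(v <= 0)) stop("decimal acuity must be positive", call. = FALSE)
  lm <- -log10(v)
  if (is.finite(digits)) lm <- round(lm, digits) + 0  # drop -0
  lm
}

#' Convert LogMAR to decimal visual acuity
#' @param logmar LogMAR value(s).
#' @return decimal acuity 10^(-LogMAR).
#' @export
logmar_to_decimal <- function(logmar) {
  10^(-logmar)
}

#' Grade of visual limitation
#'
#' Keratoconus severity graded by spectacle-corrected distance visual
#' acuity: grade I for CDVA of 0.90 or better; II for 0.60 or better but
#' worse than 0.90; III for 0.40 to below 0.60; IV for 0.20 to below 0.40;
#' Plus for CDVA worse than 0.20.
#'
#' @param cdva decimal corrected distance visual acuity (> 0, vectorized).
#' @return factor with levels `I`, `II`, `III`, `IV`, `Plus`.
#' @export
#' @examples
#' grade_visual_limitation(c(0.95, 0.60, 0.45, 0.25, 0.15))
grade_visual_limitation <- function(cdva) {
  if (any(cdva <= 0)) stop("decimal acuity must be positive", call. = FALSE)
  g <- ifelse(cdva >= 0.90, "I",
       ifelse(cdva >= 0.60, "II",
       ifelse(cdva >= 0.40, "III",
       ifelse(cdva >= 0.20, "IV", "Plus"))))
  factor(g, levels = c("I", "II", "III", "IV", "Plus"))
}

# algebraic (Kasa) circle fit to a meridional profile (s in mm, z in mm);
# returns radius of curvature in mm
circle_fit_radius <- function(s, z) {
  A <- cbind(s, z, 1)
  b <- -(s^2 + z^2)
  sol <- qr.coef(qr(A), b)
  r2 <- (sol[1]^2 + sol[2]^2) / 4 - sol[3]
  if (!is.finite(r2) || r2 <= 0) return(NA_real_)
  sqrt(r2)
}

#' Simulated keratometry
#'
#' Corneal power in the central zone, by meridian: the elevation profile
#' along each meridian (sampled across the full zone diameter through the
#' map origin) is fitted with a circle, and the radius of curvature is
#' converted to dioptres with the keratometric index,
#' K = (n_k - 1) * 1000 / R_mm. K1 and K2 are the flattest and steepest
#' meridians; mean Sim-K is their average.
#'
#' @param map an [elevation_map].
#' @param zone_mm zone diameter (default 3).
#' @param n_meridians number of meridians sampled over 180 degrees
#'   (default 180, i.e. 1-degree steps).
#' @param n_samples samples along each meridian profile (default 33).
#' @param keratometric_index default 1.3375.
#' @return object of class `k_readings`: list with `k1`, `k2`, `mean_simk`
#'   (dioptres), `axis1_deg`, `axis2_deg`, `zone_mm`.
#' @export
simulated_keratometry <- function(map, zone_mm = 3, n_meridians = 180,
                                  n_samples = 33,
                                  keratometric_index = 1.3375) {
  stopifnot(inherits(map, "elevation_map"), zone_mm > 0)
  s <- seq(-zone_mm / 2, zone_mm / 2, length.out = n_samples)
  angles <- seq(0, 180, length.out = n_meridians + 1)[seq_len(n_meridians)]
  K <- rep(NA_real_, n_meridians)
  for (i in seq_len(n_meridians)) {
    th <- angles[i] * pi / 180
    z_um <- interp_bicubic(map, s * cos(th), s * sin(th))
    ok <- is.finite(z_um)
    if (sum(ok) < 5L || max(abs(s[ok])) < 0.9 * zone_mm / 2) {
      stop("insufficient elevation samples: the ", zone_mm,
           " mm zone is not covered along meridian ", angles[i],
           " degrees", call. = FALSE)
    }
    R <- circle_fit_radius(s[ok], z_um[ok] / 1000)
    K[i] <- (keratometric_index - 1) * 1000 / R
  }
  if (anyNA(K)) stop("curvature fit failed on some meridians", call. = FALSE)
  i1 <- which.min(K); i2 <- which.max(K)
  structure(list(k1 = K[i1], k2 = K[i2], mean_simk = (K[i1] + K[i2]) / 2,
                 axis1_deg = angles[i1], axis2_deg = angles[i2],
                 zone_mm = zone_mm, meridian_k = K,
                 meridian_deg = angles),
            class = "k_readings")
}

#' @export
print.k_readings <- function(x, ...) {
  cat(sprintf(
    "Simulated keratometry (%g mm zone): K1 %.2f D @ %g, K2 %.2f D @ %g, mean Sim-K %.2f D\n",
    x$zone_mm, x$k1, x$axis1_deg, x$k2, x$axis2_deg, x$mean_simk))
  invisible(x)
}

#' Construct a surgical case record
#'
#' One ICRS case: pre- and post-operative Zernike elevation coefficients
#' (8 mm), visual acuities (decimal), spherical equivalents (dioptres), RMS
#' aberration groups (6 mm), and the implanted segments.
#'
#' @param preop_zernike,postop_zernike [zernike_coef] at 8 mm, order 7.
#' @param preop_udva,postop_udva,preop_cdva,postop_cdva decimal acuities.
#' @param preop_se,postop_se spherical equivalents (D).
#' @param preop_rms,postop_rms [rms_groups] at 6 mm.
#' @param implant list of 1 or 2 [segment_spec] objects.
#' @param months_followup follow-up at which the post-op data were taken.
#' @return object of class `case_record`.
#' @export
case_record <- function(preop_zernike, postop_zernike,
                        preop_udva, postop_udva,
                        preop_cdva, postop_cdva,
                        preop_se, postop_se,
                        preop_rms, postop_rms,
                        implant, months_followup = 6) {
  stopifnot(inherits(preop_zernike, "zernike_coef"),
            inherits(postop_zernike, "zernike_coef"),
            inherits(preop_rms, "rms_groups"),
            inherits(postop_rms, "rms_groups"))
  if (!is.list(implant) || !length(implant) %in% 1:2 ||
      !all(vapply(implant, inherits, TRUE, "segment_spec"))) {
    stop("implant must be a list of 1 or 2 segment_spec objects", call. = FALSE)
  }
  stopifnot(months_followup >= 0)
  structure(list(preop_zernike = preop_zernike,
                 postop_zernike = postop_zernike,
                 preop_udva = preop_udva, postop_udva = postop_udva,
                 preop_cdva = preop_cdva, postop_cdva = postop_cdva,
                 preop_se = preop_se, postop_se = postop_se,
                 preop_rms = preop_rms, postop_rms = postop_rms,
                 implant = implant,
                 months_followup = as.integer(months_followup)),
            class = "case_record")
}

#' @export
print.case_record <- function(x, ...) {
  segs <- vapply(x$implant, format_segment, "")
  cat("ICRS case record (", x$months_followup, " months follow-up)\n", sep = "")
  cat("  implant:", paste(segs, collapse = " + "), "\n")
  cat(sprintf("  UDVA %.2f -> %.2f | CDVA %.2f -> %.2f | SE %+.2f -> %+.2f D\n",
              x$preop_udva, x$postop_udva, x$preop_cdva, x$postop_cdva,
              x$preop_se, x$postop_se))
  cat(sprintf("  HOA %.2f -> %.2f um | coma-like %.2f -> %.2f um\n",
              x$preop_rms$hoa, x$postop_rms$hoa,
              x$preop_rms$coma_like, x$postop_rms$coma_like))
  invisible(x)
}

#' Surgical success filter
#'
#' A case counts as a success when, at follow-up, it shows at least one of:
#' (A) an improvement of one line (0.1 LogMAR) or more in uncorrected or
#' corrected distance visual acuity; (B) a decrease of 2 D or more in the
#' magnitude of the spherical equivalent (movement toward zero); (C) a
#' decrease of at least 1 um in the RMS of the corneal higher-order or
#' coma-like aberrations.
#'
#' @param case a [case_record].
#' @return list with `is_success` and the three named criterion flags
#'   `va_line_gain`, `se_decrease`, `rms_decrease`.
#' @export
success_filter <- function(case) {
  stopifnot(inherits(case, "case_record"))
  needed <- c("preop_udva", "postop_udva", "preop_cdva", "postop_cdva",
              "preop_se", "postop_se", "preop_rms", "postop_rms")
  for (f in needed) {
    if (is.null(case[[f]]) || anyNA(case[[f]][1])) {
      stop("case record field '", f, "' is missing", call. = FALSE)
    }
  }
  eps <- 1e-9
  d_ud <- decimal_to_logmar(case$preop_udva, Inf) -
    decimal_to_logmar(case$postop_udva, Inf)
  d_cd <- decimal_to_logmar(case$preop_cdva, Inf) -
    decimal_to_logmar(case$postop_cdva, Inf)
  crit_a <- (d_ud >= 0.1 - eps) || (d_cd >= 0.1 - eps)
  crit_b <- (abs(case$preop_se) - abs(case$postop_se)) >= 2 - eps
  crit_c <- (case$preop_rms$hoa - case$postop_rms$hoa >= 1 - eps) ||
    (case$preop_rms$coma_like - case$postop_rms$coma_like >= 1 - eps)
  list(is_success = crit_a || crit_b || crit_c,
       va_line_gain = crit_a, se_decrease = crit_b, rms_decrease = crit_c)
}

#' Keratoconus progression criterion
#'
#' Progression (the indication for collagen cross-linking) is flagged when
#' both the steepest-meridian simulated keratometry has increased by at
#' least 1 D and the refractive astigmatism has increased by at least 1 D
#' between the two time points.
#'
#' @param prior,current lists (or [simulated_keratometry()] results amended
#'   with `astigmatism_d`) carrying `k2` (D) and `astigmatism_d` (D).
#' @return logical flag.
#' @export
progression_criterion <- function(prior, current) {
  for (p in list(prior, current)) {
    if (is.null(p$k2) || is.null(p$astigmatism_d)) {
      stop("both time points need fields k2 and astigmatism_d", call. = FALSE)
    }
  }
  eps <- 1e-9
  (current$k2 - prior$k2 >= 1 - eps) &&
    (abs(current$astigmatism_d) - abs(prior$astigmatism_d) >= 1 - eps)
}

# ---- case record serialization (flat DCF text blocks) ----

fmt_num <- function(v) paste(format(v, digits = 15, trim = TRUE,
                                    scientific = FALSE), collapse = " ")

#' Write case records to a flat text file
#'
#' One Debian-control-format block per case with named fields; coefficient
#' vectors are space-separated. Round-trips with [read_case_records()].
#'
#' @param cases list of [case_record] objects.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_case_records <- function(cases, path) {
  blocks <- lapply(cases, function(cs) {
    segf <- vapply(cs$implant, function(s) {
      sprintf("%s-%d th=%d axis=%g", s$model, s$arc_deg, s$thickness_um,
              s$bisecting_line_deg)
    }, "")
    c(preop_zernike_um_8mm = fmt_num(as.numeric(cs$preop_zernike)),
      postop_zernike_um_8mm = fmt_num(as.numeric(cs$postop_zernike)),
      preop_udva = fmt_num(cs$preop_udva), postop_udva = fmt_num(cs$postop_udva),
      preop_cdva = fmt_num(cs$preop_cdva), postop_cdva = fmt_num(cs$postop_cdva),
      preop_se_d = fmt_num(cs$preop_se), postop_se_d = fmt_num(cs$postop_se),
      preop_rms_um_6mm = fmt_num(unlist(cs$preop_rms[c("total", "hoa",
        "astigmatism", "coma_like", "spherical_like")])),
      postop_rms_um_6mm = fmt_num(unlist(cs$postop_rms[c("total", "hoa",
        "astigmatism", "coma_like", "spherical_like")])),
      implant = paste(segf, collapse = "; "),
      months_followup = fmt_num(cs$months_followup))
  })
  m <- do.call(rbind, blocks)
  write.dcf(m, path)
  invisible(path)
}

parse_segment_field <- function(txt) {
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  lapply(trimws(parts), function(p) {
    m <- regmatches(p, regexec(
      "^(SI[56])-(\\d+) th=(\\d+) axis=([0-9.]+)$", p))[[1]]
    if (length(m) != 5L) stop("cannot parse implant field: '", p, "'",
                              call. = FALSE)
    segment_spec(m[2], as.numeric(m[3]), as.numeric(m[4]), as.numeric(m[5]))
  })
}

#' Read case records from a flat text file
#'
#' @param path file written by [write_case_records()].
#' @return list of [case_record] objects.
#' @export
read_case_records <- function(path) {
  m <- read.dcf(path)
  nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  rms_from <- function(v) {
    structure(list(total = v[1], hoa = v[2], astigmatism = v[3],
                   coma_like = v[4], spherical_like = v[5],
                   residual_hoa = sqrt(max(v[2]^2 - v[4]^2 - v[5]^2, 0)),
                   pupil_diameter_mm = 6),
              class = "rms_groups")
  }
  lapply(seq_len(nrow(m)), function(i) {
    row <- m[i, ]
    case_record(
      preop_zernike = zernike_coef(nums(row["preop_zernike_um_8mm"]),
                                   pupil_diameter_mm = 8),
      postop_zernike = zernike_coef(nums(row["postop_zernike_um_8mm"]),
                                    pupil_diameter_mm = 8),
      preop_udva = nums(row["preop_udva"]),
      postop_udva = nums(row["postop_udva"]),
      preop_cdva = nums(row["preop_cdva"]),
      postop_cdva = nums(row["postop_cdva"]),
      preop_se = nums(row["preop_se_d"]),
      postop_se = nums(row["postop_se_d"]),
      preop_rms = rms_from(nums(row["preop_rms_um_6mm"])),
      postop_rms = rms_from(nums(row["postop_rms_um_6mm"])),
      implant = parse_segment_field(row["implant"]),
      months_followup = nums(row["months_followup"]))
  })
}
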