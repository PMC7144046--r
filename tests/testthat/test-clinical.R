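test_that("decimal acuity converts to the published LogMAR values", {
  pairs <- read.csv(system.file("extdata", "va_conversion_examples.csv",
                                package = "icrsplan"))
  expect_equal(decimal_to_logmar(pairs$decimal), pairs$logmar)
  expect_equal(decimal_to_logmar(1.0), 0)
  expect_error(decimal_to_logmar(0), "positive")
})

test_that("LogMAR conversion round-trips within rounding", {
  v <- c(0.1, 0.2, 0.5, 0.73, 1.0, 1.5)
  back <- logmar_to_decimal(decimal_to_logmar(v, digits = Inf))
  expect_equal(back, v, tolerance = 1e-12)
  expect_equal(decimal_to_logmar(logmar_to_decimal(0.22)), 0.22)
})

test_that("visual-limitation grading respects the published boundaries", {
  expect_equal(as.character(grade_visual_limitation(0.95)), "I")
  expect_equal(as.character(grade_visual_limitation(0.90)), "I")
  expect_equal(as.character(grade_visual_limitation(0.89)), "II")
  expect_equal(as.character(grade_visual_limitation(0.60)), "II")
  expect_equal(as.character(grade_visual_limitation(0.59)), "III")
  expect_equal(as.character(grade_visual_limitation(0.40)), "III")
  expect_equal(as.character(grade_visual_limitation(0.20)), "IV")
  expect_equal(as.character(grade_visual_limitation(0.15)), "Plus")
})

test_that("grading is monotone in acuity", {
  v <- sort(runif(50, 0.01, 1.5))
  g <- as.integer(grade_visual_limitation(v))
  expect_true(all(diff(g) <= 0))
})

test_that("simulated keratometry recovers a sphere's power", {
  p <- cornea_params(apical_radius_mm = 7.8, asphericity_q = 0,
                     cone_amplitude_um = 0, astigmatism_d = 0,
                     noise_sd_um = 0)
  k <- simulated_keratometry(generate_cornea(p))
  expect_equal(k$mean_simk, 337.5 / 7.8, tolerance = 0.01)
  expect_lt(k$k2 - k$k1, 0.01)
})

test_that("simulated keratometry recovers a toric surface per meridian", {
  xs <- seq(-4.5, 4.5, length.out = 121)
  g <- expand.grid(x = xs, y = xs)
  th <- atan2(g$y, g$x); r2 <- g$x^2 + g$y^2
  R <- 1 / (cos(th)^2 / 8.0 + sin(th)^2 / 7.5)
  z <- 1000 * (R - sqrt(R^2 - r2))
  m <- elevation_map(xs, xs, matrix(z, 121, 121), diameter_mm = 8)
  k <- simulated_keratometry(m)
  expect_equal(k$k1, 337.5 / 8.0, tolerance = 0.02)
  expect_equal(k$k2, 337.5 / 7.5, tolerance = 0.02)
  gap <- abs(k$axis2_deg - k$axis1_deg)
  expect_equal(min(gap, 180 - gap), 90, tolerance = 6)
  expect_lte(k$k1, k$k2)
  expect_equal(k$mean_simk, (k$k1 + k$k2) / 2)
})

test_that("keratometry refuses a zone not covered by the map", {
  xs <- seq(-0.5, 0.5, length.out = 11)
  m <- elevation_map(xs, xs, matrix(0, 11, 11), diameter_mm = 1)
  expect_error(simulated_keratometry(m, zone_mm = 3), "insufficient")
})

test_that("success filter fires on each criterion independently", {
  # criterion B: spherical equivalent moves toward zero by >= 2 D
  b <- toy_case(udva = c(0.2, 0.2), cdva = c(0.5, 0.5),
                se = c(-5, -2.5), hoa = c(3, 3), coma = c(2.5, 2.5))
  fb <- success_filter(b)
  expect_true(fb$is_success); expect_true(fb$se_decrease)
  expect_false(fb$va_line_gain); expect_false(fb$rms_decrease)

  # criterion C only: coma-like falls by >= 1 um
  cc <- toy_case(udva = c(0.2, 0.2), cdva = c(0.5, 0.5),
                 se = c(-5, -5), hoa = c(3.6, 3.2), coma = c(3.6, 2.4))
  fc <- success_filter(cc)
  expect_true(fc$is_success); expect_true(fc$rms_decrease)
  expect_false(fc$va_line_gain); expect_false(fc$se_decrease)

  # criterion A only: one line of CDVA
  a <- toy_case(udva = c(0.2, 0.2), cdva = c(0.5, 0.63),
                se = c(-5, -5), hoa = c(3, 3), coma = c(2.5, 2.5))
  fa <- success_filter(a)
  expect_true(fa$is_success); expect_true(fa$va_line_gain)

  # unchanged case is not a success
  none <- toy_case(udva = c(0.2, 0.2), cdva = c(0.5, 0.5),
                   se = c(-5, -5), hoa = c(3, 3), coma = c(2.5, 2.5))
  expect_false(success_filter(none)$is_success)
})

test_that("success filter names missing fields", {
  cs <- toy_case()
  cs$postop_se <- NULL
  expect_error(success_filter(cs), "postop_se")
})

test_that("progression requires both steep-K and astigmatism increases", {
  prior <- list(k2 = 48, astigmatism_d = 2)
  expect_true(progression_criterion(prior, list(k2 = 49.2, astigmatism_d = 3.1)))
  expect_false(progression_criterion(prior, list(k2 = 49.2, astigmatism_d = 2.5)))
  expect_false(progression_criterion(prior, list(k2 = 48, astigmatism_d = 2)))
  expect_error(progression_criterion(list(k2 = 48), prior), "astigmatism_d")
})

test_that("case records round-trip through the flat text format", {
  cases <- list(toy_case(), toy_case(postop = random_coef(5),
                                     se = c(-6, -3.5)))
  cases[[2]]$implant <- list(segment_spec("SI5", 160, 300, 272.5),
                             segment_spec("SI6", 90, 150, 90))
  path <- tempfile(fileext = ".dcf")
  write_case_records(cases, path)
  back <- read_case_records(path)
  expect_equal(length(back), 2L)
  for (i in 1:2) {
    expect_equal(as.numeric(back[[i]]$preop_zernike),
                 as.numeric(cases[[i]]$preop_zernike))
    expect_equal(back[[i]]$postop_se, cases[[i]]$postop_se)
    expect_equal(back[[i]]$preop_rms$coma_like, cases[[i]]$preop_rms$coma_like)
    expect_equal(length(back[[i]]$implant), length(cases[[i]]$implant))
    expect_equal(back[[i]]$implant[[1]]$bisecting_line_deg,
                 cases[[i]]$implant[[1]]$bisecting_line_deg)
  }
})
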