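test_that("feature encoding honours the slot layout", {
  preop <- random_coef(1)
  one <- encode_features(preop, list(segment_spec("SI6", 150, 250, 90)))
  expect_equal(length(one), 296L)
  expect_equal(unname(one[1:36]), as.numeric(preop))
  seg2 <- grepl("^seg2_", names(one))
  expect_true(all(one[seg2] == 0))
  expect_equal(unname(one["seg1_present"]), 1)
  expect_equal(unname(one["seg2_present"]), 0)
  # axis 90 degrees: (sin, cos) = (1, 0)
  expect_equal(unname(one["seg1_axis_sin"]), 1)
  expect_equal(unname(one["seg1_axis_cos"]), 0, tolerance = 1e-12)
})

test_that("axis 0 and axis 360 encode identically", {
  preop <- random_coef(1)
  a <- encode_features(preop, list(segment_spec("SI5", 120, 200, 0)))
  b <- encode_features(preop, list(segment_spec("SI5", 120, 200, 360)))
  expect_equal(a, b)
})

test_that("more than two segments are refused", {
  preop <- random_coef(1)
  segs <- replicate(3, segment_spec("SI5", 90, 150, 0), simplify = FALSE)
  expect_error(encode_features(preop, segs), "at most 2")
})

test_that("analytic gradients match central finite differences", {
  set.seed(3)
  X <- matrix(rnorm(30), 10, 3); Y <- matrix(rnorm(20), 10, 2)
  par <- icrsplan:::nn_init(c(3, 4, 2), seed = 5)
  par$skip[] <- rnorm(length(par$skip)) * 0.1
  g <- icrsplan:::nn_loss_grad(par, X, Y)
  h <- 1e-6
  fd <- function(set) {
    p1 <- set(par, h); p2 <- set(par, -h)
    (icrsplan:::nn_loss_grad(p1, X, Y)$loss -
       icrsplan:::nn_loss_grad(p2, X, Y)$loss) / (2 * h)
  }
  worst <- 0
  for (l in 1:2) {
    for (k in seq_along(par$W[[l]])) {
      num <- fd(function(p, e) { p$W[[l]][k] <- p$W[[l]][k] + e; p })
      worst <- max(worst, abs(g$gW[[l]][k] - num) / max(abs(num), 1e-8))
    }
    for (k in seq_along(par$b[[l]])) {
      num <- fd(function(p, e) { p$b[[l]][k] <- p$b[[l]][k] + e; p })
      worst <- max(worst, abs(g$gb[[l]][k] - num) / max(abs(num), 1e-8))
    }
  }
  for (k in seq_along(par$skip)) {
    num <- fd(function(p, e) { p$skip[k] <- p$skip[k] + e; p })
    worst <- max(worst, abs(g$gskip[k] - num) / max(abs(num), 1e-8))
  }
  expect_lt(worst, 1e-4)
})

make_teacher_cases <- function(n, seed, slope = 0.8) {
  # synthetic linear teacher: postop = slope * preop (plus a fixed bowl)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    pre <- zernike_coef(rnorm(36, 0, 2), 7, 8)
    post <- zernike_coef(slope * as.numeric(pre), 7, 8)
    toy_case(preop = pre, postop = post)
  })
}

test_that("zero epochs returns the seeded initialization unchanged", {
  cases <- make_teacher_cases(12, seed = 2)
  mod <- icrs_surrogate(cases, epochs = 0, init_bypass = FALSE, seed = 77)
  init <- icrsplan:::nn_init(mod$layer_sizes, seed = 77)
  expect_identical(mod$W, init$W)
  expect_identical(mod$b, init$b)
  expect_identical(mod$skip, init$skip)
  # the warm-started bypass is deterministic, not seed-dependent
  m1 <- icrs_surrogate(cases, epochs = 0, seed = 1)
  m2 <- icrs_surrogate(cases, epochs = 0, seed = 2)
  expect_identical(m1$skip, m2$skip)
})

test_that("training is bit-reproducible for a fixed seed", {
  cases <- make_teacher_cases(15, seed = 4)
  m1 <- icrs_surrogate(cases, epochs = 200, seed = 5)
  m2 <- icrs_surrogate(cases, epochs = 200, seed = 5)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$skip, m2$skip)
  m3 <- icrs_surrogate(cases, epochs = 200, seed = 6)
  expect_false(identical(m1$W, m3$W))
})

test_that("training loss is non-increasing without momentum at a stable rate", {
  cases <- make_teacher_cases(20, seed = 8)
  mod <- icrs_surrogate(cases, epochs = 400, learning_rate = 0.005,
                        momentum = 0, weight_decay = 0, seed = 1)
  expect_true(all(diff(mod$loss_trajectory) <= 1e-12))
})

test_that("an unstable learning rate raises a divergence error", {
  cases <- make_teacher_cases(12, seed = 9)
  expect_error(icrs_surrogate(cases, epochs = 5000, learning_rate = 30,
                              momentum = 0.95, weight_decay = 0, seed = 1),
               "learning rate")
})

test_that("non-success cases are rejected as training material", {
  ok <- make_teacher_cases(11, seed = 10)
  bad <- toy_case(udva = c(0.2, 0.2), cdva = c(0.5, 0.5), se = c(-5, -5),
                  hoa = c(3, 3), coma = c(2.5, 2.5))
  expect_error(icrs_surrogate(c(ok, list(bad))), "success filter")
  expect_error(icrs_surrogate(ok[1:5]), "at least 10")
})

test_that("a converged network reproduces a linear teacher on held-out data", {
  train <- make_teacher_cases(60, seed = 12)
  test <- make_teacher_cases(25, seed = 13)
  mod <- icrs_surrogate(train, epochs = 3000, seed = 3)
  res <- residuals(mod, test)
  Y <- t(vapply(test, function(cs) as.numeric(cs$postop_zernike), numeric(36)))
  rel <- sqrt(mean(res^2)) / sd(as.numeric(Y))
  expect_lt(rel, 0.05)
})

test_that("prediction is deterministic and respects the output contract", {
  cases <- make_teacher_cases(12, seed = 14)
  mod <- icrs_surrogate(cases, epochs = 100, seed = 1)
  preop <- random_coef(99)
  segs <- list(segment_spec("SI5", 210, 300, 45))
  p1 <- predict(mod, preop, segs)
  p2 <- predict(mod, preop, segs)
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_equal(length(p1), 36L)
  expect_equal(attr(p1, "pupil_diameter_mm"), 8)
})

test_that("model files round-trip with identical predictions", {
  cases <- make_teacher_cases(12, seed = 15)
  mod <- icrs_surrogate(cases, epochs = 150, seed = 2)
  path <- tempfile(fileext = ".json")
  write_surrogate(mod, path)
  back <- read_surrogate(path)
  preop <- random_coef(7)
  segs <- list(segment_spec("SI6", 120, 200, 10),
               segment_spec("SI6", 90, 150, 200))
  expect_equal(as.numeric(predict(back, preop, segs)),
               as.numeric(predict(mod, preop, segs)), tolerance = 1e-12)
  expect_error(read_surrogate({
    p <- tempfile(); jsonlite::write_json(list(format = "x"), p); p
  }), "not an icrsplan")
})
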