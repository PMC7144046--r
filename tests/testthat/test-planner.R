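# mechanistic prediction function standing in for a trained surrogate:
# applies the ring-effect model to the map held in its closure and refits
mechanistic_oracle <- function(map, effect = ring_effect_params()) {
  design <- zernike_fit_design(map, 8, 7)
  function(preop, segments) {
    fit_elevation(apply_ring_effect(map, segments, effect), 8, 7,
                  basis = design)
  }
}

test_that("the planner scores the full enumerated candidate space", {
  m <- generate_cornea(cornea_params(seed = 3))
  plan <- plan_icrs(m, mechanistic_oracle(m), axis_step_deg = 120,
                    thickness_set = 200, max_segments = 1, top_k = 100)
  expect_equal(attr(plan, "n_candidates"), 8 * 1 * 3)
  expect_equal(nrow(plan), 24L)
  expect_equal(plan$rank, 1:24)
  expect_true(all(diff(plan$strehl) <= 1e-12))
})

test_that("the planner agrees with an independent brute-force argmax", {
  m <- generate_cornea(cornea_params(seed = 6))
  eff <- ring_effect_params()
  plan <- plan_icrs(m, mechanistic_oracle(m, eff), axis_step_deg = 60,
                    thickness_set = c(200, 300), max_segments = 1,
                    include_second_order = FALSE, top_k = 1)
  # brute force, written independently of plan_icrs
  design <- zernike_fit_design(m, 8, 7)
  cat8 <- keraring_catalog()
  best <- list(strehl = -Inf)
  for (r in seq_len(nrow(cat8))) for (th in c(200, 300)) {
    for (ax in seq(0, 300, by = 60)) {
      seg <- segment_spec(cat8$model[r], cat8$arc_deg[r], th, ax)
      cf <- fit_elevation(apply_ring_effect(m, seg, eff), 8, 7,
                          basis = design)
      w <- apply_second_order_toggle(
        elevation_to_wavefront(rescale_pupil(cf, 6)), FALSE)
      s <- strehl_ratio(w, 550, 64, 2)
      if (s > best$strehl) best <- list(strehl = s, seg = seg)
    }
  }
  expect_equal(plan$strehl[1], best$strehl, tolerance = 1e-10)
  expect_equal(plan$model1[1], best$seg$model)
  expect_equal(plan$arc1[1], best$seg$arc_deg)
  expect_equal(plan$axis1[1], best$seg$bisecting_line_deg)
})

test_that("planning is deterministic", {
  m <- generate_cornea(cornea_params(seed = 7))
  f <- mechanistic_oracle(m)
  p1 <- plan_icrs(m, f, axis_step_deg = 90, thickness_set = 250,
                  max_segments = 1)
  p2 <- plan_icrs(m, f, axis_step_deg = 90, thickness_set = 250,
                  max_segments = 1)
  expect_equal(as.data.frame(p1), as.data.frame(p2))
})

test_that("ties break on fewer segments, then thickness, then code", {
  m <- generate_cornea(cornea_params(seed = 8))
  constant_pred <- function(preop, segments) preop  # all candidates tie
  plan <- plan_icrs(m, constant_pred, axis_step_deg = 180,
                    thickness_set = c(300, 150), max_segments = 2,
                    top_k = 1000)
  expect_true(all(diff(plan$n_segments) >= 0))
  singles <- plan[plan$n_segments == 1, ]
  expect_true(all(diff(singles$thickness1) >= 0))
  within_th <- singles$code[singles$thickness1 == 150]
  expect_equal(within_th, sort(within_th))
})

test_that("a near-perfect cornea yields a no-benefit flag", {
  p <- cornea_params(apical_radius_mm = 7.5, asphericity_q = 0,
                     cone_amplitude_um = 0, astigmatism_d = 0,
                     noise_sd_um = 0)
  m <- generate_cornea(p)
  plan <- plan_icrs(m, mechanistic_oracle(m), axis_step_deg = 120,
                    thickness_set = c(150, 300), max_segments = 1,
                    include_second_order = FALSE)
  expect_true(attr(plan, "no_benefit"))
  expect_lte(plan$strehl[1], attr(plan, "baseline_strehl") + 1e-6)
})

test_that("refining the axis grid or thickness set never lowers the top Strehl", {
  m <- generate_cornea(cornea_params(seed = 12))
  f <- mechanistic_oracle(m)
  coarse <- plan_icrs(m, f, axis_step_deg = 120, thickness_set = 200,
                      max_segments = 1, include_second_order = FALSE)
  fine_axis <- plan_icrs(m, f, axis_step_deg = 60, thickness_set = 200,
                         max_segments = 1, include_second_order = FALSE)
  more_th <- plan_icrs(m, f, axis_step_deg = 120,
                       thickness_set = c(200, 300), max_segments = 1,
                       include_second_order = FALSE)
  expect_gte(fine_axis$strehl[1], coarse$strehl[1] - 1e-12)
  expect_gte(more_th$strehl[1], coarse$strehl[1] - 1e-12)
})

test_that("candidate failures carry the candidate context", {
  m <- generate_cornea(cornea_params(seed = 2))
  boom <- function(preop, segments) stop("prediction backend down")
  expect_error(plan_icrs(m, boom, axis_step_deg = 360, thickness_set = 200,
                         max_segments = 1),
               "SI5-090.*prediction backend down")
})
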