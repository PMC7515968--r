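test_that("window statistic is exact on flat and ring profiles", {
  # uniform green: both windows equal, contrast zero
  st <- profile_statistic(make_aligned(rep(4.2, 101)), noise_scale = 1)
  expect_equal(st$mean_near, 4.2)
  expect_equal(st$mean_far, 4.2)
  expect_equal(st$contrast, 0)
  expect_equal(st$z_contrast, 0)

  # noiseless rendered ring of amplitude A and width 3: near window
  # recovers A and the far window stays empty (edge-smoothing tolerance)
  fx <- fine_vessel_fixture(ring_amplitude = 8)
  al <- align_abluminal(fx$profile, locate_lumen_edges(fx$profile))
  for (side in al) {
    st <- profile_statistic(side, noise_scale = 1)
    expect_equal(st$mean_near, 8, tolerance = 0.05)
    expect_lt(abs(st$mean_far), 0.05 * 8)
  }
})

test_that("contrast is exactly linear in ring amplitude", {
  contrasts <- vapply(c(1, 2, 4, 8), function(A) {
    fx <- fine_vessel_fixture(ring_amplitude = A)
    al <- align_abluminal(fx$profile, locate_lumen_edges(fx$profile))
    profile_statistic(al$right, noise_scale = 1)$contrast
  }, 0)
  expect_equal(contrasts / contrasts[1], c(1, 2, 4, 8), tolerance = 1e-9)
  expect_true(all(diff(contrasts) > 0))
})

test_that("background-only contrast is bounded by the radial gradient", {
  # vessel in a pure diffusion background (no ring): the contrast cannot
  # exceed the concentration drop across the analysis span
  cfg <- sim_config(field_size_um = 200, image_px = 512, n_vessels = 0,
                    source_xy_um = c(100, 100), injected_mass = 5000,
                    edge_margin_um = 20, seed = 1)
  ves <- data.frame(id = 1L, x_um = 130, y_um = 100, angle_rad = 0,
                    diameter_um = 8, is_positive = FALSE,
                    distance_to_source_um = 30)
  fr <- render_frame(cfg, ves, 10)
  p <- extract_profile(fr, c(130, 100), 0, length_um = 60, step_um = 0.25)
  al <- align_abluminal(p, locate_lumen_edges(p))
  st <- profile_statistic(al$right, noise_scale = 1)   # outward side
  D <- cfg$diffusion_coeff_um2_per_min
  Cr <- function(r) cfg$injected_mass / (4 * pi * D * 10) *
    exp(-r^2 / (4 * D * 10))
  edge_r <- 30 + al$right$edge_pos_um - 0   # distance of edge from source
  bound <- Cr(edge_r) - Cr(edge_r + 10)
  expect_gt(st$contrast, 0)
  expect_lt(st$contrast, bound + 1e-6)
})

test_that("window means are stable under sampling-step refinement", {
  fx <- fine_vessel_fixture(ring_amplitude = 5, injected_mass = 20000)
  vals <- lapply(c(0.1, 0.05), function(s) {
    p <- extract_profile(fx$frame, c(25.6, 25.6), 0.4, length_um = 40,
                         step_um = s)
    al <- align_abluminal(p, locate_lumen_edges(p))
    profile_statistic(al$right, noise_scale = 1)
  })
  expect_lt(abs(vals[[1]]$mean_near - vals[[2]]$mean_near) /
              vals[[2]]$mean_near, 0.01)
  expect_lt(abs(vals[[1]]$mean_far - vals[[2]]$mean_far) /
              max(vals[[2]]$mean_far, 1e-6), 0.01)
})

test_that("classification rules implement their arithmetic", {
  rule <- classification_rule()
  # zero contrast on both sides: negative under every mode
  flat <- list(make_stat(z = 0, near = 1, far = 1, side = "left"),
               make_stat(z = 0, near = 1, far = 1, side = "right"))
  expect_false(classify_vessel(flat, rule))
  expect_false(classify_vessel(flat, classification_rule("ratio")))
  expect_false(classify_vessel(flat, classification_rule("group_test")))

  # z = (10, 8) across sides at threshold 3: positive
  expect_true(classify_vessel(list(make_stat(z = 10), make_stat(z = 8)),
                              rule))
  # side averaging: (5, -1) -> mean 2 < 3 -> negative
  expect_false(classify_vessel(list(make_stat(z = 5), make_stat(z = -1)),
                               rule))
  # no usable side: undefined
  expect_true(is.na(classify_vessel(list(), rule)))

  # ratio mode with the far mean floored at the noise scale
  expect_true(classify_vessel(list(make_stat(near = 12, far = 5,
                                             noise = 1)),
                              classification_rule("ratio")))
  expect_false(classify_vessel(list(make_stat(near = 1.1, far = 1,
                                              noise = 1)),
                               classification_rule("ratio")))
  # far ~ 0: denominator floored at the noise scale, not at zero
  expect_true(classify_vessel(list(make_stat(near = 5, far = 0,
                                             noise = 2)),
                              classification_rule("ratio")))

  # group test across repeated frames
  reps <- lapply(1 + 0.1 * sin(1:6), function(d)
    make_stat(near = 3 + d, far = 3))
  expect_true(classify_vessel(reps, classification_rule("group_test")))
  null_reps <- lapply(0.3 * sin(1:6), function(d)
    make_stat(near = 3 + d, far = 3))
  expect_false(classify_vessel(null_reps,
                               classification_rule("group_test")))
})

test_that("colocalization coefficient matches its Pearson definition", {
  fx <- default_grid_vessel(diameter_um = 8)
  fr <- fx$frame
  # green an affine copy of red: r = 1; anti-correlated: r = -1
  plus <- image_frame(2 * fr$red + 5, fr$red, fr$pixel_size_um, 0)
  expect_equal(coloc_coefficient(plus, c(207.3, 214.1), 4), 1,
               tolerance = 1e-12)
  minus <- image_frame(-fr$red + 50, fr$red, fr$pixel_size_um, 0)
  expect_equal(coloc_coefficient(minus, c(207.3, 214.1), 4), -1,
               tolerance = 1e-12)
  # independent noise channels: |r| below the 3/sqrt(n) null bound
  cfg <- fx$cfg
  set.seed(4)
  nz <- image_frame(matrix(rnorm(512^2), 512, 512), fr$red +
                      matrix(rnorm(512^2), 512, 512),
                    fr$pixel_size_um, 0)
  px_area <- fr$pixel_size_um^2
  n_px <- floor(pi * (7^2 - 4^2) / px_area)
  expect_lt(abs(coloc_coefficient(nz, c(207.3, 214.1), 4)),
            3 / sqrt(n_px * 0.8))
  # degenerate: constant channel is reported undefined
  flat <- image_frame(matrix(1, 512, 512), fr$red, fr$pixel_size_um, 0)
  expect_true(is.na(coloc_coefficient(flat, c(207.3, 214.1), 4)))
  # tiny annulus rejected
  expect_error(coloc_coefficient(fr, c(207.3, 214.1), 0.4,
                                 annulus_um = c(0, 0.2)), "30")
})

test_that("frame analysis reproduces its frozen seeded confusion matrix", {
  conf <- field_confusion(100) + field_confusion(101) +
    field_confusion(102) + field_confusion(103)
  expect_identical(unname(conf),
                   c(65L, 0L, 0L, 135L, 0L))
})

test_that("excluded vessels are bookkept, not classified", {
  # a vessel whose line exits the field is excluded with a reason and a
  # NA call that positive_fraction then drops from both counts
  cfg <- sim_config(n_vessels = 0, injected_mass = 0)
  ves <- data.frame(id = c(1L, 2L),
                    x_um = c(30, 212), y_um = c(212, 212),
                    angle_rad = 0, diameter_um = 8,
                    is_positive = c(FALSE, TRUE),
                    distance_to_source_um = 0)
  fr <- add_noise(render_frame(cfg, ves, 20), cfg, 0L)
  calls <- vessel_calls(analyze_frame(fr, ves))
  expect_true(calls$excluded[calls$vessel_id == 1])
  expect_match(calls$exclude_reason[calls$vessel_id == 1], "exits")
  expect_true(is.na(calls$predicted_positive[calls$vessel_id == 1]))
  expect_equal(positive_fraction(calls$predicted_positive), 100)
})
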