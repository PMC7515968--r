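test_that("positive fraction counts only usable vessels", {
  expect_equal(positive_fraction(c(rep(TRUE, 3), rep(FALSE, 7))), 30)
  expect_equal(positive_fraction(c(TRUE, NA, FALSE, FALSE)), 100 / 3)
  expect_warning(out <- positive_fraction(c(NA, NA)), "undefined")
  expect_true(is.na(out))
  # invariant to ordering and to duplication of excluded vessels
  x <- c(TRUE, FALSE, NA, TRUE, FALSE, FALSE)
  expect_equal(positive_fraction(x), positive_fraction(rev(x)))
  expect_equal(positive_fraction(x), positive_fraction(c(x, NA, NA)))
})

test_that("noiseless FWHM diameters recover truth within 0.3 um", {
  errs <- c()
  for (d in seq(5, 13, by = 2)) for (ang in c(0, 0.7)) {
    fx <- default_grid_vessel(diameter_um = d, angle = ang)
    p <- extract_profile(fx$frame, c(207.3, 214.1), ang)
    errs <- c(errs, measure_diameter(p) - d)
  }
  expect_lt(max(abs(errs)), 0.3)
})

test_that("noisy diameter estimates are unbiased at SNR 10", {
  cfg <- sim_config(n_vessels = 0, injected_mass = 0, noise_gain = 0,
                    read_noise_sd = 10, seed = 21)   # lumen 100 -> SNR 10
  ves <- data.frame(id = 1L, x_um = 207.3, y_um = 214.1, angle_rad = 0.5,
                    diameter_um = 8, is_positive = FALSE,
                    distance_to_source_um = 0)
  base <- render_frame(cfg, ves, 0)
  reps <- vapply(1:100, function(k) {
    fr <- add_noise(base, cfg, k)
    measure_diameter(extract_profile(fr, c(207.3, 214.1), 0.5))
  }, 0)
  expect_lt(abs(mean(reps) - 8), 0.5)
})

test_that("time course segments a trapezoidal fraction series", {
  fs <- data.frame(t_min = seq(0, 40, 5),
                   n_vessels_usable = 50,
                   n_positive = c(0, 5, 10, 15, 15, 15, 10, 5, 0),
                   positive_fraction_pct =
                     100 * c(0, 5, 10, 15, 15, 15, 10, 5, 0) / 50,
                   mean_diam_pos_um = 8, mean_diam_neg_um = 6)
  tc <- time_course(fs[sample(nrow(fs)), ])     # order must not matter
  expect_identical(tc$t_min, seq(0, 40, 5))
  seg <- attr(tc, "segmentation")
  expect_identical(seg$plateau_times, c(15, 20, 25))
  expect_identical(seg$plateau_start, 15)
  expect_identical(seg$plateau_end, 25)
  # fewer than 3 frames: no segmentation
  expect_null(attr(time_course(fs[1:2, ]), "segmentation"))
})

test_that("simulated time course plateaus over the configured window", {
  run_tc <- function(amp) {
    cfg <- sim_config(image_px = 256, n_vessels = 10, p_positive = 1,
                      ring_amplitude = amp, injected_mass = 0,
                      noise_gain = 0, read_noise_sd = 0, seed = 31)
    ves <- sample_vessels(cfg)
    fs <- do.call(rbind, lapply(cfg$frame_times_min, function(t) {
      fr <- render_frame(cfg, ves, t)
      calls <- vessel_calls(analyze_frame(fr, ves, noise_scale = 2))
      frame_summary(calls)
    }))
    time_course(fs)
  }
  tc <- run_tc(100)                      # saturated: 50x the noise scale
  seg <- attr(tc, "segmentation")
  expect_true(all(c(15, 20, 25) %in% seg$plateau_times))
  # doubling a saturated amplitude cannot change the segmentation
  tc2 <- run_tc(200)
  expect_identical(attr(tc2, "segmentation"), seg)
  expect_identical(tc2$t_min, tc$t_min)

  # zero amplitude: flat series at the (here zero) false-positive rate
  cfg0 <- sim_config(image_px = 256, n_vessels = 10, p_positive = 1,
                     ring_amplitude = 0, injected_mass = 0,
                     noise_gain = 0, read_noise_sd = 0, seed = 31)
  ves0 <- sample_vessels(cfg0)
  f0 <- vapply(c(0, 15, 25), function(t)
    frame_summary(vessel_calls(analyze_frame(render_frame(cfg0, ves0, t),
                                             ves0, noise_scale = 2)))$
      positive_fraction_pct, 0)
  expect_true(all(f0 == 0))
})

test_that("distance strata bin correctly and detect no spurious trend", {
  # all vessels at one distance: a single occupied bin
  calls <- data.frame(vessel_id = 1:20, predicted_positive = TRUE,
                      distance_to_source_um = 45)
  st <- distance_strata(calls)
  expect_equal(sum(st$n_usable > 0), 1)
  expect_equal(st$n_usable[st$bin_lo_um == 40], 20)
  # distances beyond 360 fall in the open-ended bin; a source outside the
  # field simply yields large distances, no error
  far <- data.frame(vessel_id = 1:5, predicted_positive = FALSE,
                    distance_to_source_um = c(500, 700, 900, 361, 1e4))
  stf <- distance_strata(far)
  expect_equal(stf$n_usable[is.infinite(stf$bin_hi_um)], 5)
  # uniform positivity in space: no significant trend across bins
  set.seed(8)
  n <- 4000
  big <- data.frame(vessel_id = seq_len(n),
                    predicted_positive = runif(n) < 0.2,
                    distance_to_source_um = runif(n, 0, 400))
  stb <- distance_strata(big)
  keep <- stb$n_usable > 0
  chi <- suppressWarnings(stats::chisq.test(
    cbind(stb$n_positive[keep], stb$n_usable[keep] - stb$n_positive[keep])))
  expect_gt(chi$p.value, 0.05)
  expect_true(all(stb$low_n == (stb$n_usable < 3)))
})

test_that("animal-mean aggregation differs from vessel pooling", {
  # unbalanced animals: A has 10 vessels at 50%, B has 2 vessels at 0%
  fsA <- data.frame(t_min = 0, n_vessels_usable = 10, n_positive = 5,
                    positive_fraction_pct = 50, mean_diam_pos_um = 8,
                    mean_diam_neg_um = 6)
  fsB <- data.frame(t_min = 0, n_vessels_usable = 2, n_positive = 0,
                    positive_fraction_pct = 0, mean_diam_pos_um = NA,
                    mean_diam_neg_um = 6)
  a <- rbind(animal_summary("a1", "control", "small", fsA),
             animal_summary("a2", "control", "small", fsB))
  gs <- group_summary(a)
  expect_equal(gs$mean, 25)                       # mean of animal means
  pooled <- 100 * (5 + 0) / (10 + 2)              # 41.7%: not the default
  expect_false(isTRUE(all.equal(gs$mean, pooled)))
})
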