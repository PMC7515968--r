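test_that("ring time course is trapezoidal with the documented legs", {
  cfg <- sim_config(ring_amplitude = 6)
  expect_equal(ring_amplitude_at(cfg, 0), 0)
  expect_equal(ring_amplitude_at(cfg, 15 + 5), 6)        # mid-plateau
  expect_equal(ring_amplitude_at(cfg, 32.5), 3)          # mid-decay
  expect_equal(ring_amplitude_at(cfg, 60), 0)
  # monotone on the rise, non-increasing after the plateau
  tt <- seq(0, 15, by = 0.5)
  expect_true(all(diff(ring_amplitude_at(cfg, tt)) >= 0))
  tt <- seq(25, 60, by = 0.5)
  expect_true(all(diff(ring_amplitude_at(cfg, tt)) <= 0))
  expect_error(ring_amplitude_at(cfg, -1), ">= 0")
  expect_error(sim_config(rise_min = -5), "non-negative")
})

test_that("tracer field matches the 2-D heat kernel in closed form", {
  # source placed exactly on a pixel centre: 100 um field, 100 px
  cfg <- sim_config(field_size_um = 100, image_px = 100, n_vessels = 0,
                    source_xy_um = c(50.5, 50.5), injected_mass = 1,
                    diffusion_coeff_um2_per_min = 10)
  C <- tracer_field(cfg, 10)
  expect_equal(max(C), 1 / (4 * pi * 10 * 10), tolerance = 1e-12)
  # closed-form ratio C(20 um) / C(0) = exp(-1) at D = 10, t = 10
  i0 <- 51; j0 <- 51                       # pixel centred on the source
  expect_equal(C[i0, j0 + 20] / C[i0, j0], exp(-1), tolerance = 1e-6)
  expect_error(tracer_field(cfg, 0), "positive")
  expect_error(tracer_field(cfg, -3), "positive")
})

test_that("heat-kernel mass is conserved on a sufficiently large grid", {
  cfg <- sim_config(n_vessels = 0)         # 425 um field, source centred
  px <- cfg$pixel_size_um
  for (t in c(10, 40)) {                   # grid reaches >= 6*sqrt(2 D t)
    total <- sum(tracer_field(cfg, t)) * px^2
    expect_equal(total, cfg$injected_mass, tolerance = 0.01)
  }
})

test_that("vessel sampling honours positivity probability and geometry", {
  expect_true(all(!sample_vessels(sim_config(p_positive = 0,
                                             seed = 5))$is_positive))
  expect_true(all(sample_vessels(sim_config(p_positive = 1,
                                            seed = 5))$is_positive))
  v <- sample_vessels(sim_config(n_vessels = 50, p_positive = 0.30,
                                 seed = 42))
  # inside the binomial 99% interval for Binom(50, 0.3), and the frozen
  # count of this seeded draw as a regression value
  expect_gte(sum(v$is_positive), 4)
  expect_lte(sum(v$is_positive), 27)
  expect_identical(sum(v$is_positive), 17L)
  # determinism
  expect_identical(v, sample_vessels(sim_config(n_vessels = 50,
                                                p_positive = 0.30,
                                                seed = 42)))
  # lumens never overlap (and honour the configured clearance)
  for (s in 1:3) {
    cfg <- sim_config(seed = s)
    vv <- sample_vessels(cfg)
    dmat <- as.matrix(stats::dist(vv[, c("x_um", "y_um")]))
    need <- outer(vv$diameter_um, vv$diameter_um, "+") / 2 +
      cfg$min_separation_um
    diag(need) <- 0
    expect_true(all(dmat >= need - 1e-9))
    # fully inside the field
    r <- vv$diameter_um / 2
    expect_true(all(vv$x_um - r > 0 & vv$x_um + r < cfg$field_size_um &
                      vv$y_um - r > 0 & vv$y_um + r < cfg$field_size_um))
  }
})

test_that("impossible vessel packing fails with a clear message", {
  cfg <- sim_config(field_size_um = 150, image_px = 64, n_vessels = 50,
                    vessel_diameter_range_um = c(10, 13),
                    edge_margin_um = 20, seed = 1)
  expect_error(sample_vessels(cfg), "crowded")
})

test_that("noise model is unbiased, seeded, and degenerates to identity", {
  cfg0 <- sim_config(noise_gain = 0, read_noise_sd = 0)
  base <- image_frame(matrix(7, 64, 64), matrix(3, 64, 64), 1, 0)
  expect_identical(add_noise(base, cfg0)$green, base$green)

  cfg <- sim_config(noise_gain = 1, read_noise_sd = 2, seed = 9)
  plane <- image_frame(matrix(50, 200, 200), matrix(50, 200, 200), 1, 0)
  noisy <- add_noise(plane, cfg, 0L)
  # CLT: sample mean of 4e4 pixels within 3 standard errors of the truth
  se <- sqrt((50 + 4) / 4e4)
  expect_lt(abs(mean(noisy$green) - 50), 3 * se)
  # determinism: same seed and frame index give bit-identical frames
  expect_identical(noisy$green, add_noise(plane, cfg, 0L)$green)
  # different frame index gives a different stream
  expect_false(identical(noisy$green, add_noise(plane, cfg, 1L)$green))
  expect_error(sim_config(read_noise_sd = -1), "non-negative")
})

test_that("rendered frames separate channels and place rings abluminally", {
  # all vessels negative, no tracer mass: green identically zero
  cfg <- sim_config(n_vessels = 0, injected_mass = 0)
  ves <- data.frame(id = 1:2, x_um = c(150, 300), y_um = c(150, 300),
                    angle_rad = 0, diameter_um = c(6, 10),
                    is_positive = FALSE, distance_to_source_um = 0)
  fr <- render_frame(cfg, ves, 20)
  expect_true(all(fr$green == 0))
  expect_gt(max(fr$red), 0.99 * cfg$lumen_intensity)

  # single positive vessel: ring occupies (edge, edge + 3 um], green is
  # zero inside the lumen, and the annulus mean recovers the amplitude
  fx <- fine_vessel_fixture(ring_amplitude = 10)
  px <- fx$frame$pixel_size_um
  cc <- (seq_len(512) - 0.5) * px
  r <- sqrt(outer((cc - 25.6)^2, (cc - 25.6)^2, "+"))
  expect_true(all(fx$frame$green[r <= 4 - px] == 0))
  ring_mean <- mean(fx$frame$green[r > 4 + px & r <= 7 - px])
  expect_equal(ring_mean, 10, tolerance = 0.05)
  displaced <- mean(fx$frame$green[r > 14 + px & r <= 17 - px])
  expect_equal(ring_mean - displaced, 10, tolerance = 0.05)
  expect_true(all(fx$frame$green[r > 7 + px] == 0))
})

test_that("green channel carries no vessel signal in a null field", {
  # no tracer, no positive vessels, noise on: the tracer channel is pure
  # clipped read noise, whose mean is rs/sqrt(2*pi) (clipping at zero
  # halves the Gaussian), within 3 standard errors
  cfg <- sim_config(n_vessels = 5, p_positive = 0, injected_mass = 0,
                    noise_gain = 0, read_noise_sd = 2, seed = 3)
  ves <- sample_vessels(cfg)
  fr <- add_noise(render_frame(cfg, ves, 20), cfg, 0L)
  n <- length(fr$green)
  clip_mean <- 2 / sqrt(2 * pi)
  clip_sd <- sqrt(2^2 * (1 / 2 - 1 / (2 * pi)))
  expect_lt(abs(mean(fr$green) - clip_mean), 3 * clip_sd / sqrt(n))
})

test_that("datasets round-trip through TIFF/CSV/YAML byte-faithfully", {
  cfg <- sim_config(image_px = 64, n_vessels = 2, field_size_um = 425.10,
                    vessel_diameter_range_um = c(8, 13), seed = 11)
  out <- file.path(tempdir(), "ds1")
  unlink(out, recursive = TRUE)
  res <- generate_dataset(cfg, out)
  # 9 frames at t = 0, 5, ..., 40
  tifs <- list.files(out, pattern = "^frame_t[0-9]+\\.tif$")
  expect_length(tifs, 9)
  expect_true(all(sprintf("frame_t%02d.tif", seq(0, 40, 5)) %in% tifs))
  ds <- read_dataset(out)
  expect_equal(nrow(ds$vessels), 2)
  expect_identical(ds$vessels$is_positive, res$vessels$is_positive)
  # round trip equals the in-memory arrays to 32-bit float precision
  fr_mem <- add_noise(render_frame(cfg, res$vessels, 20), cfg, 4L)
  expect_equal(ds$frames[[5]]$green, fr_mem$green,
               tolerance = 1e-6)
  expect_equal(ds$frames[[5]]$red, fr_mem$red, tolerance = 1e-6)
  # regenerating reproduces identical files
  out2 <- file.path(tempdir(), "ds2")
  unlink(out2, recursive = TRUE)
  generate_dataset(cfg, out2)
  for (f in c(tifs, "annotations.csv"))
    expect_identical(unname(tools::md5sum(file.path(out, f))),
                     unname(tools::md5sum(file.path(out2, f))))

  # empty dataset still writes a valid stack and empty annotations
  cfg0 <- sim_config(image_px = 64, n_vessels = 0, seed = 1)
  out0 <- file.path(tempdir(), "ds0")
  unlink(out0, recursive = TRUE)
  generate_dataset(cfg0, out0)
  ds0 <- read_dataset(out0)
  expect_equal(nrow(ds0$vessels), 0)
  expect_length(ds0$frames, 9)
})
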