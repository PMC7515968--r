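# Shared fixtures, all generated in code.

# A single vessel centred in a small noiseless field at ~0.1 um/px, fine
# enough that pixelation is negligible against the 0.5 um optical edge.
fine_vessel_fixture <- function(ring_amplitude = 8, diameter_um = 8,
                                angle = 0.4, positive = TRUE,
                                injected_mass = 0) {
  cfg <- sim_config(field_size_um = 51.2, image_px = 512, n_vessels = 0,
                    injected_mass = injected_mass,
                    ring_amplitude = ring_amplitude,
                    edge_margin_um = 20, seed = 1)
  ves <- data.frame(id = 1L, x_um = 25.6, y_um = 25.6, angle_rad = angle,
                    diameter_um = diameter_um, is_positive = positive,
                    distance_to_source_um = 0)
  frame <- render_frame(cfg, ves, t_min = 20)
  profile <- extract_profile(frame, c(25.6, 25.6), angle, length_um = 40,
                             step_um = 0.1, vessel_id = 1L)
  list(cfg = cfg, vessels = ves, frame = frame, profile = profile)
}

# One noiseless vessel on the default 425-um/512-px grid.
default_grid_vessel <- function(diameter_um = 8, angle = 0.3,
                                center = c(207.3, 214.1)) {
  cfg <- sim_config(n_vessels = 0, injected_mass = 0)
  ves <- data.frame(id = 1L, x_um = center[1], y_um = center[2],
                    angle_rad = angle, diameter_um = diameter_um,
                    is_positive = FALSE, distance_to_source_um = 0)
  list(cfg = cfg, vessels = ves,
       frame = render_frame(cfg, ves, t_min = 0))
}

# Hand-built edge-aligned profile (for rule arithmetic tests).
make_aligned <- function(green, step = 0.25, side = "right", red = NULL,
                         id = 1L) {
  x <- seq(0, by = step, length.out = length(green))
  structure(list(side = side, abluminal_positions_um = x, green = green,
                 red = red %||% rep(0, length(green)), edge_pos_um = 4,
                 usable = TRUE, reason = NA_character_, vessel_id = id),
            class = "edge_aligned_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built profile_statistic (classification rule inputs).
make_stat <- function(z = NA, near = 0, far = 0, noise = 1,
                      side = "left", id = 1L) {
  structure(list(vessel_id = id, side = side, mean_near = near,
                 mean_far = far, contrast = near - far,
                 z_contrast = z, noise_scale = noise),
            class = "profile_statistic")
}

# Simulate one animal's field at the plateau time and return its measured
# positive fraction (the per-animal unit of the group designs).
animal_positive_fraction <- function(seed, p_positive) {
  cfg <- sim_config(p_positive = p_positive, seed = seed)
  ves <- sample_vessels(cfg)
  fr <- add_noise(render_frame(cfg, ves, 20), cfg, 4L)
  positive_fraction(vessel_calls(analyze_frame(fr, ves))$predicted_positive)
}

# Confusion counts of the classifier on one simulated field.
field_confusion <- function(seed, p_positive = 0.3, t_min = 20) {
  cfg <- sim_config(p_positive = p_positive, seed = seed)
  ves <- sample_vessels(cfg)
  fr <- add_noise(render_frame(cfg, ves, t_min), cfg, 4L)
  calls <- vessel_calls(analyze_frame(fr, ves))
  ok <- !is.na(calls$predicted_positive)
  truth <- ves$is_positive[match(calls$vessel_id, ves$id)]
  c(tp = sum(calls$predicted_positive[ok] & truth[ok]),
    fn = sum(!calls$predicted_positive[ok] & truth[ok]),
    fp = sum(calls$predicted_positive[ok] & !truth[ok]),
    tn = sum(!calls$predicted_positive[ok] & !truth[ok]),
    excluded = sum(!ok))
}

# Rectangular wall mask with exactly 600/130/270 endothelium/intramural/
# basement pixels around a 20x20 lumen (wall block 35x40 minus lumen).
rational_wall_mask <- function(shuffle_seed = NULL) {
  lab <- matrix(0L, 45, 50)
  lab[4:38, 4:43] <- 2L                    # 35 x 40 block = 1400 px
  lab[11:30, 14:33] <- 1L                  # 20 x 20 lumen = 400 px
  wall_idx <- which(lab == 2L)             # 1000 wall pixels
  if (!is.null(shuffle_seed)) {
    set.seed(shuffle_seed)
    wall_idx <- sample(wall_idx)
  }
  lab[wall_idx[1:600]] <- 2L
  lab[wall_idx[601:730]] <- 3L
  lab[wall_idx[731:1000]] <- 4L
  wall_mask(lab, pixel_size_um = 0.05)
}
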