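#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic two-channel
#' imaging experiment.  The defaults emulate a cortical two-photon field of
#' view: a 425.10 x 425.10 um plane imaged at 512 x 512 pixels every 5 min
#' for 40 min, with a point-source bolus of labelled tracer diffusing into
#' the neuropil, sulforhodamine-filled vessel lumens, and a subset of
#' vessels accumulating tracer in a thin abluminal ring whose amplitude
#' rises over 15 min, plateaus for 10 min and decays over 15 min.
#'
#' Intensities are in arbitrary detector units.  With the default noise
#' model (photon shot noise at `noise_gain = 1` plus Gaussian read noise of
#' SD 2) the default ring amplitude of 20 is ten times the background noise
#' scale, i.e. a clearly tracer-positive vessel.
#'
#' @param field_size_um side of the square field of view, um.
#' @param image_px image side in pixels (>= 64).
#' @param n_vessels number of vessels to place.
#' @param vessel_diameter_range_um numeric length-2, min/max lumen diameter
#'   (um); diameters are drawn uniformly in this range.
#' @param p_positive probability that a vessel is tracer-positive.
#' @param source_xy_um injection-source position, um (default: field centre).
#' @param injected_mass tracer mass of the point source, intensity units
#'   times um^2.
#' @param diffusion_coeff_um2_per_min tracer diffusion coefficient.
#' @param ring_amplitude peak intensity of the perivascular ring.
#' @param ring_width_um radial width of the ring, starting at the lumen edge.
#' @param rise_min,plateau_min,decay_min durations of the trapezoidal ring
#'   time course, minutes.
#' @param frame_interval_min,total_min acquisition grid; the interval must
#'   divide the total.
#' @param lumen_intensity lumen-dye intensity inside vessels.
#' @param noise_gain detector gain of the photon-noise stage; `0` disables
#'   shot noise (pure Gaussian read noise).
#' @param read_noise_sd SD of additive Gaussian read noise.
#' @param edge_margin_um minimum distance of vessel centres from the field
#'   border, so that a default 100-um measuring line never leaves the field.
#' @param min_separation_um minimum clearance between lumen surfaces.  The
#'   default (ring width + the 10-um analysis span) keeps every annotated
#'   vessel analyzable by construction -- no neighbouring lumen or ring
#'   inside another vessel's near/far windows -- emulating the manually
#'   selected, clearly profiled vessels of the in vivo protocol; it is
#'   still much denser packing than real cortical capillary spacing.
#' @param seed integer; all simulator randomness derives from it.
#' @return object of class `sim_config` (a validated named list).
#' @seealso [sample_vessels()], [render_frame()], [generate_dataset()]
#' @export
#' @examples
#' cfg <- sim_config(n_vessels = 5, seed = 1)
#' cfg$frame_times_min
sim_config <- function(field_size_um = 425.10,
                       image_px = 512L,
                       n_vessels = 50L,
                       vessel_diameter_range_um = c(5, 13),
                       p_positive = 0.3,
                       source_xy_um = NULL,
                       injected_mass = 25000,
                       diffusion_coeff_um2_per_min = 10,
                       ring_amplitude = 20,
                       ring_width_um = 3,
                       rise_min = 15,
                       plateau_min = 10,
                       decay_min = 15,
                       frame_interval_min = 5,
                       total_min = 40,
                       lumen_intensity = 100,
                       noise_gain = 1,
                       read_noise_sd = 2,
                       edge_margin_um = 51,
                       min_separation_um = ring_width_um + 10,
                       seed = 1L) {
  cfg <- list(
    field_size_um = as.numeric(field_size_um),
    image_px = as.integer(image_px),
    n_vessels = as.integer(n_vessels),
    vessel_diameter_range_um = as.numeric(vessel_diameter_range_um),
    p_positive = as.numeric(p_positive),
    source_xy_um = as.numeric(source_xy_um %||%
                                rep(field_size_um / 2, 2)),
    injected_mass = as.numeric(injected_mass),
    diffusion_coeff_um2_per_min = as.numeric(diffusion_coeff_um2_per_min),
    ring_amplitude = as.numeric(ring_amplitude),
    ring_width_um = as.numeric(ring_width_um),
    rise_min = as.numeric(rise_min),
    plateau_min = as.numeric(plateau_min),
    decay_min = as.numeric(decay_min),
    frame_interval_min = as.numeric(frame_interval_min),
    total_min = as.numeric(total_min),
    lumen_intensity = as.numeric(lumen_intensity),
    noise_gain = as.numeric(noise_gain),
    read_noise_sd = as.numeric(read_noise_sd),
    edge_margin_um = as.numeric(edge_margin_um),
    min_separation_um = as.numeric(min_separation_um),
    seed = as.integer(seed))
  cfg$pixel_size_um <- cfg$field_size_um / cfg$image_px
  cfg$frame_times_min <- seq(0, cfg$total_min, by = cfg$frame_interval_min)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    "field_size_um must be > 0" = cfg$field_size_um > 0,
    "image_px must be >= 64" = cfg$image_px >= 64L,
    "p_positive must be in [0, 1]" =
      cfg$p_positive >= 0 && cfg$p_positive <= 1,
    "vessel_diameter_range_um must be two positive increasing values" =
      length(cfg$vessel_diameter_range_um) == 2 &&
      all(cfg$vessel_diameter_range_um > 0) &&
      diff(cfg$vessel_diameter_range_um) >= 0,
    "source_xy_um must have length 2" = length(cfg$source_xy_um) == 2,
    "diffusion coefficient must be > 0" = cfg$diffusion_coeff_um2_per_min > 0,
    "ring_width_um must be > 0" = cfg$ring_width_um > 0,
    "durations must be non-negative" =
      all(c(cfg$rise_min, cfg$plateau_min, cfg$decay_min) >= 0),
    "frame_interval_min must be > 0" = cfg$frame_interval_min > 0,
    "noise parameters must be non-negative" =
      cfg$noise_gain >= 0 && cfg$read_noise_sd >= 0,
    "n_vessels must be non-negative" = cfg$n_vessels >= 0L)
  if (abs(cfg$total_min / cfg$frame_interval_min -
          round(cfg$total_min / cfg$frame_interval_min)) > 1e-9)
    stop("frame_interval_min (", cfg$frame_interval_min,
         ") must divide total_min (", cfg$total_min, ")")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic imaging configuration\n")
  cat(sprintf("  field: %.2f x %.2f um at %d px (%.3f um/px)\n",
              x$field_size_um, x$field_size_um, x$image_px, x$pixel_size_um))
  cat(sprintf("  vessels: %d, diameters %.1f-%.1f um, P(positive) = %.2f\n",
              x$n_vessels, x$vessel_diameter_range_um[1],
              x$vessel_diameter_range_um[2], x$p_positive))
  cat(sprintf("  frames: t = %s min\n",
              paste(x$frame_times_min, collapse = ", ")))
  cat(sprintf("  ring: amplitude %.1f, width %.1f um, rise/plateau/decay %g/%g/%g min\n",
              x$ring_amplitude, x$ring_width_um,
              x$rise_min, x$plateau_min, x$decay_min))
  cat(sprintf("  noise: gain %.2f, read SD %.2f; seed %d\n",
              x$noise_gain, x$read_noise_sd, x$seed))
  invisible(x)
}

#' Sample non-overlapping vessel geometry with ground truth
#'
#' Places `n_vessels` circular lumens uniformly in the field (centres at
#' least `edge_margin_um` from the border), with diameters drawn uniformly
#' in `vessel_diameter_range_um` and uniform random cross-line
#' orientations.  Each vessel is independently flagged tracer-positive with
#' probability `p_positive`.  Placement uses rejection sampling: a
#' candidate is accepted only if its lumen surface keeps
#' `min_separation_um` of clearance from every previously accepted lumen,
#' so no lumen or perivascular ring intrudes into another vessel's
#' analysis span.
#'
#' @param config a [sim_config()].
#' @return data frame with one row per vessel: `id`, `x_um`, `y_um`,
#'   `angle_rad`, `diameter_um`, `is_positive` (logical ground truth) and
#'   `distance_to_source_um`.
#' @export
sample_vessels <- function(config) {
  validate_sim_config(config)
  n <- config$n_vessels
  out <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                    angle_rad = numeric(0), diameter_um = numeric(0),
                    is_positive = logical(0),
                    distance_to_source_um = numeric(0))
  if (n == 0L) return(out)
  lo <- config$edge_margin_um
  hi <- config$field_size_um - config$edge_margin_um
  if (hi <= lo)
    stop("edge_margin_um leaves no room for vessel centres")
  dr <- config$vessel_diameter_range_um
  clearance <- config$min_separation_um %||% (config$ring_width_um + 10)
  with_seed(mix_seed(config$seed, 1L), {
    xs <- numeric(n); ys <- numeric(n); ds <- numeric(n)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 1000L * n
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("could not place ", n, " non-overlapping vessels in a ",
             round(config$field_size_um), " um field after ", max_attempts,
             " attempts: field too crowded; reduce n_vessels or diameters")
      x <- stats::runif(1, lo, hi)
      y <- stats::runif(1, lo, hi)
      d <- stats::runif(1, dr[1], dr[2])
      if (placed > 0L) {
        sep <- sqrt((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2)
        if (any(sep < (ds[seq_len(placed)] + d) / 2 + clearance)) next
      }
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y; ds[placed] <- d
    }
    ang <- stats::runif(n, 0, pi)
    pos <- stats::runif(n) < config$p_positive
    out <- data.frame(
      id = seq_len(n),
      x_um = xs, y_um = ys,
      angle_rad = ang,
      diameter_um = ds,
      is_positive = pos,
      distance_to_source_um = sqrt((xs - config$source_xy_um[1])^2 +
                                     (ys - config$source_xy_um[2])^2))
  })
  out
}

#' Free-diffusion tracer background
#'
#' Noiseless tracer concentration on the pixel grid at time `t_min` after
#' release of a point source of mass `M` at `source_xy_um`, under free 2-D
#' diffusion: `C(r, t) = M / (4 pi D t) * exp(-r^2 / (4 D t))`.
#'
#' @param config a [sim_config()].
#' @param t_min time since injection, min; must be > 0.
#' @return `image_px` x `image_px` numeric matrix.
#' @export
tracer_field <- function(config, t_min) {
  validate_sim_config(config)
  if (!is.numeric(t_min) || length(t_min) != 1 || t_min <= 0)
    stop("t_min must be a single positive time (got ", t_min, ")")
  px <- pixel_size_um(config)
  cc <- pixel_centers_um(config$image_px, px)
  D <- config$diffusion_coeff_um2_per_min
  s <- 4 * D * t_min
  r2 <- outer((cc - config$source_xy_um[2])^2,
              (cc - config$source_xy_um[1])^2, "+")
  config$injected_mass / (pi * s) * exp(-r2 / s)
}

#' Trapezoidal time course of the perivascular ring
#'
#' Ring amplitude as a function of time: linear rise from 0 to
#' `ring_amplitude` over `rise_min`, constant plateau for `plateau_min`,
#' linear decay back to 0 over `decay_min`, and 0 afterwards.
#'
#' @param config a [sim_config()].
#' @param t_min time(s) since injection, min; must be >= 0.
#' @return numeric vector of amplitudes, same length as `t_min`.
#' @export
ring_amplitude_at <- function(config, t_min) {
  validate_sim_config(config)
  if (any(t_min < 0)) stop("t_min must be >= 0")
  A <- config$ring_amplitude
  r <- config$rise_min; p <- config$plateau_min; d <- config$decay_min
  up <- if (r > 0) t_min / r else as.numeric(t_min >= 0)
  down <- if (d > 0) (r + p + d - t_min) / d else as.numeric(t_min <= r + p)
  A * pmax(0, pmin(1, up, down))
}

#' Construct an image frame
#'
#' @param green,red equal-sized numeric matrices (tracer and lumen-dye
#'   channels).
#' @param pixel_size_um pixel size, um.
#' @param t_min acquisition time, min.
#' @return object of class `image_frame`.
#' @export
image_frame <- function(green, red, pixel_size_um, t_min = NA_real_) {
  stopifnot("green and red must be matrices of identical shape" =
              is.matrix(green) && is.matrix(red) &&
              identical(dim(green), dim(red)),
            "pixel_size_um must be > 0" = pixel_size_um > 0)
  structure(list(green = green, red = red,
                 pixel_size_um = as.numeric(pixel_size_um),
                 t_min = as.numeric(t_min)),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("image_frame: %d x %d px (%.3f um/px), t = %g min\n",
              nrow(x$green), ncol(x$green), x$pixel_size_um, x$t_min))
  cat(sprintf("  green [%.2f, %.2f], red [%.2f, %.2f]\n",
              min(x$green), max(x$green), min(x$red), max(x$red)))
  invisible(x)
}

# Radial distance matrix (um) of a pixel box around a centre; returns the
# box indices and distances.  Internal to the renderer.
vessel_box <- function(config, cx, cy, reach_um) {
  px <- pixel_size_um(config)
  n <- config$image_px
  i0 <- max(1L, floor((cy - reach_um) / px))
  i1 <- min(n, ceiling((cy + reach_um) / px) + 1L)
  j0 <- max(1L, floor((cx - reach_um) / px))
  j1 <- min(n, ceiling((cx + reach_um) / px) + 1L)
  yy <- pixel_centers_um(n, px)[i0:i1]
  xx <- pixel_centers_um(n, px)[j0:j1]
  list(rows = i0:i1, cols = j0:j1,
       r = sqrt(outer((yy - cy)^2, (xx - cx)^2, "+")))
}

#' Render a noiseless two-channel frame
#'
#' Red (lumen-dye) channel: each lumen is a disk of `lumen_intensity`
#' whose edge is smoothed by a fixed 0.5 um Gaussian (an error-function
#' radial edge; the half-maximum crossing sits exactly at the true
#' radius).  Green (tracer) channel: the free-diffusion background of
#' [tracer_field()] (zeroed inside lumens, since the tracer is
#' extravascular), plus, for each ground-truth-positive vessel, an
#' abluminal annulus of width `ring_width_um` starting at the lumen edge
#' with amplitude [ring_amplitude_at()]`(t)`.  At `t_min = 0` (before the
#' injection bolus has spread) the green channel is identically zero.
#'
#' @param config a [sim_config()].
#' @param vessels data frame from [sample_vessels()].
#' @param t_min acquisition time, min (>= 0).
#' @return an [image_frame()].
#' @export
render_frame <- function(config, vessels, t_min) {
  validate_sim_config(config)
  if (t_min < 0) stop("t_min must be >= 0")
  n <- config$image_px
  px <- pixel_size_um(config)
  red <- matrix(0, n, n)
  green <- if (t_min > 0 && config$injected_mass > 0)
    tracer_field(config, t_min) else matrix(0, n, n)
  amp <- ring_amplitude_at(config, t_min)
  w <- config$ring_width_um
  if (nrow(vessels) > 0) {
    for (k in seq_len(nrow(vessels))) {
      R <- vessels$diameter_um[k] / 2
      box <- vessel_box(config, vessels$x_um[k], vessels$y_um[k],
                        R + w + 4 * EDGE_SIGMA_UM + px)
      red[box$rows, box$cols] <- red[box$rows, box$cols] +
        config$lumen_intensity * stats::pnorm((R - box$r) / EDGE_SIGMA_UM)
      g <- green[box$rows, box$cols]
      g[box$r <= R] <- 0                      # no intravascular tracer
      if (vessels$is_positive[k] && amp > 0)
        g <- g + amp * (box$r > R & box$r <= R + w)
      green[box$rows, box$cols] <- g
    }
  }
  image_frame(green, red, px, t_min)
}

#' Apply the detector noise model
#'
#' Each pixel intensity `I` becomes
#' `noise_gain * Poisson(I / noise_gain) + Normal(0, read_noise_sd)`,
#' clipped at zero.  `noise_gain = 0` skips the photon (shot-noise) stage.
#' The result is deterministic given `config$seed` and `frame_index`:
#' every frame of a stack draws from its own derived RNG stream.
#'
#' @param frame an [image_frame()] (noiseless).
#' @param config a [sim_config()].
#' @param frame_index integer stream index (e.g. position of the frame in
#'   the time series).
#' @return a new [image_frame()] with noisy channels.
#' @export
add_noise <- function(frame, config, frame_index = 0L) {
  validate_sim_config(config)
  g <- config$noise_gain; rs <- config$read_noise_sd
  noisify <- function(m, stream) {
    with_seed(mix_seed(config$seed, 1000L + 2L * frame_index + stream), {
      v <- as.numeric(m)
      if (g > 0) v <- g * stats::rpois(length(v), v / g)
      if (rs > 0) v <- v + stats::rnorm(length(v), 0, rs)
      matrix(pmax(v, 0), nrow(m), ncol(m))
    })
  }
  image_frame(noisify(frame$green, 0L), noisify(frame$red, 1L),
              frame$pixel_size_um, frame$t_min)
}

#' Generate and write a complete synthetic dataset
#'
#' Samples vessels, renders and noise-corrupts one frame per acquisition
#' time, and writes: one two-page 32-bit float TIFF per time point
#' (`frame_t{mm}.tif`, page 1 = tracer channel "AB40", page 2 = lumen-dye
#' channel "SR101"), the vessel annotation CSV (`annotations.csv`), and
#' the fully resolved configuration (`config.yaml`).  Stored TIFF values
#' are intensities divided by the recorded `intensity_scale` (the TIFF
#' writer stores [0, 1] floats); readers multiply back, see
#' [read_dataset()].  Re-running with an identical configuration
#' reproduces identical files.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `vessels`, `files`, `intensity_scale`.
#' @export
generate_dataset <- function(config, out_dir) {
  validate_sim_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  vessels <- sample_vessels(config)
  times <- config$frame_times_min
  frames <- lapply(seq_along(times), function(k)
    add_noise(render_frame(config, vessels, times[k]), config, k - 1L))
  peak <- max(1, vapply(frames, function(f) max(f$green, f$red), 0))
  scale <- peak * 1.0001
  files <- character(0)
  for (k in seq_along(times)) {
    path <- file.path(out_dir, sprintf("frame_t%02d.tif", round(times[k])))
    ok <- tryCatch(
      tiff::writeTIFF(list(frames[[k]]$green / scale,
                           frames[[k]]$red / scale),
                      path, bits.per.sample = 32L, reduce = FALSE),
      error = function(e) stop("failed to write TIFF ", path, ": ",
                               conditionMessage(e)))
    files <- c(files, path)
  }
  ann <- vessels
  ann$is_positive <- as.integer(ann$is_positive)
  ann_path <- file.path(out_dir, "annotations.csv")
  utils::write.csv(ann, ann_path, row.names = FALSE, quote = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  cfg_out <- unclass(config)
  cfg_out$intensity_scale <- scale
  cfg_out$channel_pages <- c("AB40", "SR101")
  yaml::write_yaml(cfg_out, cfg_path)
  invisible(list(vessels = vessels,
                 files = c(files, ann_path, cfg_path),
                 intensity_scale = scale))
}

#' Read one frame of a written stack
#'
#' @param path TIFF written by [generate_dataset()] (two 32-bit float
#'   pages: tracer, lumen dye).
#' @param pixel_size_um pixel size, um.
#' @param t_min acquisition time, min.
#' @param intensity_scale scale recorded in the dataset `config.yaml`.
#' @return an [image_frame()].
#' @export
read_frame_tiff <- function(path, pixel_size_um, t_min = NA_real_,
                            intensity_scale = 1) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("failed to read TIFF ", path, ": ",
                           conditionMessage(e)))
  if (length(pages) < 2)
    stop("failed to read TIFF ", path, ": expected 2 channel pages, found ",
         length(pages))
  image_frame(pages[[1]] * intensity_scale, pages[[2]] * intensity_scale,
              pixel_size_um, t_min)
}

#' Read a dataset written by [generate_dataset()]
#'
#' @param dir dataset directory.
#' @return list with `config` (named list incl. `intensity_scale`),
#'   `vessels` (annotation data frame, `is_positive` as logical) and
#'   `frames` (list of [image_frame()], time-ordered).
#' @export
read_dataset <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  ann <- utils::read.csv(file.path(dir, "annotations.csv"))
  if (nrow(ann) > 0) ann$is_positive <- ann$is_positive > 0
  times <- cfg$frame_times_min
  frames <- lapply(seq_along(times), function(k)
    read_frame_tiff(file.path(dir, sprintf("frame_t%02d.tif",
                                           round(times[k]))),
                    cfg$pixel_size_um, times[k],
                    cfg$intensity_scale %||% 1))
  list(config = cfg, vessels = ann, frames = frames)
}
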