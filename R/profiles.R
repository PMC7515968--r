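#' Extract a cross-vessel line profile
#'
#' Samples both channels along a straight line of `length_um` centred on
#' the vessel, at `step_um` spacing, by bilinear sub-pixel interpolation.
#' Positions are in um relative to the vessel centre (negative to positive
#' along the line direction `angle_rad`).
#'
#' @param frame an [image_frame()].
#' @param center_xy_um numeric length-2, vessel centre in um.
#' @param angle_rad orientation of the measuring line (0 = along x).
#' @param length_um total line length (default 100 um).
#' @param step_um sampling step; must not exceed the pixel size.
#' @param vessel_id optional id used in error messages and exports.
#' @return object of class `raw_profile`: list with `positions_um`,
#'   `green`, `red`, `step_um`, `vessel_id`.
#' @export
extract_profile <- function(frame, center_xy_um, angle_rad,
                            length_um = 100, step_um = 0.25,
                            vessel_id = NA_integer_) {
  stopifnot(inherits(frame, "image_frame"),
            length(center_xy_um) == 2, length_um > 0, step_um > 0)
  if (step_um > frame$pixel_size_um + 1e-12)
    stop("step_um (", step_um, ") must not exceed the pixel size (",
         signif(frame$pixel_size_um, 4), " um)")
  half <- length_um / 2
  pos <- seq(-half, half, by = step_um)
  dx <- cos(angle_rad); dy <- sin(angle_rad)
  x <- center_xy_um[1] + pos * dx
  y <- center_xy_um[2] + pos * dy
  fx <- ncol(frame$green) * frame$pixel_size_um
  fy <- nrow(frame$green) * frame$pixel_size_um
  over <- max(0, -min(x), -min(y), max(x) - fx, max(y) - fy)
  if (over > 1e-9)
    stop("measuring line for vessel ", vessel_id, " exits the field by ",
         signif(over, 3), " um")
  structure(list(positions_um = pos,
                 green = bilinear_sample(frame$green, x, y,
                                         frame$pixel_size_um),
                 red = bilinear_sample(frame$red, x, y,
                                       frame$pixel_size_um),
                 step_um = step_um,
                 vessel_id = vessel_id),
            class = "raw_profile")
}

#' Locate the lumen edges on the lumen-dye channel
#'
#' Starting from the red-channel maximum (the lumen plateau), walks
#' outward on each side and returns the first position where the red
#' intensity falls below `background + threshold_frac * (plateau -
#' background)`, linearly interpolated between samples.  `threshold_frac =
#' 0.5` is the full-width-at-half-maximum convention.  The per-side
#' background is the median of the outer 20% of samples on that side.
#'
#' @param profile a [extract_profile()] result.
#' @param threshold_frac fraction of the background-subtracted plateau at
#'   which the edge is crossed (default 0.5).
#' @param peak_search_um half-width of the central window searched for the
#'   lumen plateau (default 15 um).  The line is centred on the annotated
#'   vessel, so its lumen peak lies near position 0; restricting the
#'   search keeps a second vessel crossed further out along the line from
#'   hijacking the edge detection.
#' @return list with `left_edge_um`, `right_edge_um` (positions in profile
#'   coordinates), `plateau`, `background` (length-2) and `threshold`
#'   (length-2).
#' @export
locate_lumen_edges <- function(profile, threshold_frac = 0.5,
                               peak_search_um = 15) {
  stopifnot(inherits(profile, "raw_profile"),
            threshold_frac > 0, threshold_frac < 1)
  red <- profile$red
  pos <- profile$positions_um
  n <- length(red)
  central <- which(abs(pos) <= peak_search_um)
  m <- central[which.max(red[central])]
  plateau <- red[m]
  n_out <- max(1L, floor(0.2 * n))
  bg <- c(stats::median(red[seq_len(n_out)]),
          stats::median(red[seq(n - n_out + 1L, n)]))
  if (any(plateau <= bg))
    stop("no lumen signal: red plateau (", signif(plateau, 4),
         ") does not rise above background (",
         paste(signif(bg, 4), collapse = "/"), ")")
  thr <- bg + threshold_frac * (plateau - bg)

  cross_out <- function(idx, thr_s) {
    # idx: sample indices walking outward from the peak (excluding it)
    below <- which(red[idx] < thr_s)
    if (length(below) == 0)
      stop("open lumen: red never falls below threshold on one side ",
           "of the profile")
    i <- idx[below[1]]                       # first sample below threshold
    j <- i - sign(i - m)                     # neighbour towards the peak
    # linear interpolation of the crossing between samples j and i
    pos[j] + (thr_s - red[j]) * (pos[i] - pos[j]) / (red[i] - red[j])
  }

  left <- cross_out(rev(seq_len(m - 1L)), thr[1])
  right <- cross_out(if (m < n) seq(m + 1L, n) else integer(0), thr[2])
  list(left_edge_um = left, right_edge_um = right,
       plateau = plateau, background = bg, threshold = thr)
}

#' Re-index a profile to abluminal coordinates
#'
#' Splits the raw profile at the detected lumen edges and returns one
#' profile per side with positions measured outward from the edge
#' (abluminal distance, 0 at the edge).  Both channels are resampled onto
#' a regular abluminal grid of the original step by linear interpolation.
#' A side with less than `min_extent_um` of abluminal extent is flagged
#' unusable (`usable = FALSE`, reason `"truncated side"`) rather than
#' dropped, so pipelines can keep exclusion bookkeeping.
#'
#' @param profile a [extract_profile()] result.
#' @param edges result of [locate_lumen_edges()].
#' @param min_extent_um minimum usable abluminal extent (default 10 um,
#'   the analysis span of the near + far windows).
#' @return list with elements `left` and `right`, each of class
#'   `edge_aligned_profile`: `side`, `abluminal_positions_um`, `green`,
#'   `red`, `edge_pos_um`, `usable`, `reason`, `vessel_id`.
#' @export
align_abluminal <- function(profile, edges, min_extent_um = 10) {
  stopifnot(inherits(profile, "raw_profile"))
  pos <- profile$positions_um
  step <- profile$step_um

  one_side <- function(side) {
    edge <- if (side == "left") edges$left_edge_um else edges$right_edge_um
    if (side == "left") {
      ab_raw <- edge - pos          # decreasing in pos; positive outward
      sel <- ab_raw >= 0
    } else {
      ab_raw <- pos - edge
      sel <- ab_raw >= 0
    }
    extent <- max(ab_raw[sel])
    grid <- seq(0, floor(extent / step + 1e-9) * step, by = step)
    o <- order(ab_raw[sel])
    xs <- ab_raw[sel][o]
    res <- structure(list(
      side = side,
      abluminal_positions_um = grid,
      green = stats::approx(xs, profile$green[sel][o], xout = grid,
                            rule = 2)$y,
      red = stats::approx(xs, profile$red[sel][o], xout = grid,
                          rule = 2)$y,
      edge_pos_um = edge,
      usable = extent >= min_extent_um,
      reason = if (extent >= min_extent_um) NA_character_
               else "truncated side",
      vessel_id = profile$vessel_id),
      class = "edge_aligned_profile")
    res
  }

  list(left = one_side("left"), right = one_side("right"))
}

#' Suggest a cross-vessel line orientation
#'
#' Estimates the direction across a vessel from the red-channel structure
#' tensor in a disk around the centre: intensity gradients of a tubular
#' structure point across its axis, so the dominant eigenvector of the
#' summed outer product of gradients is the cross direction.  Annotated
#' orientations should take precedence; this is a convenience for
#' un-annotated data.
#'
#' @param frame an [image_frame()].
#' @param center_xy_um vessel centre, um.
#' @param radius_um neighbourhood radius (default 6 um).
#' @return angle in radians in `[0, pi)`.
#' @export
suggest_cross_angle <- function(frame, center_xy_um, radius_um = 6) {
  px <- frame$pixel_size_um
  n <- nrow(frame$red)
  i0 <- max(2L, floor((center_xy_um[2] - radius_um) / px))
  i1 <- min(n - 1L, ceiling((center_xy_um[2] + radius_um) / px))
  j0 <- max(2L, floor((center_xy_um[1] - radius_um) / px))
  j1 <- min(n - 1L, ceiling((center_xy_um[1] + radius_um) / px))
  sub <- frame$red[(i0 - 1L):(i1 + 1L), (j0 - 1L):(j1 + 1L)]
  nr <- nrow(sub); nc <- ncol(sub)
  gx <- (sub[2:(nr - 1), 3:nc] - sub[2:(nr - 1), 1:(nc - 2)]) / (2 * px)
  gy <- (sub[3:nr, 2:(nc - 1)] - sub[1:(nr - 2), 2:(nc - 1)]) / (2 * px)
  yy <- pixel_centers_um(n, px)[i0:i1] - center_xy_um[2]
  xx <- pixel_centers_um(n, px)[j0:j1] - center_xy_um[1]
  w <- outer(yy^2, xx^2, "+") <= radius_um^2
  sxx <- sum(gx^2 * w); syy <- sum(gy^2 * w); sxy <- sum(gx * gy * w)
  ang <- 0.5 * atan2(2 * sxy, sxx - syy)
  ang %% pi
}

#' Export edge-aligned profiles as a tidy CSV
#'
#' One row per abluminal sample: `vessel_id`, `side`, `abluminal_um`,
#' `green` -- the format used for audit plots of individual vessels.
#'
#' @param aligned list of `edge_aligned_profile` objects (or the
#'   `left`/`right` lists returned by [align_abluminal()]).
#' @param path output CSV path; if `NULL`, the data frame is returned.
#' @return the data frame, invisibly when written.
#' @export
profiles_to_csv <- function(aligned, path = NULL) {
  flat <- list()
  collect <- function(x) {
    if (inherits(x, "edge_aligned_profile")) flat[[length(flat) + 1L]] <<- x
    else if (is.list(x)) lapply(x, collect)
    invisible(NULL)
  }
  collect(aligned)
  df <- do.call(rbind, lapply(flat, function(p)
    data.frame(vessel_id = p$vessel_id, side = p$side,
               abluminal_um = p$abluminal_positions_um, green = p$green)))
  if (is.null(path)) return(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' @export
print.raw_profile <- function(x, ...) {
  cat(sprintf("raw_profile (vessel %s): %d samples, %g um step, span %g um\n",
              x$vessel_id, length(x$positions_um), x$step_um,
              diff(range(x$positions_um))))
  invisible(x)
}

#' @export
print.edge_aligned_profile <- function(x, ...) {
  cat(sprintf("edge_aligned_profile (vessel %s, %s side): edge at %.2f um, extent %.1f um%s\n",
              x$vessel_id, x$side, x$edge_pos_um,
              max(x$abluminal_positions_um),
              if (x$usable) "" else paste0(" [unusable: ", x$reason, "]")))
  invisible(x)
}
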