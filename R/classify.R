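# Window geometry of the classifying statistic, in um on the abluminal
# axis.  The near window is the first 3 um outside the lumen edge, the far
# window the next 7 um; both half-open (a, b].
NEAR_UM <- 3
FAR_UM <- 10
NOISE_WINDOW_UM <- c(15, 25)

#' Near/far window statistic of an abluminal profile
#'
#' The classifying quantity: the mean tracer (green) intensity over the
#' first `(0, 3]` um outside the lumen edge (`mean_near`), the mean over
#' the next `(3, 10]` um (`mean_far`), their difference (`contrast`), and
#' the contrast standardised by a local background-noise scale
#' (`z_contrast`).  A tracer-positive vessel compacts tracer directly on
#' its wall, so `mean_near` exceeds `mean_far`; for a negative vessel both
#' windows see only the smooth parenchymal background.
#'
#' Unless supplied, `noise_scale` is estimated robustly as
#' `1.4826 * MAD` of the green samples in a far annulus (15-25 um), which
#' lies beyond both the ring and the steepest part of the diffusion
#' background but is still local to the vessel.
#'
#' @param p an `edge_aligned_profile` (see [align_abluminal()]), usable,
#'   with at least 10 um of abluminal extent.
#' @param noise_scale optional known noise SD of single profile samples.
#' @return object of class `profile_statistic`: `vessel_id`, `side`,
#'   `mean_near`, `mean_far`, `contrast`, `z_contrast`, `noise_scale`.
#' @export
profile_statistic <- function(p, noise_scale = NULL) {
  stopifnot(inherits(p, "edge_aligned_profile"))
  if (!isTRUE(p$usable))
    stop("profile side is unusable (", p$reason, ")")
  x <- p$abluminal_positions_um
  if (max(x) < FAR_UM)
    stop("abluminal extent (", signif(max(x), 3), " um) is below the ",
         FAR_UM, " um analysis span")
  near <- p$green[x > 0 & x <= NEAR_UM]
  far <- p$green[x > NEAR_UM & x <= FAR_UM]
  if (length(near) == 0 || length(far) == 0)
    stop("internal error: empty analysis window")   # cannot occur at step <= 0.25
  if (is.null(noise_scale)) {
    s <- p$green[x > NOISE_WINDOW_UM[1] & x <= NOISE_WINDOW_UM[2]]
    noise_scale <- if (length(s) >= 10) stats::mad(s) else NA_real_
  }
  contrast <- mean(near) - mean(far)
  structure(list(vessel_id = p$vessel_id,
                 side = p$side,
                 mean_near = mean(near),
                 mean_far = mean(far),
                 contrast = contrast,
                 z_contrast = if (isTRUE(noise_scale > 0))
                   contrast / noise_scale else NA_real_,
                 noise_scale = noise_scale),
            class = "profile_statistic")
}

#' @export
print.profile_statistic <- function(x, ...) {
  cat(sprintf(
    "profile_statistic (vessel %s, %s): near %.3f, far %.3f, contrast %.3f (z = %s)\n",
    x$vessel_id, x$side, x$mean_near, x$mean_far, x$contrast,
    if (is.na(x$z_contrast)) "NA" else sprintf("%.2f", x$z_contrast)))
  invisible(x)
}

#' Per-vessel classification rule
#'
#' The default (`zscore`) calls a vessel positive when the mean over its
#' usable sides of the noise-standardised contrast reaches `z_threshold`.
#' `ratio` compares the side-averaged near mean against the side-averaged
#' far mean (floored at the noise scale); `group_test` runs a one-sided
#' paired comparison of near vs far means across the supplied
#' measurements, for vessels observed in several frames.
#'
#' @param mode `"zscore"`, `"ratio"` or `"group_test"`.
#' @param z_threshold z threshold of the default mode (default 3).
#' @param ratio_threshold near/far ratio threshold (default 1.2).
#' @param alpha significance level of the group test (default 0.01).
#' @return object of class `classification_rule`.
#' @export
classification_rule <- function(mode = c("zscore", "ratio", "group_test"),
                                z_threshold = 3, ratio_threshold = 1.2,
                                alpha = 0.01) {
  mode <- match.arg(mode)
  stopifnot(z_threshold > 0, ratio_threshold > 0, alpha > 0, alpha < 1)
  structure(list(mode = mode, z_threshold = z_threshold,
                 ratio_threshold = ratio_threshold, alpha = alpha),
            class = "classification_rule")
}

#' Classify one vessel from its profile statistics
#'
#' Sides are averaged, not OR-ed: the two sides of a lumen are treated as
#' two measurements of the same vessel.  With no usable side the vessel is
#' undefined (`NA`) and must be excluded from positive-fraction
#' denominators.
#'
#' @param stats list of [profile_statistic()] objects for one vessel
#'   (sides, possibly across frames for `group_test`).
#' @param rule a [classification_rule()].
#' @return `TRUE`, `FALSE`, or `NA` (no usable side).
#' @export
classify_vessel <- function(stats, rule = classification_rule()) {
  stopifnot(inherits(rule, "classification_rule"))
  if (inherits(stats, "profile_statistic")) stats <- list(stats)
  if (length(stats) == 0) return(NA)
  switch(rule$mode,
    zscore = {
      z <- vapply(stats, `[[`, 0, "z_contrast")
      z <- z[!is.na(z)]
      if (length(z) == 0) return(NA)
      mean(z) >= rule$z_threshold
    },
    ratio = {
      mn <- mean(vapply(stats, `[[`, 0, "mean_near"))
      mf <- mean(vapply(stats, `[[`, 0, "mean_far"))
      ns <- vapply(stats, `[[`, 0, "noise_scale")
      ns <- if (all(is.na(ns))) 0 else mean(ns, na.rm = TRUE)
      denom <- max(mf, ns, .Machine$double.eps)
      mn / denom >= rule$ratio_threshold
    },
    group_test = {
      near <- vapply(stats, `[[`, 0, "mean_near")
      far <- vapply(stats, `[[`, 0, "mean_far")
      if (length(near) < 2) return(NA)
      d <- near - far
      if (stats::sd(d) == 0) return(d[1] > 0)
      stats::t.test(near, far, paired = TRUE,
                    alternative = "greater")$p.value < rule$alpha
    })
}

#' Colocalization of the two channels in an abluminal annulus
#'
#' Pearson correlation of red vs green over the set of pixels whose
#' distance from the vessel centre lies in `lumen_radius_um + annulus_um`
#' (the abluminal annulus grown from the measured lumen edge).  Mirrors
#' the colocalization reading of tracer-positive walls: tracer compacted
#' on the wall varies spatially with the lumen dye.
#'
#' @param frame an [image_frame()].
#' @param center_xy_um vessel centre, um.
#' @param lumen_radius_um measured lumen radius (e.g. half of
#'   [measure_diameter()]).
#' @param annulus_um length-2, annulus bounds outward of the lumen edge,
#'   um (default `c(0, 3)`, the near window).
#' @return Pearson correlation in `[-1, 1]`, or `NA` (with a `"reason"`
#'   attribute) when either channel has zero variance over the annulus.
#' @export
coloc_coefficient <- function(frame, center_xy_um, lumen_radius_um,
                              annulus_um = c(0, 3)) {
  stopifnot(inherits(frame, "image_frame"), length(annulus_um) == 2,
            lumen_radius_um > 0, diff(annulus_um) > 0)
  px <- frame$pixel_size_um
  cc_y <- pixel_centers_um(nrow(frame$green), px) - center_xy_um[2]
  cc_x <- pixel_centers_um(ncol(frame$green), px) - center_xy_um[1]
  r <- sqrt(outer(cc_y^2, cc_x^2, "+"))
  sel <- r > lumen_radius_um + annulus_um[1] &
    r <= lumen_radius_um + annulus_um[2]
  if (sum(sel) < 30)
    stop("annulus contains only ", sum(sel), " pixels (< 30)")
  g <- frame$green[sel]; rd <- frame$red[sel]
  if (stats::sd(g) == 0 || stats::sd(rd) == 0)
    return(structure(NA_real_, reason = "zero variance in a channel"))
  stats::cor(rd, g)
}

# Red-channel clarity check on an aligned side: a profile is "unclear"
# when the lumen dye rises again inside the analysis span (typically a
# neighbouring vessel crossed by the line), so the green windows would mix
# two vessels.  Checked beyond 1 um so the half-maximum shoulder of the
# own edge is not flagged.
side_is_unclear <- function(aligned_side, edges) {
  x <- aligned_side$abluminal_positions_um
  sel <- x > 1 & x <= FAR_UM
  if (!any(sel)) return(FALSE)
  thr <- if (aligned_side$side == "left") edges$threshold[1]
         else edges$threshold[2]
  any(aligned_side$red[sel] > thr)
}

#' Analyse all annotated vessels of one frame
#'
#' Runs the full per-frame pipeline: profile extraction along the
#' annotated cross line, lumen-edge detection, abluminal alignment,
#' near/far statistics per usable side, and per-vessel classification.
#' Vessels whose profile cannot be measured (line exits the field, no
#' lumen signal, open lumen, both sides truncated or unclear) are marked
#' excluded with a reason and enter neither numerator nor denominator of
#' positive fractions.
#'
#' @param frame an [image_frame()].
#' @param vessels annotation data frame (columns `id`, `x_um`, `y_um`,
#'   `angle_rad`; see [sample_vessels()]).
#' @param rule a [classification_rule()].
#' @param noise_scale optional known per-sample noise SD; estimated per
#'   side from the 15-25 um annulus when `NULL`.
#' @param length_um,step_um line geometry passed to [extract_profile()].
#' @return data frame with one row per vessel side (excluded vessels get
#'   one `side = NA` row): `vessel_id`, `frame_t`, `side`, `mean_near`,
#'   `mean_far`, `contrast`, `z_contrast`, `diameter_um`,
#'   `predicted_positive`, `excluded`, `exclude_reason`.
#' @export
analyze_frame <- function(frame, vessels, rule = classification_rule(),
                          noise_scale = NULL, length_um = 100,
                          step_um = 0.25) {
  rows <- list()
  emit <- function(id, side, st, diam, pred, excl, reason) {
    rows[[length(rows) + 1L]] <<- data.frame(
      vessel_id = id, frame_t = frame$t_min,
      side = if (is.null(side)) NA_character_ else side,
      mean_near = if (is.null(st)) NA_real_ else st$mean_near,
      mean_far = if (is.null(st)) NA_real_ else st$mean_far,
      contrast = if (is.null(st)) NA_real_ else st$contrast,
      z_contrast = if (is.null(st)) NA_real_ else st$z_contrast,
      diameter_um = diam,
      predicted_positive = pred,
      excluded = excl,
      exclude_reason = reason)
  }
  for (k in seq_len(nrow(vessels))) {
    id <- vessels$id[k]
    res <- tryCatch({
      prof <- extract_profile(frame, c(vessels$x_um[k], vessels$y_um[k]),
                              vessels$angle_rad[k], length_um = length_um,
                              step_um = step_um, vessel_id = id)
      edges <- locate_lumen_edges(prof)
      aligned <- align_abluminal(prof, edges)
      diam <- edges$right_edge_um - edges$left_edge_um
      stats_list <- list()
      reasons <- character(0)
      for (side in aligned) {
        if (!side$usable) { reasons <- c(reasons, side$reason); next }
        if (side_is_unclear(side, edges)) {
          reasons <- c(reasons, "unclear profile"); next
        }
        stats_list[[length(stats_list) + 1L]] <-
          profile_statistic(side, noise_scale = noise_scale)
      }
      if (length(stats_list) == 0) {
        emit(id, NULL, NULL, diam, NA, TRUE,
             paste(unique(reasons), collapse = "; "))
      } else {
        pred <- classify_vessel(stats_list, rule)
        for (st in stats_list) emit(id, st$side, st, diam, pred, FALSE,
                                    NA_character_)
      }
      TRUE
    }, error = function(e) e)
    if (inherits(res, "error"))
      emit(id, NULL, NULL, NA_real_, NA, TRUE, conditionMessage(res))
  }
  if (length(rows) == 0)
    return(data.frame(vessel_id = integer(0), frame_t = numeric(0),
                      side = character(0), mean_near = numeric(0),
                      mean_far = numeric(0), contrast = numeric(0),
                      z_contrast = numeric(0), diameter_um = numeric(0),
                      predicted_positive = logical(0), excluded = logical(0),
                      exclude_reason = character(0)))
  do.call(rbind, rows)
}

#' Collapse side-level results to one row per vessel
#'
#' @param side_df result of [analyze_frame()].
#' @return data frame with one row per vessel: `vessel_id`, `frame_t`,
#'   `diameter_um`, `n_sides_used`, `predicted_positive`, `excluded`,
#'   `exclude_reason`.
#' @export
vessel_calls <- function(side_df) {
  ids <- unique(side_df$vessel_id)
  do.call(rbind, lapply(ids, function(id) {
    v <- side_df[side_df$vessel_id == id, , drop = FALSE]
    data.frame(vessel_id = id, frame_t = v$frame_t[1],
               diameter_um = v$diameter_um[1],
               n_sides_used = sum(!is.na(v$side)),
               predicted_positive = v$predicted_positive[1],
               excluded = v$excluded[1],
               exclude_reason = v$exclude_reason[1])
  }))
}
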