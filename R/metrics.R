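#' Lumen diameter of a vessel profile (FWHM convention)
#'
#' The distance between the two half-maximum crossings of the lumen-dye
#' channel, i.e. the full width at half maximum of the lumen.
#'
#' @param profile a [extract_profile()] result.
#' @param threshold_frac crossing fraction, see [locate_lumen_edges()].
#' @return diameter in um.
#' @export
measure_diameter <- function(profile, threshold_frac = 0.5) {
  e <- locate_lumen_edges(profile, threshold_frac)
  e$right_edge_um - e$left_edge_um
}

#' Percentage of tracer-positive vessels
#'
#' `100 * n_positive / n_usable`; vessels with undefined classification
#' (`NA`) are excluded from both numerator and denominator.  With no
#' usable vessel the fraction is undefined (`NA`) and a warning is
#' raised.
#'
#' @param predicted logical vector of per-vessel calls (`NA` = excluded).
#' @return percentage in `[0, 100]`, or `NA`.
#' @export
positive_fraction <- function(predicted) {
  usable <- !is.na(predicted)
  if (!any(usable)) {
    warning("no usable vessels: positive fraction undefined")
    return(NA_real_)
  }
  100 * sum(predicted[usable]) / sum(usable)
}

#' Per-frame summary of vessel calls
#'
#' @param calls vessel-level data frame (see [vessel_calls()]) for one
#'   frame, with `predicted_positive` and `diameter_um`.
#' @param t_min frame time; defaults to the `frame_t` of the calls.
#' @return one-row data frame: `t_min`, `n_vessels_usable`, `n_positive`,
#'   `positive_fraction_pct`, `mean_diam_pos_um`, `mean_diam_neg_um`.
#' @export
frame_summary <- function(calls, t_min = NULL) {
  usable <- !is.na(calls$predicted_positive)
  pos <- usable & calls$predicted_positive
  neg <- usable & !calls$predicted_positive
  data.frame(
    t_min = t_min %||% calls$frame_t[1],
    n_vessels_usable = sum(usable),
    n_positive = sum(pos),
    positive_fraction_pct = if (any(usable))
      100 * sum(pos) / sum(usable) else NA_real_,
    mean_diam_pos_um = if (any(pos)) mean(calls$diameter_um[pos])
                       else NA_real_,
    mean_diam_neg_um = if (any(neg)) mean(calls$diameter_um[neg])
                       else NA_real_)
}

#' Time course of the positive-vessel fraction
#'
#' Orders per-frame summaries by time and, when at least three frames are
#' present, reports a descriptive rise/plateau/decay segmentation: the
#' time of the maximum fraction and the first/last frames at or above 90%
#' of the maximum (the plateau).
#'
#' @param frame_summaries data frame of [frame_summary()] rows.
#' @return the time-ordered data frame, with attribute `"segmentation"`
#'   (list `t_peak`, `plateau_start`, `plateau_end`, `plateau_times`) when
#'   computable.
#' @export
time_course <- function(frame_summaries) {
  ts <- frame_summaries[order(frame_summaries$t_min), , drop = FALSE]
  rownames(ts) <- NULL
  if (nrow(ts) >= 3 && any(is.finite(ts$positive_fraction_pct))) {
    f <- ts$positive_fraction_pct
    peak <- max(f, na.rm = TRUE)
    if (peak > 0) {
      on <- which(!is.na(f) & f >= 0.9 * peak)
      attr(ts, "segmentation") <- list(
        t_peak = ts$t_min[which.max(f)],
        plateau_start = ts$t_min[min(on)],
        plateau_end = ts$t_min[max(on)],
        plateau_times = ts$t_min[on])
    }
  }
  ts
}

#' Positive fractions stratified by distance to the injection source
#'
#' Bins vessels by centre-to-source distance (default 20-um bins up to
#' 360 um, then open-ended) and reports per-bin usable counts and
#' positive fractions; bins with fewer than 3 usable vessels are flagged
#' low-n.
#'
#' @param calls vessel-level data frame with `predicted_positive` and
#'   `distance_to_source_um`.
#' @param bin_edges_um increasing bin edges; default
#'   `c(0, 20, 40, ..., 360, Inf)`.
#' @return data frame: `bin_lo_um`, `bin_hi_um`, `n_usable`, `n_positive`,
#'   `positive_fraction_pct`, `low_n`.
#' @export
distance_strata <- function(calls,
                            bin_edges_um = c(seq(0, 360, by = 20), Inf)) {
  stopifnot(all(diff(bin_edges_um) > 0))
  idx <- findInterval(calls$distance_to_source_um, bin_edges_um,
                      rightmost.closed = FALSE)
  nb <- length(bin_edges_um) - 1L
  out <- do.call(rbind, lapply(seq_len(nb), function(b) {
    sel <- idx == b & !is.na(calls$predicted_positive)
    n <- sum(sel)
    data.frame(bin_lo_um = bin_edges_um[b], bin_hi_um = bin_edges_um[b + 1L],
               n_usable = n,
               n_positive = sum(calls$predicted_positive[sel]),
               positive_fraction_pct = if (n > 0)
                 100 * sum(calls$predicted_positive[sel]) / n else NA_real_,
               low_n = n < 3)
  }))
  out
}

#' Per-animal summary
#'
#' Averages per-frame summaries to one row per animal.  The animal is the
#' statistical unit of the design: data are averaged first per animal,
#' then per treatment group, and group tests run on animal means.
#'
#' @param animal_id animal identifier.
#' @param group `"control"` or `"treated"`.
#' @param volume_class `"small"` or `"large"` injected volume.
#' @param frame_summaries data frame of [frame_summary()] rows for the
#'   animal.
#' @return one-row data frame with the animal-mean positive fraction and
#'   diameters.
#' @export
animal_summary <- function(animal_id, group, volume_class,
                           frame_summaries) {
  data.frame(
    animal_id = animal_id, group = group, volume_class = volume_class,
    mean_positive_fraction_pct =
      mean(frame_summaries$positive_fraction_pct, na.rm = TRUE),
    mean_diam_pos_um = mean(frame_summaries$mean_diam_pos_um, na.rm = TRUE),
    mean_diam_neg_um = mean(frame_summaries$mean_diam_neg_um, na.rm = TRUE),
    n_frames = nrow(frame_summaries))
}

#' Group means from animal summaries
#'
#' The default aggregation path: group statistics are computed from
#' animal means (never from vessels pooled across animals; pooling is
#' available via [positive_fraction()] on a pooled call table but is not
#' the default because it weights animals by their vessel counts).
#'
#' @param animal_summaries data frame of [animal_summary()] rows.
#' @param value column to summarise (default the positive fraction).
#' @return data frame per group: n animals, mean, SD, formatted
#'   `mean ± SD`.
#' @export
group_summary <- function(animal_summaries,
                          value = "mean_positive_fraction_pct") {
  sp <- split(animal_summaries[[value]], animal_summaries$group)
  do.call(rbind, lapply(names(sp), function(gr)
    data.frame(group = gr, n_animals = length(sp[[gr]]),
               mean = mean(sp[[gr]]), sd = stats::sd(sp[[gr]]),
               formatted = format_mean_sd(sp[[gr]]))))
}

#' Plot a positive-fraction time course
#'
#' @param tc result of [time_course()] (or a list of them, drawn as
#'   multiple lines).
#' @param labels optional legend labels when `tc` is a list.
#' @param ... passed to [graphics::plot()].
#' @export
plot_time_course <- function(tc, labels = NULL, ...) {
  tcs <- if (is.data.frame(tc)) list(tc) else tc
  xr <- range(unlist(lapply(tcs, `[[`, "t_min")))
  yr <- c(0, max(unlist(lapply(tcs, `[[`, "positive_fraction_pct")),
                 na.rm = TRUE) * 1.1)
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "time (min)",
                 ylab = "tracer-positive vessels (%)", ...)
  for (i in seq_along(tcs))
    graphics::lines(tcs[[i]]$t_min, tcs[[i]]$positive_fraction_pct,
                    type = "b", pch = 19, col = i, lty = i)
  if (!is.null(labels))
    graphics::legend("topright", legend = labels,
                     col = seq_along(tcs), lty = seq_along(tcs), pch = 19)
  invisible(NULL)
}

#' Plot an edge-aligned profile pair
#'
#' Red and green intensity against abluminal distance, with the near/far
#' analysis windows shaded -- the per-vessel audit view.
#'
#' @param aligned result of [align_abluminal()] (list with `left`,
#'   `right`).
#' @param ... passed to [graphics::plot()].
#' @export
plot_profile <- function(aligned, ...) {
  sides <- Filter(function(s) isTRUE(s$usable), aligned)
  if (length(sides) == 0) stop("no usable side to plot")
  xr <- c(0, max(vapply(sides, function(s)
    max(s$abluminal_positions_um), 0)))
  yr <- range(unlist(lapply(sides, function(s) c(s$green, s$red))))
  graphics::plot(NA, xlim = xr, ylim = yr,
                 xlab = "abluminal distance (um)", ylab = "intensity", ...)
  graphics::rect(0, yr[1], NEAR_UM, yr[2],
                 col = grDevices::adjustcolor("green", 0.10), border = NA)
  graphics::rect(NEAR_UM, yr[1], FAR_UM, yr[2],
                 col = grDevices::adjustcolor("grey", 0.15), border = NA)
  for (i in seq_along(sides)) {
    s <- sides[[i]]
    graphics::lines(s$abluminal_positions_um, s$green, col = "darkgreen",
                    lty = i)
    graphics::lines(s$abluminal_positions_um, s$red, col = "red", lty = i)
  }
  invisible(NULL)
}
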