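# Label codes of vessel-wall masks (electron-microscopy section analog).
WALL_CODES <- c(background = 0L, lumen = 1L, endothelium = 2L,
                intramural = 3L, basement = 4L)

# Flood fill: TRUE iff all TRUE pixels of `m` form one 4-connected
# component.  Vectorised frontier expansion; O(diameter) iterations.
single_component <- function(m) {
  if (!any(m)) return(FALSE)
  visited <- matrix(FALSE, nrow(m), ncol(m))
  start <- which(m)[1]
  visited[start] <- TRUE
  frontier <- visited
  repeat {
    nb <- matrix(FALSE, nrow(m), ncol(m))
    nb[-1, ] <- nb[-1, ] | frontier[-nrow(m), ]
    nb[-nrow(m), ] <- nb[-nrow(m), ] | frontier[-1, ]
    nb[, -1] <- nb[, -1] | frontier[, -ncol(m)]
    nb[, -ncol(m)] <- nb[, -ncol(m)] | frontier[, -1]
    frontier <- nb & m & !visited
    if (!any(frontier)) break
    visited <- visited | frontier
  }
  all(visited[m])
}

# TRUE iff some pixel of `a` is 4-adjacent to a pixel of `b`.
adjacent_classes <- function(a, b) {
  any(a[-1, ] & b[-nrow(a), ]) || any(a[-nrow(a), ] & b[-1, ]) ||
    any(a[, -1] & b[, -ncol(a)]) || any(a[, -ncol(a)] & b[, -1])
}

#' Construct and validate a vessel-wall mask
#'
#' A labelled 2-D section of one vessel with integer codes 0 background,
#' 1 lumen, 2 endothelium, 3 intramural cell, 4 basement membrane.
#' Validation enforces the mask topology assumed by the morphometry:
#' exactly one 4-connected lumen component, and a wall (classes 2-4) that
#' completely separates the lumen from the background.
#'
#' @param labels integer matrix with codes 0-4.
#' @param pixel_size_um pixel size, um.
#' @return object of class `wall_mask`.
#' @export
wall_mask <- function(labels, pixel_size_um) {
  stopifnot(is.matrix(labels), pixel_size_um > 0)
  if (!all(labels %in% WALL_CODES))
    stop("labels must use codes 0 (background), 1 (lumen), 2 (endothelium), ",
         "3 (intramural cell), 4 (basement membrane)")
  lum <- labels == 1L
  if (!any(lum)) stop("mask contains no lumen (code 1)")
  if (!single_component(lum))
    stop("mask must contain exactly one connected lumen component")
  if (adjacent_classes(lum, labels == 0L))
    stop("lumen touches the background: wall ring (codes 2-4) is not closed")
  if (!any(labels %in% 2:4)) stop("mask contains no wall pixels (codes 2-4)")
  structure(list(labels = labels, pixel_size_um = as.numeric(pixel_size_um)),
            class = "wall_mask")
}

#' Wall-composition area fractions
#'
#' Percentage of the wall area (classes 2-4) occupied by the endothelium,
#' intramural cells and basement membrane, from pixel counts; the three
#' percentages sum to 100 up to floating-point rounding.
#'
#' @param mask a [wall_mask()].
#' @return object of class `composition_result`: `pct_endothelium`,
#'   `pct_intramural`, `pct_basement`, plus the raw pixel `counts`.
#' @export
wall_composition <- function(mask) {
  stopifnot(inherits(mask, "wall_mask"))
  counts <- c(endothelium = sum(mask$labels == 2L),
              intramural = sum(mask$labels == 3L),
              basement = sum(mask$labels == 4L))
  total <- sum(counts)
  if (total == 0) stop("zero wall area")
  structure(list(pct_endothelium = 100 * counts[["endothelium"]] / total,
                 pct_intramural = 100 * counts[["intramural"]] / total,
                 pct_basement = 100 * counts[["basement"]] / total,
                 counts = counts),
            class = "composition_result")
}

#' @export
print.composition_result <- function(x, ...) {
  cat(sprintf(
    "wall composition: endothelium %.2f%%, intramural cells %.2f%%, basement membrane %.2f%%\n",
    x$pct_endothelium, x$pct_intramural, x$pct_basement))
  invisible(x)
}

#' Abluminal basement-membrane thickness (thickest region)
#'
#' Casts `n_rays` rays from the lumen centroid and measures, per ray, the
#' radial run length of basement-membrane pixels (code 4) lying outward
#' of endothelium/intramural pixels (codes 2-3); only abluminal membrane
#' counts, i.e. the run must reach the background (or the image border).
#' The result is the maximum over rays -- the thickness at the thickest
#' region.  Rays that never cross an abluminal membrane are skipped; if
#' no ray qualifies the measurement is undefined (`NA` with a `"reason"`
#' attribute), mirroring exclusion of vessels with no measurable
#' abluminal membrane.
#'
#' @param mask a [wall_mask()].
#' @param n_rays number of rays (default 360, i.e. 1 degree resolution).
#' @return thickness in um, or flagged `NA`.
#' @export
bm_thickness <- function(mask, n_rays = 360) {
  stopifnot(inherits(mask, "wall_mask"), n_rays >= 4)
  lab <- mask$labels
  px <- mask$pixel_size_um
  lum_idx <- which(lab == 1L, arr.ind = TRUE)
  cy <- mean(lum_idx[, 1] - 0.5) * px
  cx <- mean(lum_idx[, 2] - 0.5) * px
  step <- px / 4
  max_r <- sqrt((nrow(lab) * px)^2 + (ncol(lab) * px)^2)
  rr <- seq(step, max_r, by = step)
  angles <- (seq_len(n_rays) - 1) * 2 * pi / n_rays
  best <- NA_real_
  for (th in angles) {
    xs <- cx + rr * cos(th)
    ys <- cy + rr * sin(th)
    ii <- floor(ys / px) + 1L
    jj <- floor(xs / px) + 1L
    inside <- ii >= 1L & ii <= nrow(lab) & jj >= 1L & jj <= ncol(lab)
    codes <- integer(length(rr))              # outside counts as background
    codes[inside] <- lab[cbind(ii[inside], jj[inside])]
    runs <- rle(codes)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    wall_end <- max(c(0L, ends[runs$values %in% 2:3]))
    if (wall_end == 0L) next                  # no endothelium/intramural on ray
    for (q in which(runs$values == 4L)) {
      if (starts[q] <= wall_end) next         # membrane not outward of wall
      after <- if (q < length(runs$values)) runs$values[q + 1L] else 0L
      if (after != 0L) next                   # not abluminal (no background beyond)
      thick <- runs$lengths[q] * step
      if (is.na(best) || thick > best) best <- thick
      break                                   # first abluminal run on this ray
    }
  }
  if (is.na(best))
    return(structure(NA_real_,
                     reason = "no abluminal basement membrane on any ray"))
  best
}

#' Pearson correlation of vessel diameter and wall thickness
#'
#' Reports the correlation in the `r(df) = r, P = p` convention with
#' `df = n - 2` and the two-sided p-value from the exact t transform.
#'
#' @param diameter_um,thickness_um paired numeric vectors, n >= 3.
#' @return object of class `dt_correlation`: `r`, `df`, `p_value`, `n`.
#' @export
diameter_thickness_correlation <- function(diameter_um, thickness_um) {
  ok <- is.finite(diameter_um) & is.finite(thickness_um)
  d <- diameter_um[ok]; w <- thickness_um[ok]
  if (length(d) < 3) stop("need at least 3 finite pairs")
  if (stats::sd(d) == 0 || stats::sd(w) == 0)
    return(structure(list(r = NA_real_, df = length(d) - 2L,
                          p_value = NA_real_, n = length(d),
                          reason = "zero variance"),
                     class = "dt_correlation"))
  ct <- stats::cor.test(d, w, method = "pearson")
  structure(list(r = unname(ct$estimate), df = unname(ct$parameter),
                 p_value = ct$p.value, n = length(d)),
            class = "dt_correlation")
}

#' @export
print.dt_correlation <- function(x, ...) {
  if (is.na(x$r)) cat("diameter-thickness correlation undefined (",
                      x$reason, ")\n", sep = "")
  else cat(sprintf("r(%d) = %.3f, P = %.4g %s\n", x$df, x$r, x$p_value,
                   p_stars(x$p_value)))
  invisible(x)
}

#' Parameterised synthetic wall mask
#'
#' Builds a concentric-annulus vessel section: lumen disk, endothelium,
#' intramural-cell and basement-membrane rings, background beyond.  An
#' optional angular sector can carry a thicker membrane (to exercise the
#' "thickest region" semantics), and the membrane can be made internal
#' (buried under an extra intramural ring) to exercise the
#' abluminal-only rule.
#'
#' @param image_px mask side in pixels.
#' @param pixel_size_um pixel size (default 0.05 um, an EM-like scale).
#' @param lumen_radius_um,endo_um,intramural_um,bm_um radial extents:
#'   lumen radius and the widths of the three wall rings.
#' @param thick_sector optional list `(from, to, factor)`: angles in
#'   radians within which the membrane width is multiplied by `factor`.
#' @param internal_bm if `TRUE`, an intramural ring of width `bm_um` is
#'   added outside the membrane, making the membrane non-abluminal.
#' @param center_um optional centre (default: mask centre).
#' @return a [wall_mask()].
#' @export
synthetic_wall_mask <- function(image_px = 256, pixel_size_um = 0.05,
                                lumen_radius_um = 3, endo_um = 0.6,
                                intramural_um = 0.4, bm_um = 0.5,
                                thick_sector = NULL, internal_bm = FALSE,
                                center_um = NULL) {
  cc <- pixel_centers_um(image_px, pixel_size_um)
  ctr <- center_um %||% rep(image_px * pixel_size_um / 2, 2)
  dy <- cc - ctr[2]; dx <- cc - ctr[1]
  r <- sqrt(outer(dy^2, dx^2, "+"))
  theta <- atan2(matrix(dy, image_px, image_px),
                 matrix(dx, image_px, image_px, byrow = TRUE)) %% (2 * pi)
  r1 <- lumen_radius_um
  r2 <- r1 + endo_um
  r3 <- r2 + intramural_um
  bm_w <- matrix(bm_um, image_px, image_px)
  if (!is.null(thick_sector))
    bm_w[theta >= thick_sector$from & theta <= thick_sector$to] <-
      bm_um * thick_sector$factor
  r4 <- r3 + bm_w
  lab <- matrix(0L, image_px, image_px)
  lab[r <= r4] <- 4L
  lab[r <= r3] <- 3L
  lab[r <= r2] <- 2L
  lab[r <= r1] <- 1L
  if (internal_bm) lab[lab == 0L & r <= r4 + bm_um] <- 3L
  wall_mask(lab, pixel_size_um)
}

#' Write a wall mask as an 8-bit single-channel image
#'
#' Label codes are stored directly as 8-bit grey values (TIFF or PNG by
#' file extension).
#'
#' @param mask a [wall_mask()].
#' @param path output path ending in `.tif`/`.tiff` or `.png`.
#' @export
write_wall_mask <- function(mask, path) {
  stopifnot(inherits(mask, "wall_mask"))
  img <- mask$labels / 255
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::writeTIFF(img, path, bits.per.sample = 8L, reduce = FALSE)
  else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the png package is required to write PNG masks")
    png::writePNG(img, path)
  } else stop("unsupported mask format: ", path)
  invisible(path)
}

#' Read a wall mask written by [write_wall_mask()]
#'
#' @param path mask image path.
#' @param pixel_size_um pixel size, um.
#' @return a [wall_mask()].
#' @export
read_wall_mask <- function(path, pixel_size_um) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path)
  else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the png package is required to read PNG masks")
    png::readPNG(path)
  } else stop("unsupported mask format: ", path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  wall_mask(matrix(as.integer(round(img * 255)), nrow(img), ncol(img)),
            pixel_size_um)
}
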