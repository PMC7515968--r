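# Internal unit and sampling helpers.  All user-facing coordinates are in
# micrometres: origin at the top-left corner of the field, x rightwards
# (matrix columns), y downwards (matrix rows).  The centre of pixel
# (row i, col j), 1-based, sits at ((j - 0.5) * px, (i - 0.5) * px).

# Gaussian edge smoothing applied to the rendered lumen dye, in um.
# This is the lateral blur of the simulated optics; the half-maximum
# crossing of the smoothed disk stays exactly at the true lumen radius.
EDGE_SIGMA_UM <- 0.5

pixel_size_um <- function(config) config$field_size_um / config$image_px

# Pixel-centre coordinates (um) for an n-pixel axis.
pixel_centers_um <- function(n, px_um) (seq_len(n) - 0.5) * px_um

#' Bilinear sub-pixel sampling of an image
#'
#' Samples an intensity image at arbitrary continuous positions by bilinear
#' interpolation between the four surrounding pixel centres.  Positions are
#' in micrometres in the field coordinate system; at the field border the
#' edge pixel row/column is extended (constant extrapolation over at most
#' half a pixel).
#'
#' @param img numeric matrix, rows = y, cols = x.
#' @param x_um,y_um numeric vectors of equal length, positions in um.
#' @param px_um pixel size in um.
#' @return numeric vector of interpolated intensities.
#' @keywords internal
bilinear_sample <- function(img, x_um, y_um, px_um) {
  nr <- nrow(img); nc <- ncol(img)
  fx <- x_um / px_um - 0.5          # 0-based continuous column index
  fy <- y_um / px_um - 0.5
  jx <- pmin(pmax(floor(fx), 0), nc - 2L)
  iy <- pmin(pmax(floor(fy), 0), nr - 2L)
  dx <- pmin(pmax(fx - jx, 0), 1)
  dy <- pmin(pmax(fy - iy, 0), 1)
  i1 <- iy + 1L; j1 <- jx + 1L
  img[cbind(i1, j1)]           * (1 - dx) * (1 - dy) +
    img[cbind(i1, j1 + 1L)]    * dx       * (1 - dy) +
    img[cbind(i1 + 1L, j1)]    * (1 - dx) * dy +
    img[cbind(i1 + 1L, j1 + 1L)] * dx     * dy
}

# Run code with a temporary RNG state seeded from `seed`; the caller's
# .Random.seed is restored afterwards so package randomness never leaks
# into (or depends on) the session RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

# Derive a 31-bit sub-seed from a base seed and a stream index; exact in
# double arithmetic, keeps every derived seed inside the integer range.
mix_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) * 2654435761 + as.numeric(k) * 40503 + 1) %%
               2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
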