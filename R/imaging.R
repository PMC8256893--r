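#' Rasterize a resistance vector onto the (s-1) x (s-1) cell grid
#'
#' Each raster cell (k, j) -- the unit square with node N\[k,j\] at its
#' top-left corner -- takes the arithmetic mean of its four bounding
#' resistors: horizontal z_h\[k,j\] and z_h\[k+1,j\], vertical z_v\[k,j\] and
#' z_v\[k,j+1\]. Symmetric and orientation-agnostic; no claim is made of
#' reproducing any particular figure's interpolation.
#'
#' @param z Canonical resistance vector of length `2*(s^2-s)`, or an
#'   `eit_grid`.
#' @param s Grid side (ignored when `z` is an `eit_grid`).
#' @return Numeric `(s-1) x (s-1)` matrix of cell resistances (ohms); rows
#'   index k (top to bottom), columns j (left to right).
#' @export
rasterize <- function(z, s) {
  if (inherits(z, "eit_grid")) {
    s <- z$s
    grid <- z
  } else {
    s <- check_grid_side(s)
    if (length(z) != num_resistors(s)) {
      stop("'z' must have length 2*(s^2-s) = ", num_resistors(s), call. = FALSE)
    }
    grid <- grid_from_vector(z, s)
  }
  kk <- seq_len(s - 1L)
  jj <- seq_len(s - 1L)
  (grid$z_h[kk, jj, drop = FALSE] + grid$z_h[kk + 1L, jj, drop = FALSE] +
    grid$z_v[kk, jj, drop = FALSE] + grid$z_v[kk, jj + 1L, drop = FALSE]) / 4
}

#' Normalize a pixel array to [0, 1]
#'
#' Applies (x - min) / (max - min) so that tomograms share a consistent
#' color contrast: the minimum maps to 0 and the maximum to 1 whenever the
#' input is non-constant. A constant array maps to all zeros (degenerate
#' convention). Invariant under positive affine transforms of the input.
#'
#' @param pixels Finite numeric matrix (pre-normalization resistances).
#' @param extent_mm Physical side length represented by the raster.
#' @param colormap_label Free-text label stored with the image.
#' @return An object of class `eit_tomogram`: list with `pixels` in [0, 1],
#'   `extent_mm`, `colormap_label`.
#' @export
normalize01 <- function(pixels, extent_mm = 130, colormap_label = "gray") {
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels))) {
    stop("'pixels' must be finite", call. = FALSE)
  }
  rng <- range(pixels)
  px <- if (rng[1] == rng[2]) {
    matrix(0, nrow(pixels), ncol(pixels))
  } else {
    (pixels - rng[1]) / (rng[2] - rng[1])
  }
  structure(list(pixels = px, extent_mm = extent_mm,
                 colormap_label = colormap_label),
            class = "eit_tomogram")
}

#' Normalized tomogram of a mesh or reconstruction
#'
#' Rasterizes the resistance distribution and rescales it to [0, 1].
#'
#' @param x An `eit_grid`, `eit_recon`, or canonical resistance vector.
#' @param ... Further arguments: `s` when `x` is a bare vector;
#'   `colormap_label` passed to [normalize01()].
#' @return An `eit_tomogram`.
#' @export
tomogram <- function(x, ...) UseMethod("tomogram")

#' @export
tomogram.eit_grid <- function(x, colormap_label = "gray", ...) {
  normalize01(rasterize(x), x$extent_mm, colormap_label)
}

#' @export
tomogram.eit_recon <- function(x, ...) tomogram(x$grid, ...)

#' @export
tomogram.numeric <- function(x, s, extent_mm = 130, colormap_label = "gray", ...) {
  normalize01(rasterize(x, s), extent_mm, colormap_label)
}

#' @export
print.eit_tomogram <- function(x, ...) {
  cat("EIT tomogram:", nrow(x$pixels), "x", ncol(x$pixels),
      "pixels in [0,1],", x$extent_mm, "mm extent\n")
  invisible(x)
}

#' Display a tomogram
#'
#' Renders the normalized resistance map with `graphics::image()`, axes in
#' template millimetres, the y axis pointing down the template rows as on
#' the physical device.
#'
#' @param x An `eit_tomogram`.
#' @param col Color palette; default 256-level grayscale (dark = low
#'   resistance).
#' @param main Plot title.
#' @param ... Passed to `graphics::image()`.
#' @export
plot.eit_tomogram <- function(x, col = grDevices::gray.colors(256, 0, 1),
                              main = "Normalized resistance", ...) {
  n <- nrow(x$pixels)
  ctr <- (seq_len(n) - 0.5) * x$extent_mm / n
  # image() draws z[i,j] at x[i], y[j]: transpose so rows become y, and flip
  # y so row 1 is at the top
  graphics::image(ctr, ctr, t(x$pixels[n:1, , drop = FALSE]),
                  zlim = c(0, 1), col = col, asp = 1,
                  xlab = "x (mm)", ylab = "y (mm)", main = main,
                  yaxt = "n", ...)
  at <- pretty(c(0, x$extent_mm))
  graphics::axis(2, at = at, labels = rev(at))
  invisible(x)
}

#' Physical centroid of the extreme-resistance region
#'
#' Localizes an inclusion in a raster: selects the cells whose value lies in
#' the lowest (direction = "min") or highest ("max") tenth of the value
#' range and returns the mean of their physical cell-centre coordinates.
#' Used to compare a reconstruction against the known phantom geometry.
#'
#' @param x An `eit_grid`, `eit_recon`, `eit_tomogram`, or raster matrix.
#' @param direction "min" for conductive inclusions, "max" for resistive.
#' @param frac Fraction of the value range defining the region (default 0.1).
#' @param extent_mm Physical extent when `x` is a bare matrix.
#' @return Named numeric vector `c(x_mm, y_mm)`.
#' @export
peak_region_centroid <- function(x, direction = c("min", "max"), frac = 0.1,
                                 extent_mm = 130) {
  direction <- match.arg(direction)
  if (inherits(x, "eit_recon")) x <- x$grid
  if (inherits(x, "eit_grid")) {
    extent_mm <- x$extent_mm
    x <- rasterize(x)
  } else if (inherits(x, "eit_tomogram")) {
    extent_mm <- x$extent_mm
    x <- x$pixels
  }
  x <- as.matrix(x)
  rng <- range(x)
  sel <- if (direction == "min") {
    x <= rng[1] + frac * diff(rng)
  } else {
    x >= rng[2] - frac * diff(rng)
  }
  n <- nrow(x)
  h <- extent_mm / n
  idx <- which(sel, arr.ind = TRUE)
  c(x_mm = mean((idx[, "col"] - 0.5) * h),
    y_mm = mean((idx[, "row"] - 0.5) * h))
}
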