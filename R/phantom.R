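#' Describe a synthetic phantom
#'
#' A phantom is a uniform background medium with zero or more inclusions of
#' contrasting resistance, emulating bench scenarios such as an aluminum
#' cylinder in saline or a meat sample cast in gelatin. Inclusions later in
#' the list override earlier ones where they overlap.
#'
#' @param s Grid side (default 26, the standard template mesh).
#' @param background_ohms Background resistance in ohms.
#' @param inclusions List of inclusions from [circle_inclusion()] /
#'   [rect_inclusion()].
#' @param extent_mm Physical side length in millimetres.
#' @return An object of class `phantom_spec`.
#' @examples
#' ps <- phantom_spec(26, 5,
#'   list(circle_inclusion(c(65, 65), 19, 0.001)))
#' g <- generate_phantom(ps)
#' @export
phantom_spec <- function(s = 26L, background_ohms = 5,
                         inclusions = list(), extent_mm = 130) {
  s <- check_grid_side(s)
  if (!is.finite(background_ohms) || background_ohms <= 0) {
    stop("'background_ohms' must be positive", call. = FALSE)
  }
  for (inc in inclusions) {
    if (!inherits(inc, "eit_inclusion")) {
      stop("each inclusion must come from circle_inclusion() or rect_inclusion()",
           call. = FALSE)
    }
    if (!inclusion_within(inc, extent_mm)) {
      stop("inclusion geometry extends outside the template extent", call. = FALSE)
    }
  }
  structure(list(s = s, background_ohms = background_ohms,
                 inclusions = inclusions, extent_mm = extent_mm),
            class = "phantom_spec")
}

#' Circular inclusion for a phantom
#'
#' @param center_mm Numeric length-2: (x, y) centre in template millimetres.
#' @param radius_mm Radius in millimetres.
#' @param ohms Inclusion resistance in ohms. Conductive metal objects are
#'   modelled as a small positive resistance (e.g. 1e-3), never zero, so the
#'   conductance 1/z stays finite.
#' @return An `eit_inclusion`.
#' @export
circle_inclusion <- function(center_mm, radius_mm, ohms) {
  stopifnot(length(center_mm) == 2L, radius_mm > 0, is.finite(ohms), ohms > 0)
  structure(list(shape = "circle", center = as.numeric(center_mm),
                 radius = as.numeric(radius_mm), ohms = as.numeric(ohms)),
            class = "eit_inclusion")
}

#' Rectangular inclusion for a phantom
#'
#' @param center_mm Numeric length-2: (x, y) centre in template millimetres.
#' @param half_extents_mm Numeric length-2: half-width and half-height in mm.
#' @param ohms Inclusion resistance in ohms (> 0).
#' @return An `eit_inclusion`.
#' @export
rect_inclusion <- function(center_mm, half_extents_mm, ohms) {
  stopifnot(length(center_mm) == 2L, length(half_extents_mm) == 2L,
            all(half_extents_mm > 0), is.finite(ohms), ohms > 0)
  structure(list(shape = "rectangle", center = as.numeric(center_mm),
                 half_extents = as.numeric(half_extents_mm),
                 ohms = as.numeric(ohms)),
            class = "eit_inclusion")
}

inclusion_within <- function(inc, extent_mm) {
  if (inc$shape == "circle") {
    all(inc$center - inc$radius >= 0) && all(inc$center + inc$radius <= extent_mm)
  } else {
    all(inc$center - inc$half_extents >= 0) &&
      all(inc$center + inc$half_extents <= extent_mm)
  }
}

point_in_inclusion <- function(x, y, inc) {
  if (inc$shape == "circle") {
    (x - inc$center[1])^2 + (y - inc$center[2])^2 <= inc$radius^2
  } else {
    abs(x - inc$center[1]) <= inc$half_extents[1] &
      abs(y - inc$center[2]) <= inc$half_extents[2]
  }
}

#' Generate a resistor mesh from a phantom description
#'
#' Every resistor whose physical midpoint falls inside an inclusion takes the
#' inclusion resistance; all others take the background. Later inclusions
#' override earlier ones. The construction is fully deterministic.
#'
#' @param spec A [phantom_spec()].
#' @return An `eit_grid`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  tmpl <- resistor_table(eit_grid(spec$s, 1, 1, spec$extent_mm))
  z <- rep(spec$background_ohms, nrow(tmpl))
  for (inc in spec$inclusions) {
    inside <- point_in_inclusion(tmpl$x_mm, tmpl$y_mm, inc)
    z[inside] <- inc$ohms
  }
  grid_from_vector(z, spec$s, spec$extent_mm)
}

#' Does a point lie inside any inclusion of a phantom?
#'
#' Used by tests and by the localization summary to define the true
#' inclusion support.
#'
#' @param spec A [phantom_spec()].
#' @param x_mm,y_mm Coordinates in template millimetres (vectorised).
#' @return Logical vector.
#' @export
in_inclusion <- function(spec, x_mm, y_mm) {
  stopifnot(inherits(spec, "phantom_spec"))
  inside <- rep(FALSE, length(x_mm))
  for (inc in spec$inclusions) {
    inside <- inside | point_in_inclusion(x_mm, y_mm, inc)
  }
  inside
}
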