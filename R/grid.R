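#' Number of resistors in a square resistor mesh
#'
#' A square mesh with `s` nodes per side contains `s*(s-1)` horizontal and
#' `s*(s-1)` vertical resistors, i.e. `2*(s^2 - s)` in total. The standard
#' 26-node mesh used with the 13x13 brachytherapy template therefore holds
#' 1,300 resistors.
#'
#' @param s Number of nodes per side (integer, >= 2).
#' @return Integer resistor count `2*(s^2 - s)`.
#' @examples
#' num_resistors(26)  # 1300
#' @export
num_resistors <- function(s) {
  s <- check_grid_side(s)
  2L * (s * s - s)
}

check_grid_side <- function(s) {
  if (length(s) != 1L || !is.finite(s) || s != as.integer(s) || s < 2L) {
    stop("grid side 's' must be a single integer >= 2", call. = FALSE)
  }
  as.integer(s)
}

#' Physical size of one resistor cell
#'
#' Each resistor of an `s`-node mesh overlaid on a template of physical side
#' `extent_mm` represents a region of `extent_mm/(s-1)` by `extent_mm/(2s-1)`
#' millimetres.
#'
#' @param s Number of nodes per side (>= 2).
#' @param extent_mm Physical side length of the template in millimetres
#'   (default 130, the standard brachytherapy template).
#' @return Named numeric vector `c(width_mm, height_mm)`.
#' @examples
#' resistor_cell_size(26)  # 5.2 x 2.549 mm
#' @export
resistor_cell_size <- function(s, extent_mm = 130) {
  s <- check_grid_side(s)
  if (!is.finite(extent_mm) || extent_mm <= 0) {
    stop("'extent_mm' must be a positive number", call. = FALSE)
  }
  c(width_mm = extent_mm / (s - 1), height_mm = extent_mm / (2 * s - 1))
}

#' Row-major linear index of a node
#'
#' Nodes are labelled N\[k, j\] with row `k` and column `j`, both 1-based.
#' The flat index is `(k-1)*s + j`, a bijection onto `1..s^2`.
#'
#' @param k Node row (1-based), vectorised.
#' @param j Node column (1-based), vectorised.
#' @param s Grid side.
#' @return Integer flat index in `1..s^2`.
#' @export
node_flat <- function(k, j, s) {
  s <- check_grid_side(s)
  if (any(k < 1L | k > s | j < 1L | j > s)) {
    stop("node index out of range for grid side ", s, call. = FALSE)
  }
  (as.integer(k) - 1L) * s + as.integer(j)
}

#' Inverse of [node_flat()]: recover (k, j) from the flat index
#'
#' @param flat Flat node index in `1..s^2`, vectorised.
#' @param s Grid side.
#' @return Integer matrix with columns `k`, `j`.
#' @export
node_kj <- function(flat, s) {
  s <- check_grid_side(s)
  flat <- as.integer(flat)
  if (any(flat < 1L | flat > s^2L)) {
    stop("flat node index out of range for grid side ", s, call. = FALSE)
  }
  cbind(k = (flat - 1L) %/% s + 1L, j = (flat - 1L) %% s + 1L)
}

#' Map a brachytherapy-template hole to its mesh node
#'
#' The standard template has 13 insertion points per side; the mesh side is
#' the even multiple s = 26 so that every insertion point coincides with a
#' node. Template hole (a, b) (column a, row b, both in 1..13) sits on node
#' N\[2b-1, 2a-1\] -- the odd sublattice anchored at node (1, 1).
#'
#' @param a Template column, 1..13 (vectorised).
#' @param b Template row, 1..13 (vectorised).
#' @param s Grid side; must be large enough that node (2b-1, 2a-1) exists.
#' @return Data frame with columns `k`, `j`, `flat`.
#' @examples
#' map_template_to_node(1, 1)    # corner -> node (1,1)
#' map_template_to_node(13, 13)  # opposite corner -> node (25,25)
#' @export
map_template_to_node <- function(a, b, s = 26L) {
  s <- check_grid_side(s)
  if (any(a < 1L | a > 13L | b < 1L | b > 13L)) {
    stop("template coordinates must lie in 1..13", call. = FALSE)
  }
  k <- 2L * as.integer(b) - 1L
  j <- 2L * as.integer(a) - 1L
  if (any(k > s | j > s)) {
    stop("template point maps outside the grid (side ", s, ")", call. = FALSE)
  }
  data.frame(k = k, j = j, flat = node_flat(k, j, s))
}

#' Construct a resistor-mesh medium
#'
#' The discrete medium is a square lattice of `s^2` nodes joined by
#' `2*(s^2-s)` resistors: `z_h[k, j]` spans nodes N\[k,j\]--N\[k,j+1\] and
#' `z_v[k, j]` spans N\[k,j\]--N\[k+1,j\]. Boundary resistors that would leave
#' the lattice are simply absent (the "infinite resistance" convention).
#'
#' @param s Grid side (>= 2).
#' @param z_h Horizontal resistances in ohms: `s x (s-1)` matrix, or a single
#'   value recycled.
#' @param z_v Vertical resistances in ohms: `(s-1) x s` matrix, or a single
#'   value recycled.
#' @param extent_mm Physical side length in millimetres (default 130).
#' @return An object of class `eit_grid`.
#' @examples
#' g <- eit_grid(26, 5, 5)   # uniform 5-ohm medium
#' num_resistors(g$s)
#' @export
eit_grid <- function(s, z_h = 1, z_v = z_h, extent_mm = 130) {
  force(z_v)  # the default mirrors z_h before it is reshaped below
  s <- check_grid_side(s)
  if (length(z_h) == 1L) z_h <- matrix(z_h, s, s - 1L)
  if (length(z_v) == 1L) z_v <- matrix(z_v, s - 1L, s)
  z_h <- as.matrix(z_h)
  z_v <- as.matrix(z_v)
  if (!identical(dim(z_h), c(s, s - 1L))) {
    stop("'z_h' must be an s x (s-1) matrix", call. = FALSE)
  }
  if (!identical(dim(z_v), c(s - 1L, s))) {
    stop("'z_v' must be an (s-1) x s matrix", call. = FALSE)
  }
  if (!all(is.finite(z_h)) || !all(is.finite(z_v)) ||
      any(z_h <= 0) || any(z_v <= 0)) {
    stop("all resistances must be strictly positive and finite", call. = FALSE)
  }
  if (!is.finite(extent_mm) || extent_mm <= 0) {
    stop("'extent_mm' must be a positive number", call. = FALSE)
  }
  structure(list(s = s, z_h = z_h, z_v = z_v, extent_mm = extent_mm),
            class = "eit_grid")
}

#' @export
print.eit_grid <- function(x, ...) {
  z <- resistor_vector(x)
  cat("Resistor mesh:", x$s, "x", x$s, "nodes,",
      num_resistors(x$s), "resistors,", x$extent_mm, "mm extent\n")
  cat(sprintf("  resistance range: %.4g -- %.4g ohm (median %.4g)\n",
              min(z), max(z), stats::median(z)))
  invisible(x)
}

#' Flatten a mesh's resistances to the canonical vector
#'
#' The resistance vector z stacks all horizontal resistors first (row-major:
#' k = 1..s, j = 1..s-1) followed by all vertical resistors (row-major:
#' k = 1..s-1, j = 1..s); its length is `2*(s^2-s)`. This ordering is the one
#' used by the Jacobian columns and the reconstruction update.
#'
#' @param grid An `eit_grid`.
#' @return Numeric vector of length `2*(s^2-s)`.
#' @export
resistor_vector <- function(grid) {
  stopifnot(inherits(grid, "eit_grid"))
  c(as.vector(t(grid$z_h)), as.vector(t(grid$z_v)))
}

#' Rebuild a mesh from a canonical resistance vector
#'
#' Inverse of [resistor_vector()].
#'
#' @param z Numeric vector of length `2*(s^2-s)`.
#' @param s Grid side.
#' @param extent_mm Physical side length in millimetres.
#' @return An `eit_grid`.
#' @export
grid_from_vector <- function(z, s, extent_mm = 130) {
  s <- check_grid_side(s)
  nh <- s * (s - 1L)
  if (length(z) != 2L * nh) {
    stop("'z' must have length 2*(s^2-s) = ", 2L * nh, call. = FALSE)
  }
  z_h <- matrix(z[seq_len(nh)], nrow = s, ncol = s - 1L, byrow = TRUE)
  z_v <- matrix(z[nh + seq_len(nh)], nrow = s - 1L, ncol = s, byrow = TRUE)
  eit_grid(s, z_h, z_v, extent_mm)
}

#' Tabulate every resistor with its terminal nodes and physical midpoint
#'
#' Node N\[k,j\] sits at physical position x = (j-1)*h, y = (k-1)*h with node
#' pitch h = extent/(s-1); a resistor's midpoint is the average of its two
#' terminal node positions. Midpoints drive phantom rasterization.
#'
#' @param grid An `eit_grid`.
#' @return Data frame with one row per resistor, in canonical vector order:
#'   columns `resistor_id`, `orientation` ("h"/"v"), `k`, `j`, `node_a`,
#'   `node_b` (flat indices), `ohms`, `x_mm`, `y_mm`.
#' @export
resistor_table <- function(grid) {
  stopifnot(inherits(grid, "eit_grid"))
  s <- grid$s
  h <- grid$extent_mm / (s - 1)
  kh <- rep(seq_len(s), each = s - 1L)
  jh <- rep(seq_len(s - 1L), times = s)
  kv <- rep(seq_len(s - 1L), each = s)
  jv <- rep(seq_len(s), times = s - 1L)
  data.frame(
    resistor_id = seq_len(2L * s * (s - 1L)),
    orientation = rep(c("h", "v"), each = s * (s - 1L)),
    k = c(kh, kv),
    j = c(jh, jv),
    node_a = c(node_flat(kh, jh, s), node_flat(kv, jv, s)),
    node_b = c(node_flat(kh, jh + 1L, s), node_flat(kv + 1L, jv, s)),
    ohms = resistor_vector(grid),
    x_mm = c((jh - 0.5) * h, (jv - 1) * h),
    y_mm = c((kh - 1) * h, (kv - 0.5) * h)
  )
}

#' Default ground node for a mesh
#'
#' One node must be grounded before the nodal system can be solved; the
#' package convention is the corner node N\[s, s\], which never coincides
#' with a template insertion point (those sit on the odd sublattice). The
#' same ground must be used for simulation and reconstruction.
#'
#' @param s Grid side.
#' @return Flat node index of node (s, s).
#' @export
default_ground <- function(s) {
  s <- check_grid_side(s)
  node_flat(s, s, s)
}
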