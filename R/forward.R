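#' Assemble the nodal conductivity matrix
#'
#' Kirchhoff's current law at every node yields a linear system C* Vf = I in
#' the nodal voltages. C* is the s^2 x s^2 matrix of conductances: each
#' diagonal entry is the sum of the conductances 1/z incident on the node,
#' each off-diagonal entry is minus the conductance of the shared resistor,
#' and absent boundary neighbours contribute nothing (the infinite-resistance
#' boundary convention). C* is symmetric with zero row sums and is singular
#' until one node is grounded with [ground_conductivity()].
#'
#' @param grid An `eit_grid`.
#' @return Dense symmetric `s^2 x s^2` matrix of conductances (siemens).
#' @export
assemble_conductivity <- function(grid) {
  stopifnot(inherits(grid, "eit_grid"))
  s <- grid$s
  n <- s^2L
  tab <- resistor_table(grid)
  g <- 1 / tab$ohms
  C <- matrix(0, n, n)
  # accumulate each two-terminal conductance into the Laplacian stencil
  ia <- tab$node_a
  ib <- tab$node_b
  C[cbind(ia, ib)] <- C[cbind(ia, ib)] - g
  C[cbind(ib, ia)] <- C[cbind(ib, ia)] - g
  diag(C) <- -rowSums(C)
  C
}

#' Ground one node of the conductivity matrix
#'
#' Zeroes row and column `g` of C* and sets the (g, g) entry to exactly 1
#' (the Hadamard-product construction with G\[g,g\] = 1/C*\[g,g\]), making the
#' system non-singular and forcing v\[g\] = 0 in every solution.
#'
#' @param C_star Ungrounded conductivity matrix from
#'   [assemble_conductivity()].
#' @param ground Flat index of the node to ground.
#' @return The grounded, non-singular matrix C.
#' @export
ground_conductivity <- function(C_star, ground) {
  n <- nrow(C_star)
  ground <- as.integer(ground)
  if (length(ground) != 1L || ground < 1L || ground > n) {
    stop("'ground' must be a single flat node index in 1..", n, call. = FALSE)
  }
  if (C_star[ground, ground] == 0) {
    stop("cannot ground an isolated node (zero diagonal)", call. = FALSE)
  }
  G <- matrix(1, n, n)
  G[ground, ] <- 0
  G[, ground] <- 0
  G[ground, ground] <- 1 / C_star[ground, ground]
  C_star * G
}

#' Build an adjacent-method injection/measurement protocol
#'
#' Current is injected through consecutive electrode pairs (1,2), (2,3), ...,
#' (E,1); for each injection pattern the differential voltage is read on
#' every other consecutive electrode pair, excluding any pair touching the
#' source or sink (needles carrying current are never used for measurement).
#' With E = 8 electrodes this yields 8 patterns of 5 measurement pairs each:
#' 40 unique measurements.
#'
#' @param electrodes The needle positions, in ring order: either a vector of
#'   flat node indices, or a two-column matrix/data frame of node (k, j)
#'   rows, or the data frame returned by [map_template_to_node()].
#' @param s Grid side the electrodes live on.
#' @param amplitude_A Injection amplitude in amperes (default 0.015, i.e.
#'   15 mA).
#' @return An object of class `eit_protocol` with elements `s`, `electrodes`
#'   (flat indices), `amplitude_A`, `patterns` (data frame `pattern`,
#'   `source`, `sink` as electrode ordinals) and `pairs` (data frame
#'   `pattern`, `a`, `b` as electrode ordinals, a < b positions in the ring).
#' @export
adjacent_protocol <- function(electrodes, s, amplitude_A = 0.015) {
  s <- check_grid_side(s)
  if (is.data.frame(electrodes) && all(c("k", "j") %in% names(electrodes))) {
    electrodes <- node_flat(electrodes$k, electrodes$j, s)
  } else if (is.matrix(electrodes) && ncol(electrodes) == 2L) {
    electrodes <- node_flat(electrodes[, 1L], electrodes[, 2L], s)
  }
  electrodes <- as.integer(electrodes)
  E <- length(electrodes)
  if (E < 4L) {
    stop("the adjacent protocol needs at least 4 electrodes ",
         "(no measurement pair exists otherwise)", call. = FALSE)
  }
  if (anyDuplicated(electrodes) || any(electrodes < 1L | electrodes > s^2L)) {
    stop("electrodes must be distinct nodes inside the grid", call. = FALSE)
  }
  if (!is.finite(amplitude_A)) {
    stop("'amplitude_A' must be finite", call. = FALSE)
  }
  nxt <- function(e) e %% E + 1L
  patterns <- data.frame(pattern = seq_len(E),
                         source = seq_len(E),
                         sink = nxt(seq_len(E)))
  pairs <- do.call(rbind, lapply(seq_len(E), function(p) {
    drive <- c(patterns$source[p], patterns$sink[p])
    a <- seq_len(E)
    b <- nxt(a)
    keep <- !(a %in% drive | b %in% drive)
    data.frame(pattern = p, a = a[keep], b = b[keep])
  }))
  rownames(pairs) <- NULL
  structure(list(s = s, electrodes = electrodes, amplitude_A = amplitude_A,
                 patterns = patterns, pairs = pairs),
            class = "eit_protocol")
}

#' @export
print.eit_protocol <- function(x, ...) {
  cat("Adjacent EIT protocol:", length(x$electrodes), "electrodes,",
      nrow(x$patterns), "injection patterns,", nrow(x$pairs),
      "measurements,", x$amplitude_A * 1000, "mA on a", x$s, "x", x$s,
      "node mesh\n")
  invisible(x)
}

#' Nodal current vector for one injection pattern
#'
#' All entries are zero except +amplitude at the source node and -amplitude
#' at the sink node, so the vector sums to zero (no net charge). The ground
#' row is left at zero.
#'
#' @param protocol An `eit_protocol`.
#' @param pattern Pattern number (row of `protocol$patterns`).
#' @param ground Flat index of the grounded node; must not be an electrode.
#' @return Numeric vector of length `s^2`.
#' @export
current_vector <- function(protocol, pattern, ground = default_ground(protocol$s)) {
  stopifnot(inherits(protocol, "eit_protocol"))
  p <- protocol$patterns[pattern, , drop = FALSE]
  if (nrow(p) != 1L || is.na(p$pattern)) {
    stop("unknown pattern ", pattern, call. = FALSE)
  }
  if (ground %in% protocol$electrodes) {
    stop("the ground node must not be an electrode", call. = FALSE)
  }
  I <- numeric(protocol$s^2L)
  I[protocol$electrodes[p$source]] <- protocol$amplitude_A
  I[protocol$electrodes[p$sink]] <- -protocol$amplitude_A
  I
}

#' Solve the grounded nodal system for one injection pattern
#'
#' Computes the nodal voltage vector Vf with C Vf = I. The solve uses a
#' Cholesky factorization of the grounded matrix rather than an explicit
#' inverse; the result is identical and better conditioned.
#'
#' @param C Grounded conductivity matrix (or a pre-computed Cholesky factor
#'   of it, as returned by `chol()`).
#' @param pattern Pattern number.
#' @param protocol An `eit_protocol`.
#' @param ground Flat index of the grounded node.
#' @return Numeric vector of nodal voltages (volts); exactly 0 at the ground.
#' @export
solve_nodal_voltages <- function(C, pattern, protocol,
                                 ground = default_ground(protocol$s)) {
  I <- current_vector(protocol, pattern, ground)
  R <- if (inherits(C, "eit_chol")) C else chol_factor(C)
  solve_chol(R, I)
}

#' Nodal voltages for an arbitrary source/sink node pair
#'
#' Lower-level companion to [solve_nodal_voltages()]: injects `amplitude_A`
#' into node `source` and extracts it at node `sink` (flat indices), with
#' node `ground` held at zero volts.
#'
#' @param grid An `eit_grid`.
#' @param source,sink Flat node indices of the injection pair.
#' @param ground Flat index of the grounded node.
#' @param amplitude_A Injected current in amperes.
#' @return Numeric vector of nodal voltages (volts).
#' @examples
#' # unit square of 1-ohm resistors: inject 1 A across the top edge
#' v <- nodal_voltages(eit_grid(2, 1, 1), source = 1, sink = 2,
#'                     ground = 4, amplitude_A = 1)
#' all.equal(v, c(0.5, -0.25, 0.25, 0))
#' @export
nodal_voltages <- function(grid, source, sink, ground = default_ground(grid$s),
                           amplitude_A = 0.015) {
  stopifnot(inherits(grid, "eit_grid"), source != sink)
  C <- ground_conductivity(assemble_conductivity(grid), ground)
  I <- numeric(grid$s^2L)
  I[source] <- amplitude_A
  I[sink] <- -amplitude_A
  I[ground] <- 0
  solve_chol(chol_factor(C), I)
}

# Cached Cholesky factor; the grounded matrix is symmetric positive definite.
chol_factor <- function(C) {
  structure(chol(C), class = "eit_chol")
}

solve_chol <- function(R, b) {
  backsolve(R, backsolve(R, b, transpose = TRUE))
}

#' Simulate the boundary-voltage measurements of a protocol
#'
#' For every injection pattern, solves the nodal system and records the
#' differential voltage v\[a\] - v\[b\] on each measurement pair (a the lower
#' electrode ordinal). Deterministic given the mesh and protocol.
#'
#' @param grid An `eit_grid`.
#' @param protocol An `eit_protocol`; electrode nodes must be disjoint from
#'   the ground.
#' @param ground Flat index of the grounded node.
#' @param frequency_khz Frequency label attached to the frame (the circuit
#'   model is purely resistive; the label only tags the acquisition).
#' @return An `eit_frame`: data frame with columns `pattern`, `source`,
#'   `sink`, `meas_a`, `meas_b` (electrode ordinals) and `voltage` (volts),
#'   with attributes `frequency_khz`, `amplitude_A`, `s` and `ground`.
#' @export
simulate_measurements <- function(grid, protocol,
                                  ground = default_ground(grid$s),
                                  frequency_khz = 1) {
  stopifnot(inherits(grid, "eit_grid"), inherits(protocol, "eit_protocol"))
  if (grid$s != protocol$s) {
    stop("grid and protocol are defined on different mesh sides", call. = FALSE)
  }
  C <- ground_conductivity(assemble_conductivity(grid), ground)
  R <- chol_factor(C)
  pairs <- protocol$pairs
  volts <- numeric(nrow(pairs))
  for (p in protocol$patterns$pattern) {
    v <- solve_nodal_voltages(R, p, protocol, ground)
    rows <- which(pairs$pattern == p)
    volts[rows] <- v[protocol$electrodes[pairs$a[rows]]] -
      v[protocol$electrodes[pairs$b[rows]]]
  }
  new_frame(data.frame(pattern = pairs$pattern,
                       source = protocol$patterns$source[pairs$pattern],
                       sink = protocol$patterns$sink[pairs$pattern],
                       meas_a = pairs$a, meas_b = pairs$b,
                       voltage = volts),
            frequency_khz = frequency_khz,
            amplitude_A = protocol$amplitude_A,
            s = protocol$s, ground = as.integer(ground))
}

new_frame <- function(df, frequency_khz, amplitude_A, s, ground) {
  structure(df, frequency_khz = frequency_khz, amplitude_A = amplitude_A,
            s = s, ground = ground,
            class = c("eit_frame", "data.frame"))
}

#' @export
print.eit_frame <- function(x, ...) {
  cat("EIT measurement frame:", nrow(x), "measurements over",
      length(unique(x$pattern)), "patterns at",
      attr(x, "frequency_khz"), "kHz\n")
  print.data.frame(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("  ... and", nrow(x) - 5L, "more rows\n")
  invisible(x)
}

#' Extract a frame's voltages as a plain vector
#'
#' @param frame An `eit_frame`.
#' @return Numeric voltage vector in frame row order.
#' @export
frame_voltages <- function(frame) {
  stopifnot(inherits(frame, "eit_frame"))
  frame$voltage
}

#' Add seeded Gaussian measurement noise to a frame
#'
#' The noise is zero-mean Gaussian with a standard deviation chosen so that
#' the ratio of signal power (mean square of the clean voltages) to noise
#' power equals the requested SNR in decibels. Seeded and reproducible; the
#' caller's RNG state is untouched. `snr_db = Inf` returns the frame
#' unchanged.
#'
#' @param frame An `eit_frame`.
#' @param snr_db Requested signal-to-noise ratio in dB.
#' @param seed Integer seed.
#' @return A noisy `eit_frame` with identical metadata.
#' @export
add_noise <- function(frame, snr_db, seed = 1L) {
  stopifnot(inherits(frame, "eit_frame"))
  if (is.infinite(snr_db) && snr_db > 0) return(frame)
  if (!is.finite(snr_db)) stop("'snr_db' must be finite or +Inf", call. = FALSE)
  rms <- sqrt(mean(frame$voltage^2))
  sd_noise <- rms * 10^(-snr_db / 20)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  frame$voltage <- frame$voltage + stats::rnorm(nrow(frame), 0, sd_noise)
  frame
}

#' Frequency-difference frame
#'
#' Subtracts two frames acquired under the same protocol at two injection
#' frequencies; the resulting difference frame is fed to the same
#' reconstruction machinery as an absolute frame. The frequency label of the
#' result records both inputs (e.g. "179-1").
#'
#' @param frame_f1,frame_f2 Two `eit_frame`s with identical protocol layout
#'   and measurement ordering.
#' @return An `eit_frame` holding `frame_f1 - frame_f2` voltages.
#' @export
frequency_difference_frame <- function(frame_f1, frame_f2) {
  stopifnot(inherits(frame_f1, "eit_frame"), inherits(frame_f2, "eit_frame"))
  layout <- c("pattern", "source", "sink", "meas_a", "meas_b")
  if (nrow(frame_f1) != nrow(frame_f2) ||
      !identical(as.data.frame(frame_f1)[layout], as.data.frame(frame_f2)[layout]) ||
      !identical(attr(frame_f1, "s"), attr(frame_f2, "s"))) {
    stop("frames were not acquired under the same protocol layout", call. = FALSE)
  }
  out <- frame_f1
  out$voltage <- frame_f1$voltage - frame_f2$voltage
  attr(out, "frequency_khz") <- paste0(attr(frame_f1, "frequency_khz"), "-",
                                       attr(frame_f2, "frequency_khz"))
  out
}
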