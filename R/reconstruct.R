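#' Least-squares voltage misfit
#'
#' The objective driving the reconstruction: half the sum of squared
#' differences between calculated and measured voltages,
#' theta(z) = (1/2) (V - V0)' (V - V0).
#'
#' @param V Calculated voltages: an `eit_frame` or numeric vector.
#' @param V0 Measured voltages: an `eit_frame` or numeric vector of the same
#'   layout/length.
#' @return Non-negative scalar.
#' @export
objective <- function(V, V0) {
  v <- if (inherits(V, "eit_frame")) frame_voltages(V) else as.numeric(V)
  v0 <- if (inherits(V0, "eit_frame")) frame_voltages(V0) else as.numeric(V0)
  if (length(v) != length(v0)) {
    stop("calculated and measured frames are not conformable (",
         length(v), " vs ", length(v0), " readings)", call. = FALSE)
  }
  0.5 * sum((v - v0)^2)
}

#' One Marquardt-damped Gauss-Newton update
#'
#' Solves for the resistance update
#'   dz = -(J'J + lambda W)^{-1} J' (V - V0),
#' with W the identity. Because the number of measurements n is far smaller
#' than the number of resistors, the update is evaluated through the exact
#' push-through identity (J'J + lambda I)^{-1} J' = J' (J J' + lambda I)^{-1},
#' an n x n solve with identical result.
#'
#' @param z Current resistance vector (ohms). Only its length is checked
#'   against the Jacobian; the update itself depends on z through J and V.
#' @param J Jacobian matrix (n measurements x length(z) resistors).
#' @param V Calculated voltages (frame or vector).
#' @param V0 Measured voltages (frame or vector).
#' @param lambda Marquardt damping scalar (> 0).
#' @return The update vector dz, same length as `z`.
#' @export
mnr_update <- function(z, J, V, V0, lambda) {
  v <- if (inherits(V, "eit_frame")) frame_voltages(V) else as.numeric(V)
  v0 <- if (inherits(V0, "eit_frame")) frame_voltages(V0) else as.numeric(V0)
  if (length(v) != length(v0) || length(v) != nrow(J) || length(z) != ncol(J)) {
    stop("Jacobian, voltages and resistance vector are not conformable",
         call. = FALSE)
  }
  if (!is.finite(lambda) || lambda <= 0) {
    stop("'lambda' must be a positive scalar", call. = FALSE)
  }
  r <- v - v0
  A <- tcrossprod(J)
  diag(A) <- diag(A) + lambda
  y <- tryCatch(solve(A, r), error = function(e) {
    stop("damped normal equations are numerically singular; ",
         "increase 'lambda'", call. = FALSE)
  })
  -drop(crossprod(J, y))
}

#' Reconstruct the internal resistance distribution (Modified Newton-Raphson)
#'
#' The model fitting function of the package. Starting from a uniform
#' initial distribution z0, it repeats: simulate voltages V(z) on the
#' current mesh, form the adjoint Jacobian, take the Marquardt-damped
#' Gauss-Newton step dz = -(J'J + lambda I)^{-1} J'(V - V0), and update
#' z <- z + dz, clamped to a small positive floor. Iteration stops when the
#' infinity norm of dz falls below `delta_tol` or after `max_iter`
#' iterations (default 3, after which the update has stabilized).
#'
#' The initial value matters: recovery is reliable when z0 is within about
#' 10 ohms of the true background resistance.
#'
#' @param V0 Measured (or simulated) `eit_frame`.
#' @param protocol The `eit_protocol` that produced `V0`.
#' @param z0 Initial uniform resistance in ohms (e.g. 5 for saline media,
#'   60 for gelatin).
#' @param lambda Marquardt damping scalar; default 1e-8 (useful range about
#'   1e-9 to 1e-8 for this protocol).
#' @param max_iter Iteration cap (default 3).
#' @param delta_tol Stop when max(abs(dz)) < delta_tol; default 0, so the
#'   iteration cap governs. No canonical threshold exists; choose one per
#'   application if early stopping is wanted.
#' @param ground Flat index of the grounded node; must equal the ground used
#'   during acquisition/simulation.
#' @param jacobian_method "adjoint" (default) or "finite_difference".
#' @param z_floor Positivity floor in ohms applied after each update.
#' @param extent_mm Physical mesh extent for the reconstructed grid.
#' @return An object of class `eit_recon`: list with `z` (final resistance
#'   vector), `grid` (the reconstructed `eit_grid`), `trace` (per-iteration
#'   data frame: `iteration`, `objective`, `update_norm`), `converged_by`
#'   ("tolerance" or "max_iter"), `fitted_voltages`, `measured` (V0),
#'   `protocol`, and the configuration used.
#' @seealso [tomogram()] to render the result, [coef.eit_recon()],
#'   [plot.eit_recon()].
#' @examples
#' ph <- phantom_spec(8, 5, list(circle_inclusion(c(65, 65), 25, 0.5)))
#' truth <- generate_phantom(ph)
#' el <- rbind(c(1, 3), c(1, 6), c(4, 8), c(8, 6), c(8, 3), c(5, 1))
#' prot <- adjacent_protocol(el, s = 8)
#' fit <- eit_reconstruct(simulate_measurements(truth, prot), prot, z0 = 5)
#' fit
#' @export
eit_reconstruct <- function(V0, protocol, z0, lambda = 1e-8, max_iter = 3L,
                            delta_tol = 0, ground = default_ground(protocol$s),
                            jacobian_method = c("adjoint", "finite_difference"),
                            z_floor = 1e-6, extent_mm = 130) {
  stopifnot(inherits(V0, "eit_frame"), inherits(protocol, "eit_protocol"))
  jacobian_method <- match.arg(jacobian_method)
  if (!is.finite(z0) || z0 <= 0) stop("'z0' must be positive", call. = FALSE)
  if (!is.finite(lambda) || lambda <= 0) stop("'lambda' must be positive", call. = FALSE)
  if (max_iter < 1L) stop("'max_iter' must be at least 1", call. = FALSE)
  if (nrow(V0) != nrow(protocol$pairs)) {
    stop("'V0' does not match the protocol's measurement count", call. = FALSE)
  }
  s <- protocol$s
  v0 <- frame_voltages(V0)
  z <- rep(z0, num_resistors(s))
  trace <- data.frame(iteration = integer(), objective = numeric(),
                      update_norm = numeric())
  converged_by <- "max_iter"
  for (it in seq_len(max_iter)) {
    grid_k <- grid_from_vector(z, s, extent_mm)
    v <- frame_voltages(simulate_measurements(grid_k, protocol, ground,
                                              attr(V0, "frequency_khz")))
    J <- eit_jacobian(grid_k, protocol, ground, jacobian_method)
    dz <- mnr_update(z, J, v, v0, lambda)
    if (!all(is.finite(dz))) {
      stop("non-finite update at iteration ", it,
           "; the reconstruction diverged", call. = FALSE)
    }
    upd <- max(abs(dz))
    trace <- rbind(trace, data.frame(iteration = it,
                                     objective = objective(v, v0),
                                     update_norm = upd))
    if (upd < delta_tol) {
      converged_by <- "tolerance"
      break
    }
    z <- pmax(z + dz, z_floor)
  }
  grid_final <- grid_from_vector(z, s, extent_mm)
  v_final <- frame_voltages(simulate_measurements(grid_final, protocol, ground,
                                                  attr(V0, "frequency_khz")))
  structure(list(z = z, grid = grid_final, trace = trace,
                 converged_by = converged_by,
                 fitted_voltages = v_final, measured = V0,
                 protocol = protocol,
                 config = list(z0 = z0, lambda = lambda, max_iter = max_iter,
                               delta_tol = delta_tol, ground = ground,
                               jacobian_method = jacobian_method,
                               z_floor = z_floor, extent_mm = extent_mm)),
            class = "eit_recon")
}

#' @export
print.eit_recon <- function(x, ...) {
  cat("EIT resistance reconstruction (Modified Newton-Raphson)\n")
  cat(sprintf("  mesh: %d x %d nodes (%d resistors), %d electrodes, %d measurements\n",
              x$protocol$s, x$protocol$s, length(x$z),
              length(x$protocol$electrodes), nrow(x$measured)))
  cat(sprintf("  z0 = %g ohm, lambda = %g, stopped by %s after %d iteration(s)\n",
              x$config$z0, x$config$lambda, x$converged_by, nrow(x$trace)))
  cat(sprintf("  final objective: %.4g V^2, resistance range %.4g -- %.4g ohm\n",
              utils::tail(x$trace$objective, 1), min(x$z), max(x$z)))
  invisible(x)
}

#' @export
summary.eit_recon <- function(object, ...) {
  structure(list(fit = object,
                 z_summary = summary(object$z),
                 residuals = residuals(object)),
            class = "summary.eit_recon")
}

#' @export
print.summary.eit_recon <- function(x, ...) {
  print(x$fit)
  cat("\nIteration trace:\n")
  print(x$fit$trace, row.names = FALSE)
  cat("\nReconstructed resistances (ohm):\n")
  print(x$z_summary)
  cat(sprintf("\nVoltage residuals: RMS %.4g V, max |r| %.4g V\n",
              sqrt(mean(x$residuals^2)), max(abs(x$residuals))))
  invisible(x)
}

#' @export
coef.eit_recon <- function(object, ...) object$z

#' @export
fitted.eit_recon <- function(object, ...) object$fitted_voltages

#' @export
residuals.eit_recon <- function(object, ...) {
  object$fitted_voltages - frame_voltages(object$measured)
}

#' Plot a reconstruction as a normalized tomogram
#'
#' @param x An `eit_recon`.
#' @param ... Passed to [plot.eit_tomogram()].
#' @export
plot.eit_recon <- function(x, ...) {
  plot(tomogram(x), ...)
}
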