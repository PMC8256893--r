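#' Sensitivity (Jacobian) of the measurements to the mesh resistors
#'
#' Row m, column i of the Jacobian is the derivative of measurement m with
#' respect to resistor z\[i\]. The default adjoint formulation reuses one
#' Cholesky factorization of the grounded system: with u_p the nodal field of
#' the injection pattern and u_m the field driven by a unit current through
#' the measurement pair, the sensitivity to the resistor spanning nodes
#' (alpha, beta) is
#'
#'   dV_m/dz_i = (1/z_i^2) * (u_p\[alpha\] - u_p\[beta\]) *
#'               (u_m\[alpha\] - u_m\[beta\]).
#'
#' A central finite-difference evaluation is available as an independent
#' (much slower) cross-check.
#'
#' @param grid An `eit_grid`.
#' @param protocol An `eit_protocol` on the same mesh.
#' @param ground Flat index of the grounded node.
#' @param method "adjoint" (default) or "finite_difference".
#' @param fd_rel Relative perturbation for the finite-difference method.
#' @return Numeric matrix, one row per measurement (frame row order), one
#'   column per resistor (canonical vector order).
#' @export
eit_jacobian <- function(grid, protocol, ground = default_ground(grid$s),
                         method = c("adjoint", "finite_difference"),
                         fd_rel = 1e-6) {
  method <- match.arg(method)
  stopifnot(inherits(grid, "eit_grid"), inherits(protocol, "eit_protocol"))
  if (grid$s != protocol$s) {
    stop("grid and protocol are defined on different mesh sides", call. = FALSE)
  }
  if (method == "adjoint") {
    jacobian_adjoint(grid, protocol, ground)
  } else {
    jacobian_fd(grid, protocol, ground, fd_rel)
  }
}

jacobian_adjoint <- function(grid, protocol, ground) {
  tab <- resistor_table(grid)
  C <- ground_conductivity(assemble_conductivity(grid), ground)
  R <- chol_factor(C)
  n_nodes <- grid$s^2L
  # forward fields, one per injection pattern
  U_p <- vapply(protocol$patterns$pattern,
                function(p) solve_nodal_voltages(R, p, protocol, ground),
                numeric(n_nodes))
  # measurement fields: unit current through each distinct electrode pair
  pair_key <- paste(protocol$pairs$a, protocol$pairs$b)
  distinct <- !duplicated(pair_key)
  U_m <- vapply(which(distinct), function(i) {
    I <- numeric(n_nodes)
    I[protocol$electrodes[protocol$pairs$a[i]]] <- 1
    I[protocol$electrodes[protocol$pairs$b[i]]] <- -1
    solve_chol(R, I)
  }, numeric(n_nodes))
  colnames(U_m) <- pair_key[distinct]
  inv_z2 <- 1 / tab$ohms^2
  J <- matrix(0, nrow(protocol$pairs), nrow(tab))
  for (m in seq_len(nrow(protocol$pairs))) {
    dp <- U_p[tab$node_a, protocol$pairs$pattern[m]] -
      U_p[tab$node_b, protocol$pairs$pattern[m]]
    dm <- U_m[tab$node_a, pair_key[m]] - U_m[tab$node_b, pair_key[m]]
    J[m, ] <- inv_z2 * dp * dm
  }
  J
}

jacobian_fd <- function(grid, protocol, ground, fd_rel) {
  z <- resistor_vector(grid)
  nr <- length(z)
  sim <- function(zv) {
    frame_voltages(simulate_measurements(
      grid_from_vector(zv, grid$s, grid$extent_mm), protocol, ground))
  }
  J <- matrix(0, nrow(protocol$pairs), nr)
  for (i in seq_len(nr)) {
    eps <- fd_rel * z[i]
    zp <- z; zp[i] <- z[i] + eps
    zm <- z; zm[i] <- z[i] - eps
    J[, i] <- (sim(zp) - sim(zm)) / (2 * eps)
  }
  J
}
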