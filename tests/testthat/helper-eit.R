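# Shared fixtures: small random meshes and electrode rings for reduced-size
# protocols. All randomness is locally seeded so tests are order-independent.

random_grid <- function(s, seed, lo = 0.5, hi = 5, extent_mm = 130) {
  set.seed(seed)
  grid_from_vector(runif(num_resistors(s), lo, hi), s, extent_mm)
}

# boundary nodes of an s-grid in clockwise ring order, as (k, j) rows
boundary_ring <- function(s) {
  top <- cbind(1L, seq_len(s))
  right <- cbind(seq(2L, s), s)
  bottom <- cbind(s, seq(s - 1L, 1L))
  left <- cbind(seq(s - 1L, 2L), 1L)
  rbind(top, right, bottom, left)
}

# E electrodes spread around the boundary ring, avoiding the default ground
# corner (s, s)
ring_electrodes <- function(s, E = 6L) {
  ring <- boundary_ring(s)
  keep <- !(ring[, 1] == s & ring[, 2] == s)
  ring <- ring[keep, , drop = FALSE]
  idx <- round(seq(1, nrow(ring), length.out = E + 1L))[seq_len(E)]
  ring[idx, , drop = FALSE]
}

small_protocol <- function(s, E = 6L, amplitude_A = 0.015) {
  adjacent_protocol(ring_electrodes(s, E), s, amplitude_A)
}

# standard 26-node scenario fixture: truth grid, protocol, noiseless frame
scenario_fixture <- function(name) {
  sc <- scenario_phantom(name)
  truth <- generate_phantom(sc$spec)
  prot <- adjacent_protocol(
    map_template_to_node(sc$electrodes$a, sc$electrodes$b, sc$spec$s),
    sc$spec$s)
  list(scenario = sc, truth = truth, protocol = prot,
       frame = simulate_measurements(truth, prot))
}
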