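test_that("unit-square assembly reproduces the hand-built 4x4 Laplacian", {
  C <- assemble_conductivity(eit_grid(2, 1, 1))
  expect_equal(C, matrix(c(2, -1, -1, 0,
                           -1, 2, 0, -1,
                           -1, 0, 2, -1,
                           0, -1, -1, 2), 4, 4, byrow = TRUE))
})

test_that("conductivity matrix is symmetric with zero row sums; conductance is linear", {
  for (s in c(3L, 5L, 6L)) {
    g <- random_grid(s, seed = s)
    C <- assemble_conductivity(g)
    expect_equal(C, t(C))
    expect_equal(rowSums(C), rep(0, s^2), tolerance = 1e-12)
    # doubling every resistance halves every entry
    g2 <- grid_from_vector(2 * resistor_vector(g), s)
    expect_equal(assemble_conductivity(g2), C / 2)
  }
})

test_that("grounding zeroes row/column g, pins the diagonal at 1, and is non-singular", {
  C4 <- assemble_conductivity(eit_grid(2, 1, 1))
  G4 <- ground_conductivity(C4, 4)
  expect_equal(G4[4, ], c(0, 0, 0, 1))
  expect_equal(G4[, 4], c(0, 0, 0, 1))
  expect_equal(G4[1:3, 1:3], C4[1:3, 1:3])
  for (s in 2:4) {
    C <- assemble_conductivity(eit_grid(s, 1, 1))
    Cg <- ground_conductivity(C, default_ground(s))
    expect_gt(abs(det(Cg)), 0)
    # re-grounding the same node leaves row/column g fixed
    Cg2 <- ground_conductivity(Cg, default_ground(s))
    expect_equal(Cg2[default_ground(s), ], Cg[default_ground(s), ])
  }
  expect_error(ground_conductivity(C4, 9), "flat node index")
})

test_that("hand-solved loop voltages are reproduced to machine precision", {
  v <- nodal_voltages(eit_grid(2, 1, 1), source = 1, sink = 2,
                      ground = 4, amplitude_A = 1)
  expect_equal(v, c(0.5, -0.25, 0.25, 0), tolerance = 1e-14)
  expect_identical(v[4], 0)
})

test_that("nodal solutions are linear in amplitude and in uniform scaling of z", {
  g <- random_grid(5, seed = 11)
  prot <- small_protocol(5)
  v1 <- solve_nodal_voltages(ground_conductivity(assemble_conductivity(g),
                                                 default_ground(5)),
                             1, prot)
  prot3 <- adjacent_protocol(ring_electrodes(5), 5, amplitude_A = 3 * 0.015)
  v3 <- solve_nodal_voltages(ground_conductivity(assemble_conductivity(g),
                                                 default_ground(5)),
                             1, prot3)
  expect_equal(v3, 3 * v1, tolerance = 1e-12)
  # zero amplitude: all-zero field
  prot0 <- adjacent_protocol(ring_electrodes(5), 5, amplitude_A = 0)
  f0 <- simulate_measurements(g, prot0)
  expect_true(all(f0$voltage == 0))
  # scaling all resistances by c scales all measured voltages by c
  f1 <- simulate_measurements(g, prot)
  gc <- grid_from_vector(2.5 * resistor_vector(g), 5)
  fc <- simulate_measurements(gc, prot)
  expect_equal(fc$voltage, 2.5 * f1$voltage, tolerance = 1e-12)
})

test_that("the assembled current vector sums to exactly zero and ground stays at 0 V", {
  for (s in c(4L, 6L)) {
    g <- random_grid(s, seed = 20 + s)
    prot <- small_protocol(s)
    C <- ground_conductivity(assemble_conductivity(g), default_ground(s))
    for (p in prot$patterns$pattern) {
      I <- current_vector(prot, p)
      expect_identical(sum(I), 0)
      v <- solve_nodal_voltages(C, p, prot)
      expect_identical(v[default_ground(s)], 0)
    }
  }
})

test_that("adjacent protocol enumerates patterns and non-driven consecutive pairs", {
  prot8 <- adjacent_protocol(map_template_to_node(default_electrodes()$a,
                                                  default_electrodes()$b, 26),
                             26)
  expect_identical(nrow(prot8$patterns), 8L)
  expect_identical(nrow(prot8$pairs), 40L)
  expect_true(all(table(prot8$pairs$pattern) == 5L))
  p1 <- prot8$pairs[prot8$pairs$pattern == 1, ]
  expect_equal(p1$a, 3:7)
  expect_equal(p1$b, 4:8)
  # no measurement pair touches its pattern's drive electrodes
  drive <- prot8$patterns[prot8$pairs$pattern, c("source", "sink")]
  expect_false(any(prot8$pairs$a == drive$source | prot8$pairs$a == drive$sink |
                   prot8$pairs$b == drive$source | prot8$pairs$b == drive$sink))
  # E=4 degenerates to one pair per pattern
  prot4 <- adjacent_protocol(ring_electrodes(6, 4), 6)
  expect_identical(nrow(prot4$patterns), 4L)
  expect_identical(nrow(prot4$pairs), 4L)
  expect_error(adjacent_protocol(ring_electrodes(6, 3), 6), "at least 4")
})

test_that("transfer voltages obey reciprocity on random grids", {
  for (s in 4:6) {
    g <- random_grid(s, seed = 100 + s)
    ground <- default_ground(s)
    nodes <- node_flat(c(1, 1, s, 2), c(1, s, 1, 3), s)
    # drive pair (n1, n2), measure (n3, n4) vs drive (n3, n4), measure (n1, n2)
    v_a <- nodal_voltages(g, nodes[1], nodes[2], ground, amplitude_A = 0.015)
    v_b <- nodal_voltages(g, nodes[3], nodes[4], ground, amplitude_A = 0.015)
    expect_equal(v_a[nodes[3]] - v_a[nodes[4]],
                 v_b[nodes[1]] - v_b[nodes[2]], tolerance = 1e-12)
  }
})

test_that("inclusion perturbs most the electrodes facing it", {
  sc <- scenario_phantom("saline_offcenter_disc")
  truth <- generate_phantom(sc$spec)
  uniform <- generate_phantom(phantom_spec(26, 5))
  prot <- adjacent_protocol(map_template_to_node(sc$electrodes$a,
                                                 sc$electrodes$b, 26), 26)
  d <- abs(simulate_measurements(truth, prot)$voltage -
             simulate_measurements(uniform, prot)$voltage)
  # residual magnitude per measurement pair's nearest electrode distance to
  # the inclusion centre: nearest third must out-rank the farthest third
  ctr <- sc$spec$inclusions[[1]]$center
  el_kj <- node_kj(prot$electrodes, 26)
  el_xy <- cbind((el_kj[, "j"] - 1) * 5.2, (el_kj[, "k"] - 1) * 5.2)
  el_dist <- sqrt(rowSums(sweep(el_xy, 2, ctr)^2))
  pair_dist <- pmin(el_dist[prot$pairs$a], el_dist[prot$pairs$b])
  expect_gt(mean(d[pair_dist <= quantile(pair_dist, 1 / 3)]),
            mean(d[pair_dist >= quantile(pair_dist, 2 / 3)]))
})

test_that("seeded Gaussian noise hits the requested SNR and is reproducible", {
  g <- random_grid(5, seed = 3)
  prot <- small_protocol(5)
  frame <- simulate_measurements(g, prot)
  expect_identical(add_noise(frame, Inf, 1), frame)
  n1 <- add_noise(frame, 30, seed = 42)
  n2 <- add_noise(frame, 30, seed = 42)
  expect_identical(n1$voltage, n2$voltage)
  expect_false(identical(n1$voltage, add_noise(frame, 30, seed = 43)$voltage))
  # Monte-Carlo SNR check on a long replicated frame
  big <- eitmesh:::new_frame(
    data.frame(pattern = 1L, source = 1L, sink = 2L, meas_a = 3L, meas_b = 4L,
               voltage = rep(frame$voltage, length.out = 10000)),
    frequency_khz = 1, amplitude_A = 0.015, s = 5L, ground = default_ground(5))
  noisy <- add_noise(big, 20, seed = 7)
  snr_hat <- 10 * log10(mean(big$voltage^2) / mean((noisy$voltage - big$voltage)^2))
  expect_lt(abs(snr_hat - 20), 0.5)
})

test_that("frequency-difference frames subtract elementwise and check layout", {
  g1 <- random_grid(5, seed = 51)
  g2 <- grid_from_vector(resistor_vector(g1) * runif(num_resistors(5), 0.9, 1.1),
                         5)
  prot <- small_protocol(5)
  fa <- simulate_measurements(g1, prot, frequency_khz = 179)
  fb <- simulate_measurements(g2, prot, frequency_khz = 1)
  d <- frequency_difference_frame(fa, fb)
  expect_equal(d$voltage, fa$voltage - fb$voltage)
  expect_identical(attr(d, "frequency_khz"), "179-1")
  # antisymmetry and the zero self-difference
  expect_equal(frequency_difference_frame(fb, fa)$voltage, -d$voltage)
  expect_true(all(frequency_difference_frame(fa, fa)$voltage == 0))
  # layout mismatch is rejected
  prot2 <- small_protocol(5, E = 5)
  fc <- simulate_measurements(g1, prot2)
  expect_error(frequency_difference_frame(fa, fc), "protocol layout")
})
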