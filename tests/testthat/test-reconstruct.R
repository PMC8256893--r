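test_that("objective is half the summed squared misfit", {
  v <- rnorm(40)
  expect_identical(objective(v, v), 0)
  expect_identical(objective(rep(1, 40), rep(0, 40)), 20)
  set.seed(9)
  a <- rnorm(25); b <- rnorm(25)
  expect_equal(objective(a, b), 0.5 * sum((a - b)^2))
  expect_error(objective(a, b[1:10]), "conformable")
})

test_that("the Marquardt step matches the normal-equation oracle", {
  set.seed(77)
  n <- 4L; m <- 6L
  J <- matrix(rnorm(n * m), n, m)
  z <- runif(m, 1, 5)
  v0 <- rnorm(n)
  v <- v0 + rnorm(n, sd = 0.1)
  for (lambda in c(1e-8, 1e-3, 1)) {
    dz <- mnr_update(z, J, v, v0, lambda)
    # independent oracle: direct solve of (J'J + lambda I) dz = -J' r
    oracle <- solve(crossprod(J) + lambda * diag(m), -crossprod(J, v - v0))
    # both routes solve the same damped system; at lambda = 1e-8 its
    # condition number (~1/lambda) bounds achievable agreement
    expect_equal(dz, drop(oracle), tolerance = 1e-5)
  }
  # zero residual gives a zero step
  expect_equal(mnr_update(z, J, v0, v0, 1e-8), rep(0, m))
  # huge damping degenerates to a vanishing gradient-descent step
  lam <- 1e6
  expect_equal(mnr_update(z, J, v, v0, lam),
               drop(-crossprod(J, v - v0) / lam), tolerance = 1e-4)
  expect_error(mnr_update(z, J, v, v0, -1), "positive")
  expect_error(mnr_update(z, J[, 1:3], v, v0, 1), "conformable")
})

test_that("self-consistent uniform data is a fixed point of the reconstruction", {
  s <- 6L
  z0 <- 5
  prot <- small_protocol(s)
  frame <- simulate_measurements(eit_grid(s, z0, z0), prot)
  fit <- eit_reconstruct(frame, prot, z0 = z0)
  expect_equal(coef(fit), rep(z0, num_resistors(s)), tolerance = 1e-10)
  expect_lt(fit$trace$update_norm[1], 1e-10)
  expect_equal(fit$trace$objective[1], 0, tolerance = 1e-20)
})

test_that("small-mesh recovery moves inclusion resistance in the correct direction", {
  s <- 8L
  prot <- adjacent_protocol(rbind(c(1, 3), c(1, 6), c(3, 8), c(6, 8),
                                  c(8, 6), c(8, 3), c(6, 1), c(3, 1)), s)
  for (inc_ohms in c(0.5, 40)) {   # conductive and resistive inclusions
    spec <- phantom_spec(s, 10, list(circle_inclusion(c(65, 65), 20, inc_ohms)))
    truth <- generate_phantom(spec)
    frame <- simulate_measurements(truth, prot)
    fit <- eit_reconstruct(frame, prot, z0 = 10)  # |z0 - background| < 10
    tab <- resistor_table(fit$grid)
    inside <- in_inclusion(spec, tab$x_mm, tab$y_mm)
    if (inc_ohms < 10) {
      expect_lt(mean(coef(fit)[inside]), mean(coef(fit)[!inside]))
    } else {
      expect_gt(mean(coef(fit)[inside]), mean(coef(fit)[!inside]))
    }
    # noiseless runs keep the misfit non-increasing across iterations
    expect_true(all(diff(fit$trace$objective) <= 1e-15))
  }
})

test_that("reconstruction respects the positivity floor and records its trace", {
  s <- 6L
  prot <- small_protocol(s)
  spec <- phantom_spec(s, 5, list(circle_inclusion(c(65, 65), 30, 1e-3)))
  frame <- simulate_measurements(generate_phantom(spec), prot)
  fit <- eit_reconstruct(frame, prot, z0 = 5, max_iter = 3)
  expect_true(all(coef(fit) >= fit$config$z_floor))
  expect_identical(nrow(fit$trace), 3L)
  expect_identical(fit$converged_by, "max_iter")
  expect_true(all(fit$trace$objective >= 0))
  # tolerance-based stop on self-consistent data
  uframe <- simulate_measurements(eit_grid(s, 5, 5), prot)
  ufit <- eit_reconstruct(uframe, prot, z0 = 5, delta_tol = 1e-8)
  expect_identical(ufit$converged_by, "tolerance")
  expect_identical(nrow(ufit$trace), 1L)
})

test_that("fit accessors expose voltages, residuals and a readable summary", {
  s <- 6L
  prot <- small_protocol(s)
  spec <- phantom_spec(s, 5, list(circle_inclusion(c(65, 65), 25, 1)))
  frame <- simulate_measurements(generate_phantom(spec), prot)
  fit <- eit_reconstruct(frame, prot, z0 = 5)
  expect_length(fitted(fit), nrow(frame))
  expect_equal(residuals(fit), fitted(fit) - frame$voltage)
  expect_lt(sum(residuals(fit)^2) / 2, fit$trace$objective[1])
  expect_output(print(fit), "Modified Newton-Raphson")
  expect_output(print(summary(fit)), "Iteration trace")
  # frame/protocol mismatch is rejected
  expect_error(eit_reconstruct(frame, small_protocol(s, E = 5), z0 = 5),
               "measurement count")
})

test_that("a zero frequency-difference frame reconstructs to the uniform start", {
  s <- 6L
  prot <- small_protocol(s)
  g <- random_grid(s, seed = 8, lo = 4, hi = 6)
  fa <- simulate_measurements(g, prot, frequency_khz = 179)
  fb <- simulate_measurements(g, prot, frequency_khz = 1)
  d <- frequency_difference_frame(fa, fb)
  expect_true(all(d$voltage == 0))
  # reconstructing the (zero) difference against a uniform reference mesh:
  # the measured difference equals the uniform-mesh self-difference, so the
  # fixed point is z0. Emulated by reconstructing a frame whose voltages are
  # the uniform-mesh forward solution plus the (zero) difference.
  ref <- simulate_measurements(eit_grid(s, 5, 5), prot, frequency_khz = 179)
  target <- ref
  target$voltage <- ref$voltage + d$voltage
  fit <- eit_reconstruct(target, prot, z0 = 5)
  expect_equal(coef(fit), rep(5, num_resistors(s)), tolerance = 1e-10)
})
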