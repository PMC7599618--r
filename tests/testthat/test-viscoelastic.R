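test_that("tensor equilibrium sums back to the stress for any state", {
  tau0 <- c(1, 2, 3, 0.4, -0.5, 0.6)
  G <- tensor_equilibrium(tau0, c(0, 0, 0))
  expect_equal(G[, , 1], outer(d3q19_weights(), tau0))
  expect_equal(tensor_equilibrium(matrix(0, 3, 3), c(0.05, 0, 0))[, , 1],
               matrix(0, 19, 6))
  set.seed(3)
  for (k in 1:5) {
    tau <- matrix(rnorm(12), 6, 2)
    u <- matrix(runif(6, -0.08, 0.08), 3, 2)
    G <- tensor_equilibrium(tau, u)
    expect_equal(apply(G, 3, colSums), tau)  # velocity terms cancel exactly
  }
})

test_that("source tensor: relaxation limit and steady-shear fixed point", {
  spec <- polymer_spec(beta = 0.3, eta_t = 1 / 3, lambda_p = 100)
  expect_equal(source_tensor(matrix(0, 3, 3), matrix(0, 3, 3), spec),
               matrix(0, 3, 3))
  tau <- diag(c(1, 2, 3))
  expect_equal(source_tensor(tau, matrix(0, 3, 3), spec), -tau / 100)
  # steady simple shear is a fixed point: chi = 0 exactly
  gd <- 0.01
  gu <- matrix(0, 3, 3); gu[2, 1] <- gd   # (grad u)[y, x] = du_x/dy
  tau_ss <- matrix(0, 3, 3)
  tau_ss[1, 2] <- tau_ss[2, 1] <- spec$eta_p * gd
  tau_ss[1, 1] <- 2 * spec$lambda_p * spec$eta_p * gd^2
  chi <- source_tensor(tau_ss, gu, spec)
  expect_lt(max(abs(chi)), 1e-18)
  expect_error(source_tensor(tau, gu, polymer_spec(0.3, 1, 0)), "Newtonian")
})

test_that("recover_stress matches a brute-force per-node summation", {
  set.seed(11)
  G <- array(rnorm(19 * 6 * 4), c(19, 6, 4))
  tau <- recover_stress(G)
  for (n in 1:4) for (m in 1:6) {
    s <- 0
    for (a in 1:19) s <- s + G[a, m, n]
    expect_equal(tau[m, n], s)
  }
  expect_equal(recover_stress(array(0, c(19, 6, 2))), matrix(0, 6, 2))
})

test_that("tensor collide-and-stream: fixed point, relaxation, LBGK algebra", {
  spec <- polymer_spec(beta = 0.3, eta_t = 1 / 3, lambda_p = 50, lambda_g = 0.6)
  dims <- c(3, 3, 3); nn <- prod(dims)
  tau0 <- c(0.2, 0.1, -0.05, 0.03, 0, 0.01)
  u0 <- c(0.02, 0, -0.01)
  G <- tensor_equilibrium(matrix(tau0, 6, nn), matrix(u0, 3, nn))
  zero6 <- matrix(0, 6, nn)
  G1 <- tensor_collide_and_stream(G, dims, matrix(u0, 3, nn), zero6, zero6, spec)
  expect_equal(G1, G, tolerance = 1e-13)
  # pure relaxation tracks dtau/dt = -tau/lambda_p (2nd-order in dt).
  # chi_prev is warm-started at its t = 0 value so the two-step source
  # extrapolation has a consistent history from the first step.
  nstep <- 100
  tau <- matrix(tau0, 6, nn)
  G <- tensor_equilibrium(tau, matrix(0, 3, nn))
  chi_prev <- -tau / spec$lambda_p
  u <- matrix(0, 3, nn)
  gu <- array(0, c(3, 3, nn))
  norms <- numeric(nstep)
  for (k in 1:nstep) {
    tau <- recover_stress(G)
    chi <- source_tensor(tau, gu, spec)
    G <- tensor_collide_and_stream(G, dims, u, chi, chi_prev, spec)
    chi_prev <- chi
    norms[k] <- max(abs(recover_stress(G)))
  }
  expect_true(all(diff(norms) < 0))  # monotone decay
  expect_rel_equal(recover_stress(G)[, 1], tau0 * exp(-nstep / spec$lambda_p),
                   5e-3)
  # one collide without streaming scales the non-equilibrium by 1 - 1/lambda_g
  dims1 <- c(1, 1, 1)
  set.seed(5)
  G <- array(rnorm(19 * 6, sd = 0.01), c(19, 6, 1))
  tau <- recover_stress(G)
  Geq <- tensor_equilibrium(tau, c(0, 0, 0))
  G1 <- tensor_collide_and_stream(G, dims1, matrix(0, 3, 1),
                                  matrix(0, 6, 1), matrix(0, 6, 1), spec)
  expect_equal(G1 - Geq, (1 - 1 / spec$lambda_g) * (G - Geq), tolerance = 1e-12)
})

test_that("velocity gradient: exact on linear fields, 2nd-order on smooth ones", {
  dims <- c(6, 8, 5); nn <- prod(dims)
  u <- matrix(0.37, 3, nn)
  expect_equal(velocity_gradient(u, dims), array(0, c(3, 3, nn)))
  # u_x = a y: single exact entry at (grad)[y, x], checked away from the wrap
  a <- 0.002
  gy <- rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3])
  u <- rbind(a * gy, 0, 0)
  gu <- velocity_gradient(u, dims)
  interior <- gy > 1 & gy < dims[2]
  expect_equal(gu[2, 1, interior], rep(a, sum(interior)))
  expect_equal(max(abs(gu[c(1, 3), , interior])), 0)
  # smooth sine field: error drops ~4x when the grid is refined 2x
  err <- sapply(c(16, 32), function(n) {
    d <- c(4, n, 3)
    y <- rep(rep(seq_len(n), each = 4), times = 3)
    uu <- rbind(sin(2 * pi * y / n), 0, 0)
    g <- velocity_gradient(uu, d)
    max(abs(g[2, 1, ] - 2 * pi / n * cos(2 * pi * y / n)))
  })
  expect_gt(err[1] / err[2], 3.4)
})

test_that("elastic force equals the stress divergence", {
  dims <- c(5, 9, 9); nn <- prod(dims)
  tau <- matrix(0.3, 6, nn)
  expect_equal(elastic_force(tau, dims), matrix(0, 3, nn))
  # tau_xy = k y: F = (k, 0, 0) exactly in the interior
  gy <- rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3])
  gz <- rep(seq_len(dims[3]), each = dims[1] * dims[2])
  k <- 0.004
  tau <- matrix(0, 6, nn); tau[4, ] <- k * gy
  Fv <- elastic_force(tau, dims)
  interior <- gy > 1 & gy < dims[2]
  expect_equal(Fv[1, interior], rep(k, sum(interior)))
  expect_equal(max(abs(Fv[2:3, interior])), 0)
  # analytic tube stress: tau_xy = c y, tau_xz = c z, tau_xx quadratic
  # (x-independent) -> F = (2c, 0, 0); finite differences are exact here
  cc <- -0.002
  yc <- 5
  tau <- matrix(0, 6, nn)
  tau[4, ] <- cc * (gy - yc); tau[5, ] <- cc * (gz - yc)
  tau[1, ] <- 0.1 * ((gy - yc)^2 + (gz - yc)^2)
  Fv <- elastic_force(tau, dims)
  interior <- interior & gz > 1 & gz < dims[3]
  expect_equal(Fv[1, interior], rep(2 * cc, sum(interior)))
})
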