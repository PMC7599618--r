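test_that("channel geometry computes the characteristic length", {
  g <- channel_geometry(40e-6, w = 80e-6)
  expect_equal(g$L, 2 * 40e-6 * 80e-6 / (120e-6))
  expect_equal(g$AR, 0.5)
  expect_equal(channel_geometry(50e-6, AR = 1)$L, 50e-6)
  g <- channel_geometry(40e-6, AR = 1 / 4)
  expect_equal(g$w, 160e-6)
  expect_error(channel_geometry(40e-6), "w or AR")
})

test_that("wall extrapolation copies the non-equilibrium part verbatim", {
  # fluid neighbour exactly at equilibrium, resting wall -> wall equilibrium
  f_f <- drop(equilibrium_distribution(1.1, c(0, 0, 0)))
  expect_equal(wall_populations_f(f_f, 1.1, c(0, 0, 0)),
               drop(equilibrium_distribution(1.1, c(0, 0, 0))))
  # arbitrary state: non-equilibrium parts agree by construction
  set.seed(9)
  f_f <- drop(equilibrium_distribution(1.05, c(0.02, 0.01, 0))) + rnorm(19, sd = 1e-3)
  u_f <- c(0.02, 0.01, 0)
  fw <- wall_populations_f(f_f, 1.05, u_f, u_w = c(0.01, 0, 0))
  neq_wall <- fw - drop(equilibrium_distribution(1.05, c(0.01, 0, 0)))
  neq_fluid <- f_f - drop(equilibrium_distribution(1.05, u_f))
  expect_equal(neq_wall, neq_fluid)
  # tensor analogue with zero fluid stress and resting wall
  Gf <- tensor_equilibrium(rep(0, 6), c(0.02, 0, 0))[, , 1]
  expect_equal(wall_populations_G(Gf, rep(0, 6), c(0.02, 0, 0)),
               matrix(0, 19, 6))
})

test_that("driving acceleration follows the Poiseuille relation", {
  expect_equal(driving_acceleration(0, 1e-6, 50e-6), 0)
  # nu = 1e-6 m2/s, Re = 1, L = 50 um (independent arithmetic: 256 m/s2)
  expect_equal(driving_acceleration(1, 1e-6, 50e-6),
               32 * 1e-12 / 1.25e-13)
  expect_equal(driving_acceleration(1, 1e-6, 50e-6), 256)
  a1 <- driving_acceleration(2.5, 3e-6, 40e-6)
  expect_equal(driving_acceleration(2.5, 3e-6, 80e-6), a1 / 8)
})

test_that("domain builders classify nodes and assign wall neighbours", {
  d <- duct_domain(4, 7, 9)
  ty <- array(d$node_type, d$dims)
  expect_true(all(ty[, c(1, 7), ] == 1L), all(ty[, , c(1, 9)] == 1L))
  expect_true(all(ty[, 2:6, 2:8] == 0L))
  # corner wall nodes extrapolate from the diagonal interior neighbour
  corner <- viscolbm:::node_index(d$dims, 2L, 1L, 1L)
  expect_equal(d$wall_nbr[corner], viscolbm:::node_index(d$dims, 2L, 2L, 2L))
  # edge wall nodes use the inward normal
  edge <- viscolbm:::node_index(d$dims, 2L, 1L, 5L)
  expect_equal(d$wall_nbr[edge], viscolbm:::node_index(d$dims, 2L, 2L, 5L))
  # tube: closed wall layer, plausible effective radius
  tb <- tube_domain(3, 6.5)
  expect_equal(tb$meta$r_eff, 7.0)
  expect_true(all(tb$wall_nbr[tb$node_type == 1L] > 0))
  # every fluid node's stencil neighbours are fluid or wall, never inactive
  dirs <- d3q19_directions(); dims <- tb$dims
  ty <- tb$node_type
  gx <- rep(seq_len(dims[1]), times = prod(dims[2:3]))
  gy <- rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3])
  gz <- rep(seq_len(dims[3]), each = prod(dims[1:2]))
  fl <- which(ty == 0L)
  for (a in 2:19) {
    nb <- viscolbm:::node_index(dims,
      (gx[fl] + dirs[1, a] - 1) %% dims[1] + 1,
      (gy[fl] + dirs[2, a] - 1) %% dims[2] + 1,
      (gz[fl] + dirs[3, a] - 1) %% dims[3] + 1)
    expect_true(all(ty[nb] != 2L))
  }
})

test_that("shear box drives a linear Couette profile (Newtonian)", {
  cfg <- sim_config(list(kind = "shear_box", u_wall = 0.02, gap = 12),
                    Wi = 0, beta = 1, nx = 8, steps = 3000,
                    record_every = 1000, diag_every = 1000)
  run <- run_simulation(cfg)
  dims <- run$domain$dims
  gd <- run$domain$meta$shear_rate
  ua <- array(run$fields$u[1, ], dims)
  yc <- (1 + dims[2]) / 2
  prof <- ua[1, , 4]
  expect_lt(max(abs(prof - gd * (seq_len(dims[2]) - yc))), 0.01 * 0.02)
  # quiescent box stays quiescent
  cfg0 <- sim_config(list(kind = "shear_box", u_wall = 0, gap = 12),
                     Wi = 0, beta = 1, nx = 8, steps = 50,
                     record_every = 50, diag_every = 50)
  expect_lt(run_simulation(cfg0)$summary$max_u, 1e-14)
})

test_that("Oldroyd-B Couette reaches the uniform analytic shear stress", {
  cfg <- sim_config(list(kind = "shear_box", u_wall = 0.02, gap = 12),
                    Wi = 0.5, beta = 0.3, nx = 8, steps = 2500,
                    record_every = 1000, diag_every = 1000)
  run <- run_simulation(cfg)
  dims <- run$domain$dims
  gd <- run$domain$meta$shear_rate
  calib <- run$calibration
  txy <- array(run$fields$tau[4, ], dims)[1, 2:(dims[2] - 1), 4]
  expect_lt(max(abs(txy - calib$eta_p * gd)) / (calib$eta_p * gd), 0.02)
})

test_that("driven duct flow is x-invariant and mirror-symmetric", {
  cfg <- sim_config(channel_geometry(12e-6, AR = 1), Re = 0.5, Wi = 0,
                    beta = 1, nx = 4, steps = 2500,
                    record_every = 1000, diag_every = 1000)
  run <- run_simulation(cfg)
  dims <- run$domain$dims
  ua <- array(run$fields$u[1, ], dims)
  ucl <- ua[1, (dims[2] + 1) / 2, (dims[3] + 1) / 2]
  # translation invariance along the flow axis
  xvar <- max(apply(ua, c(2, 3), function(v) diff(range(v))))
  expect_lt(xvar, 1e-10 * ucl)
  # mirror symmetry about both cross-section midlines
  expect_lt(max(abs(ua[1, , ] - ua[1, rev(seq_len(dims[2])), ])), 1e-12 * ucl)
  expect_lt(max(abs(ua[1, , ] - ua[1, , rev(seq_len(dims[3]))])), 1e-12 * ucl)
})
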