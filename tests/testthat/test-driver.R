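test_that("lattice calibration inverts the viscosity relation", {
  cfg <- sim_config(channel_geometry(40e-6, AR = 1), Re = 1, Wi = 0.3,
                    beta = 0.3)
  calib <- lattice_calibration(cfg)
  # nu = 1e-6 m2/s, dx = 1e-6 m, dt = 1e-7 s -> lambda = 1/2 + 0.3 = 0.8
  expect_equal(calib$lambda_f, 0.8)
  # round trip: viscosity recomputed from lambda reproduces the input
  expect_equal((calib$lambda_f - 1 / 2) / 3 * cfg$dx^2 / cfg$dt, cfg$nu)
  expect_equal(calib$nu_t, calib$nu_s / 0.3)
  expect_equal(calib$U, calib$groups$Re * calib$nu_t / calib$L)
  expect_gt(calib$lambda_p, 0)
  # zero and excessive viscosity are rejected
  expect_error(lattice_calibration(sim_config(channel_geometry(40e-6, AR = 1),
                                              nu = 0)), "stability")
  expect_error(lattice_calibration(sim_config(channel_geometry(40e-6, AR = 1),
                                              nu = 6e-6)), "stability")
})

test_that("analytic Poiseuille fixture identities", {
  p <- analytic_poiseuille(0, a = 1e-4, nu_t = 1 / 3, beta = 0.3,
                           lambda_p = 400, R = 10, geometry = "tube")
  expect_equal(p$tau_xx, 0)  # centreline: no shear
  expect_equal(p$tau_xy, 0)
  y <- seq(-9, 9, by = 1.5)
  p <- analytic_poiseuille(y, 1e-4, 1 / 3, 0.3, 400, 10, "tube")
  # eliminate du/dy between the two stress components
  eta_p <- (1 - 0.3) / 3
  expect_equal(p$tau_xx, 2 * 400 * p$tau_xy^2 / eta_p)
  # Newtonian limit: tau_xx -> 0, tau_xy unchanged
  p0 <- analytic_poiseuille(y, 1e-4, 1 / 3, 0.3, 0, 10, "tube")
  expect_equal(p0$tau_xx, rep(0, length(y)))
  expect_equal(p0$tau_xy, p$tau_xy)
  # planar variant uses the half-channel curvature
  pp <- analytic_poiseuille(y, 1e-4, 1 / 3, 0.3, 400, 10, "planar")
  expect_equal(pp$u, p$u * 2)
})

test_that("zero-step run returns the initial snapshot only", {
  cfg <- sim_config(channel_geometry(10e-6, AR = 1), Re = 0.5, Wi = 0,
                    beta = 1, nx = 4, steps = 0)
  run <- run_simulation(cfg)
  expect_equal(run$summary$steps_done, 0)
  expect_equal(run$fields$rho[run$domain$node_type == 0L],
               rep(1, sum(run$domain$node_type == 0L)))
  expect_equal(nrow(run$diagnostics), 1)
})

test_that("compiled stepper reproduces the composed R operations", {
  # fluid-only viscoelastic duct
  tt <- tiny_setup(with_particle = FALSE)
  st_r <- tt$state
  for (i in 1:4) st_r <- reference_step(st_r, tt$setup)
  st_c <- viscolbm:::cpp_run(tt$state, tt$setup, 4L, 1L, 4L)$state
  expect_lt(max(abs(st_r$f - st_c$f)), 1e-13)
  expect_lt(max(abs(st_r$G - st_c$G)), 1e-15)
  expect_lt(max(abs(st_r$chi_prev - st_c$chi_prev)), 1e-15)
  # with an immersed particle (exercises membrane + IBM coupling)
  tt <- tiny_setup(with_particle = TRUE)
  st_r <- tt$state
  for (i in 1:3) st_r <- reference_step(st_r, tt$setup)
  st_c <- viscolbm:::cpp_run(tt$state, tt$setup, 3L, 1L, 3L)$state
  expect_lt(max(abs(st_r$f - st_c$f)), 1e-13)
  expect_lt(max(abs(st_r$G - st_c$G)), 1e-15)
  expect_lt(max(abs(st_r$X - st_c$X)), 1e-12)
})

test_that("configuration validation", {
  expect_error(sim_config(channel_geometry(20e-6, AR = 1),
                          particles = list(list(), list())), "single-particle")
  expect_error(sim_config(channel_geometry(20e-6, AR = 1), Wi = 0.3, beta = 1),
               "beta")
  cfg <- sim_config(channel_geometry(10e-6, AR = 1), Re = 0.5, Wi = 0, beta = 1,
                    particles = list(list(diameter = 8e-6, n_faces = 120,
                                          yz0 = c(0, 0))), steps = 1)
  expect_error(run_simulation(cfg), "does not fit")
})

test_that("presets reproduce the published channel dimensions", {
  cfg <- preset_config("AR1")
  expect_equal(cfg$geometry$h, 50e-6)
  expect_equal(cfg$geometry$w, 50e-6)
  cfg <- preset_config("AR1_3")
  expect_equal(cfg$geometry$w, 120e-6)
  expect_equal(lattice_calibration(cfg)$L, 2 * 40 * 120 / 160)
  cfg <- preset_config("AR1_2", coarse = TRUE)
  expect_equal(cfg$geometry$ny, 25L)  # ~24 lattice nodes across the height
})

test_that("figure presets encode the published parameter grid", {
  cfg <- figure_preset("fig5c")
  expect_equal(cfg$Re, 1)
  expect_equal(cfg$Wi, 0.3)
  expect_equal(cfg$geometry$h, 50e-6)
  expect_equal(cfg$steps, 1200000L)
  # El is authoritative where a caption's Wi disagrees: fig6a has El=0.01
  cfg <- figure_preset("fig6a")
  expect_equal(cfg$Wi / cfg$Re, 0.01)
  # the 12 um particles use the 480-face mesh
  expect_equal(figure_preset("fig9b")$particles[[1]]$n_faces, 480)
  expect_equal(figure_preset("fig11d", coarse = TRUE)$Wi, 0.6)
  expect_error(figure_preset("fig99"), "unknown preset")
})

test_that("mesh and flow writers produce readable files", {
  m <- generate_sphere_mesh(5, 120)
  off <- tempfile(fileext = ".off")
  write_off(m, off)
  m2 <- read_off(off)
  expect_equal(m2$nodes, m$nodes, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(m2$faces, m$faces, ignore_attr = TRUE)
  ply <- tempfile(fileext = ".ply")
  write_ply(m, ply)
  expect_equal(readLines(ply)[1], "ply")
  cfg <- sim_config(channel_geometry(10e-6, AR = 1), Re = 0.5, Wi = 0,
                    beta = 1, nx = 4, steps = 10)
  run <- run_simulation(cfg)
  vtk <- tempfile(fileext = ".vtk")
  write_vtk_snapshot(run, vtk)
  lines <- readLines(vtk)
  expect_equal(lines[4], "DATASET STRUCTURED_POINTS")
  expect_equal(sum(lines == "LOOKUP_TABLE default"), 9)  # rho, p, 6 tau, N1
  expect_equal(length(grep("^VECTORS velocity", lines)), 1)
})

test_that("CLI subcommands work end to end", {
  off <- tempfile(fileext = ".off")
  expect_output(viscolbm_cli(c("mesh", "--diameter", "6", "--faces", "120",
                               "--out", off)), "wrote")
  expect_equal(nrow(read_off(off)$faces), 120)
  expect_output(ret <- viscolbm_cli("validate"), "passed")
  expect_equal(ret, 0L)
  tr <- data.frame(y = rep(0.1, 200), z = rep(-0.2, 200))
  csv <- tempfile(fileext = ".csv")
  write.csv(tr, csv, row.names = FALSE)
  expect_output(viscolbm_cli(c("analyze", "--trajectory", csv)), "converged: TRUE")
})
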