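# Shared fixture builders. Everything is generated in code; no data files.

# Tiny viscoelastic duct setup (internal plumbing) used by the
# reference-vs-compiled stepper tests.
tiny_setup <- function(with_particle = FALSE, Wi = 0.3) {
  cfg <- sim_config(channel_geometry(10e-6, AR = 1, dx = 1e-6),
                    Re = 0.5, Wi = Wi, beta = 0.3, nx = 8,
                    particles = if (with_particle) {
                      list(list(diameter = 4e-6, n_faces = 120, yz0 = c(-0.2, 0.1)))
                    } else list(),
                    steps = 3, record_every = 1, diag_every = 1)
  calib <- lattice_calibration(cfg)
  domain <- viscolbm:::build_domain(cfg, calib)
  mesh <- viscolbm:::build_particle(cfg, calib, domain)
  setup <- viscolbm:::build_setup(cfg, calib, domain, mesh)
  state <- viscolbm:::init_state(domain, mesh, setup$visco)
  list(cfg = cfg, calib = calib, domain = domain, mesh = mesh,
       setup = setup, state = state)
}

# random positive population field a bit away from equilibrium
random_f <- function(nn, seed = 1) {
  set.seed(seed)
  matrix(d3q19_weights(), 19, nn) * (1 + 0.05 * matrix(runif(19 * nn, -1, 1), 19, nn))
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(abs(y), 1e-300), tol)
}
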