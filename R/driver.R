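# Run orchestration: build the domain, initialise both distribution
# sets, hand the state to the fused C++ stepper, and package trajectory,
# diagnostics and field outputs.

build_domain <- function(cfg, calib) {
  g <- cfg$geometry
  has_p <- length(cfg$particles) > 0
  d_l <- if (has_p) cfg$particles[[1]]$diameter / cfg$dx else 0
  nx <- cfg$nx
  if (is.null(nx)) nx <- if (has_p) max(16L, as.integer(ceiling(d_l)) + 10L) else 4L
  switch(g$kind,
    duct = duct_domain(nx, g$ny, g$nz),
    tube = tube_domain(nx, g$diameter / cfg$dx / 2),
    shear_box = shear_box(g$u_wall, g$gap, nx = nx, nz = nx))
}

# Cross-section centre and half extents of a domain, in lattice coords.
domain_frame <- function(domain) {
  if (domain$kind == "tube") {
    c0 <- domain$meta$centre
    list(centre = c0, half = rep(domain$meta$radius, 2))
  } else {
    ny <- domain$dims[2]; nz <- domain$dims[3]
    list(centre = c((1 + ny) / 2, (1 + nz) / 2),
         half = c((ny - 1) / 2, (nz - 1) / 2))
  }
}

build_particle <- function(cfg, calib, domain) {
  if (!length(cfg$particles)) return(NULL)
  p <- cfg$particles[[1]]
  # a prebuilt mesh (lattice units, already positioned) takes precedence;
  # used e.g. for mirrored paired runs
  if (!is.null(p$mesh)) return(p$mesh)
  d_l <- p$diameter / cfg$dx
  fr <- domain_frame(domain)
  if (domain$kind != "shear_box" &&
      d_l / 2 + 2 > min(fr$half)) {
    stop("particle does not fit: d/2 + 2 dx must stay below the half extent")
  }
  yz0 <- if (is.null(p$yz0)) c(0, 0) else p$yz0
  centre <- c((1 + domain$dims[1]) / 2,
              fr$centre[1] + yz0[1] * fr$half[1],
              fr$centre[2] + yz0[2] * fr$half[2])
  moduli <- if (is.null(p$moduli)) rigid_moduli() else p$moduli
  mesh <- generate_sphere_mesh(d_l, n_faces = p$n_faces,
                               moduli = moduli_to_lattice(moduli, calib$scale),
                               centre = centre)
  mesh
}

build_setup <- function(cfg, calib, domain, mesh) {
  nn <- prod(domain$dims)
  setup <- list(
    dims = domain$dims, node_type = domain$node_type,
    wall_nbr = ifelse(is.na(domain$wall_nbr), -1L,
                      domain$wall_nbr - 1L),
    wall_u = domain$wall_u,
    lambda_f = calib$lambda_f, visco = !calib$newtonian,
    lambda_g = calib$lambda_g, lambda_p = calib$lambda_p,
    eta_p = calib$eta_p, accel = calib$accel,
    has_particle = !is.null(mesh),
    check_every = 200L, max_u_warn = 0.1, max_u_abort = 0.3)
  if (!is.null(mesh)) {
    setup$faces <- mesh$faces - 1L
    setup$edges <- mesh$edges - 1L
    setup$refM <- mesh$ref$M
    setup$A0f <- mesh$ref$A0f
    setup$phi0 <- mesh$ref$phi0
    setup$A0 <- mesh$ref$A0
    setup$V0 <- mesh$ref$V0
    setup$moduli <- unlist(mesh$moduli[c("ks", "kalpha", "kb", "ka", "kv")])
  }
  setup
}

init_state <- function(domain, mesh, visco, calib = NULL, init = "rest") {
  nn <- prod(domain$dims)
  dims <- domain$dims
  if (init == "couette" && domain$kind == "shear_box") {
    # start from the developed Couette state: linear velocity profile and
    # (for Oldroyd-B) the uniform steady simple-shear stress, which is a
    # fixed point of the constitutive update. Cuts the start-up transient
    # from gap^2/nu steps to the particle spin-up time.
    gd <- domain$meta$shear_rate
    yc <- (1 + dims[2]) / 2
    gy <- rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3])
    u <- rbind(gd * (gy - yc), 0, 0)
    f <- equilibrium_distribution(rep(1, nn), u, warn = FALSE)
    G <- numeric(0)
    if (visco) {
      tau0 <- c(2 * calib$lambda_p * calib$eta_p * gd^2, 0, 0,
                calib$eta_p * gd, 0, 0)
      G <- as.numeric(tensor_equilibrium(matrix(tau0, 6, nn), u))
    }
    return(list(f = as.numeric(f), G = G, chi_prev = numeric(6 * nn),
                X = if (is.null(mesh)) matrix(0, 0, 3) else mesh$nodes,
                step = 0L))
  }
  f <- matrix(d3q19_weights(), 19, nn)
  f[, domain$node_type == NODE_INACTIVE] <- 0
  list(f = as.numeric(f),
       G = if (visco) numeric(114 * nn) else numeric(0),
       chi_prev = numeric(6 * nn),
       X = if (is.null(mesh)) matrix(0, 0, 3) else mesh$nodes,
       step = 0L)
}

#' Run a simulation
#'
#' Initialises the solvent at rest at unit density (f at equilibrium),
#' the polymer stress at zero, releases the particle (if any) at its
#' configured cross-section position at zero velocity, and advances the
#' coupled LBM/IBM loop in compiled code. Reruns from a checkpointed
#' state are bit-identical to uninterrupted runs (the method has no
#' stochastic element).
#'
#' @param cfg A [sim_config()].
#' @param state Optional state list from a previous run (resume).
#' @param steps Number of steps (defaults to `cfg$steps`).
#' @param out_dir Optional directory: writes `trajectory.csv`, a final
#'   VTK snapshot and an RDS checkpoint there.
#' @return Object of class `viscolbm_run`: `config`, `calibration`,
#'   `domain`, `mesh`, `state` (for resuming), `trajectory` (data frame),
#'   `diagnostics` (data frame), `fields` (rho, u, tau, N1 on the final
#'   step), `summary` (nominal vs measured groups, extrema).
#' @export
run_simulation <- function(cfg, state = NULL, steps = NULL, out_dir = NULL) {
  calib <- lattice_calibration(cfg)
  domain <- build_domain(cfg, calib)
  mesh <- build_particle(cfg, calib, domain)
  setup <- build_setup(cfg, calib, domain, mesh)
  init <- if (is.null(cfg$geometry$init)) "rest" else cfg$geometry$init
  if (is.null(state)) state <- init_state(domain, mesh, setup$visco, calib, init)
  if (is.null(steps)) steps <- cfg$steps
  res <- cpp_run(state, setup, as.integer(steps),
                 as.integer(cfg$record_every), as.integer(cfg$diag_every))
  if (res$max_u_seen > setup$max_u_warn) {
    warning(sprintf("max |u| = %.3g exceeded 0.1 c during the run",
                    res$max_u_seen))
  }
  fr <- domain_frame(domain)
  traj <- as.data.frame(res$traj)
  names(traj) <- c("step", "x", "y", "z", "Px", "Py", "Pz")
  if (nrow(traj)) {
    traj$y_n <- (traj$y - fr$centre[1]) / fr$half[1]
    traj$z_n <- (traj$z - fr$centre[2]) / fr$half[2]
    ang <- rotation_angles(as.matrix(traj[, c("Px", "Py", "Pz")]))
    ang <- if (is.matrix(ang)) ang else matrix(ang, 1, 3)
    traj$theta_x <- ang[, 1]; traj$theta_y <- ang[, 2]; traj$theta_z <- ang[, 3]
    om <- rotation_speed(as.matrix(traj[, c("Px", "Py", "Pz")]),
                         dt_sample = cfg$record_every)
    traj$omega <- c(NA_real_, om)
  }
  diag <- as.data.frame(res$diag)
  names(diag) <- c("step", "mass", "mean_ux", "max_u", "max_tau")
  fluid <- domain$node_type == NODE_FLUID
  u <- res$fields$u
  U_meas <- mean(u[1, fluid])
  groups <- if (domain$kind == "shear_box") calib$groups else
    dimensionless_groups(cfg$Re, cfg$Wi, calib$L, calib$nu_t, calib$U,
                         d = if (!is.null(mesh)) cfg$particles[[1]]$diameter else NULL,
                         h = if (cfg$geometry$kind == "duct") cfg$geometry$h else NULL,
                         U_measured = U_meas)
  tau <- res$fields$tau
  n1 <- first_normal_stress_difference(tau, "y")
  out <- structure(list(
    config = cfg, calibration = calib, domain = domain, mesh = mesh,
    state = res$state, trajectory = traj, diagnostics = diag,
    fields = list(rho = res$fields$rho, u = u, tau = tau, N1 = n1,
                  pressure = res$fields$rho / 3),
    summary = list(groups = groups, U_measured = U_meas,
                   max_u = res$max_u_seen, steps_done = res$state$step)
  ), class = "viscolbm_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trajectory_csv(out, file.path(out_dir, "trajectory.csv"))
    write_vtk_snapshot(out, file.path(out_dir,
      sprintf("snapshot_%07d.vtk", res$state$step)))
    save_checkpoint(out, file.path(out_dir,
      sprintf("checkpoint_%07d.rds", res$state$step)))
  }
  out
}

#' @export
print.viscolbm_run <- function(x, ...) {
  g <- x$summary$groups
  cat("<viscolbm_run>", x$domain$kind, paste(x$domain$dims, collapse = "x"),
      "steps:", x$summary$steps_done, "\n")
  cat(sprintf("  nominal  Re = %.4g, Wi = %.4g\n", g$Re, g$Wi))
  if (!is.null(g$Re_measured)) {
    cat(sprintf("  measured Re = %.4g, Wi = %.4g, El = %.4g\n",
                g$Re_measured, g$Wi_measured, g$El_measured))
  }
  cat(sprintf("  max |u| = %.4g c\n", x$summary$max_u))
  invisible(x)
}

#' One reference step of the coupled loop (pure R composition)
#'
#' Composes the exported module operations (moments, forcing, both
#' collide-and-stream updates, wall extrapolation, stress divergence,
#' IBM spreading/interpolation/advection) into a single step, in the
#' exact phase order of the production C++ stepper. Used to validate the
#' fused stepper; far too slow for production runs.
#'
#' @param state State list as produced by [run_simulation()]'s `state`.
#' @param setup Internal setup list (see tests for construction).
#' @return Updated state list.
#' @export
reference_step <- function(state, setup) {
  dims <- setup$dims; nn <- prod(dims)
  type <- setup$node_type
  fluid <- type == NODE_FLUID; wall <- type == NODE_WALL
  active <- type != NODE_INACTIVE
  f <- matrix(state$f, 19, nn)
  visco <- isTRUE(setup$visco)
  G <- if (visco) array(state$G, c(19, 6, nn)) else NULL
  tau <- if (visco) recover_stress(G) else matrix(0, 6, nn)
  # moments without force
  rho <- colSums(f)
  rho[!active] <- 1
  u <- sweep(d3q19_directions() %*% f, 2, rho, "/")
  # total force on fluid nodes
  F <- matrix(0, 3, nn)
  F[1, fluid] <- rho[fluid] * setup$accel
  if (visco) {
    # wall stress is a zeroth-order copy; differentiate fluid values only
    Fv <- elastic_force(tau, dims, usable = fluid)
    F[, fluid] <- F[, fluid] + Fv[, fluid]
  }
  if (isTRUE(setup$has_particle)) {
    mesh <- list(faces = setup$faces + 1L, edges = setup$edges + 1L,
                 ref = list(M = setup$refM, A0f = setup$A0f,
                            phi0 = setup$phi0, A0 = setup$A0, V0 = setup$V0),
                 moduli = as.list(setup$moduli))
    names(mesh$moduli) <- c("ks", "kalpha", "kb", "ka", "kv")
    class(mesh) <- "membrane_mesh"
    fn <- nodal_forces(mesh, state$X)
    FA <- spread_forces(state$X, fn, dims)
    F[, fluid] <- F[, fluid] + FA[, fluid]
  }
  # half-force corrected velocity; walls carry the wall velocity
  u <- u + sweep(F, 2, 2 * rho, "/")
  u[, wall] <- setup$wall_u[, wall]
  u[, !active] <- 0
  chi_prev <- matrix(state$chi_prev, 6, nn)
  if (visco) {
    gu <- velocity_gradient(u, dims, usable = active)
    chi <- source_tensor_raw(tau, gu, setup$eta_p, setup$lambda_p)
    chi[, !active] <- 0
    eff <- 1.5 * chi - 0.5 * chi_prev
  }
  sources <- stream_sources(dims)
  # solvent collide + wall extrapolation + stream
  feq <- equilibrium_distribution(rho, u, warn = FALSE)
  fpost <- f + (feq - f) / setup$lambda_f + force_term(u, F, setup$lambda_f)
  if (any(wall)) {
    widx <- which(wall); nb <- setup$wall_nbr[widx] + 1L
    feq_w <- equilibrium_distribution(rho[nb], setup$wall_u[, widx, drop = FALSE],
                                      warn = FALSE)
    fpost[, widx] <- feq_w +
      (1 - 1 / setup$lambda_f) * (f[, nb, drop = FALSE] -
                                    feq[, nb, drop = FALSE])
  }
  fpost[, !active] <- 0
  fnew <- fpost
  for (a in 1:19) fnew[a, ] <- fpost[a, sources[a, ]]
  out <- list(f = as.numeric(fnew))
  if (visco) {
    Geq <- tensor_equilibrium(tau, u)
    kap <- (setup$lambda_g - 1 / 2) / setup$lambda_g
    cu <- crossprod(d3q19_directions(), u)
    wprof <- d3q19_weights() * (1 + 3 * kap * cu)
    Gpost <- G + (Geq - G) / setup$lambda_g
    for (m in 1:6) {
      Gpost[, m, ] <- Gpost[, m, ] + wprof * rep(eff[m, ], each = 19)
    }
    if (any(wall)) {
      widx <- which(wall); nb <- setup$wall_nbr[widx] + 1L
      Geq_w <- tensor_equilibrium(tau[, nb, drop = FALSE],
                                  setup$wall_u[, widx, drop = FALSE])
      Gpost[, , widx] <- Geq_w +
        (1 - 1 / setup$lambda_g) * (G[, , nb, drop = FALSE] -
                                      Geq[, , nb, drop = FALSE])
    }
    Gpost[, , !active] <- 0
    Gnew <- Gpost
    for (a in 1:19) Gnew[a, , ] <- Gpost[a, , sources[a, ]]
    out$G <- as.numeric(Gnew)
    out$chi_prev <- as.numeric(chi)
  } else {
    out$G <- numeric(0)
    out$chi_prev <- state$chi_prev
  }
  if (isTRUE(setup$has_particle)) {
    # post-update velocity (half-force correction reuses F(t))
    rho_new <- colSums(fnew)
    rho_new[!active] <- 1
    u_new <- sweep(d3q19_directions() %*% fnew + F / 2, 2, rho_new, "/")
    u_new[, wall] <- setup$wall_u[, wall]
    u_new[, !active] <- 0
    up <- interpolate_velocity(u_new, state$X, dims)
    # unwrapped advection: wrapping individual nodes would tear the mesh
    if (max(abs(up)) > 0.5) stop("stability error: node displacement > 0.5 dx")
    out$X <- state$X + up
  } else {
    out$X <- state$X
  }
  out$step <- state$step + 1L
  out
}

# source tensor from raw lattice parameters (no polymer_spec needed)
source_tensor_raw <- function(tau, gu, eta_p, lambda_p) {
  nn <- ncol(tau)
  chi <- matrix(0, 6, nn)
  for (m in 1:6) {
    i <- SYM_I[m]; j <- SYM_J[m]
    acc <- numeric(nn)
    for (k in 1:3) {
      acc <- acc + tau[SYM_MAP[i, k], ] * gu[k, j, ] +
        gu[k, i, ] * tau[SYM_MAP[k, j], ]
    }
    dij <- (gu[i, j, ] + gu[j, i, ]) / 2
    chi[m, ] <- acc + (2 * eta_p * dij - tau[m, ]) / lambda_p
  }
  chi
}

#' Analytic steady Poiseuille solution for an Oldroyd-B fluid
#'
#' Velocity and polymer stresses of body-force-driven flow, for a
#' circular tube of radius R (coordinate r) or a planar channel of half
#' height R (coordinate y):
#' u = a (R^2 - y^2) / (k nu_t) with k = 4 (tube) or 2 (planar),
#' tau_xx = 2 lambda_p eta_t (1 - beta) (du/dy)^2,
#' tau_xy = eta_t (1 - beta) (du/dy). Unit density, so eta_t = nu_t.
#'
#' @param y Wall-normal (or radial) coordinate, vectorised.
#' @param a Driving acceleration.
#' @param nu_t Total kinematic viscosity.
#' @param beta Viscosity ratio; `beta = 1` gives zero polymer stress.
#' @param lambda_p Polymer relaxation time.
#' @param R Tube radius / channel half height.
#' @param geometry `"tube"` or `"planar"`.
#' @return List with `u`, `dudy`, `tau_xx`, `tau_xy`.
#' @export
analytic_poiseuille <- function(y, a, nu_t, beta, lambda_p, R,
                                geometry = c("tube", "planar")) {
  geometry <- match.arg(geometry)
  k <- if (geometry == "tube") 4 else 2
  u <- a * (R^2 - y^2) / (k * nu_t)
  dudy <- -2 * a * y / (k * nu_t)
  eta_p <- (1 - beta) * nu_t
  list(u = u, dudy = dudy,
       tau_xx = 2 * lambda_p * eta_p * dudy^2,
       tau_xy = eta_p * dudy)
}
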