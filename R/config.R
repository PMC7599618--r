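# Simulation configuration and physical-to-lattice calibration.
#
# Inputs are SI; the solver works in lattice units with dx = dt = 1 and
# unit density. The config `nu` is the SOLVENT kinematic viscosity: it is
# the quantity the LBGK relaxation time controls (nu = (lambda - 1/2)/3
# in lattice units), while the dimensionless groups Re and Wi are defined
# with the TOTAL viscosity nu_t = nu / beta, and the driving acceleration
# a = 32 nu_t^2 Re / L^3 targets the mean velocity U = Re nu_t / L of a
# circular pipe (re-measured for ducts).

#' Build a simulation configuration
#'
#' @param geometry A [channel_geometry()], or a list like
#'   `list(kind = "tube", diameter = 21e-6)` (SI diameter) or
#'   `list(kind = "shear_box", u_wall = 0.4, gap = 21)` (lattice units).
#' @param Re Target Reynolds number (total-viscosity based).
#' @param Wi Target Weissenberg number; `Wi = 0` selects Newtonian mode.
#' @param beta Solvent/total viscosity ratio (ignored in Newtonian mode).
#' @param nu Solvent kinematic viscosity in m^2/s.
#' @param dx,dt Lattice spacing (m) and time step (s).
#' @param rho0 Physical fluid density (kg/m^3), used only to convert the
#'   membrane moduli; particles are neutrally buoyant.
#' @param lambda_g Tensor-lattice relaxation parameter (> 1/2; default
#'   0.505, see [polymer_spec()]).
#' @param particles List of particle specs, each
#'   `list(diameter =, n_faces =, yz0 = c(y, z), moduli = rigid_moduli())`
#'   with `yz0` in normalised cross-section coordinates. At most one
#'   particle (the method is single-particle, as published).
#' @param steps Number of lattice steps to run.
#' @param record_every Trajectory sampling cadence (steps).
#' @param diag_every Physics-digest cadence (steps).
#' @param nx Lattice extent along the flow axis; default 4 without a
#'   particle, `ceiling(d) + 10` with one.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(geometry, Re = 1, Wi = 0, beta = 0.3, nu = 1e-6,
                       dx = 1e-6, dt = 1e-7, rho0 = 1000, lambda_g = 0.505,
                       particles = list(), steps = 1000L,
                       record_every = 100L, diag_every = 1000L, nx = NULL) {
  if (inherits(geometry, "channel_geometry")) {
    geometry <- c(list(kind = "duct"), unclass(geometry))
  }
  stopifnot(geometry$kind %in% c("duct", "tube", "shear_box"))
  if (length(particles) > 1) {
    stop("single-particle simulations only; got ", length(particles))
  }
  if (Wi > 0 && (beta <= 0 || beta >= 1)) {
    stop("viscoelastic mode needs 0 < beta < 1")
  }
  structure(list(geometry = geometry, Re = Re, Wi = Wi, beta = beta,
                 nu = nu, dx = dx, dt = dt, rho0 = rho0,
                 lambda_g = lambda_g, particles = particles,
                 steps = as.integer(steps),
                 record_every = as.integer(record_every),
                 diag_every = as.integer(diag_every), nx = nx),
            class = "sim_config")
}

#' Named channel presets
#'
#' `"AR1"` is the 50 x 50 micron square channel; `"AR1_2"`, `"AR1_3"`,
#' `"AR1_4"` are the 40 micron high rectangular channels of width
#' h / AR. `coarse = TRUE` scales the cross-section to roughly 24 lattice
#' nodes (desk resolution) by enlarging dx while keeping the
#' dimensionless groups fixed.
#'
#' @param name One of "AR1", "AR1_2", "AR1_3", "AR1_4".
#' @param coarse Use the coarse desk resolution.
#' @param ... Passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
preset_config <- function(name = c("AR1", "AR1_2", "AR1_3", "AR1_4"),
                          coarse = FALSE, ...) {
  name <- match.arg(name)
  geom <- switch(name,
    AR1 = list(h = 50e-6, AR = 1),
    AR1_2 = list(h = 40e-6, AR = 1 / 2),
    AR1_3 = list(h = 40e-6, AR = 1 / 3),
    AR1_4 = list(h = 40e-6, AR = 1 / 4))
  dx <- if (coarse) geom$h / 24 else 1e-6
  sim_config(channel_geometry(geom$h, AR = geom$AR, dx = dx), ...)
}

#' Published figure parameter sets
#'
#' Returns a ready [sim_config()] for the parameter combination of one
#' published trajectory-map panel: square channel sweeps `fig5a`-`fig5d`
#' (Re = 1, El = 0.05/0.1/0.3/0.6, 6 um particle), AR = 1/2 sweeps
#' `fig6a`-`fig6d` (Re = 2.5, El = 0.01/0.08/0.24/0.48), low-aspect
#' panels `fig7a`/`fig7b` (AR = 1/3 and 1/4, Re = 2.5, Wi = 0.2), the
#' square-channel size pair `fig9a`/`fig9b` (d = 6/12 um, Wi = 0.3), the
#' AR = 1/2 size pair `fig10a`/`fig10b`, and the AR = 1/3 size/El grid
#' `fig11a`-`fig11d`. Where a panel caption's Wi and El disagree, El is
#' taken as authoritative (Wi = El * Re).
#'
#' At full resolution these runs take ~1.2 million steps on a cluster;
#' pass `coarse = TRUE` (and a smaller `steps`) for desk-scale
#' qualitative runs.
#'
#' @param name Panel name, e.g. `"fig5c"`.
#' @param coarse Use the ~24-node coarse cross-section.
#' @param steps Run length (defaults to the published 1.2e6).
#' @param yz0 Release position in normalised cross-section coordinates.
#' @return A [sim_config()].
#' @export
figure_preset <- function(name, coarse = FALSE, steps = 1200000,
                          yz0 = c(-0.25, -0.1)) {
  tab <- list(
    fig5a = list("AR1", 1.0, 0.05, 6e-6), fig5b = list("AR1", 1.0, 0.1, 6e-6),
    fig5c = list("AR1", 1.0, 0.3, 6e-6),  fig5d = list("AR1", 1.0, 0.6, 6e-6),
    fig6a = list("AR1_2", 2.5, 0.025, 6e-6), fig6b = list("AR1_2", 2.5, 0.2, 6e-6),
    fig6c = list("AR1_2", 2.5, 0.6, 6e-6),   fig6d = list("AR1_2", 2.5, 1.2, 6e-6),
    fig7a = list("AR1_3", 2.5, 0.2, 6e-6), fig7b = list("AR1_4", 2.5, 0.2, 6e-6),
    fig9a = list("AR1", 1.0, 0.3, 6e-6),  fig9b = list("AR1", 1.0, 0.3, 12e-6),
    fig10a = list("AR1_2", 2.5, 0.2, 6e-6), fig10b = list("AR1_2", 2.5, 0.2, 12e-6),
    fig11a = list("AR1_3", 2.5, 0.2, 6e-6), fig11b = list("AR1_3", 2.5, 0.2, 12e-6),
    fig11c = list("AR1_3", 2.5, 0.6, 6e-6), fig11d = list("AR1_3", 2.5, 0.6, 12e-6))
  if (is.null(tab[[name]])) {
    stop("unknown preset '", name, "'; known: ", paste(names(tab), collapse = ", "))
  }
  p <- tab[[name]]
  preset_config(p[[1]], coarse = coarse, Re = p[[2]], Wi = p[[3]],
                particles = list(list(diameter = p[[4]], n_faces =
                                        if (p[[4]] > 9e-6) 480 else 120,
                                      yz0 = yz0)),
                steps = steps)
}

#' Lattice calibration of a configuration
#'
#' Inverts the LBGK viscosity relation for the relaxation time
#' (lambda = 1/2 + 3 nu dt / dx^2), converts the polymer relaxation time
#' to steps, the driving acceleration and elastic moduli to lattice
#' units, and records the nominal dimensionless groups.
#'
#' @param cfg A [sim_config()].
#' @return List of class `lattice_calibration`: `lambda_f`, `nu_s`
#'   (lattice solvent viscosity), `nu_t`, `L` (lattice characteristic
#'   length), `U` (nominal mean velocity), `accel`, `lambda_p` (steps),
#'   `eta_p`, `groups` (a [dimensionless_groups()]), plus unit scales.
#' @export
lattice_calibration <- function(cfg) {
  dx <- cfg$dx; dt <- cfg$dt
  nu_s <- cfg$nu * dt / dx^2
  lambda_f <- 1 / 2 + 3 * nu_s
  if (lambda_f <= 1 / 2) stop("stability error: lambda = ", lambda_f,
                              " means zero or negative solvent viscosity")
  if (lambda_f >= 2) {
    stop("stability error: lambda = ", signif(lambda_f, 4),
         " >= 2; reduce nu, enlarge dx or shrink dt")
  }
  newtonian <- cfg$Wi == 0
  beta <- if (newtonian) 1 else cfg$beta
  nu_t <- nu_s / beta
  g <- cfg$geometry
  L <- switch(g$kind,
    duct = 2 * (g$h / dx) * (g$w / dx) / ((g$h + g$w) / dx),
    tube = g$diameter / dx,
    shear_box = NA_real_)
  if (g$kind == "shear_box") {
    U <- g$u_wall
    accel <- 0
    lambda_p <- if (newtonian) 0 else cfg$Wi / (2 * g$u_wall / g$gap)
    groups <- dimensionless_groups(Re = U * g$gap / nu_t, Wi = cfg$Wi,
                                   L = g$gap, nu_t = nu_t, U = U)
  } else {
    U <- cfg$Re * nu_t / L
    accel <- driving_acceleration(cfg$Re, nu_t, L)
    lambda_p <- if (newtonian) 0 else cfg$Wi * L / U
    groups <- dimensionless_groups(Re = cfg$Re, Wi = cfg$Wi, L = L,
                                   nu_t = nu_t, U = U)
  }
  structure(list(
    lambda_f = lambda_f, nu_s = nu_s, nu_t = nu_t, beta = beta,
    newtonian = newtonian, lambda_g = cfg$lambda_g, L = L, U = U,
    accel = accel, lambda_p = lambda_p, eta_p = (1 - beta) * nu_t,
    groups = groups,
    scale = list(length = dx, time = dt, velocity = dx / dt,
                 stress = cfg$rho0 * dx^2 / dt^2,
                 surf_modulus = cfg$rho0 * dx^3 / dt^2,
                 energy = cfg$rho0 * dx^5 / dt^2,
                 vol_modulus = cfg$rho0 * dx^2 / dt^2)
  ), class = "lattice_calibration")
}

# Convert SI moduli to lattice units.
moduli_to_lattice <- function(moduli, scale) {
  list(ks = moduli$ks / scale$surf_modulus,
       kalpha = moduli$kalpha / scale$surf_modulus,
       kb = moduli$kb / scale$energy,
       ka = moduli$ka / scale$surf_modulus,
       kv = moduli$kv / scale$vol_modulus)
}

#' @export
print.sim_config <- function(x, ...) {
  g <- x$geometry
  cat("<sim_config>", g$kind, "\n")
  if (g$kind == "duct") {
    cat(sprintf("  h = %.3g um, w = %.3g um (AR = %.3g)\n",
                g$h * 1e6, g$w * 1e6, g$AR))
  } else if (g$kind == "tube") {
    cat(sprintf("  diameter = %.3g um\n", g$diameter * 1e6))
  } else {
    cat(sprintf("  u_wall = %.3g (lattice), gap = %d\n", g$u_wall,
                as.integer(g$gap)))
  }
  cat(sprintf("  Re = %.3g, Wi = %.3g, beta = %.3g, nu = %.3g m2/s\n",
              x$Re, x$Wi, x$beta, x$nu))
  cat(sprintf("  particles: %d, steps: %d\n", length(x$particles), x$steps))
  invisible(x)
}
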