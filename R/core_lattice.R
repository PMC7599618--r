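# Single-relaxation-time (LBGK) solvent update on the D3Q19 lattice.
#
# These are the transparent reference implementations; production runs go
# through the fused C++ stepper (see run_simulation), which is tested
# against the composition of these functions.

#' Equilibrium distribution
#'
#' Second-order Maxwellian equilibrium
#' \deqn{f_\alpha^{eq} = \omega_\alpha \rho \left[1 + 3 c_\alpha\cdot u
#'   + 4.5 (c_\alpha\cdot u)^2 - 1.5 u^2\right]}
#' in lattice units (c = 1). Its zeroth and first moments are exactly
#' rho and rho u by the stencil's quadrature identities.
#'
#' @param rho Density, scalar or length-n vector (must be positive).
#' @param u Velocity: length-3 vector or 3 x n matrix.
#' @param warn Issue a warning when |u| exceeds 0.1 c (compressibility
#'   errors grow quadratically in the Mach number).
#' @return 19 x n matrix (a vector drops to 19 x 1).
#' @export
equilibrium_distribution <- function(rho, u, warn = TRUE) {
  u <- as.matrix(u)
  if (nrow(u) != 3) u <- t(u)
  if (any(!is.finite(rho)) || any(rho <= 0)) {
    stop("invalid state: non-positive or non-finite density")
  }
  umag2 <- colSums(u^2)
  if (warn && any(umag2 > 0.01)) {
    warning("velocity exceeds 0.1 c at ", sum(umag2 > 0.01),
            " node(s); LBGK is weakly compressible")
  }
  dirs <- d3q19_directions()
  w <- d3q19_weights()
  cu <- crossprod(dirs, u)              # 19 x n
  feq <- w * sweep(1 + 3 * cu + 4.5 * cu^2, 2, 1.5 * umag2, "-")
  sweep(feq, 2, rho, "*")
}

#' Discrete body-force term (Guo forcing)
#'
#' \deqn{F_\alpha = \left(1 - \tfrac{1}{2\lambda}\right)\omega_\alpha
#'   \left[3(c_\alpha - u) + 9 (c_\alpha\cdot u)\, c_\alpha\right]\cdot F}
#' The half-force velocity shift of [macroscopic_moments()] belongs to the
#' same scheme; together they recover the forced Navier-Stokes equations
#' to second order.
#'
#' @param u Velocity, length-3 vector or 3 x n matrix.
#' @param F Body force per node, same shape as `u`.
#' @param lambda_f LBGK relaxation time (in units of dt), > 1/2.
#' @return 19 x n matrix of per-direction source terms.
#' @export
force_term <- function(u, F, lambda_f) {
  # lambda_f = 1/2 is allowed here: the prefactor vanishes identically
  if (lambda_f < 1 / 2) stop("lambda_f must be at least 1/2 (positive viscosity)")
  u <- as.matrix(u); F <- as.matrix(F)
  if (nrow(u) != 3) u <- t(u)
  if (nrow(F) != 3) F <- t(F)
  dirs <- d3q19_directions()
  w <- d3q19_weights()
  cu <- crossprod(dirs, u)              # 19 x n
  cF <- crossprod(dirs, F)
  uF <- colSums(u * F)
  pref <- (1 - 1 / (2 * lambda_f)) * w
  pref * (sweep(3 * cF, 2, 3 * uF, "-") + 9 * cu * cF)
}

#' Macroscopic moments of the distribution field
#'
#' Density rho = sum_a f_a and momentum rho u = sum_a c_a f_a + F dt / 2
#' (the half-force correction of the forcing scheme). Also reports the
#' kinematic viscosity nu = (lambda - 1/2) / 3 implied by the relaxation
#' time, in lattice units.
#'
#' @param f 19 x n matrix of populations.
#' @param F Optional 3 x n body-force matrix (defaults to zero).
#' @param lambda_f Relaxation time, used only for the viscosity report.
#' @return List with `rho` (length n), `u` (3 x n) and `nu` (scalar or NULL).
#' @export
macroscopic_moments <- function(f, F = NULL, lambda_f = NULL) {
  if (any(!is.finite(f))) stop("numerical blow-up: non-finite populations")
  rho <- colSums(f)
  if (any(rho <= 0)) {
    stop("invalid state: non-positive density at node ", which(rho <= 0)[1])
  }
  mom <- d3q19_directions() %*% f
  if (!is.null(F)) mom <- mom + as.matrix(F) / 2
  u <- sweep(mom, 2, rho, "/")
  nu <- if (!is.null(lambda_f)) (lambda_f - 1 / 2) / 3 else NULL
  list(rho = rho, u = u, nu = nu)
}

#' One LBGK collide-and-stream step (reference implementation)
#'
#' Relaxes the populations toward equilibrium, adds the discrete force
#' term, and propagates each direction one link with periodic wrap on all
#' axes (walls are imposed separately, see [apply_walls_f()]).
#'
#' @param f 19 x nn population matrix.
#' @param dims Lattice extents c(nx, ny, nz).
#' @param lambda_f Relaxation time.
#' @param F Optional 3 x nn body-force matrix.
#' @param sources Optional precomputed [stream_sources()] matrix.
#' @return 19 x nn matrix of post-streaming populations.
#' @export
collide_and_stream <- function(f, dims, lambda_f, F = NULL, sources = NULL) {
  if (any(!is.finite(f))) {
    bad <- which(!is.finite(f), arr.ind = TRUE)[1, ]
    stop("numerical blow-up at node ", bad[2], ", direction ", bad[1])
  }
  mom <- macroscopic_moments(f, F = F, lambda_f = lambda_f)
  feq <- equilibrium_distribution(mom$rho, mom$u, warn = FALSE)
  fpost <- f + (feq - f) / lambda_f
  if (!is.null(F)) fpost <- fpost + force_term(mom$u, F, lambda_f)
  if (is.null(sources)) sources <- stream_sources(dims)
  fnew <- fpost
  for (a in 1:19) fnew[a, ] <- fpost[a, sources[a, ]]
  fnew
}
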