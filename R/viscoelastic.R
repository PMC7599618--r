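# Oldroyd-B polymer stress transport via a second D3Q19 distribution.
#
# The six independent components of the symmetric polymer stress tau are
# each carried by a 19-direction tensor distribution G_ij,alpha that
# relaxes toward an advected equilibrium and is fed by the constitutive
# source chi = tau.grad(u) + grad(u)^T.tau + (2 eta_p d - tau)/lambda_p.
# Summing G over directions recovers tau; the relaxation parameter
# lambda_g of the G lattice sets a small artificial stress diffusivity
# nu_tilde = (lambda_g - 1/2)/3 that regularises sharp stress gradients.

# Symmetric-tensor storage order used throughout: xx, yy, zz, xy, xz, yz.
SYM_I <- c(1L, 2L, 3L, 1L, 1L, 2L)
SYM_J <- c(1L, 2L, 3L, 2L, 3L, 3L)
# full 3x3 -> packed index
SYM_MAP <- matrix(c(1L, 4L, 5L, 4L, 2L, 6L, 5L, 6L, 3L), 3, 3)

#' Polymer (Oldroyd-B) parameter record
#'
#' @param beta Solvent-to-total viscosity ratio eta_s/eta_t in (0, 1].
#' @param eta_t Total dynamic viscosity (lattice units; rho = 1 so this
#'   equals the total kinematic viscosity).
#' @param lambda_p Polymer relaxation time (lattice steps), >= 0.
#' @param lambda_g Relaxation parameter of the tensor lattice, > 1/2.
#'   Default 0.505 keeps the artificial stress-diffusion boundary layer sqrt(nu_tilde lambda_p) below one lattice spacing at desk resolutions.
#' @return List of class `polymer_spec` with the fields above plus
#'   `eta_p = (1 - beta) eta_t` and `nu_tilde = (lambda_g - 1/2)/3`.
#' @export
polymer_spec <- function(beta, eta_t, lambda_p, lambda_g = 0.505) {
  stopifnot(beta > 0, beta <= 1, eta_t > 0, lambda_p >= 0, lambda_g > 1 / 2)
  structure(list(beta = beta, eta_t = eta_t, eta_p = (1 - beta) * eta_t,
                 lambda_p = lambda_p, lambda_g = lambda_g,
                 nu_tilde = (lambda_g - 1 / 2) / 3),
            class = "polymer_spec")
}

# Coerce a stress argument to packed 6 x n form.
as_sym6 <- function(tau) {
  if (is.matrix(tau) && nrow(tau) == 3 && ncol(tau) == 3) {
    matrix(tau[cbind(SYM_I, SYM_J)], 6, 1)
  } else if (is.matrix(tau) && nrow(tau) == 6) {
    tau
  } else if (is.numeric(tau) && length(tau) == 6) {
    matrix(tau, 6, 1)
  } else stop("tau must be a 3x3 matrix, a length-6 vector or a 6 x n matrix")
}

# Packed 6-vector -> full symmetric 3x3.
sym_to_full <- function(s) matrix(s[SYM_MAP], 3, 3)

#' Equilibrium tensor distribution
#'
#' \deqn{G_{ij\alpha}^{eq} = \omega_\alpha \tau_{ij}\left[1 +
#'   3 c_\alpha\cdot u + 4.5 (c_\alpha\cdot u)^2 - 1.5 u^2\right]}
#' i.e. the same advected weight profile as the solvent equilibrium, with
#' tau_ij in place of rho. The direction sum returns tau_ij exactly.
#'
#' @param tau Stress: 3x3 matrix, packed length-6 vector, or 6 x n matrix
#'   (component order xx, yy, zz, xy, xz, yz).
#' @param u Velocity: length-3 vector or 3 x n matrix.
#' @return Array of dimension c(19, 6, n).
#' @export
tensor_equilibrium <- function(tau, u) {
  tau <- as_sym6(tau)
  u <- as.matrix(u)
  if (nrow(u) != 3) u <- t(u)
  n <- ncol(tau)
  dirs <- d3q19_directions()
  w <- d3q19_weights()
  cu <- crossprod(dirs, u)
  prof <- w * sweep(1 + 3 * cu + 4.5 * cu^2, 2, 1.5 * colSums(u^2), "-")
  G <- array(0, c(19, 6, n))
  for (m in 1:6) G[, m, ] <- prof * rep(tau[m, ], each = 19)
  G
}

#' Constitutive source tensor
#'
#' \deqn{\chi = \tau\cdot\nabla u + (\nabla u)^T\cdot\tau +
#'   \tfrac{1}{\lambda_p}\left(2(1-\beta)\eta_t d - \tau\right)}
#' with d the rate-of-strain tensor. The gradient convention is
#' (grad u)[k, l] = d u_l / d x_k, so that steady simple shear produces a
#' positive streamwise normal stress (positive N1).
#'
#' @param tau Stress (3x3, length-6, or 6 x n packed).
#' @param grad_u Velocity gradient: 3x3 matrix or 3 x 3 x n array.
#' @param spec A [polymer_spec()].
#' @return Packed 6 x n matrix (or a 3x3 matrix if both inputs were 3x3).
#' @export
source_tensor <- function(tau, grad_u, spec) {
  if (spec$lambda_p == 0) {
    stop("lambda_p = 0: no polymer time scale; run the solver in Newtonian mode")
  }
  full_in <- is.matrix(tau) && nrow(tau) == 3 && ncol(tau) == 3
  tau <- as_sym6(tau)
  n <- ncol(tau)
  gu <- if (length(dim(grad_u)) == 2) array(grad_u, c(3, 3, n)) else grad_u
  if (any(!is.finite(gu))) stop("non-finite velocity gradient")
  chi <- matrix(0, 6, n)
  for (m in 1:6) {
    i <- SYM_I[m]; j <- SYM_J[m]
    acc <- numeric(n)
    for (k in 1:3) {
      acc <- acc + tau[SYM_MAP[i, k], ] * gu[k, j, ] +
        gu[k, i, ] * tau[SYM_MAP[k, j], ]
    }
    dij <- (gu[i, j, ] + gu[j, i, ]) / 2
    chi[m, ] <- acc + (2 * spec$eta_p * dij - tau[m, ]) / spec$lambda_p
  }
  if (full_in && n == 1) sym_to_full(chi[, 1]) else chi
}

#' Recover the stress tensor from the tensor populations
#'
#' tau_ij = sum_alpha G_ij,alpha, per node. Symmetry is guaranteed by the
#' packed six-component storage.
#'
#' @param G Array c(19, 6, n) of tensor populations.
#' @return 6 x n packed stress matrix.
#' @export
recover_stress <- function(G) {
  if (any(!is.finite(G))) stop("numerical blow-up: non-finite tensor populations")
  apply(G, 3, colSums)  # 6 x n
}

#' One tensor-lattice collide-and-stream step (reference implementation)
#'
#' LBGK relaxation toward [tensor_equilibrium()] plus the weighted source
#' \deqn{\chi_{ij\alpha} = \omega_\alpha \chi_{ij}\left[1 +
#'   3\tfrac{\lambda_g - 1/2}{\lambda_g} c_\alpha\cdot u\right]}
#' and half of its backward-difference time derivative, then one-link
#' propagation with periodic wrap (walls via [apply_walls_G()]).
#'
#' @param G Array c(19, 6, nn).
#' @param dims Lattice extents.
#' @param u 3 x nn velocity.
#' @param chi 6 x nn source tensor at the current step.
#' @param chi_prev 6 x nn source tensor of the previous step (zeros at
#'   step 0).
#' @param spec A [polymer_spec()].
#' @param sources Optional precomputed [stream_sources()].
#' @return Array c(19, 6, nn) of post-streaming tensor populations.
#' @export
tensor_collide_and_stream <- function(G, dims, u, chi, chi_prev, spec,
                                      sources = NULL) {
  tau <- recover_stress(G)
  Geq <- tensor_equilibrium(tau, u)
  dirs <- d3q19_directions()
  w <- d3q19_weights()
  kappa <- (spec$lambda_g - 1 / 2) / spec$lambda_g
  cu <- crossprod(dirs, u)              # 19 x nn
  wprof <- w * (1 + 3 * kappa * cu)     # 19 x nn source profile
  # chi + 0.5 * (chi - chi_prev): source plus half backward time derivative
  eff <- 1.5 * chi - 0.5 * chi_prev
  Gpost <- G + (Geq - G) / spec$lambda_g
  for (m in 1:6) {
    Gpost[, m, ] <- Gpost[, m, ] + wprof * rep(eff[m, ], each = 19)
  }
  if (is.null(sources)) sources <- stream_sources(dims)
  Gnew <- Gpost
  for (a in 1:19) Gnew[a, , ] <- Gpost[a, , sources[a, ]]
  Gnew
}

# Finite-difference derivative of a scalar lattice field along one axis.
# Central second order where both neighbours are usable (fluid or wall),
# one-sided second order (falling back to first order) where only one
# side is; `usable` marks nodes whose value may enter a stencil.
fd_derivative <- function(field, dims, axis, usable = NULL) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  arr <- array(field, dims)
  shift <- function(a, k) {
    idx <- list(seq_len(nx), seq_len(ny), seq_len(nz))
    idx[[axis]] <- ((idx[[axis]] - 1L - k) %% dims[axis]) + 1L
    a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  if (is.null(usable)) {
    return(as.vector((shift(arr, -1) - shift(arr, 1)) / 2))
  }
  ua <- array(usable, dims)
  up1 <- shift(arr, -1); um1 <- shift(arr, 1)
  ok_p <- shift(ua, -1); ok_m <- shift(ua, 1)
  d <- (up1 - um1) / 2
  one_sided <- ok_p & !ok_m
  if (any(one_sided)) {
    up2 <- shift(arr, -2); ok_p2 <- shift(ua, -2)
    d[one_sided & ok_p2] <- (-3 * arr[one_sided & ok_p2] +
      4 * up1[one_sided & ok_p2] - up2[one_sided & ok_p2]) / 2
    d[one_sided & !ok_p2] <- up1[one_sided & !ok_p2] - arr[one_sided & !ok_p2]
  }
  one_sided <- ok_m & !ok_p
  if (any(one_sided)) {
    um2 <- shift(arr, 2); ok_m2 <- shift(ua, 2)
    d[one_sided & ok_m2] <- (3 * arr[one_sided & ok_m2] -
      4 * um1[one_sided & ok_m2] + um2[one_sided & ok_m2]) / 2
    d[one_sided & !ok_m2] <- arr[one_sided & !ok_m2] - um1[one_sided & !ok_m2]
  }
  d[!ua & !(ok_p | ok_m)] <- 0
  as.vector(d)
}

#' Velocity gradient field
#'
#' Second-order central differences in the interior; one-sided
#' second-order stencils next to inactive (outside-mask) nodes. On-lattice
#' wall nodes carry the wall velocity, so wall-adjacent fluid nodes use
#' plain central differences through the wall value. Convention:
#' `out[k, l, node] = d u_l / d x_k`.
#'
#' @param u 3 x nn velocity matrix.
#' @param dims Lattice extents.
#' @param usable Optional logical mask of nodes whose values may be read
#'   (fluid and wall nodes); defaults to all.
#' @return Array c(3, 3, nn).
#' @export
velocity_gradient <- function(u, dims, usable = NULL) {
  nn <- prod(dims)
  gu <- array(0, c(3, 3, nn))
  for (l in 1:3) {
    for (k in 1:3) {
      gu[k, l, ] <- fd_derivative(u[l, ], dims, k, usable)
    }
  }
  gu
}

#' Elastic body force, the divergence of the polymer stress
#'
#' (F_V)_j = sum_k d tau_kj / d x_k, using the same finite-difference
#' stencils as [velocity_gradient()].
#'
#' @param tau 6 x nn packed stress matrix.
#' @param dims Lattice extents.
#' @param usable Optional logical stencil mask as in [velocity_gradient()].
#' @return 3 x nn force matrix.
#' @export
elastic_force <- function(tau, dims, usable = NULL) {
  nn <- prod(dims)
  Fv <- matrix(0, 3, nn)
  for (j in 1:3) {
    acc <- numeric(nn)
    for (k in 1:3) {
      acc <- acc + fd_derivative(tau[SYM_MAP[k, j], ], dims, k, usable)
    }
    Fv[j, ] <- acc
  }
  Fv
}
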