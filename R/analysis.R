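# Dimensionless groups, cross-section symmetry, trajectory and rotation
# analysis, and first-normal-stress-difference diagnostics.

#' Dimensionless groups of a channel flow
#'
#' Re = rho U L / eta_t, Wi = lambda_p U / L, El = Wi / Re, with
#' L = 2hw/(h+w) and U the mean streamwise velocity. When a measured mean
#' velocity is supplied the achieved groups are reported alongside the
#' nominal ones (the circular-pipe driving formula under-drives a
#' rectangular duct, so nominal and measured differ there).
#'
#' @param Re,Wi Nominal Reynolds and Weissenberg numbers.
#' @param L Characteristic length (metres).
#' @param nu_t Total kinematic viscosity (m^2/s).
#' @param U Nominal characteristic velocity (defaults to Re nu_t / L).
#' @param d Particle diameter, for the blockage ratio (optional).
#' @param h Channel height, for the blockage ratio (optional).
#' @param U_measured Optional measured mean streamwise velocity.
#' @return List of class `dimensionless_groups` with `Re`, `Wi`, `El`,
#'   `U`, `L`, `blockage`, and (when measured) `Re_measured`,
#'   `Wi_measured`, `El_measured`.
#' @export
dimensionless_groups <- function(Re, Wi, L, nu_t, U = Re * nu_t / L,
                                 d = NULL, h = NULL, U_measured = NULL) {
  lambda_p <- if (U > 0) Wi * L / U else 0
  out <- list(Re = Re, Wi = Wi, El = if (Re > 0) Wi / Re else NA_real_,
              U = U, L = L, lambda_p = lambda_p,
              blockage = if (!is.null(d) && !is.null(h)) d / h else NA_real_)
  if (!is.null(U_measured)) {
    out$U_measured <- U_measured
    out$Re_measured <- U_measured * L / nu_t
    out$Wi_measured <- lambda_p * U_measured / L
    out$El_measured <- out$Wi_measured / out$Re_measured
  }
  structure(out, class = "dimensionless_groups")
}

#' Orientation angles of the particle marker vector
#'
#' theta_k = arccos(P . e_k / |P|) in degrees, for the three coordinate
#' axes; the squared direction cosines sum to one.
#'
#' @param P Length-3 orientation vector (or n x 3 matrix of vectors).
#' @return Length-3 vector c(theta_x, theta_y, theta_z) in degrees (or an
#'   n x 3 matrix).
#' @export
rotation_angles <- function(P) {
  P <- if (is.matrix(P)) P else matrix(P, 1)
  nrm <- sqrt(rowSums(P^2))
  if (any(nrm == 0)) stop("zero orientation vector")
  ang <- acos(pmin(pmax(P / nrm, -1), 1)) * 180 / pi
  colnames(ang) <- c("theta_x", "theta_y", "theta_z")
  if (nrow(ang) == 1) drop(ang) else ang
}

#' Rotation speed from successive orientation vectors
#'
#' The angle swept between consecutive marker vectors divided by the
#' sampling interval, in radians per lattice step.
#'
#' @param P n x 3 matrix of orientation vectors, one sample per row.
#' @param dt_sample Steps between samples.
#' @return Length n-1 vector of rotation speeds.
#' @export
rotation_speed <- function(P, dt_sample = 1) {
  n <- nrow(P)
  if (n < 2) return(numeric(0))
  a <- P[-n, , drop = FALSE]; b <- P[-1, , drop = FALSE]
  cosang <- rowSums(a * b) / sqrt(rowSums(a^2) * rowSums(b^2))
  acos(pmin(pmax(cosang, -1), 1)) / dt_sample
}

#' First normal stress difference
#'
#' N1 = tau_xx - tau_nn with x the flow axis and n the shear-gradient
#' axis along which the profile is taken ("y" or "z"). Optionally
#' non-dimensionalised by eta_t U / L.
#'
#' @param tau 6 x nn packed stress (order xx, yy, zz, xy, xz, yz).
#' @param axis `"y"` or `"z"`: the transverse axis of the profile.
#' @param scale Optional eta_t U / L to non-dimensionalise by.
#' @return Vector of N1 per node.
#' @export
first_normal_stress_difference <- function(tau, axis = c("y", "z"),
                                           scale = NULL) {
  axis <- match.arg(axis)
  n1 <- tau[1, ] - tau[if (axis == "y") 2 else 3, ]
  if (!is.null(scale)) n1 <- n1 / scale
  n1
}

#' Map cross-section points into the canonical symmetry sector
#'
#' Cross-section coordinates are normalised by the half extents, so a
#' point reads like (y, z) in [-1, 1]^2. A square cross-section has an
#' 8-fold symmetry group (both mirrors and the diagonal swap); the
#' canonical sector is 0 <= z <= y. A rectangle keeps only the two
#' mirrors; the canonical sector is the quadrant y >= 0, z >= 0.
#'
#' @param yz n x 2 matrix (or length-2 vector) of normalised coordinates.
#' @param square Logical: full 8-fold square symmetry?
#' @return n x 2 matrix of canonical representatives.
#' @export
sector_canonical <- function(yz, square = TRUE) {
  yz <- if (is.matrix(yz)) yz else matrix(yz, 1)
  out <- abs(yz)
  if (square) {
    swap <- out[, 2] > out[, 1]
    out[swap, ] <- out[swap, 2:1]
  }
  out
}

#' Mirror a sector trajectory across the cross-section symmetry group
#'
#' Applies every element of the symmetry group (8 for a square, 4 for a
#' rectangle) to a trajectory simulated in one sector, tiling the full
#' cross-section as the flow symmetry guarantees.
#'
#' @param yz n x 2 matrix of normalised cross-section positions.
#' @param square Logical: square channel?
#' @return List of n x 2 matrices, one per group element (the first is
#'   the identity).
#' @export
sector_reduce_and_mirror <- function(yz, square = TRUE) {
  yz <- if (is.matrix(yz)) yz else matrix(yz, 1)
  signs <- expand.grid(sy = c(1, -1), sz = c(1, -1))
  out <- list()
  for (r in seq_len(nrow(signs))) {
    m <- cbind(yz[, 1] * signs$sy[r], yz[, 2] * signs$sz[r])
    out[[length(out) + 1]] <- m
    if (square) out[[length(out) + 1]] <- m[, 2:1, drop = FALSE]
  }
  out
}

#' Plot a cross-section trajectory map
#'
#' Renders one or more sector trajectories, mirrored through the
#' cross-section symmetry group, as the conventional migration map:
#' dots mark release positions, lines the migration paths.
#'
#' @param trajectories A single n x 2 matrix of normalised (y, z)
#'   positions or a list of them (one per release position).
#' @param square Square-channel (8-fold) or rectangular (4-fold)
#'   symmetry.
#' @param ... Passed to [graphics::plot()] (e.g. `main`).
#' @return Invisibly, the list of mirrored trajectory sets.
#' @export
plot_trajectory_map <- function(trajectories, square = TRUE, ...) {
  if (!is.list(trajectories)) trajectories <- list(trajectories)
  graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1,
                 xlab = "y / (h/2)", ylab = "z / (w/2)", ...)
  graphics::rect(-1, -1, 1, 1, border = "grey40")
  out <- list()
  for (i in seq_along(trajectories)) {
    tr <- trajectories[[i]]
    imgs <- sector_reduce_and_mirror(tr, square = square)
    out[[i]] <- imgs
    for (m in imgs) {
      graphics::lines(m[, 1], m[, 2], col = i + 1)
      graphics::points(m[1, 1], m[1, 2], pch = 16, cex = 0.6, col = i + 1)
    }
  }
  invisible(out)
}

#' Detect a focusing equilibrium from a trajectory
#'
#' Declares convergence when the cross-section displacement over the
#' trailing window stays below `tol` (normalised half-extent units), and
#' reports the window-mean position.
#'
#' @param yz n x 2 matrix of normalised cross-section positions.
#' @param window Number of trailing samples forming the window.
#' @param tol Maximum displacement within the window.
#' @return List with `converged`, `position` (window mean, or NA), and
#'   `drift` (max displacement from the window mean).
#' @export
detect_equilibrium <- function(yz, window = 50, tol = 0.005) {
  yz <- if (is.matrix(yz)) yz else matrix(yz, 1)
  n <- nrow(yz)
  if (n < 2 * window) {
    return(list(converged = FALSE, position = c(NA_real_, NA_real_),
                drift = NA_real_))
  }
  tail_yz <- yz[(n - window + 1):n, , drop = FALSE]
  ctr <- colMeans(tail_yz)
  drift <- max(sqrt(rowSums(sweep(tail_yz, 2, ctr)^2)))
  list(converged = drift < tol, position = ctr, drift = drift)
}
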