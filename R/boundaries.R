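# Channel geometry, node classification and the non-equilibrium
# extrapolation no-slip condition for both distribution sets.
#
# Wall nodes sit ON the physical boundary (on-lattice walls): a channel of
# height h spans h/dx - 1 interior fluid nodes plus one wall layer on each
# side. Each wall node extrapolates the non-equilibrium part of its
# populations from a designated adjacent fluid node (the nearest interior
# neighbour along the inward normal; corners fall back to the diagonal).

NODE_FLUID <- 0L
NODE_WALL <- 1L
NODE_INACTIVE <- 2L

#' Rectangular channel geometry
#'
#' @param h Channel height in metres.
#' @param w Channel width in metres; give either `w` or `AR`.
#' @param AR Aspect ratio h/w (1 = square, < 1 wider than tall).
#' @param dx Lattice spacing in metres.
#' @return List of class `channel_geometry` with `h`, `w`, `AR`,
#'   the characteristic length `L = 2hw/(h+w)`, `dx`, and the lattice
#'   cross-section extents `ny`, `nz` (fluid interior plus the wall layer).
#' @export
channel_geometry <- function(h, w = NULL, AR = NULL, dx = 1e-6) {
  if (is.null(w) && is.null(AR)) stop("give either w or AR")
  if (is.null(w)) w <- h / AR
  stopifnot(h > 0, w > 0, dx > 0)
  structure(list(
    h = h, w = w, AR = h / w, L = 2 * h * w / (h + w), dx = dx,
    ny = as.integer(round(h / dx)) + 1L,
    nz = as.integer(round(w / dx)) + 1L
  ), class = "channel_geometry")
}

# Assign each wall node its adjacent fluid node: scan the 18 finite
# directions in stencil order (axis neighbours first, then diagonals), so
# edges pick the inward normal and corners the interior diagonal.
assign_wall_neighbours <- function(node_type, dims) {
  dirs <- d3q19_directions()
  nn <- prod(dims)
  nbr <- rep(NA_integer_, nn)
  walls <- which(node_type == NODE_WALL)
  if (!length(walls)) return(nbr)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  wx <- ((walls - 1L) %% nx) + 1L
  wy <- (((walls - 1L) %/% nx) %% ny) + 1L
  wz <- ((walls - 1L) %/% (nx * ny)) + 1L
  for (a in 2:19) {
    need <- is.na(nbr[walls])
    if (!any(need)) break
    cx <- ((wx - 1L + dirs[1, a]) %% nx) + 1L
    cy <- ((wy - 1L + dirs[2, a]) %% ny) + 1L
    cz <- ((wz - 1L + dirs[3, a]) %% nz) + 1L
    cand <- node_index(dims, cx, cy, cz)
    take <- need & node_type[cand] == NODE_FLUID
    nbr[walls[take]] <- cand[take]
  }
  if (anyNA(nbr[walls])) {
    stop("configuration error: wall node without an adjacent fluid node")
  }
  nbr
}

new_domain <- function(dims, node_type, wall_u = NULL, kind = "custom",
                       meta = list()) {
  nn <- prod(dims)
  if (is.null(wall_u)) wall_u <- matrix(0, 3, nn)
  structure(list(
    dims = as.integer(dims), node_type = node_type,
    wall_nbr = assign_wall_neighbours(node_type, dims),
    wall_u = wall_u, kind = kind, meta = meta
  ), class = "lattice_domain")
}

#' Rectangular duct domain
#'
#' Periodic along x; a one-node wall layer closes the y/z cross-section
#' boundary (corner lines included).
#'
#' @param nx,ny,nz Lattice extents including the wall layer.
#' @return A `lattice_domain`.
#' @export
duct_domain <- function(nx, ny, nz) {
  dims <- c(nx, ny, nz)
  ty <- array(NODE_FLUID, dims)
  ty[, c(1, ny), ] <- NODE_WALL
  ty[, , c(1, nz)] <- NODE_WALL
  new_domain(dims, as.integer(ty), kind = "duct",
             meta = list(half_y = (ny - 1) / 2, half_z = (nz - 1) / 2))
}

#' Circular-cross-section (tube) domain
#'
#' Nodes with cross-section radius below `radius` are fluid; non-fluid
#' nodes touching a fluid node through any of the 18 stencil links form
#' the staircase wall layer, the rest are inactive. The effective no-slip
#' radius of the staircase, `r_eff`, is reported as the mean radial
#' distance of the wall-layer nodes (a purely geometric quantity used by
#' the analytic comparisons).
#'
#' @param nx Extent along the periodic flow axis.
#' @param radius Mask radius in lattice units (e.g. 10.5 for 21 fluid
#'   nodes across the diameter).
#' @return A `lattice_domain` with `meta$radius`, `meta$r_eff`,
#'   `meta$centre` (y, z lattice coordinates of the axis).
#' @export
tube_domain <- function(nx, radius) {
  half <- ceiling(radius) + 1
  cy <- half + 1; n_cs <- 2L * as.integer(half) + 1L
  dims <- c(nx, n_cs, n_cs)
  gy <- rep(rep(seq_len(n_cs), each = nx), times = n_cs)
  gz <- rep(seq_len(n_cs), each = nx * n_cs)
  r2 <- (gy - cy)^2 + (gz - cy)^2
  ty <- ifelse(r2 < radius^2, NODE_FLUID, NODE_INACTIVE)
  # wall layer: inactive nodes with a fluid stencil neighbour
  dirs <- d3q19_directions()
  arr <- array(ty, dims)
  fluid <- arr == NODE_FLUID
  touch <- array(FALSE, dims)
  for (a in 2:19) {
    sh <- fluid
    for (ax in 1:3) {
      k <- dirs[ax, a]
      if (k != 0) {
        idx <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
        idx[[ax]] <- ((idx[[ax]] - 1L - k) %% dims[ax]) + 1L
        sh <- sh[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
        dim(sh) <- dims
      }
    }
    touch <- touch | sh
  }
  arr[touch & !fluid] <- NODE_WALL
  ty <- as.integer(arr)
  wall_r <- sqrt(r2[ty == NODE_WALL])
  # On-node walls put the no-slip surface ON the wall nodes; along the
  # symmetry axes (where the staircase is flattest) those sit at
  # radius + 0.5, which is the effective hydrodynamic radius the analytic
  # comparisons use. The mean wall-node radius is kept as a diagnostic.
  new_domain(dims, ty, kind = "tube",
             meta = list(radius = radius, r_eff = radius + 0.5,
                         r_wall_mean = mean(wall_r), centre = c(cy, cy)))
}

#' Planar shear (Couette) box
#'
#' Moving no-slip walls at the bottom and top y planes with equal and
#' opposite x velocities; periodic along x and z. The nominal shear rate
#' is `2 u_wall / gap`, with `gap = ny - 1` the wall-plane separation.
#'
#' @param u_wall Wall speed in lattice units.
#' @param gap Wall-plane separation in lattice units (>= 8).
#' @param nx,nz Periodic extents (default `gap + 3`).
#' @return A `lattice_domain` with `meta$shear_rate` and `meta$u_wall`.
#' @export
shear_box <- function(u_wall, gap, nx = gap + 3, nz = gap + 3) {
  stopifnot(gap >= 8)
  ny <- as.integer(gap) + 1L
  dims <- c(nx, ny, nz)
  ty <- array(NODE_FLUID, dims)
  ty[, c(1, ny), ] <- NODE_WALL
  ty <- as.integer(ty)
  wall_u <- matrix(0, 3, prod(dims))
  arr <- array(seq_len(prod(dims)), dims)
  wall_u[1, as.vector(arr[, 1, ])] <- -u_wall
  wall_u[1, as.vector(arr[, ny, ])] <- u_wall
  new_domain(dims, ty, wall_u = wall_u, kind = "shear_box",
             meta = list(u_wall = u_wall, gap = ny - 1L,
                         shear_rate = 2 * u_wall / (ny - 1L)))
}

#' Non-equilibrium extrapolation wall populations (solvent lattice)
#'
#' f_alpha(wall) = f_alpha^eq(rho_f, u_w) + [f_alpha(x_f) -
#' f_alpha^eq(rho_f, u_f)]: wall equilibrium at the wall velocity plus the
#' adjacent fluid node's non-equilibrium part, copied verbatim.
#'
#' @param f_fluid Length-19 populations of the adjacent fluid node.
#' @param rho_f,u_f Density and velocity of the adjacent fluid node.
#' @param u_w Wall velocity (length 3).
#' @return Length-19 wall populations.
#' @export
wall_populations_f <- function(f_fluid, rho_f, u_f, u_w = c(0, 0, 0)) {
  drop(equilibrium_distribution(rho_f, u_w, warn = FALSE)) +
    (f_fluid - drop(equilibrium_distribution(rho_f, u_f, warn = FALSE)))
}

#' Non-equilibrium extrapolation wall populations (tensor lattice)
#'
#' The Eq.-for-G analogue of [wall_populations_f()], with the adjacent
#' fluid node's stress in place of its density.
#'
#' @param G_fluid 19 x 6 matrix of the fluid node's tensor populations.
#' @param tau_f Packed length-6 stress of the fluid node.
#' @param u_f,u_w Fluid-node and wall velocities.
#' @return 19 x 6 matrix of wall populations.
#' @export
wall_populations_G <- function(G_fluid, tau_f, u_f, u_w = c(0, 0, 0)) {
  Geq_w <- tensor_equilibrium(tau_f, u_w)[, , 1]
  Geq_f <- tensor_equilibrium(tau_f, u_f)[, , 1]
  Geq_w + (G_fluid - Geq_f)
}

#' Apply the wall condition to every wall node of a solvent field
#'
#' @param f 19 x nn population matrix.
#' @param domain A `lattice_domain`.
#' @return The updated population matrix.
#' @export
apply_walls_f <- function(f, domain) {
  walls <- which(domain$node_type == NODE_WALL)
  if (!length(walls)) return(f)
  nb <- domain$wall_nbr[walls]
  mom <- macroscopic_moments(f[, nb, drop = FALSE])
  feq_f <- equilibrium_distribution(mom$rho, mom$u, warn = FALSE)
  feq_w <- equilibrium_distribution(mom$rho, domain$wall_u[, walls, drop = FALSE],
                                    warn = FALSE)
  f[, walls] <- feq_w + (f[, nb, drop = FALSE] - feq_f)
  f
}

#' Apply the wall condition to every wall node of a tensor field
#'
#' @param G Array c(19, 6, nn).
#' @param domain A `lattice_domain`.
#' @param u 3 x nn velocity field (for the fluid-node equilibria).
#' @return The updated tensor population array.
#' @export
apply_walls_G <- function(G, domain, u) {
  walls <- which(domain$node_type == NODE_WALL)
  if (!length(walls)) return(G)
  nb <- domain$wall_nbr[walls]
  tau_f <- recover_stress(G[, , nb, drop = FALSE])
  Geq_f <- tensor_equilibrium(tau_f, u[, nb, drop = FALSE])
  Geq_w <- tensor_equilibrium(tau_f, domain$wall_u[, walls, drop = FALSE])
  G[, , walls] <- Geq_w + (G[, , nb, drop = FALSE] - Geq_f)
  G
}

#' Body-force calibration from the target Reynolds number
#'
#' Poiseuille relation `a = 32 nu^2 Re / L^3` (exact for a circular pipe
#' of diameter L; for rectangular ducts the achieved mean velocity, hence
#' the achieved Re, deviates from the target and is re-measured by the
#' driver). `nu` is the total kinematic viscosity of the viscoelastic
#' fluid, consistent with Re = U L / nu_t.
#'
#' @param Re Target Reynolds number.
#' @param nu Total kinematic viscosity.
#' @param L Characteristic length 2hw/(h+w) (the diameter for a tube).
#' @return The driving acceleration (same unit system as the inputs).
#' @export
driving_acceleration <- function(Re, nu, L) {
  stopifnot(L > 0)
  32 * nu^2 * Re / L^3
}
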