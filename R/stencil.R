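# D3Q19 stencil constants and lattice bookkeeping.
#
# All solver-internal quantities are expressed in lattice units with
# dx = dt = 1 (so the lattice speed c = 1 and the speed of sound
# cs^2 = 1/3); physical parameters are converted once at setup by
# lattice_calibration().

#' D3Q19 discrete velocity set
#'
#' The 19 discrete lattice velocities of the D3Q19 model, one per column:
#' the rest direction, the 6 axis directions (speed 1) and the 12 face
#' diagonals (speed sqrt(2)). Opposite directions are stored as
#' consecutive pairs (columns 2/3, 4/5, ...).
#'
#' @return Integer matrix with 3 rows and 19 columns.
#' @seealso [d3q19_weights()]
#' @export
d3q19_directions <- function() {
  matrix(c(
    0, 0, 0,
    1, 0, 0,  -1, 0, 0,
    0, 1, 0,   0,-1, 0,
    0, 0, 1,   0, 0,-1,
    1, 1, 0,  -1,-1, 0,
    1,-1, 0,  -1, 1, 0,
    1, 0, 1,  -1, 0,-1,
    1, 0,-1,  -1, 0, 1,
    0, 1, 1,   0,-1,-1,
    0, 1,-1,   0,-1, 1), nrow = 3)
}

#' D3Q19 quadrature weights
#'
#' @return Numeric vector of length 19: 1/3 for the rest direction, 1/18
#'   for the axis directions, 1/36 for the diagonals. The weights sum to
#'   one and their first moment vanishes.
#' @export
d3q19_weights <- function() {
  c(1 / 3, rep(1 / 18, 6), rep(1 / 36, 12))
}

#' Lattice stencil specification
#'
#' Bundles the D3Q19 constants together with the lattice speed, mostly as
#' a self-describing record for snapshots and tests.
#'
#' @param c Lattice speed dx/dt. The solver always works at c = 1.
#' @return A list of class `lattice_spec` with elements `c`, `directions`
#'   (3 x 19), `weights` (length 19), `cs2` (squared speed of sound) and
#'   `opposite` (index of the reversed direction, 1-based).
#' @export
lattice_spec <- function(c = 1) {
  dirs <- d3q19_directions()
  opp <- integer(19)
  for (a in 1:19) {
    opp[a] <- which(colSums((dirs + dirs[, a])^2) == 0)
  }
  structure(list(c = c, directions = dirs, weights = d3q19_weights(),
                 cs2 = c^2 / 3, opposite = opp),
            class = "lattice_spec")
}

# Column-major linear index of lattice nodes; x is the (periodic) flow axis.
node_index <- function(dims, x, y, z) {
  x + dims[1] * (y - 1L) + dims[1] * dims[2] * (z - 1L)
}

# 19 x nn matrix of 1-based source indices: streaming writes the
# post-collision value of direction a at `node` into `node + c_a`, i.e.
# f_new[a, ] = f_post[a, stream_sources(dims)[a, ]] pulls from upstream.
stream_sources <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  dirs <- d3q19_directions()
  gx <- rep(seq_len(nx), times = ny * nz)
  gy <- rep(rep(seq_len(ny), each = nx), times = nz)
  gz <- rep(seq_len(nz), each = nx * ny)
  src <- matrix(0L, 19, nx * ny * nz)
  for (a in 1:19) {
    sx <- ((gx - dirs[1, a] - 1L) %% nx) + 1L
    sy <- ((gy - dirs[2, a] - 1L) %% ny) + 1L
    sz <- ((gz - dirs[3, a] - 1L) %% nz) + 1L
    src[a, ] <- node_index(dims, sx, sy, sz)
  }
  src
}
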