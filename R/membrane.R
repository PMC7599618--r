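# Triangulated membrane particles and their elastic energies.
#
# A particle is a closed, outward-oriented triangulation of a sphere. Its
# deformation energy is the sum of an in-plane strain term (per-face
# invariants of the right Cauchy-Green tensor), a dihedral-angle bending
# term over edges, and global quadratic penalties on total area and
# enclosed volume. With the rigid preset moduli the shell deforms by well
# under a percent of the diameter and behaves as a rigid sphere.
#
# The 120-face mesh is the barycentric subdivision of the icosahedron
# (62 vertices) and the 480-face mesh its one-to-four midpoint
# refinement; both are projected onto the sphere. This is the standard
# near-uniform family that hits those two face counts exactly.

#' Rigid-limit elastic moduli (SI units)
#'
#' Shear modulus kappa_S and area-dilation modulus kappa_alpha in N/m,
#' bending modulus kappa_B in N m, global area modulus kappa_A in N/m and
#' volume modulus kappa_V in N/m^2, large enough that the particle is
#' effectively rigid.
#'
#' @return Named list with `ks`, `kalpha`, `kb`, `ka`, `kv`.
#' @export
rigid_moduli <- function() {
  list(ks = 3.2e-1, kalpha = 3.2e-1, kb = 3.2e-13, ka = 3.2e-2, kv = 3.2e4)
}

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    cbind(0, c(1, 1, -1, -1), c(phi, -phi, phi, -phi)),
    cbind(c(1, 1, -1, -1), c(phi, -phi, phi, -phi), 0),
    cbind(c(phi, -phi, phi, -phi), 0, c(1, 1, -1, -1)))
  v <- v / sqrt(1 + phi^2)
  edge2 <- 4 / (1 + phi^2)   # squared edge length after normalisation
  adj <- as.matrix(dist(v))^2 < edge2 * 1.01 & as.matrix(dist(v))^2 > 0
  faces <- NULL
  for (i in 1:10) for (j in (i + 1):11) for (k in (j + 1):12) {
    if (adj[i, j] && adj[j, k] && adj[i, k]) faces <- rbind(faces, c(i, j, k))
  }
  list(nodes = v, faces = orient_outward(v, faces))
}

orient_outward <- function(nodes, faces) {
  ctr <- colMeans(nodes)
  for (r in seq_len(nrow(faces))) {
    tri <- nodes[faces[r, ], , drop = FALSE]
    n <- pracma_cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    if (sum(n * (colMeans(tri) - ctr)) < 0) faces[r, ] <- faces[r, c(1, 3, 2)]
  }
  faces
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Barycentric subdivision: each face splits into 6 triangles around its
# centroid and edge midpoints (20 -> 120 faces on the icosahedron).
subdivide_barycentric <- function(nodes, faces) {
  env <- new.env()
  nodes_list <- split(nodes, row(nodes))
  getpt <- function(key, p) {
    if (is.null(env[[key]])) {
      nodes_list[[length(nodes_list) + 1]] <<- p
      env[[key]] <- length(nodes_list)
    }
    env[[key]]
  }
  out <- matrix(0L, 6 * nrow(faces), 3)
  r <- 0L
  for (fi in seq_len(nrow(faces))) {
    ijk <- faces[fi, ]
    i <- ijk[1]; j <- ijk[2]; k <- ijk[3]
    cidx <- getpt(paste0("c", fi), colMeans(nodes[ijk, ]))
    mid <- function(a, b) {
      getpt(paste0("m", min(a, b), "_", max(a, b)), (nodes[a, ] + nodes[b, ]) / 2)
    }
    mij <- mid(i, j); mjk <- mid(j, k); mki <- mid(k, i)
    out[r + 1:6, ] <- rbind(c(i, mij, cidx), c(mij, j, cidx),
                            c(j, mjk, cidx), c(mjk, k, cidx),
                            c(k, mki, cidx), c(mki, i, cidx))
    r <- r + 6L
  }
  list(nodes = do.call(rbind, nodes_list), faces = out)
}

# Loop-style 1 -> 4 midpoint refinement (no smoothing).
subdivide_midpoint <- function(nodes, faces) {
  env <- new.env()
  nodes_list <- split(nodes, row(nodes))
  mid <- function(a, b) {
    key <- paste0("m", min(a, b), "_", max(a, b))
    if (is.null(env[[key]])) {
      nodes_list[[length(nodes_list) + 1]] <<- (nodes[a, ] + nodes[b, ]) / 2
      env[[key]] <- length(nodes_list)
    }
    env[[key]]
  }
  out <- matrix(0L, 4 * nrow(faces), 3)
  r <- 0L
  for (fi in seq_len(nrow(faces))) {
    i <- faces[fi, 1]; j <- faces[fi, 2]; k <- faces[fi, 3]
    a <- mid(i, j); b <- mid(j, k); d <- mid(k, i)
    out[r + 1:4, ] <- rbind(c(i, a, d), c(a, j, b), c(d, b, k), c(a, b, d))
    r <- r + 4L
  }
  list(nodes = do.call(rbind, nodes_list), faces = out)
}

# Oriented edge table: one row per undirected edge with the two opposite
# vertices; face A contains the directed edge (v0 -> v1), face B the
# reverse. Errors if the surface is not closed and consistently oriented.
build_edges <- function(faces) {
  nf <- nrow(faces)
  he_from <- c(faces[, 1], faces[, 2], faces[, 3])
  he_to <- c(faces[, 2], faces[, 3], faces[, 1])
  he_opp <- c(faces[, 3], faces[, 1], faces[, 2])
  key <- paste(pmin(he_from, he_to), pmax(he_from, he_to))
  sp <- split(seq_along(key), key)
  if (any(lengths(sp) != 2)) {
    stop("not a closed surface: some edges are not shared by exactly 2 faces")
  }
  edges <- matrix(0L, length(sp), 4)
  for (r in seq_along(sp)) {
    h <- sp[[r]]
    if (he_from[h[1]] == he_from[h[2]]) {
      stop("inconsistent face orientation at edge ", names(sp)[r])
    }
    edges[r, ] <- c(he_from[h[1]], he_to[h[1]], he_opp[h[1]], he_opp[h[2]])
  }
  edges
}

face_normals_raw <- function(nodes, faces) {
  e1 <- nodes[faces[, 2], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  e2 <- nodes[faces[, 3], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Total surface area of a triangulated mesh
#' @param nodes nV x 3 node positions.
#' @param faces nF x 3 face index matrix.
#' @return Scalar area.
#' @export
mesh_area <- function(nodes, faces) {
  sum(sqrt(rowSums(face_normals_raw(nodes, faces)^2))) / 2
}

#' Signed enclosed volume of a closed triangulated mesh
#' @inheritParams mesh_area
#' @return Scalar volume (positive for outward orientation).
#' @export
mesh_volume <- function(nodes, faces) {
  v0 <- nodes[faces[, 1], , drop = FALSE]
  n <- face_normals_raw(nodes, faces)
  sum(rowSums(v0 * n)) / 6
}

#' Signed dihedral angles across mesh edges
#'
#' The angle between the outward normals of the two faces sharing each
#' edge, signed by the rotation sense about the directed edge.
#'
#' @param nodes nV x 3 node positions.
#' @param edges Edge table from the mesh (see [membrane_mesh()]).
#' @return Numeric vector, one angle (radians) per edge.
#' @export
dihedral_angles <- function(nodes, edges) {
  x0 <- nodes[edges[, 1], , drop = FALSE]
  x1 <- nodes[edges[, 2], , drop = FALSE]
  xa <- nodes[edges[, 3], , drop = FALSE]
  xb <- nodes[edges[, 4], , drop = FALSE]
  e <- x1 - x0
  crossm <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  nA <- crossm(e, xa - x0)
  nB <- crossm(x0 - x1, xb - x1)
  s <- rowSums(crossm(nA, nB) * e) / sqrt(rowSums(e^2))
  atan2(s, rowSums(nA * nB))
}

#' Construct a membrane mesh with reference geometry
#'
#' Captures the undeformed (reference) state: the inverse in-plane metric
#' of every face, per-face reference areas, per-edge reference dihedral
#' angles, and the total area and volume, so that all four energies
#' evaluate to zero at the reference configuration.
#'
#' @param nodes nV x 3 node positions of the reference configuration.
#' @param faces nF x 3 integer matrix, outward-oriented.
#' @param moduli Named list as in [rigid_moduli()] (any consistent units).
#' @return Object of class `membrane_mesh`.
#' @export
membrane_mesh <- function(nodes, faces, moduli = rigid_moduli()) {
  storage.mode(faces) <- "integer"
  edges <- build_edges(faces)
  nV <- nrow(nodes); nE <- nrow(edges); nF <- nrow(faces)
  if (nV - nE + nF != 2L) {
    stop("not a closed genus-0 surface: V - E + F = ", nV - nE + nF)
  }
  if (mesh_volume(nodes, faces) <= 0) stop("faces are not outward-oriented")
  e1 <- nodes[faces[, 2], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  e2 <- nodes[faces[, 3], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  c11 <- rowSums(e1^2); c12 <- rowSums(e1 * e2); c22 <- rowSums(e2^2)
  det0 <- c11 * c22 - c12^2
  if (any(det0 <= 0)) stop("degenerate reference face")
  # M = inverse of the reference metric C0 = [[c11 c12],[c12 c22]]
  M <- cbind(c22 / det0, -c12 / det0, c11 / det0)
  colnames(M) <- c("m11", "m12", "m22")
  n <- face_normals_raw(nodes, faces)
  structure(list(
    nodes = nodes, faces = faces, edges = edges, moduli = moduli,
    ref = list(M = M, A0f = sqrt(rowSums(n^2)) / 2,
               phi0 = dihedral_angles(nodes, edges),
               A0 = mesh_area(nodes, faces), V0 = mesh_volume(nodes, faces))
  ), class = "membrane_mesh")
}

#' Generate a near-uniform triangulated sphere
#'
#' Presets: 120 faces (barycentric subdivision of the icosahedron, used
#' for the 6 micron particle) and 480 faces (its midpoint refinement,
#' 12 micron particle); further refinements (1920, ...) are accepted.
#'
#' @param diameter Sphere diameter (any length unit; positions inherit it).
#' @param n_faces Number of triangular elements: 120 * 4^k or 480.
#' @param moduli Elastic moduli list, units consistent with `diameter`.
#' @param centre Optional length-3 centre (default origin).
#' @return A [membrane_mesh()].
#' @export
generate_sphere_mesh <- function(diameter, n_faces = 120,
                                 moduli = rigid_moduli(),
                                 centre = c(0, 0, 0)) {
  supported <- 120 * 4^(0:4)
  if (!n_faces %in% supported) {
    stop("unsupported face count ", n_faces, "; supported: ",
         paste(supported, collapse = ", "))
  }
  ico <- icosahedron()
  m <- subdivide_barycentric(ico$nodes, ico$faces)
  k <- round(log(n_faces / 120) / log(4))
  for (s in seq_len(k)) m <- subdivide_midpoint(m$nodes, m$faces)
  r <- sqrt(rowSums(m$nodes^2))
  nodes <- m$nodes / r * (diameter / 2)
  # rotate so the marker node (node 1) starts on the +x axis, the
  # conventional initial orientation vector P
  v <- nodes[1, ] / sqrt(sum(nodes[1, ]^2))
  ax <- pracma_cross(v, c(1, 0, 0))
  s2 <- sum(ax^2)
  if (s2 > 1e-24) {
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    R <- diag(3) + K + K %*% K * (1 - v[1]) / s2
    nodes <- nodes %*% t(R)
  }
  nodes <- sweep(nodes, 2, centre, "+")
  membrane_mesh(nodes, m$faces, moduli)
}

#' Mirror a membrane mesh across a coordinate plane
#'
#' Reflects the node positions about `centre` along one axis and swaps
#' the face winding so the surface stays outward-oriented. Used for
#' exact paired-run symmetry checks: the sphere triangulation is chiral,
#' so mirroring only the release position is not an exact symmetry of
#' the discrete dynamics.
#'
#' @param mesh A [membrane_mesh()].
#' @param axis Axis index (1, 2 or 3) to reflect.
#' @param centre Coordinate of the mirror plane along `axis`.
#' @return A new [membrane_mesh()] with refreshed reference geometry
#'   (all reference quantities are reflection-invariant).
#' @export
mirror_mesh <- function(mesh, axis = 3, centre = 0) {
  nodes <- mesh$nodes
  nodes[, axis] <- 2 * centre - nodes[, axis]
  membrane_mesh(nodes, mesh$faces[, c(1, 3, 2)], mesh$moduli)
}

#' In-plane strain invariants of one deformed triangle
#'
#' I1 = lambda1^2 + lambda2^2 - 2 and I2 = lambda1^2 lambda2^2 - 1, where
#' lambda are the principal in-plane stretches of the map from the
#' reference to the deformed triangle. Computed metrically (edge lengths
#' and areas), so no planar embedding is needed.
#'
#' @param ref 3 x 3 matrix, one reference vertex per row.
#' @param def 3 x 3 matrix of deformed vertices.
#' @return Named vector c(I1, I2).
#' @export
face_strain_invariants <- function(ref, def) {
  E1 <- ref[2, ] - ref[1, ]; E2 <- ref[3, ] - ref[1, ]
  c11 <- sum(E1^2); c12 <- sum(E1 * E2); c22 <- sum(E2^2)
  det0 <- c11 * c22 - c12^2
  e1 <- def[2, ] - def[1, ]; e2 <- def[3, ] - def[1, ]
  d11 <- sum(e1^2); d12 <- sum(e1 * e2); d22 <- sum(e2^2)
  I1 <- (c22 * d11 - 2 * c12 * d12 + c11 * d22) / det0 - 2
  I2 <- (d11 * d22 - d12^2) / det0 - 1
  c(I1 = I1, I2 = I2)
}

#' Principal in-plane stretches per face
#'
#' @param mesh A [membrane_mesh()].
#' @param nodes Deformed node positions (defaults to the reference).
#' @return nF x 2 matrix of (lambda1, lambda2), lambda1 >= lambda2.
#' @export
face_stretches <- function(mesh, nodes = mesh$nodes) {
  inv <- strain_invariant_fields(mesh, nodes)
  tr <- inv$I1 + 2; dt <- inv$I2 + 1
  disc <- sqrt(pmax(tr^2 - 4 * dt, 0))
  cbind(sqrt((tr + disc) / 2), sqrt(pmax((tr - disc) / 2, 0)))
}

strain_invariant_fields <- function(mesh, nodes) {
  faces <- mesh$faces; M <- mesh$ref$M
  e1 <- nodes[faces[, 2], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  e2 <- nodes[faces[, 3], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  d11 <- rowSums(e1^2); d12 <- rowSums(e1 * e2); d22 <- rowSums(e2^2)
  n2 <- d11 * d22 - d12^2
  if (any(n2 <= 0)) {
    stop("degenerate deformed face ", which(n2 <= 0)[1])
  }
  detM <- M[, 1] * M[, 3] - M[, 2]^2
  list(I1 = M[, 1] * d11 + 2 * M[, 2] * d12 + M[, 3] * d22 - 2,
       I2 = n2 * detM - 1)
}

#' In-plane strain energy of the membrane
#'
#' Per element, kappa_S/12 (I1^2 + 2 I1 - 2 I2) + kappa_alpha/12 I2^2,
#' weighted by the element's reference area (the moduli are surface
#' densities, N/m, so the weight makes the sum an energy).
#'
#' @param mesh A [membrane_mesh()].
#' @param nodes Deformed node positions (nV x 3); defaults to reference.
#' @return Scalar energy.
#' @export
strain_energy <- function(mesh, nodes = mesh$nodes) {
  inv <- strain_invariant_fields(mesh, nodes)
  ks <- mesh$moduli$ks; ka <- mesh$moduli$kalpha
  sum(mesh$ref$A0f * (ks / 12 * (inv$I1^2 + 2 * inv$I1 - 2 * inv$I2) +
                        ka / 12 * inv$I2^2))
}

#' Bending, area and volume energies
#'
#' E_B = kappa_B/2 sum over the 3N/2 edges of (phi - phi_0)^2;
#' E_A = kappa_A/2 (A - A_0)^2 / A_0; E_V = kappa_V/2 (V - V_0)^2 / V_0.
#' The bending reference angles are those of the constructed sphere
#' (non-flat reference).
#'
#' @inheritParams strain_energy
#' @return Named vector c(E_B, E_A, E_V).
#' @export
bending_area_volume_energies <- function(mesh, nodes = mesh$nodes) {
  phi <- dihedral_angles(nodes, mesh$edges)
  A <- mesh_area(nodes, mesh$faces)
  V <- mesh_volume(nodes, mesh$faces)
  c(E_B = mesh$moduli$kb / 2 * sum((phi - mesh$ref$phi0)^2),
    E_A = mesh$moduli$ka / 2 * (A - mesh$ref$A0)^2 / mesh$ref$A0,
    E_V = mesh$moduli$kv / 2 * (V - mesh$ref$V0)^2 / mesh$ref$V0)
}

#' Total membrane deformation energy
#' @inheritParams strain_energy
#' @return Scalar E_S + E_B + E_A + E_V.
#' @export
total_membrane_energy <- function(mesh, nodes = mesh$nodes) {
  strain_energy(mesh, nodes) + sum(bending_area_volume_energies(mesh, nodes))
}

#' Nodal restoring forces
#'
#' Analytic gradient f(x_n) = -dE/dx_n of the total membrane energy with
#' respect to every node position (computed in compiled code; validated
#' against central finite differences of the R energy implementation in
#' the test suite).
#'
#' @inheritParams strain_energy
#' @return nV x 3 matrix of forces.
#' @export
nodal_forces <- function(mesh, nodes = mesh$nodes) {
  cpp_membrane_forces(nodes, mesh$faces, mesh$edges, mesh$ref$M,
                      mesh$ref$A0f, mesh$ref$phi0, mesh$ref$A0, mesh$ref$V0,
                      unlist(mesh$moduli[c("ks", "kalpha", "kb", "ka", "kv")]))
}
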