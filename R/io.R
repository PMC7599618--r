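# Output writers: legacy-ASCII VTK structured grids for flow snapshots,
# OFF/PLY particle meshes, trajectory CSV, and RDS checkpoints (exact
# restart: all populations of both lattices plus the particle nodes).

#' Write a flow snapshot as legacy ASCII VTK
#'
#' Structured-points dataset holding density, pressure, velocity, the six
#' packed stress components and N1; readable by ParaView/VisIt.
#'
#' @param run A `viscolbm_run` (or a list with `domain` and `fields`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vtk_snapshot <- function(run, path) {
  dims <- run$domain$dims
  f <- run$fields
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("viscolbm flow snapshot (lattice units)")
  wl("ASCII")
  wl("DATASET STRUCTURED_POINTS")
  wl("DIMENSIONS %d %d %d", dims[1], dims[2], dims[3])
  wl("ORIGIN 0 0 0")
  wl("SPACING 1 1 1")
  wl("POINT_DATA %d", prod(dims))
  scalar <- function(name, v) {
    wl("SCALARS %s double 1", name)
    wl("LOOKUP_TABLE default")
    writeLines(format(v, digits = 9, trim = TRUE, scientific = TRUE), con)
  }
  scalar("rho", f$rho)
  scalar("pressure", f$pressure)
  wl("VECTORS velocity double")
  writeLines(apply(format(t(f$u), digits = 9, trim = TRUE,
                          scientific = TRUE), 1, paste, collapse = " "), con)
  comp <- c("xx", "yy", "zz", "xy", "xz", "yz")
  for (m in seq_along(comp)) scalar(paste0("tau_", comp[m]), f$tau[m, ])
  scalar("N1", f$N1)
  invisible(path)
}

#' Write the particle trajectory as CSV
#'
#' Schema: step, y, z (normalised cross-section coordinates), theta_x,
#' theta_y, theta_z (degrees), omega (rad/step), plus the raw lattice
#' centroid.
#'
#' @param run A `viscolbm_run`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(run, path) {
  tr <- run$trajectory
  if (!nrow(tr)) {
    utils::write.csv(tr, path, row.names = FALSE)
    return(invisible(path))
  }
  out <- data.frame(step = tr$step, y = tr$y_n, z = tr$z_n,
                    theta_x = tr$theta_x, theta_y = tr$theta_y,
                    theta_z = tr$theta_z, omega = tr$omega,
                    x_lat = tr$x, y_lat = tr$y, z_lat = tr$z)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Save / load an exact-restart checkpoint
#'
#' The checkpoint holds every population of both lattices, the cached
#' source tensor, the particle nodes and the step counter; resuming from
#' it reproduces an uninterrupted run bit for bit.
#'
#' @param run A `viscolbm_run` (or a bare state list).
#' @param path Checkpoint file (RDS).
#' @return `path` invisibly (`save_checkpoint`); the checkpoint list
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(run, path) {
  ck <- if (inherits(run, "viscolbm_run")) {
    list(state = run$state, config = run$config)
  } else list(state = run, config = NULL)
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Write a triangulated mesh in OFF format
#'
#' @param mesh A [membrane_mesh()] (or list with `nodes` and `faces`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$nodes), nrow(mesh$faces)), con)
  writeLines(apply(format(mesh$nodes, digits = 12, trim = TRUE), 1,
                   paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1, mesh$faces[, 2] - 1,
                   mesh$faces[, 3] - 1), con)
  invisible(path)
}

#' Read an OFF mesh
#'
#' @param path OFF file.
#' @param moduli Moduli for the reconstructed [membrane_mesh()].
#' @return A [membrane_mesh()].
#' @export
read_off <- function(path, moduli = rigid_moduli()) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (trimws(lines[1]) != "OFF") stop("not an OFF file")
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  nodes <- matrix(scan(text = paste(lines[3:(2 + nv)], collapse = "\n"),
                       quiet = TRUE), nv, 3, byrow = TRUE)
  fr <- matrix(scan(text = paste(lines[(3 + nv):(2 + nv + nf)], collapse = "\n"),
                    quiet = TRUE), nf, 4, byrow = TRUE)
  membrane_mesh(nodes, fr[, 2:4] + 1L, moduli)
}

#' Write a triangulated mesh in ASCII PLY format
#'
#' @inheritParams write_off
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$nodes)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(format(mesh$nodes, digits = 12, trim = TRUE), 1,
                   paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1, mesh$faces[, 2] - 1,
                   mesh$faces[, 3] - 1), con)
  invisible(path)
}
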