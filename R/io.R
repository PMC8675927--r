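#' Export a tissue mesh as Wavefront OBJ
#'
#' Cells are written as triangulated surfaces (fan triangulation of the
#' apical, basal and lateral faces).
#'
#' @param mesh a `tissue_mesh`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_mesh_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  V <- mesh$vertices
  writeLines(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  tri <- .mesh_triangles(mesh)
  writeLines(sprintf("f %d %d %d", tri[, 1], tri[, 2], tri[, 3]), con)
  invisible(path)
}

#' Export a tissue mesh as legacy-ASCII VTK
#'
#' @inheritParams export_mesh_obj
#' @param scalars optional named list of per-cell scalar fields to attach as
#'   CELL_DATA (each replicated over the cell's triangles).
#' @export
export_mesh_vtk <- function(mesh, path, scalars = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  V <- mesh$vertices
  tri <- .mesh_triangles(mesh)
  writeLines(c("# vtk DataFile Version 3.0", "epifold tissue mesh", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nrow(V))), con)
  writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(tri), 4 * nrow(tri)), con)
  writeLines(sprintf("3 %d %d %d", tri[, 1] - 1L, tri[, 2] - 1L, tri[, 3] - 1L), con)
  if (!is.null(scalars)) {
    writeLines(sprintf("CELL_DATA %d", nrow(tri)), con)
    for (nm in names(scalars)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", scalars[[nm]][attr(tri, "cell")]), con)
    }
  }
  invisible(path)
}

# triangulated faces of every cell; attribute "cell" maps triangles to cells
.mesh_triangles <- function(mesh) {
  out <- list()
  cellof <- list()
  m <- ncol(mesh$apical)
  for (c in seq_len(mesh$n_cells)) {
    ap <- mesh$apical[c, ]
    ba <- mesh$basal[c, ]
    tris <- rbind(
      cbind(ap[1], ap[2:(m - 1)], ap[3:m]),
      cbind(ba[1], ba[3:m], ba[2:(m - 1)]),
      do.call(rbind, lapply(1:m, function(k) {
        k2 <- if (k == m) 1L else k + 1L
        rbind(c(ap[k], ba[k], ba[k2]), c(ap[k], ba[k2], ap[k2]))
      })))
    out[[c]] <- tris
    cellof[[c]] <- rep(c, nrow(tris))
  }
  tri <- do.call(rbind, out)
  attr(tri, "cell") <- unlist(cellof)
  tri
}

#' Write a membrane profile as CSV
#'
#' Columns: `s`, `s_over_L`, `A`, `P`, `B` (one row per node).
#'
#' @param field a `membrane_field`.
#' @param path output file.
#' @export
write_profile_csv <- function(field, path) {
  df <- data.frame(s = field$s, s_over_L = field$s / field$L,
                   A = field$conc[, 1], P = field$conc[, 2],
                   B = field$conc[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a coupled-run trajectory as long-format CSV
#'
#' One row per (time, cell) with `psi`, `L`, `ell_domain`, the four q
#' components and the tissue fold depth.
#'
#' @param traj a `fold_trajectory`.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  nt <- length(traj$times)
  nc <- ncol(traj$psi)
  df <- data.frame(
    time = rep(traj$times, nc),
    cell = rep(seq_len(nc), each = nt),
    psi = as.vector(traj$psi), L = as.vector(traj$L),
    ell_domain = as.vector(traj$ell_domain),
    q_K_a = as.vector(traj$q[, seq_len(nc)]),
    q_P_hat_o = as.vector(traj$q[, nc + seq_len(nc)]),
    q_lambda_b = as.vector(traj$q[, 2 * nc + seq_len(nc)]),
    q_lambda_ell = as.vector(traj$q[, 3 * nc + seq_len(nc)]),
    fold_depth = rep(traj$fold_depth, nc))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
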