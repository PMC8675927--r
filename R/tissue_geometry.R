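#' Build a flat monolayer of hexagonal-prism cells
#'
#' Constructs a hexagonally packed patch of `1 + 3 n (n + 1)` congruent
#' regular hexagonal prisms (for `n = n_rings`), with shared vertices and a
#' deduplicated registry of lateral faces. The apical surface sits at
#' `z = height`, the basal surface at `z = 0`; one model length unit
#' corresponds to 10 um.
#'
#' @param n_rings number of rings around the central cell (0 = single cell).
#' @param apical_radius circumradius of each hexagonal cross-section
#'   (centroid-to-vertex distance), model length units.
#' @param height prism height (apical-basal extent), model length units.
#' @return an object of class `tissue_mesh`: a list with `vertices`
#'   (n x 3 matrix), `apical`/`basal` (cell x 6 vertex-index matrices, apical
#'   loops counter-clockwise seen from above), `faces` (list with `verts`
#'   (n_face x 4), `owner` (n_face x 2; second column 0 for boundary faces)),
#'   `boundary_cells`, and `n_cells`.
#' @examples
#' mesh <- build_hexagonal_tissue(1)
#' mesh$n_cells  # 7
#' @export
build_hexagonal_tissue <- function(n_rings, apical_radius = 0.45, height = 1.8) {
  if (length(n_rings) != 1L || is.na(n_rings) || n_rings < 0 ||
      n_rings != round(n_rings))
    stop("'n_rings' must be a non-negative integer")
  if (!is.numeric(apical_radius) || apical_radius <= 0)
    stop("'apical_radius' must be positive")
  if (!is.numeric(height) || height <= 0)
    stop("'height' must be positive")
  R <- apical_radius

  # axial coordinates of cell centres on the triangular lattice
  ax <- expand.grid(m = -n_rings:n_rings, n = -n_rings:n_rings)
  ax <- ax[pmax(abs(ax$m), abs(ax$n), abs(ax$m + ax$n)) <= n_rings, , drop = FALSE]
  e1 <- c(1.5 * R, sqrt(3) / 2 * R)
  e2 <- c(0, sqrt(3) * R)
  centers <- cbind(ax$m * e1[1] + ax$n * e2[1], ax$m * e1[2] + ax$n * e2[2])
  n_cells <- nrow(centers)

  ang <- (0:5) * pi / 3                      # CCW from above
  hx <- R * cos(ang)
  hy <- R * sin(ang)

  # global vertex table with deduplication by rounded coordinates
  key_env <- new.env(hash = TRUE, parent = emptyenv())
  verts <- matrix(0, 0, 3)
  vcount <- 0L
  vbuf <- vector("list", 2 * 6 * n_cells)
  get_vertex <- function(x, y, z) {
    key <- paste(round(x / R, 9L), round(y / R, 9L), round(z, 9L))
    id <- key_env[[key]]
    if (is.null(id)) {
      vcount <<- vcount + 1L
      vbuf[[vcount]] <<- c(x, y, z)
      key_env[[key]] <- vcount
      id <- vcount
    }
    id
  }
  apical <- matrix(0L, n_cells, 6)
  basal <- matrix(0L, n_cells, 6)
  for (c in seq_len(n_cells)) {
    for (k in 1:6) {
      x <- centers[c, 1] + hx[k]
      y <- centers[c, 2] + hy[k]
      apical[c, k] <- get_vertex(x, y, height)
      basal[c, k] <- get_vertex(x, y, 0)
    }
  }
  vertices <- do.call(rbind, vbuf[seq_len(vcount)])
  colnames(vertices) <- c("x", "y", "z")

  # lateral face registry, deduplicated by the (sorted) apical edge
  fenv <- new.env(hash = TRUE, parent = emptyenv())
  fverts <- vector("list", 6 * n_cells)
  fowner <- vector("list", 6 * n_cells)
  nf <- 0L
  for (c in seq_len(n_cells)) {
    for (k in 1:6) {
      k2 <- if (k == 6) 1L else k + 1L
      e <- sort(c(apical[c, k], apical[c, k2]))
      key <- paste(e[1], e[2])
      id <- fenv[[key]]
      if (is.null(id)) {
        nf <- nf + 1L
        fverts[[nf]] <- c(apical[c, k], apical[c, k2], basal[c, k2], basal[c, k])
        fowner[[nf]] <- c(c, 0L)
        fenv[[key]] <- nf
      } else {
        fowner[[id]][2] <- c
      }
    }
  }
  faces <- list(verts = do.call(rbind, fverts[seq_len(nf)]),
                owner = do.call(rbind, fowner[seq_len(nf)]))
  storage.mode(faces$verts) <- "integer"
  storage.mode(faces$owner) <- "integer"

  has_boundary_face <- rep(FALSE, n_cells)
  bnd <- faces$owner[, 2] == 0L
  has_boundary_face[faces$owner[bnd, 1]] <- TRUE

  mesh <- list(vertices = vertices, apical = apical, basal = basal,
               faces = faces, boundary_cells = which(has_boundary_face),
               n_cells = n_cells, axial = cbind(m = ax$m, n = ax$n),
               apical_radius = R, height = height)
  class(mesh) <- "tissue_mesh"
  validate_tissue_mesh(mesh)
  mesh
}

validate_tissue_mesh <- function(mesh) {
  stopifnot(is.matrix(mesh$vertices), ncol(mesh$vertices) == 3)
  if (!all(is.finite(mesh$vertices))) stop("non-finite vertex positions")
  if (ncol(mesh$apical) != ncol(mesh$basal))
    stop("apical and basal loops must have equal length")
  # every shared face registered exactly once
  o <- mesh$faces$owner
  if (any(o[, 1] == o[, 2])) stop("face owned twice by the same cell")
  invisible(mesh)
}

#' @export
print.tissue_mesh <- function(x, ...) {
  nshared <- sum(x$faces$owner[, 2] != 0L)
  cat("tissue_mesh:", x$n_cells, "hexagonal-prism cells,",
      nrow(x$vertices), "vertices\n")
  cat("  lateral faces:", nrow(x$faces$verts), "(", nshared, "shared,",
      nrow(x$faces$verts) - nshared, "boundary )\n")
  cat("  boundary cells:", length(x$boundary_cells), "\n")
  invisible(x)
}

#' Select the initiating-cell population
#'
#' Returns the ids of the cells in which a polarity or mechanical
#' perturbation is applied: either a concentric patch (central cell plus its
#' first ring) or a straight row of cells through the centre (which produces
#' a furrow-like rather than pit-like fold).
#'
#' @param mesh a `tissue_mesh`.
#' @param mode `"concentric"` or `"line"`.
#' @return integer vector of cell ids.
#' @export
initiating_cells <- function(mesh, mode = c("concentric", "line")) {
  mode <- match.arg(mode)
  if (mesh$n_cells < 1) stop("empty mesh")
  ax <- mesh$axial
  hexdist <- pmax(abs(ax[, 1]), abs(ax[, 2]), abs(ax[, 1] + ax[, 2]))
  if (mode == "concentric") which(hexdist <= 1L) else which(ax[, 2] == 0L)
}

#' Per-cell shape summary
#'
#' Measures one cell (or all cells) of the mesh: mean centroid-to-vertex
#' distances of the apical and basal faces (`a`, `b`), mean lateral edge
#' length (`ell`), membrane half-perimeter `L = a + b + ell`, face areas by
#' fan triangulation, volume by tetrahedral decomposition about the cell
#' centroid, surface-to-volume ratio `psi = (A_a + A_b + A_ell) / V`, and the
#' apical perimeter.
#'
#' @param mesh a `tissue_mesh`.
#' @param cell_id cell index, or `NULL` for all cells.
#' @return a one-row data frame (or `n_cells` rows when `cell_id` is `NULL`)
#'   with columns `a`, `b`, `ell`, `L`, `A_a`, `A_b`, `A_ell`, `V`, `psi`,
#'   `P_hat_a`.
#' @export
cell_shape_summary <- function(mesh, cell_id = NULL) {
  g <- cpp_cell_geometry(mesh$vertices, mesh$apical, mesh$basal,
                         mesh$faces$verts, mesh$faces$owner)
  g <- as.data.frame(g)
  if (is.null(cell_id)) return(g)
  if (any(cell_id < 1L | cell_id > mesh$n_cells)) stop("no such cell")
  g[cell_id, , drop = FALSE]
}

#' Boundary constraint mask
#'
#' `free` applies no constraint (the default boundary condition of the
#' simulations). `pin_plane` confines all vertices of the rim cells to their
#' horizontal plane: their vertical displacement is projected out at every
#' mechanics step.
#'
#' @param mesh a `tissue_mesh`.
#' @param mode `"free"` or `"pin_plane"`.
#' @return integer vector of vertex ids whose z-motion is suppressed (empty
#'   for `"free"`).
#' @export
boundary_constraint <- function(mesh, mode = c("free", "pin_plane")) {
  mode <- match.arg(mode)
  if (mode == "free") return(integer(0))
  ids <- unique(c(mesh$apical[mesh$boundary_cells, ],
                  mesh$basal[mesh$boundary_cells, ]))
  sort(ids)
}

#' Displace a set of vertices
#'
#' Utility used by tests and scenario runners: returns a copy of the mesh
#' with given vertices translated.
#' @param mesh a `tissue_mesh`.
#' @param ids vertex ids.
#' @param dx length-3 displacement.
#' @export
displace_vertices <- function(mesh, ids, dx) {
  mesh$vertices[ids, 1] <- mesh$vertices[ids, 1] + dx[1]
  mesh$vertices[ids, 2] <- mesh$vertices[ids, 2] + dx[2]
  mesh$vertices[ids, 3] <- mesh$vertices[ids, 3] + dx[3]
  mesh
}
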