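# shared fixtures, memoised across test files (steady states are the
# expensive part of the suite)
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# the reference columnar cell (h = 1.8, r = 0.45) and its shape summary
reference_geometry <- function() {
  memo("refgeom", cell_shape_summary(build_hexagonal_tissue(0), 1))
}

# polarized membrane steady state at the published parameters
ref_steady_state <- function(n_nodes = 128L) {
  memo(paste0("ss", n_nodes), {
    g <- reference_geometry()
    p <- polarity_params()
    f0 <- initial_condition(g$a, g$ell, g$b, p, g$psi, n_nodes = n_nodes)
    integrate_to_steady_state(f0, p, g$psi, dt = 0.1, tol = 1e-7)
  })
}

ref_tissue <- function(n_rings, n_nodes = 128L) {
  memo(paste0("sys", n_rings, "_", n_nodes),
       setup_reference_tissue(n_rings = n_rings, n_nodes = n_nodes))
}

# central-difference gradient of the single-cell potential in (h, r)
num_grad_single <- function(h, r, Po, K_a, lb, ll, step = 1e-5) {
  f <- function(hh, rr) single_cell_potential(hh, rr, Po, K_a, lb, ll)
  c(h = (f(h + step, r) - f(h - step, r)) / (2 * step),
    r = (f(h, r + step) - f(h, r - step)) / (2 * step))
}

num_hess_single <- function(h, r, Po, K_a, lb, ll, step = 1e-3) {
  f <- function(hh, rr) single_cell_potential(hh, rr, Po, K_a, lb, ll)
  one <- function(s) {
    c(M11 = (f(h + s, r) - 2 * f(h, r) + f(h - s, r)) / s^2,
      M22 = (f(h, r + s) - 2 * f(h, r) + f(h, r - s)) / s^2,
      M12 = (f(h + s, r + s) - f(h + s, r - s) -
             f(h - s, r + s) + f(h - s, r - s)) / (4 * s^2))
  }
  (4 * one(step / 2) - one(step)) / 3   # Richardson-extrapolated
}

# independent divergence-theorem volume over an explicit triangle soup
# (each row: the 9 coordinates of one outward-oriented triangle)
divergence_volume <- function(tris) {
  sum(tris[, 1] * (tris[, 5] * tris[, 9] - tris[, 8] * tris[, 6]) -
      tris[, 4] * (tris[, 2] * tris[, 9] - tris[, 8] * tris[, 3]) +
      tris[, 7] * (tris[, 2] * tris[, 6] - tris[, 5] * tris[, 3])) / 6
}

# outward-oriented centroid-fan triangulation of one cell's surface (the
# same surface definition the geometry code uses: every face fanned about
# its own centroid)
cell_triangles <- function(mesh, cell) {
  V <- mesh$vertices
  fan <- function(loop) {
    pts <- V[loop, , drop = FALSE]
    ctr <- colMeans(pts)
    m <- nrow(pts)
    do.call(rbind, lapply(seq_len(m), function(k) {
      k2 <- if (k == m) 1L else k + 1L
      c(ctr, pts[k, ], pts[k2, ])
    }))
  }
  ap <- mesh$apical[cell, ]
  ba <- mesh$basal[cell, ]
  tris <- rbind(fan(ap), fan(rev(ba)))
  m <- length(ap)
  for (k in 1:m) {
    k2 <- if (k == m) 1L else k + 1L
    tris <- rbind(tris, fan(c(ap[k], ba[k], ba[k2], ap[k2])))
  }
  tris
}
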