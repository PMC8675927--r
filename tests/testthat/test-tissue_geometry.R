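test_that("hexagonal patch construction gives the expected counts", {
  m0 <- build_hexagonal_tissue(0)
  expect_equal(m0$n_cells, 1L)
  expect_equal(nrow(m0$vertices), 12L)
  expect_equal(nrow(m0$faces$verts), 6L)
  expect_equal(sum(m0$faces$owner[, 2] != 0L), 0L)

  expect_equal(build_hexagonal_tissue(2)$n_cells, 19L)
  expect_equal(build_hexagonal_tissue(3)$n_cells, 37L)

  expect_error(build_hexagonal_tissue(-1), "n_rings")
  expect_error(build_hexagonal_tissue(1, apical_radius = 0), "positive")
  expect_error(build_hexagonal_tissue(1, height = -2), "positive")
})

test_that("shared lateral faces match a brute-force pairwise scan", {
  mesh <- build_hexagonal_tissue(1)
  # oracle: enumerate all 6 lateral faces of each prism independently as
  # vertex-id quadruples and count duplicates by quadratic scan
  quads <- list()
  for (c in seq_len(mesh$n_cells)) {
    for (k in 1:6) {
      k2 <- if (k == 6) 1L else k + 1L
      quads[[length(quads) + 1]] <- sort(c(mesh$apical[c, k], mesh$apical[c, k2],
                                           mesh$basal[c, k], mesh$basal[c, k2]))
    }
  }
  expect_length(quads, 42L)
  dup <- 0L
  for (i in seq_along(quads)) for (j in seq_len(i - 1L))
    if (identical(quads[[i]], quads[[j]])) dup <- dup + 1L
  n_shared <- sum(mesh$faces$owner[, 2] != 0L)
  expect_equal(n_shared, dup)
  expect_equal(nrow(mesh$faces$verts), 42L - dup)
  # every shared face registered exactly once
  expect_equal(anyDuplicated(apply(mesh$faces$verts, 1,
                                   function(v) paste(sort(v), collapse = "-"))), 0L)
})

test_that("cell shape summary reproduces closed-form prism geometry", {
  g <- cell_shape_summary(build_hexagonal_tissue(0, 1, 1), 1)
  expect_equal(g$a, 1)
  expect_equal(g$b, 1)
  expect_equal(g$ell, 1)
  expect_equal(g$L, 3)
  expect_equal(g$A_a, 3 * sqrt(3) / 2)
  expect_equal(g$A_b, 3 * sqrt(3) / 2)
  expect_equal(g$A_ell, 6)
  expect_equal(g$V, 3 * sqrt(3) / 2)
  expect_equal(g$psi, (3 * sqrt(3) + 6) / (3 * sqrt(3) / 2))
  expect_equal(g$P_hat_a, 6)

  # scaling law: double all axes -> psi halves, L doubles
  g2 <- cell_shape_summary(build_hexagonal_tissue(0, 2, 2), 1)
  expect_equal(g2$psi, g$psi / 2)
  expect_equal(g2$L, 2 * g$L)

  # L = a + b + ell exactly and psi = area/volume exactly
  expect_identical(g$L, g$a + g$b + g$ell)
  expect_equal(g$psi, (g$A_a + g$A_b + g$A_ell) / g$V, tolerance = 1e-15)
})

test_that("volume of a perturbed prism matches the divergence-theorem oracle", {
  set.seed(42)
  mesh <- build_hexagonal_tissue(0)
  mesh$vertices <- mesh$vertices + 0.03 * matrix(rnorm(36), 12, 3)
  g <- cell_shape_summary(mesh, 1)
  V_oracle <- divergence_volume(cell_triangles(mesh, 1))
  expect_equal(g$V, V_oracle, tolerance = 1e-10)
})

test_that("psi and L are invariant under rigid motion", {
  set.seed(7)
  mesh <- build_hexagonal_tissue(1)
  mesh$vertices <- mesh$vertices + 0.02 * matrix(rnorm(3 * nrow(mesh$vertices)),
                                                 ncol = 3)
  g0 <- cell_shape_summary(mesh)
  th <- 0.73
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ax <- pi / 5
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  mesh$vertices <- sweep(mesh$vertices %*% t(Rx %*% R), 2, c(1.3, -0.4, 2.2), "+")
  g1 <- cell_shape_summary(mesh)
  expect_equal(g1$psi, g0$psi, tolerance = 1e-12)
  expect_equal(g1$L, g0$L, tolerance = 1e-12)
  expect_equal(g1$V, g0$V, tolerance = 1e-12)
})

test_that("per-cell volumes of a flat patch tile space without gaps", {
  mesh <- build_hexagonal_tissue(2)
  g <- cell_shape_summary(mesh)
  single <- cell_shape_summary(build_hexagonal_tissue(0), 1)
  expect_equal(sum(g$V), mesh$n_cells * single$V, tolerance = 1e-12)
})

test_that("initiating-cell layouts select the documented populations", {
  m2 <- build_hexagonal_tissue(2)
  expect_length(initiating_cells(m2, "concentric"), 7L)
  line <- initiating_cells(m2, "line")
  expect_length(line, 5L)
  # the line is a straight row: constant axial second coordinate
  expect_true(all(m2$axial[line, 2] == 0L))
  expect_length(initiating_cells(build_hexagonal_tissue(0), "line"), 1L)
})

test_that("boundary constraints pin rim-cell vertices vertically", {
  m2 <- build_hexagonal_tissue(2)
  expect_length(boundary_constraint(m2, "free"), 0L)
  pin <- boundary_constraint(m2, "pin_plane")
  expect_length(m2$boundary_cells, 12L)  # 6 * n_rings rim cells
  expect_setequal(pin, unique(c(m2$apical[m2$boundary_cells, ],
                                m2$basal[m2$boundary_cells, ])))
  expect_error(boundary_constraint(m2, "everywhere"))

  # pinned vertices keep their z under mechanics with vertical forces
  mech <- mechanical_state(m2$n_cells)
  mech$V_o[] <- 1.3   # inflate: vertical forces on every face
  mesh <- m2
  z0 <- mesh$vertices[pin, 3]
  for (i in 1:100) mesh <- step_mechanics(mesh, mech, dt = 0.05,
                                          constraint = pin)
  expect_equal(mesh$vertices[pin, 3], z0, tolerance = 1e-14)
  expect_gt(max(abs(mesh$vertices[-pin, 3] - m2$vertices[-pin, 3])), 1e-4)
})
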