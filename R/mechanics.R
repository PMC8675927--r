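#' Per-cell mechanical parameters of the vertex model
#'
#' Holds, for each cell: apical elastic modulus `K_a`, preferred apical
#' perimeter `P_hat_o`, basal surface tension `lambda_b`, per-owner lateral
#' surface tension `lambda_ell` (a shared face carries the sum of its two
#' owners' tensions, so interior faces are twice as tense as boundary ones),
#' volume elastic modulus `K_V` and preferred volume `V_o`; plus the global
#' friction coefficient `eta` and the 4-column modulation matrix `q`
#' (normalized `K_a`, `P_hat_o`, `lambda_b`, `lambda_ell`; effective
#' parameter = initial value x q).
#'
#' Defaults are the exact force-balance values for the reference columnar
#' cell (`h = 1.8`, `r = 0.45`, `P_hat_o = 2.16`), which round to the
#' published 0.0172 / 0.0477 / 0.0207.
#'
#' @param n_cells number of cells.
#' @param K_a,P_hat_o,lambda_b,lambda_ell,K_V,V_o scalars or length-`n_cells`
#'   vectors.
#' @param eta friction coefficient (> 0).
#' @return object of class `mechanical_state`.
#' @export
mechanical_state <- function(n_cells, K_a = NULL, P_hat_o = 2.16,
                             lambda_b = NULL, lambda_ell = NULL,
                             K_V = 1, V_o = 1, eta = 1) {
  ref <- derive_balanced_parameters(h = 1.8, r = 0.45, P_hat_o = 2.16)
  if (is.null(K_a)) K_a <- ref$K_a
  if (is.null(lambda_b)) lambda_b <- ref$lambda_b
  if (is.null(lambda_ell)) lambda_ell <- ref$lambda_ell
  rep_n <- function(x) {
    if (length(x) == 1L) rep(as.numeric(x), n_cells)
    else if (length(x) == n_cells) as.numeric(x)
    else stop("parameter length must be 1 or n_cells")
  }
  m <- list(K_a = rep_n(K_a), P_hat_o = rep_n(P_hat_o),
            lambda_b = rep_n(lambda_b), lambda_ell = rep_n(lambda_ell),
            K_V = rep_n(K_V), V_o = rep_n(V_o), eta = as.numeric(eta),
            q = matrix(1, n_cells, 4,
                       dimnames = list(NULL, c("K_a", "P_hat_o",
                                               "lambda_b", "lambda_ell"))))
  if (any(m$K_a < 0) || any(m$K_V < 0)) stop("elastic moduli must be >= 0")
  if (any(m$V_o <= 0)) stop("'V_o' must be positive")
  if (m$eta <= 0) stop("'eta' must be positive")
  class(m) <- "mechanical_state"
  m
}

#' @export
print.mechanical_state <- function(x, ...) {
  cat("mechanical_state for", length(x$K_a), "cells\n")
  cat(sprintf("  K_a=%.4g  P_hat_o=%.4g  lambda_b=%.4g  lambda_ell=%.4g  K_V=%.3g  V_o=%.3g  eta=%.3g\n",
              x$K_a[1], x$P_hat_o[1], x$lambda_b[1], x$lambda_ell[1],
              x$K_V[1], x$V_o[1], x$eta))
  if (any(x$q != 1)) cat("  modulation active: range of q =",
                         paste(format(range(x$q), digits = 4), collapse = " .. "), "\n")
  invisible(x)
}

.mech_list <- function(mech) {
  list(K_a = mech$K_a, P_hat_o = mech$P_hat_o, lambda_b = mech$lambda_b,
       lambda_ell = mech$lambda_ell, K_V = mech$K_V, V_o = mech$V_o)
}

#' Tissue potential energy
#'
#' Sums, over cells, the apical perimeter elasticity
#' `K_a (P_hat_a - P_hat_o)^2`, the basal surface tension `lambda_b A_b` and
#' the volume elasticity `K_V (V - V_o)^2`; and, over registered lateral
#' faces, the tension times area, where a shared face carries the sum of its
#' two owners' `lambda_ell`.
#'
#' @param mesh a `tissue_mesh`.
#' @param mech a `mechanical_state`.
#' @return scalar energy.
#' @export
tissue_potential <- function(mesh, mech) {
  cpp_tissue_energy(mesh$vertices, mesh$apical, mesh$basal, mesh$faces$verts,
                    mesh$faces$owner, .mech_list(mech), mech$q)
}

#' Vertex forces
#'
#' Force on vertex j is `-dU/dr_j`, estimated by central finite differences
#' of the tissue potential, component-wise (only the energy terms incident
#' to the vertex are re-evaluated).
#'
#' @param mesh a `tissue_mesh`.
#' @param mech a `mechanical_state`.
#' @param fd_step finite-difference step (length units).
#' @return n_vertices x 3 matrix of forces.
#' @export
vertex_forces <- function(mesh, mech, fd_step = 1e-6) {
  if (fd_step <= 0) stop("'fd_step' must be positive")
  cpp_vertex_forces(mesh$vertices, mesh$apical, mesh$basal, mesh$faces$verts,
                    mesh$faces$owner, .mech_list(mech), mech$q, fd_step)
}

#' One overdamped Euler step of the vertex dynamics
#'
#' `r_j <- r_j + (dt / eta) F_j`; the vertical component of constrained
#' vertices is zeroed.
#'
#' @param mesh a `tissue_mesh`.
#' @param mech a `mechanical_state`.
#' @param dt time step.
#' @param constraint integer vector of z-pinned vertex ids (see
#'   [boundary_constraint()]).
#' @param fd_step finite-difference step for the forces.
#' @return the updated `tissue_mesh`.
#' @export
step_mechanics <- function(mesh, mech, dt, constraint = integer(0),
                           fd_step = 1e-6) {
  if (dt <= 0) stop("'dt' must be positive")
  F <- vertex_forces(mesh, mech, fd_step)
  if (length(constraint)) F[constraint, 3] <- 0
  V <- mesh$vertices + dt / mech$eta * F
  if (!all(is.finite(V))) stop("numerical divergence in mechanics step")
  mesh$vertices <- V
  mesh
}

#' Relax a tissue to force balance
#'
#' Gradient descent on the tissue potential until the largest force component
#' falls below `tol` or `max_steps` is reached.
#'
#' @inheritParams step_mechanics
#' @param tol force tolerance.
#' @param max_steps iteration cap.
#' @return the relaxed `tissue_mesh`, with attributes `"converged"`,
#'   `"steps"`, `"max_force"`, `"energy"`.
#' @export
relax_to_balance <- function(mesh, mech, dt = 0.05, tol = 1e-8,
                             max_steps = 200000L, constraint = integer(0),
                             fd_step = 1e-6) {
  res <- cpp_relax(mesh$vertices, mesh$apical, mesh$basal, mesh$faces$verts,
                   mesh$faces$owner, .mech_list(mech), mech$q, dt, mech$eta,
                   fd_step, tol, as.integer(max_steps),
                   as.integer(constraint))
  mesh$vertices <- res$vertices
  attr(mesh, "converged") <- res$converged
  attr(mesh, "steps") <- res$steps
  attr(mesh, "max_force") <- res$max_force
  attr(mesh, "energy") <- res$energy
  mesh
}
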