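#' Potential energy of a single regular hexagonal prism
#'
#' Closed form of the tissue potential for one cell shaped as a regular
#' hexagonal prism of height `h` and hexagon radius `r` (= apical length
#' `a` = basal length `b`), with all six lateral faces at tension
#' `lambda_ell`:
#' \deqn{U = K_V (V - V_o)^2 + K_a(6r - \hat P_o)^2 + \lambda_b A_b + \lambda_\ell (6 h r)}
#' with \eqn{V = (3\sqrt3/2) r^2 h} and \eqn{A_b = (3\sqrt3/2) r^2}.
#'
#' @param h,r prism height and hexagon radius.
#' @param P_hat_o preferred apical perimeter.
#' @param K_a,lambda_b,lambda_ell mechanical parameters.
#' @param K_V,V_o volume elasticity (defaults 1, the model's unit choice).
#' @return scalar energy.
#' @export
single_cell_potential <- function(h, r, P_hat_o, K_a, lambda_b, lambda_ell,
                                  K_V = 1, V_o = 1) {
  V <- 3 * sqrt(3) / 2 * r^2 * h
  Ab <- 3 * sqrt(3) / 2 * r^2
  K_V * (V - V_o)^2 + K_a * (6 * r - P_hat_o)^2 + lambda_b * Ab +
    lambda_ell * 6 * h * r
}

#' Mechanical parameters that balance a regular hexagonal prism
#'
#' Solves the force-balance conditions `dU/dh = dU/dr = 0` together with the
#' frustum-suppression condition (apical and basal radial forces separately
#' zero) for the unique `(K_a, lambda_b, lambda_ell)` that hold a regular
#' prism of height `h` and radius `r` stationary:
#' \deqn{K_a = \frac{h r (2\sqrt3 - 9 h r^2)}{16 (6 r - \hat P_o)}, \quad
#'       \lambda_b = \frac{h}{4}(2 - 3\sqrt3 h r^2), \quad
#'       \lambda_\ell = \frac{r}{4}(2\sqrt3 - 9 h r^2).}
#' Positive tensions require the cell to be volumetrically compressed
#' (`V < V_o`, i.e. `P_V = 2(1 - V) > 0`) and `P_hat_o < 6r`.
#'
#' @param h,r prism height and radius.
#' @param P_hat_o preferred apical perimeter (must differ from `6 r`).
#' @return list with `K_a`, `lambda_b`, `lambda_ell`, and the volume-elastic
#'   pressure `P_V`.
#' @export
derive_balanced_parameters <- function(h, r, P_hat_o) {
  if (h <= 0 || r <= 0) stop("'h' and 'r' must be positive")
  if (abs(6 * r - P_hat_o) < 1e-12)
    stop("singular configuration: P_hat_o equals the apical perimeter 6r")
  P_V <- 2 * (1 - 3 * sqrt(3) / 2 * r^2 * h)
  K_a <- h * r * (2 * sqrt(3) - 9 * h * r^2) / (16 * (6 * r - P_hat_o))
  lambda_b <- h / 4 * (2 - 3 * sqrt(3) * h * r^2)
  lambda_ell <- r / 4 * (2 * sqrt(3) - 9 * h * r^2)
  zap <- function(x) if (abs(x) < 1e-12) 0 else x   # uncompressed limit
  K_a <- zap(K_a); lambda_b <- zap(lambda_b); lambda_ell <- zap(lambda_ell)
  if (lambda_b < 0 || lambda_ell < 0 || K_a < 0)
    stop("infeasible shape: balanced tensions would be negative ",
         "(the cell must be volumetrically compressed and P_hat_o < 6r)")
  list(K_a = K_a, lambda_b = lambda_b, lambda_ell = lambda_ell, P_V = P_V)
}

#' Linear stability of a balanced prism shape
#'
#' Hessian of the single-cell potential with respect to `(h, r)`:
#' `M11 = (27/2) r^4`,
#' `M22 = -6 sqrt(3) h + 81 h^2 r^2 + 3 sqrt(3) lambda_b + 72 K_a`,
#' `M12 = 6 (-sqrt(3) r + 9 h r^3 + lambda_ell)`.
#' The shape is mechanically stable iff the trace and determinant of `M` are
#' both positive.
#'
#' @param h,r prism height and radius.
#' @param K_a,lambda_b,lambda_ell mechanical parameters at which to evaluate
#'   the Hessian.
#' @return list with `stable` (logical), `trace`, `det`, and the components
#'   `M11`, `M22`, `M12`.
#' @export
stability_check <- function(h, r, K_a, lambda_b, lambda_ell) {
  M11 <- 27 / 2 * r^4
  M22 <- -6 * sqrt(3) * h + 81 * h^2 * r^2 + 3 * sqrt(3) * lambda_b + 72 * K_a
  M12 <- 6 * (-sqrt(3) * r + 9 * h * r^3 + lambda_ell)
  tr <- M11 + M22
  de <- M11 * M22 - M12^2
  list(stable = tr > 0 && de > 0, trace = tr, det = de,
       M11 = M11, M22 = M22, M12 = M12)
}

#' Cell deformation metric
#'
#' `delta = sqrt((a - a_c)^2 + (b - b_c)^2 + (h - h_c)^2) / (a_c + b_c + h_c)`
#' -- the change of the three cell dimensions relative to the unperturbed
#' reference `(a_c, b_c, h_c)`.
#'
#' @param a,b,h deformed apical length, basal length, height.
#' @param a_c,b_c,h_c reference dimensions (> 0).
#' @return dimensionless deformation.
#' @export
cell_deformation_delta <- function(a, b, h, a_c, b_c, h_c) {
  if (any(c(a_c, b_c, h_c) <= 0)) stop("reference dimensions must be positive")
  sqrt((a - a_c)^2 + (b - b_c)^2 + (h - h_c)^2) / (a_c + b_c + h_c)
}

#' Tissue deformation metric
#'
#' `Delta = sqrt((D_a - D_ac)^2 + (D_b - D_bc)^2) / h_c` -- the change of the
#' apical and basal fold depths relative to the unperturbed reference,
#' normalized by the reference cell height.
#'
#' @param D_a,D_b apical and basal fold depths.
#' @param D_ac,D_bc reference fold depths.
#' @param h_c reference cell height (> 0).
#' @return dimensionless deformation.
#' @export
tissue_deformation_Delta <- function(D_a, D_b, D_ac, D_bc, h_c) {
  if (h_c <= 0) stop("'h_c' must be positive")
  sqrt((D_a - D_ac)^2 + (D_b - D_bc)^2) / h_c
}

#' Fold depth of a tissue surface
#'
#' Difference between the highest and the lowest vertex of the chosen
#' surface, signed so that an inward (towards basal, i.e. downward)
#' indentation relative to the tissue rim is positive and an outward bulge
#' negative.
#'
#' @param mesh a `tissue_mesh`.
#' @param surface `"apical"` or `"basal"`.
#' @return signed fold depth (length units).
#' @export
fold_depth <- function(mesh, surface = c("apical", "basal")) {
  surface <- match.arg(surface)
  loops <- if (surface == "apical") mesh$apical else mesh$basal
  ids <- unique(as.vector(loops))
  rim <- unique(as.vector(loops[mesh$boundary_cells, , drop = FALSE]))
  cpp_fold_depth(mesh$vertices, as.integer(ids), as.integer(rim))
}

#' Perturbation-deformation scan
#'
#' For each perturbation strength (percent), reduces the central cell's
#' preferred apical perimeter `P_hat_o` (raising `K_a` to `K_a_factor` times
#' its unperturbed value at the same time) or its Par-1 total, runs the
#' system to its final state with or without the mechano-polarity feedback,
#' and reports the central cell's deformation `delta` and the tissue
#' deformation `Delta` against the unperturbed reference. Without feedback
#' the final state is the mechanical force balance at fixed parameters; with
#' feedback a coupled simulation is run for `duration` time units.
#'
#' @param n_rings tissue size.
#' @param parameter `"P_hat_o"` or `"P_total"`.
#' @param strengths percent perturbations, in `[0, 100)`.
#' @param feedback logical; run with the homeostatic coupling active.
#' @param K_a_factor multiplicative change of `K_a` applied together with
#'   `P_hat_o` perturbations (default 9).
#' @param c_o coupling rates for the feedback runs.
#' @param duration simulated time of each feedback run.
#' @param n_nodes,dt numerics of the feedback runs.
#' @param system optional precomputed [setup_reference_tissue()] output.
#' @return data frame with columns `strength`, `delta`, `Delta`, `D_a`,
#'   `D_b`, `converged`.
#' @export
perturbation_scan <- function(n_rings = 1, parameter = c("P_hat_o", "P_total"),
                              strengths = c(0, 10, 20, 40), feedback = FALSE,
                              K_a_factor = 9, c_o = c(1, 1, 5.5, 5.5),
                              duration = 2500, n_nodes = 128L, dt = 0.1,
                              system = NULL) {
  parameter <- match.arg(parameter)
  if (any(strengths < 0 | strengths >= 100)) stop("strengths must be in [0, 100)")
  base <- if (is.null(system)) setup_reference_tissue(n_rings = n_rings,
                                                      n_nodes = n_nodes)
          else system
  center <- which(base$mesh$axial[, 1] == 0 & base$mesh$axial[, 2] == 0)
  ref <- .scan_run(base, center, parameter, 0, feedback, K_a_factor, c_o,
                   duration, dt)
  gc <- ref$geom[center, ]
  out <- lapply(strengths, function(st) {
    r <- if (st == 0) ref
         else .scan_run(base, center, parameter, st, feedback, K_a_factor,
                        c_o, duration, dt)
    g <- r$geom[center, ]
    data.frame(strength = st,
               delta = cell_deformation_delta(g$a, g$b, g$ell,
                                              gc$a, gc$b, gc$ell),
               Delta = tissue_deformation_Delta(r$D_a, r$D_b, ref$D_a,
                                                ref$D_b, gc$ell),
               D_a = r$D_a, D_b = r$D_b, converged = r$converged)
  })
  do.call(rbind, out)
}

# one scan member: perturb, evolve, measure
.scan_run <- function(base, center, parameter, strength, feedback,
                      K_a_factor, c_o, duration, dt) {
  mech <- base$mech
  if (strength > 0 && parameter == "P_hat_o") {
    mech$P_hat_o[center] <- mech$P_hat_o[center] * (1 - strength / 100)
    mech$K_a[center] <- mech$K_a[center] * K_a_factor
  }
  perturb <- if (parameter == "P_total" && strength > 0)
    list(cells = center, P_total_factor = 1 - strength / 100) else NULL
  if (feedback) {
    traj <- run_coupled_simulation(
      base$mesh, mech, base$fields, base$params,
      coupling_config(c_o = c_o, sigma = 0),
      perturbation = perturb, duration = duration, dt = dt,
      record_every = 1000L)
    mesh <- traj$final_mesh
    conv <- TRUE
  } else {
    if (!is.null(perturb)) {
      # biochemical perturbation without feedback leaves mechanics, and
      # hence shape, unchanged
      mesh <- base$mesh
      conv <- TRUE
    } else {
      mesh <- relax_to_balance(base$mesh, mech, dt = dt, tol = 1e-6,
                               max_steps = 100000L)
      conv <- isTRUE(attr(mesh, "converged"))
    }
  }
  list(geom = cell_shape_summary(mesh),
       D_a = fold_depth(mesh, "apical"), D_b = fold_depth(mesh, "basal"),
       converged = conv)
}

#' Cell-shape correlation patterns under surface-specific modulation
#'
#' Sweeps one surface's mechanics around the balanced state of a single cell
#' of the given aspect ratio, relaxes to force balance at every sweep point,
#' and regresses the steady-state basal length `b` and height `h` on the
#' apical length `a`. The signs of the regression slopes summarize the
#' deformation pattern (e.g. columnar cells show anti-correlated `a` and `b`
#' under apical modulation).
#'
#' @param cell_type `"columnar"` (a/h = 0.25), `"cuboidal"` (0.50) or
#'   `"squamous"` (1.50).
#' @param modulated_surface `"apical"` (`P_hat_o`), `"basal"` (`lambda_b`) or
#'   `"lateral"` (`lambda_ell`).
#' @param sweep relative parameter multipliers (default `c(0.9, 0.95, 1.05, 1.1)`).
#' @return list with `slope_ab`, `slope_ah`, `sign_ab`, `sign_ah` and the
#'   sweep table.
#' @export
deformation_correlation_study <- function(cell_type = c("columnar", "cuboidal",
                                                        "squamous"),
                                          modulated_surface = c("apical",
                                                                "basal",
                                                                "lateral"),
                                          sweep = c(0.9, 0.95, 1.05, 1.1)) {
  cell_type <- match.arg(cell_type)
  modulated_surface <- match.arg(modulated_surface)
  shape <- switch(cell_type,
                  columnar = c(h = 1.8, r = 0.45),
                  cuboidal = c(h = 1.0, r = 0.50),
                  squamous = c(h = 0.5, r = 0.75))
  h <- shape[["h"]]; r <- shape[["r"]]
  Po <- 0.8 * 6 * r
  bal <- derive_balanced_parameters(h, r, Po)
  rows <- lapply(sweep, function(f) {
    mesh <- build_hexagonal_tissue(0, apical_radius = r, height = h)
    mech <- mechanical_state(1, K_a = bal$K_a, P_hat_o = Po,
                             lambda_b = bal$lambda_b,
                             lambda_ell = bal$lambda_ell)
    if (modulated_surface == "apical") mech$P_hat_o <- mech$P_hat_o * f
    if (modulated_surface == "basal") mech$lambda_b <- mech$lambda_b * f
    if (modulated_surface == "lateral") mech$lambda_ell <- mech$lambda_ell * f
    rel <- relax_to_balance(mesh, mech, dt = 0.05, tol = 1e-7,
                            max_steps = 100000L)
    g <- cell_shape_summary(rel, 1)
    data.frame(factor = f, a = g$a, b = g$b, h = g$ell)
  })
  tab <- do.call(rbind, rows)
  slope_ab <- unname(stats::coef(stats::lm(b ~ a, data = tab))[2])
  slope_ah <- unname(stats::coef(stats::lm(h ~ a, data = tab))[2])
  list(slope_ab = slope_ab, slope_ah = slope_ah,
       sign_ab = sign(slope_ab), sign_ah = sign(slope_ah), sweep = tab)
}
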