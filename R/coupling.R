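#' Configuration of the mechano-polarity coupling
#'
#' The homeostatic feedback law modulates each cell's normalized surface
#' mechanics `q = (K_a, P_hat_o, lambda_b, lambda_ell) / initial values`
#' down the gradient of `(ell_domain - ell_domain_o)^2`:
#' `dq_k/dt = -c_k d/dq_k (ell_domain - ell_o)^2`, with conversion rates
#' `c = c_o * (1 + xi)` and `xi ~ N(0, sigma)` resampled once per coupling
#' interval per cell.
#'
#' @param c_o length-4 deterministic conversion rates, one per q component
#'   (order `K_a`, `P_hat_o`, `lambda_b`, `lambda_ell`). Default is the
#'   published folding set `c(0.2, -0.8, 2.0, 2.0)`.
#' @param sigma noise standard deviation (>= 0).
#' @param ell_domain_o homeostatic apical domain size; `NULL` (default) means
#'   "use each cell's pre-perturbation steady-state value".
#' @param couple_every coupling update interval, in iterations.
#' @param threshold_frac homeostasis threshold for the relaxation time `tau`,
#'   as a fraction of `ell_domain_o` (in (0, 1)).
#' @param q_floor positive floor applied to every q component. The floor
#'   keeps every mechanical term present: letting a modulation run to zero
#'   deletes the corresponding restoring force, after which rings of the
#'   cell can collapse.
#' @param probe_dq relative parameter step of the sensitivity probe.
#' @param probe_dt virtual relaxation horizon of the sensitivity probe, in
#'   time units: the probed cell's vertices are relaxed for this long (rest
#'   of the tissue frozen) before the apical domain is re-measured. The
#'   horizon is fixed in time, not in steps, so the feedback gain does not
#'   depend on the integrator step; it must be long enough for the slow
#'   height mode to dominate the response (default 1.0).
#' @param sens_every sensitivity cache refresh interval for the `"step"`
#'   probe, in coupling updates (cell geometry drifts slowly, so probes need
#'   not run at every update).
#' @param dq_max per-update cap on each modulation increment `|dq_k|`; the
#'   homeostatic drive is otherwise free-running and can outpace the
#'   mechanical relaxation of the tissue (the modulation then ratchets
#'   against a shape that has not caught up, which ends in cell collapse).
#' @param probe sensitivity scheme: `"quasistatic"` (default) computes the
#'   fully relaxed response `d ell_domain / d q_k` in closed form by
#'   implicit differentiation of each cell's reduced height/radius force
#'   balance; `"step"` uses the finite-horizon virtual-relaxation probe.
#'   The finite-horizon probe can report the opposite sign for channels
#'   whose fast transient response opposes the slow, fully relaxed one (the
#'   basal-tension channel in particular), so the quasi-static scheme is
#'   the default.
#' @return object of class `coupling_config`.
#' @export
coupling_config <- function(c_o = c(0.2, -0.8, 2.0, 2.0), sigma = 0,
                            ell_domain_o = NULL, couple_every = 10L,
                            threshold_frac = 0.05, q_floor = 0.2,
                            probe_dq = 0.05, probe_dt = 1.0,
                            sens_every = 25L, dq_max = 0.002,
                            probe = c("quasistatic", "step")) {
  probe <- match.arg(probe)
  if (length(c_o) != 4) stop("'c_o' must have length 4")
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (probe_dq <= 0 || probe_dt <= 0) stop("probe settings must be positive")
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("'threshold_frac' must be in (0, 1)")
  structure(list(c_o = as.numeric(c_o), sigma = sigma,
                 ell_domain_o = ell_domain_o,
                 couple_every = as.integer(couple_every),
                 threshold_frac = threshold_frac, q_floor = q_floor,
                 probe_dq = probe_dq, probe_dt = probe_dt,
                 sens_every = as.integer(sens_every), dq_max = dq_max,
                 probe = probe),
            class = "coupling_config")
}

#' Sample noisy coupling rates
#'
#' `c = c_o * (1 + xi)` with `xi` i.i.d. Gaussian, mean 0, sd `sigma`
#' (one draw per component). Uses R's RNG stream.
#'
#' @param config a `coupling_config`.
#' @return length-4 numeric vector.
#' @export
sample_coupling_rate <- function(config) {
  if (config$sigma == 0) return(config$c_o)
  config$c_o * (1 + stats::rnorm(4, 0, config$sigma))
}

#' One homeostatic update of the modulation vector
#'
#' `q_k <- q_k - dt c_k 2 (ell_domain - ell_o) (d ell_domain / d q_k)`,
#' clipped at `q_floor`.
#'
#' @param q length-4 modulation vector.
#' @param ell_domain current apical domain size.
#' @param ell_o homeostatic apical domain size.
#' @param sensitivity length-4 vector of `d ell_domain / d q_k`.
#' @param c length-4 coupling rates.
#' @param dt time increment of this update.
#' @param q_floor positive floor.
#' @return updated q.
#' @export
homeostasis_update <- function(q, ell_domain, ell_o, sensitivity, c, dt,
                               q_floor = 0.2) {
  qn <- q - dt * c * 2 * (ell_domain - ell_o) * sensitivity
  pmax(qn, q_floor)
}

#' Sensitivity of the apical domain size to a mechanical modulation
#'
#' Central finite difference: `q_k` is displaced by `+/- probe_dq` in one
#' cell, that cell's vertices are virtually relaxed over the horizon
#' `probe_dt` (the rest of the tissue frozen), the cell geometry is
#' remeasured, the polarity field rescaled for the new length, and the
#' apical domain size re-evaluated. The probe is side-effect-free on the
#' supplied state. With `probe_dt = 0` the shape cannot respond and the
#' sensitivity is zero.
#'
#' @param mesh a `tissue_mesh`.
#' @param mech a `mechanical_state`.
#' @param field the cell's `membrane_field`.
#' @param cell cell id.
#' @param component q component index (1 = K_a, 2 = P_hat_o, 3 = lambda_b,
#'   4 = lambda_ell).
#' @param probe_dq,probe_dt probe settings (see [coupling_config()]).
#' @param fd_step finite-difference step of the underlying forces.
#' @return scalar estimate of `d ell_domain / d q_k`.
#' @export
apical_domain_sensitivity <- function(mesh, mech, field, cell, component,
                                      probe_dq = 0.05, probe_dt = 1.0,
                                      dt = 0.05, fd_step = 1e-6) {
  if (probe_dt == 0) return(0)
  ids <- unique(c(mesh$apical[cell, ], mesh$basal[cell, ]))
  peak_node <- which.max(field$conc[, 3])
  n_steps <- max(1L, round(probe_dt / dt))
  ell_of <- function(dq) {
    m2 <- mech
    m2$q[cell, component] <- m2$q[cell, component] + dq
    mesh2 <- mesh
    for (i in seq_len(n_steps)) {
      F <- vertex_forces(mesh2, m2, fd_step)
      mesh2$vertices[ids, ] <- mesh2$vertices[ids, ] +
        dt / mech$eta * F[ids, ]
    }
    g <- cell_shape_summary(mesh2, cell)
    (peak_node - 0.5) * g$L / field$n_nodes
  }
  (ell_of(probe_dq) - ell_of(-probe_dq)) / (2 * probe_dq)
}

#' Assemble the reference tissue in its coupled steady state
#'
#' Builds a hexagonal patch of reference columnar cells (`h = 1.8`,
#' `r = 0.45`), the exactly balanced mechanical state, and one polarized
#' membrane steady state (from the Heaviside initial condition at the
#' published biochemical parameters) replicated to every cell.
#'
#' @param n_rings tissue size.
#' @param n_nodes membrane grid size per cell.
#' @param params a `polarity_params`.
#' @param boundary RD boundary handling (see [step_rd()]).
#' @param dt,tol,max_steps steady-state integration controls.
#' @return list with `mesh`, `mech`, `params`, `fields` (n_nodes x 3 n_cells
#'   matrix), `field` (the per-cell `membrane_field`), `ell_domain_o`, `geom`.
#' @export
setup_reference_tissue <- function(n_rings = 2, n_nodes = 512L,
                                   params = polarity_params(),
                                   boundary = "reflect", dt = 0.1,
                                   tol = 1e-7, max_steps = 6e5) {
  mesh <- build_hexagonal_tissue(n_rings)
  mech <- mechanical_state(mesh$n_cells)
  geom <- cell_shape_summary(mesh, 1)
  f0 <- initial_condition(a = geom$a, ell = geom$ell, b = geom$b,
                          params = params, psi = geom$psi, n_nodes = n_nodes)
  ss <- integrate_to_steady_state(f0, params, geom$psi, dt = dt, tol = tol,
                                  max_steps = max_steps, boundary = boundary)
  fields <- ss$conc[, rep(1:3, mesh$n_cells)]
  ell0 <- bazooka_peak_position(ss)$ell_domain
  list(mesh = mesh, mech = mech, params = params, fields = fields,
       field = ss, ell_domain_o = ell0,
       geom = cell_shape_summary(mesh))
}

#' Run the coupled mechano-polarity simulation
#'
#' Per iteration and per cell: (1) one overdamped mechanics step for all
#' vertices; (2) cell geometry remeasured; (3) the membrane field rescaled
#' for the new half-perimeter; (4) one reaction-diffusion step at the
#' current surface-to-volume ratio; (5) every `couple_every` iterations,
#' sensitivities are probed, coupling rates sampled, and the homeostatic
#' modulation applied to each cell's effective mechanics.
#'
#' @param mesh a `tissue_mesh`.
#' @param mech a `mechanical_state` (mechanical perturbations are applied by
#'   modifying this before the call).
#' @param fields n_nodes x (3 n_cells) concentration matrix (columns A, P, B
#'   per cell), typically from [setup_reference_tissue()].
#' @param params a `polarity_params` shared by all cells.
#' @param config a `coupling_config`.
#' @param perturbation `NULL`, or a list with `cells` and multiplicative
#'   factors `P_total_factor` and/or `B_total_factor` applied to those cells
#'   at t = 0.
#' @param duration simulated time (time units).
#' @param dt shared mechanics/reaction-diffusion step.
#' @param constraint z-pinned vertex ids (see [boundary_constraint()]).
#' @param record_every recording stride, in iterations.
#' @param boundary RD boundary handling.
#' @param fd_step force finite-difference step.
#' @param feedback logical; `FALSE` freezes q (mechanics-only dynamics).
#' @param seed optional integer seed for the coupling noise.
#' @return object of class `fold_trajectory`: list with `times`, matrices
#'   `psi`, `L`, `ell_domain` (time x cell), array-like `q`
#'   (time x 4 n_cells), `fold_depth`, `final_mesh`, `final_fields`,
#'   `q_final`, `perturbed_cells`, `ell_domain_o`, `config`.
#' @export
run_coupled_simulation <- function(mesh, mech, fields, params, config,
                                   perturbation = NULL, duration = 200,
                                   dt = 0.05, constraint = integer(0),
                                   record_every = 20L, boundary = "reflect",
                                   fd_step = 1e-6, feedback = TRUE,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nc <- mesh$n_cells
  n_nodes <- nrow(fields)
  pv <- .rd_par_vector(params)
  rdpars <- matrix(pv, length(pv), nc)
  perturbed <- integer(0)
  if (!is.null(perturbation)) {
    perturbed <- as.integer(perturbation$cells)
    if (any(perturbed < 1 | perturbed > nc)) stop("perturbation references unknown cells")
    if (!is.null(perturbation$P_total_factor))
      rdpars[11, perturbed] <- rdpars[11, perturbed] * perturbation$P_total_factor
    if (!is.null(perturbation$B_total_factor))
      rdpars[15, perturbed] <- rdpars[15, perturbed] * perturbation$B_total_factor
  }
  geom <- cell_shape_summary(mesh)
  ell0 <- config$ell_domain_o
  if (is.null(ell0)) {
    ell0 <- vapply(seq_len(nc), function(c) {
      f <- membrane_field(a = geom$a[c], ell = geom$ell[c], b = geom$b[c],
                          n_nodes = n_nodes)
      f$conc <- fields[, (3 * c - 2):(3 * c)]
      bazooka_peak_position(f)$ell_domain
    }, numeric(1))
  } else if (length(ell0) == 1L) ell0 <- rep(ell0, nc)
  n_iter <- max(1L, as.integer(round(duration / dt)))
  res <- cpp_coupled_run(mesh$vertices, mesh$apical, mesh$basal,
                         mesh$faces$verts, mesh$faces$owner,
                         .mech_list(mech), mech$q, fields, rdpars,
                         .bc_code(boundary), dt, n_iter, mech$eta,
                         config$couple_every, config$c_o, config$sigma,
                         ell0, config$q_floor, config$probe_dq,
                         config$probe_dt, config$sens_every,
                         if (identical(config$probe, "step")) 1L else 0L,
                         config$dq_max, fd_step, as.integer(constraint),
                         as.integer(record_every),
                         as.integer(unique(as.vector(mesh$apical))),
                         as.integer(unique(as.vector(
                           mesh$apical[mesh$boundary_cells, , drop = FALSE]))),
                         isTRUE(feedback))
  final_mesh <- mesh
  final_mesh$vertices <- res$vertices
  out <- list(times = res$times, psi = res$psi, L = res$L,
              ell_domain = res$ell_domain, q = res$q,
              fold_depth = res$fold_depth, final_mesh = final_mesh,
              final_fields = res$fields, q_final = res$q_final,
              perturbed_cells = perturbed, ell_domain_o = ell0,
              config = config, dt = dt)
  class(out) <- "fold_trajectory"
  out
}

#' @export
print.fold_trajectory <- function(x, ...) {
  nt <- length(x$times)
  cat("fold_trajectory:", nt, "frames over", format(max(x$times)),
      "time units,", ncol(x$psi), "cells\n")
  cat("  final fold depth:", format(x$fold_depth[nt], digits = 4), "\n")
  if (length(x$perturbed_cells)) {
    pc <- x$perturbed_cells
    cat("  perturbed cells:", paste(pc, collapse = ", "), "\n")
    cat("  final ell_domain (perturbed):",
        format(mean(x$ell_domain[nt, pc]), digits = 4),
        "vs homeostatic", format(mean(x$ell_domain_o[pc]), digits = 4), "\n")
  }
  invisible(x)
}

#' Relaxation time to apical domain homeostasis
#'
#' `tau` is the first recorded time, after the perturbed cells' apical
#' domain has left the homeostatic band, at which
#' `|ell_domain - ell_o| < threshold_frac * ell_o` again holds in all
#' perturbed cells.
#'
#' With strong multiplicative noise on the coupling rates the apical domain
#' settles on a noise-shifted plateau rather than exactly on `ell_o`;
#' `mode = "settle"` therefore measures the time, after the overshoot peak,
#' at which the trajectory first comes within `threshold_frac * ell_o / 2`
#' of its own final level (finite for every completed run).
#'
#' @param traj a `fold_trajectory`.
#' @param cells cell ids (default: the trajectory's perturbed cells).
#' @param threshold_frac override of the config value.
#' @param mode `"threshold"` (return into the band around `ell_o`) or
#'   `"settle"` (approach to the trajectory's own plateau).
#' @return `tau` in time units, or `NA` if homeostasis is not reached.
#' @export
tau_relaxation <- function(traj, cells = traj$perturbed_cells,
                           threshold_frac = traj$config$threshold_frac,
                           mode = c("threshold", "settle")) {
  mode <- match.arg(mode)
  if (!length(cells)) return(NA_real_)
  ell <- traj$ell_domain[, cells, drop = FALSE]
  dev <- abs(sweep(ell, 2, traj$ell_domain_o[cells]))
  thr <- threshold_frac * traj$ell_domain_o[cells]
  if (mode == "settle") {
    nt <- nrow(ell)
    ipk <- which.max(apply(dev, 1, max))
    gap <- abs(sweep(ell, 2, ell[nt, ]))
    ok <- apply(sweep(gap, 2, thr / 2, "<"), 1, all)
    idx <- which(ok & seq_len(nt) > ipk)
    if (!length(idx)) return(traj$times[nt])
    return(traj$times[idx[1]])
  }
  outside <- sweep(dev, 2, thr, ">")
  any_out <- apply(outside, 1, any)
  i_out <- which(any_out)[1]
  if (is.na(i_out)) return(NA_real_)
  back <- which(!any_out & seq_along(any_out) > i_out)
  if (!length(back)) return(NA_real_)
  traj$times[back[1]]
}
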