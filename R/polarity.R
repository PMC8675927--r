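#' Biochemical parameters of the A/P/B polarity network
#'
#' Rate constants, interaction exponents and total concentrations of the
#' three-component polarity network: aPKC (`A`, apical), Par-1 (`P`,
#' basal-lateral) and Bazooka (`B`, junctional interface). Defaults are the
#' published simulation values (model units: 10 um length, 1 s time).
#' Membrane concentrations are per unit length; totals per unit volume.
#'
#' The reaction terms are, per node:
#' \deqn{R_A = k_{on,A}(1 + k_{AB} B^\epsilon) A_{cyto} - k_{off,A} A - k_{AP} P^\alpha A}
#' \deqn{R_P = k_{on,P} P_{cyto} - k_{off,P} P - k_{PA} A^\beta P}
#' \deqn{R_B = k_{on,B} B_{cyto} - k_{off,B} B - k_{BA} A^\gamma B - k_{BP} P^\zeta B}
#'
#' @param ... named overrides of any default.
#' @return an object of class `polarity_params` (named list).
#' @export
polarity_params <- function(...) {
  p <- list(
    D_A = 1e-4, D_P = 1e-4, D_B = 1e-4,
    k_on_A = 8.58e-4, k_off_A = 5.40e-3, A_total = 1.30e3,
    k_AB = 0.50e-2, k_AP = 5.80e-4,
    k_on_P = 4.74e-3, k_off_P = 7.30e-3, P_total = 1.00e3, k_PA = 0.20e-4,
    k_on_B = 4.29e-3, k_off_B = 5.40e-3, B_total = 1.40e3,
    k_BA = 0.40e-4, k_BP = 0.14e-4,
    alpha = 1, beta = 2, gamma = 2, zeta = 2, epsilon = 1)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  num <- unlist(p)
  if (any(!is.finite(num)) || any(num < 0))
    stop("all rates, totals and exponents must be finite and non-negative")
  if (any(unlist(p[c("alpha", "beta", "gamma", "zeta", "epsilon")]) <= 0))
    stop("reaction exponents must be positive")
  class(p) <- "polarity_params"
  p
}

# fixed flattening order shared with the C++ core
.rd_par_vector <- function(p) {
  as.numeric(p[c("D_A", "D_P", "D_B", "k_on_A", "k_off_A", "A_total", "k_AB",
                 "k_AP", "k_on_P", "k_off_P", "P_total", "k_PA", "k_on_B",
                 "k_off_B", "B_total", "k_BA", "k_BP", "alpha", "beta",
                 "gamma", "zeta", "epsilon")])
}

#' Membrane concentration field on the half-perimeter
#'
#' Discretizes the membrane path of one cell -- apical `[0, a)`, lateral
#' `[a, a + ell)`, basal `[a + ell, L]` -- on a uniform cell-centred grid of
#' `n_nodes` nodes (node i at `s = (i - 1/2) L / n_nodes`).
#'
#' @param a,ell,b apical, lateral, basal lengths (b defaults to a).
#' @param n_nodes grid size (default 512).
#' @param A,P,B optional initial concentration vectors (default zero).
#' @return object of class `membrane_field`: list with `n_nodes`, `L`, `a`,
#'   `ell`, `b`, concentration matrix `conc` (n_nodes x 3, columns A, P, B)
#'   and node positions `s`.
#' @export
membrane_field <- function(a, ell, b = a, n_nodes = 512L,
                           A = NULL, P = NULL, B = NULL) {
  if (a <= 0 || ell <= 0 || b <= 0) stop("region lengths must be positive")
  L <- a + b + ell
  n <- as.integer(n_nodes)
  conc <- matrix(0, n, 3, dimnames = list(NULL, c("A", "P", "B")))
  if (!is.null(A)) conc[, 1] <- A
  if (!is.null(P)) conc[, 2] <- P
  if (!is.null(B)) conc[, 3] <- B
  if (any(conc < 0)) stop("concentrations must be non-negative")
  f <- list(n_nodes = n, L = L, a = a, ell = ell, b = b,
            conc = conc, s = (seq_len(n) - 0.5) * L / n)
  class(f) <- "membrane_field"
  f
}

#' @export
print.membrane_field <- function(x, ...) {
  cat("membrane_field:", x$n_nodes, "nodes on [0,", format(x$L), "]",
      "(a =", format(x$a), ", ell =", format(x$ell), ", b =", format(x$b), ")\n")
  cat("  mean concentrations:", paste(colnames(x$conc),
      format(colMeans(x$conc), digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Cytosolic concentrations by mass conservation
#'
#' For each species, `rho_cyto = rho_total - psi * mean(rho)` where the mean
#' membrane concentration is the uniform-grid average over `[0, L]` and `psi`
#' is the cell's surface-to-volume ratio.
#'
#' @param field a `membrane_field`.
#' @param params a `polarity_params`.
#' @param psi surface-to-volume ratio (> 0).
#' @return named numeric vector `c(A, P, B)` of cytosolic concentrations.
#' @export
cytosolic_concentration <- function(field, params, psi) {
  if (psi <= 0) stop("'psi' must be positive")
  m <- colMeans(field$conc)
  c(A = params$A_total - psi * m[["A"]],
    P = params$P_total - psi * m[["P"]],
    B = params$B_total - psi * m[["B"]])
}

#' Nodewise reaction rates
#'
#' Evaluates the association/dissociation/antagonism kinetics of the polarity
#' network at every node, for given cytosolic concentrations.
#'
#' @param field a `membrane_field`.
#' @param params a `polarity_params`.
#' @param cytosolic named vector as returned by [cytosolic_concentration()].
#' @return n_nodes x 3 matrix of rates (columns A, P, B).
#' @export
reaction_rates <- function(field, params, cytosolic) {
  A <- field$conc[, 1]; P <- field$conc[, 2]; B <- field$conc[, 3]
  p <- params
  RA <- p$k_on_A * (1 + p$k_AB * B^p$epsilon) * cytosolic[["A"]] -
    p$k_off_A * A - p$k_AP * P^p$alpha * A
  RP <- p$k_on_P * cytosolic[["P"]] - p$k_off_P * P - p$k_PA * A^p$beta * P
  RB <- p$k_on_B * cytosolic[["B"]] - p$k_off_B * B -
    p$k_BA * A^p$gamma * B - p$k_BP * P^p$zeta * B
  cbind(A = RA, P = RP, B = RB)
}

.bc_code <- function(boundary) {
  boundary <- match.arg(boundary, c("reflect", "wrap"))
  if (boundary == "reflect") 0L else 1L
}

.check_ftcs <- function(field, params, dt) {
  ds <- field$L / field$n_nodes
  dmax <- max(params$D_A, params$D_P, params$D_B)
  if (dmax * dt / ds^2 > 0.5)
    stop(sprintf(paste("FTCS stability violated: D dt / ds^2 = %.3g > 0.5;",
                       "use dt <= %.3g"), dmax * dt / ds^2, 0.5 * ds^2 / dmax))
  invisible(TRUE)
}

#' Advance the reaction-diffusion system
#'
#' Explicit forward-time centred-space steps of the membrane
#' reaction-diffusion equations, with the cytosolic pool recomputed from the
#' pre-step field at every step. The default boundary condition (`"reflect"`)
#' treats `[0, L]` as the mirror-symmetric half of the closed membrane loop
#' (zero flux at the apical and basal centres); `"wrap"` joins `s = L` to
#' `s = 0` directly.
#'
#' @param field a `membrane_field`.
#' @param params a `polarity_params`.
#' @param psi surface-to-volume ratio.
#' @param dt time step; must satisfy `max(D) dt / ds^2 <= 0.5`.
#' @param n_steps number of steps (default 1).
#' @param boundary `"reflect"` (default) or `"wrap"`.
#' @return the updated `membrane_field`; attribute `"clamped"` counts nodes
#'   clamped at zero.
#' @export
step_rd <- function(field, params, psi, dt, n_steps = 1L,
                    boundary = c("reflect", "wrap")) {
  .check_ftcs(field, params, dt)
  res <- cpp_rd_run(field$conc, .rd_par_vector(params), psi, field$L, dt,
                    as.integer(n_steps), -1, as.integer(n_steps),
                    .bc_code(boundary))
  if (res$clamped > 0)
    warning(sprintf("%d node updates clamped at zero concentration",
                    res$clamped))
  field$conc <- res$field
  attr(field, "clamped") <- res$clamped
  field
}

#' Rescale concentrations after a change of domain length
#'
#' When the membrane length changes from `L_prev` to `L_new` between
#' iterations, the number of molecules on the membrane is conserved: every
#' node concentration is multiplied by `L_prev / L_new`.
#'
#' @param field a `membrane_field` (its current length is `L_prev`).
#' @param L_new new half-perimeter; region lengths are scaled proportionally
#'   unless `a`, `ell`, `b` are supplied.
#' @param a,ell,b optional new region lengths summing to `L_new`.
#' @return rescaled `membrane_field`.
#' @export
rescale_for_length_change <- function(field, L_new, a = NULL, ell = NULL,
                                      b = NULL) {
  if (!is.numeric(L_new) || L_new <= 0) stop("'L_new' must be positive")
  r <- field$L / L_new
  sc <- L_new / field$L
  if (is.null(a)) { a <- field$a * sc; ell <- field$ell * sc; b <- field$b * sc }
  out <- membrane_field(a = a, ell = ell, b = b, n_nodes = field$n_nodes)
  if (abs(out$L - L_new) > 1e-9 * L_new)
    stop("region lengths do not sum to 'L_new'")
  out$conc <- field$conc * r
  out
}

#' Initial condition for the polarity system
#'
#' `"heaviside_B"` places half of the Bazooka pool on the membrane as a step
#' confined to the apical half `[0, a/2)` -- mimicking the apical
#' accumulation of Bazooka at the end of cellularization -- with `A` and `P`
#' uniform, each holding half its pool on the membrane. `"uniform"` spreads
#' all three species uniformly (half pool on the membrane).
#'
#' @param a,ell,b region lengths (b defaults to a).
#' @param params a `polarity_params`.
#' @param psi surface-to-volume ratio.
#' @param style `"heaviside_B"` or `"uniform"`.
#' @param n_nodes grid size.
#' @param step_width width of the initial B step (default `a/2`).
#' @return a `membrane_field`.
#' @export
initial_condition <- function(a, ell, b = a, params = polarity_params(),
                              psi, style = c("heaviside_B", "uniform"),
                              n_nodes = 512L, step_width = a / 2) {
  style <- match.arg(style)
  f <- membrane_field(a, ell, b, n_nodes = n_nodes)
  Au <- params$A_total / (2 * psi)
  Pu <- params$P_total / (2 * psi)
  Bu <- params$B_total / (2 * psi)
  f$conc[, 1] <- Au
  f$conc[, 2] <- Pu
  if (style == "uniform") {
    f$conc[, 3] <- Bu
  } else {
    on <- f$s < step_width
    if (!any(on)) stop("'step_width' smaller than one grid spacing")
    f$conc[, 3] <- ifelse(on, Bu * f$n_nodes / sum(on), 0)
  }
  f
}

#' Integrate the polarity system to steady state
#'
#' Repeats FTCS steps until the maximum nodewise rate of change
#' `max |d rho| / dt` falls below `tol` for all species, or `max_steps` is
#' reached.
#'
#' @inheritParams step_rd
#' @param tol convergence tolerance on the nodewise rate of change
#'   (concentration units per time unit).
#' @param max_steps iteration cap.
#' @param check_every convergence check interval, in steps.
#' @return the converged `membrane_field`, with attributes `"converged"`
#'   (logical) and `"steps"`.
#' @export
integrate_to_steady_state <- function(field, params, psi, dt = 0.1,
                                      tol = 1e-7, max_steps = 1e6,
                                      check_every = 2000L,
                                      boundary = c("reflect", "wrap")) {
  .check_ftcs(field, params, dt)
  res <- cpp_rd_run(field$conc, .rd_par_vector(params), psi, field$L, dt,
                    as.integer(max_steps), tol, as.integer(check_every),
                    .bc_code(boundary))
  field$conc <- res$field
  attr(field, "converged") <- res$converged
  attr(field, "steps") <- res$steps
  field
}

#' Bazooka peak position and apical domain size
#'
#' Locates the global maximum of the Bazooka profile (first node on ties) and
#' reports its membrane position `s*` together with the apical domain size
#' `ell_domain = s*`, the membrane distance from the apical centre (`s = 0`)
#' to the peak; `junction_depth = max(0, s* - a)` is the same peak measured
#' from the apical/lateral junction down the lateral membrane. Optional
#' parabolic interpolation of the three nodes around the maximum refines
#' `s*` below the grid spacing.
#'
#' @param field a `membrane_field`.
#' @param refine logical; sub-grid parabolic refinement (default `FALSE`).
#' @return list with `s_star`, `frac` (= `s*/L`), `ell_domain`,
#'   `junction_depth`, `node`.
#' @export
bazooka_peak_position <- function(field, refine = FALSE) {
  B <- field$conc[, 3]
  if (all(B == 0)) stop("undefined peak: B is identically zero")
  i <- which.max(B)
  pos <- i - 0.5
  if (refine && i > 1 && i < field$n_nodes) {
    y1 <- B[i - 1]; y2 <- B[i]; y3 <- B[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) pos <- pos + 0.5 * (y1 - y3) / den
  }
  s_star <- pos * field$L / field$n_nodes
  list(s_star = s_star, frac = s_star / field$L, ell_domain = s_star,
       junction_depth = max(0, s_star - field$a), node = i)
}
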