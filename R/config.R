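#' Default run configuration
#'
#' All tunable settings of a simulation run in one nested list: biochemical
#' parameters, mechanical parameters (both defaulting to the published
#' values), tissue layout, numerics, coupling, perturbation schedule, seed
#' and output control. Every assumption that the underlying publications
#' leave open lives here so it can be inspected and overridden from a YAML
#' file.
#'
#' @return nested named list.
#' @export
default_run_config <- function() {
  ref <- derive_balanced_parameters(1.8, 0.45, 2.16)
  list(
    biochemistry = unclass(polarity_params()),
    mechanics = list(K_a = ref$K_a, P_hat_o = 2.16, lambda_b = ref$lambda_b,
                     lambda_ell = ref$lambda_ell, K_V = 1, V_o = 1, eta = 1),
    tissue = list(n_rings = 3L, apical_radius = 0.45, height = 1.8,
                  layout = "concentric", boundary_mode = "free"),
    numerics = list(n_nodes = 512L, dt = 0.01, rd_dt = 0.1, fd_step = 1e-6,
                    rd_tol = 1e-7, mech_tol = 1e-8, boundary = "reflect",
                    record_every = 20L),
    coupling = list(c_o = c(0.2, -0.8, 2.0, 2.0), sigma = 0,
                    ell_domain_o = NULL, couple_every = 10L,
                    threshold_frac = 0.05, q_floor = 0.2,
                    probe_dq = 0.05, probe_dt = 1.0, sens_every = 25L,
                    dq_max = 0.002, probe = "quasistatic"),
    perturbation = list(cells = "initiating", P_total_factor = 0.9,
                        B_total_factor = 1.0),
    duration = 200,
    seed = 1L,
    output = list(dir = ".", prefix = "epifold")
  )
}

#' Load and validate a YAML run configuration
#'
#' Reads a YAML file, fills unset keys with [default_run_config()] values,
#' rejects unknown keys, and validates ranges. An empty file yields the full
#' default configuration.
#'
#' @param path YAML file path.
#' @return validated nested list with class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- .merge_config(default_run_config(), user, "")
  .validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

.merge_config <- function(def, user, prefix) {
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(prefix, unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("configuration key ", prefix, nm, " must be a mapping")
      def[[nm]] <- .merge_config(def[[nm]], user[[nm]],
                                 paste0(prefix, nm, "."))
    } else {
      def[[nm]] <- user[[nm]]
    }
  }
  def
}

.validate_config <- function(cfg) {
  chk <- function(ok, key, what) if (!ok) stop("config key '", key, "' ", what)
  b <- cfg$biochemistry
  chk(all(unlist(b) >= 0), "biochemistry", "entries must be >= 0")
  chk(cfg$coupling$sigma >= 0, "coupling.sigma", "must be >= 0")
  chk(length(cfg$coupling$c_o) == 4, "coupling.c_o", "must have 4 entries")
  chk(cfg$coupling$threshold_frac > 0 && cfg$coupling$threshold_frac < 1,
      "coupling.threshold_frac", "must be in (0, 1)")
  chk(cfg$coupling$probe_dq > 0, "coupling.probe_dq", "must be > 0")
  chk(cfg$coupling$probe %in% c("quasistatic", "step"), "coupling.probe",
      "must be 'quasistatic' or 'step'")
  chk(cfg$tissue$n_rings >= 0, "tissue.n_rings", "must be >= 0")
  chk(cfg$tissue$apical_radius > 0, "tissue.apical_radius", "must be > 0")
  chk(cfg$tissue$height > 0, "tissue.height", "must be > 0")
  chk(cfg$tissue$layout %in% c("concentric", "line"), "tissue.layout",
      "must be 'concentric' or 'line'")
  chk(cfg$tissue$boundary_mode %in% c("free", "pin_plane"),
      "tissue.boundary_mode", "must be 'free' or 'pin_plane'")
  chk(cfg$numerics$n_nodes >= 8, "numerics.n_nodes", "must be >= 8")
  chk(cfg$numerics$dt > 0, "numerics.dt", "must be > 0")
  chk(cfg$numerics$boundary %in% c("reflect", "wrap"), "numerics.boundary",
      "must be 'reflect' or 'wrap'")
  chk(cfg$duration > 0, "duration", "must be > 0")
  chk(cfg$perturbation$P_total_factor > 0, "perturbation.P_total_factor",
      "must be > 0")
  chk(cfg$perturbation$B_total_factor > 0, "perturbation.B_total_factor",
      "must be > 0")
  invisible(cfg)
}

#' Write the fully resolved configuration next to run outputs
#' @param cfg a `run_config` (or plain list).
#' @param path output YAML path.
#' @export
echo_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
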