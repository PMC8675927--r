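test_that("coupling-rate sampling has the prescribed moments", {
  cfg <- coupling_config(sigma = 0)
  expect_identical(sample_coupling_rate(cfg), cfg$c_o)

  set.seed(31)
  cfg5 <- coupling_config(c_o = c(0.2, -0.8, 2, 2), sigma = 5)
  draws <- t(replicate(1e5, sample_coupling_rate(cfg5)))
  se <- 5 * abs(cfg5$c_o) / sqrt(1e5)
  expect_true(all(abs(colMeans(draws) - cfg5$c_o) < 3 * se))
  expect_equal(unname(apply(draws, 2, stats::sd)), 5 * abs(cfg5$c_o),
               tolerance = 0.02)
})

test_that("the homeostatic update follows the gradient-descent law", {
  q <- c(1, 1, 1, 1)
  expect_identical(homeostasis_update(q, 0.5, 0.5, c(1, 1, 1, 1),
                                      c(2, 2, 2, 2), 0.1), q)
  expect_identical(homeostasis_update(q, 0.9, 0.5, c(1, 1, 1, 1),
                                      c(0, 0, 0, 0), 0.1), q)
  # scalar oracle
  got <- homeostasis_update(1.2, ell_domain = 0.6, ell_o = 0.4,
                            sensitivity = -0.3, c = 2, dt = 0.05)
  expect_equal(got, 1.2 - 0.05 * 2 * 2 * (0.6 - 0.4) * (-0.3))
  # floor
  expect_equal(homeostasis_update(0.21, 1, 0, 1, 10, 1, q_floor = 0.2), 0.2)
})

test_that("the virtual probe resolves the sign of the lateral-tension response", {
  sys <- ref_tissue(0, 128L)
  # a zero-horizon probe cannot see any shape response
  expect_identical(apical_domain_sensitivity(sys$mesh, sys$mech, sys$field,
                                             1, 4, probe_dt = 0), 0)
  # long-horizon brute-force oracle: relax fully at modulated lateral
  # tension and measure the apical-domain change per unit q
  ell_relaxed <- function(dq) {
    mech <- sys$mech
    mech$q[1, 4] <- 1 + dq
    rel <- relax_to_balance(sys$mesh, mech, dt = 0.1, tol = 1e-6,
                            max_steps = 60000L)
    g <- cell_shape_summary(rel, 1)
    (which.max(sys$field$conc[, 3]) - 0.5) * g$L / sys$field$n_nodes
  }
  oracle <- (ell_relaxed(0.3) - ell_relaxed(-0.3)) / 0.6
  probe <- apical_domain_sensitivity(sys$mesh, sys$mech, sys$field, 1, 4,
                                     probe_dt = 2, dt = 0.05)
  expect_lt(oracle, 0)   # more lateral tension shortens the cell
  expect_lt(probe, 0)
  # halving the parameter step barely changes the estimate
  p1 <- apical_domain_sensitivity(sys$mesh, sys$mech, sys$field, 1, 4,
                                  probe_dq = 0.05, probe_dt = 2, dt = 0.05)
  p2 <- apical_domain_sensitivity(sys$mesh, sys$mech, sys$field, 1, 4,
                                  probe_dq = 0.025, probe_dt = 2, dt = 0.05)
  expect_lt(abs(p1 - p2), 0.05 * abs(p1))
})

test_that("an unperturbed coupled run is a fixed point", {
  sys <- ref_tissue(1, 128L)
  traj <- run_coupled_simulation(sys$mesh, sys$mech, sys$fields, sys$params,
                                 coupling_config(sigma = 0),
                                 duration = 20, dt = 0.1, record_every = 20L,
                                 seed = 1)
  expect_lt(max(abs(traj$fold_depth)), 1e-4)
  expect_equal(max(abs(traj$q - 1)), 0)
  expect_equal(max(abs(sweep(traj$ell_domain, 2, traj$ell_domain_o))), 0)
})

test_that("zero coupling reproduces the frozen-mechanics run bit-for-bit", {
  sys <- ref_tissue(1, 128L)
  pert <- list(cells = 4L, P_total_factor = 0.9)
  t1 <- run_coupled_simulation(sys$mesh, sys$mech, sys$fields, sys$params,
                               coupling_config(c_o = c(0, 0, 0, 0), sigma = 2),
                               perturbation = pert, duration = 10, dt = 0.1,
                               record_every = 10L, seed = 7)
  t2 <- run_coupled_simulation(sys$mesh, sys$mech, sys$fields, sys$params,
                               coupling_config(sigma = 0), feedback = FALSE,
                               perturbation = pert, duration = 10, dt = 0.1,
                               record_every = 10L, seed = 7)
  expect_identical(t1$final_mesh$vertices, t2$final_mesh$vertices)
  expect_identical(t1$final_fields, t2$final_fields)
  expect_identical(t1$q_final, t2$q_final)
})

test_that("membrane amount tracks the moving domain exactly", {
  sys <- ref_tissue(1, 128L)
  mech <- sys$mech
  mech$lambda_ell <- mech$lambda_ell * 1.3   # force shape change
  traj <- run_coupled_simulation(sys$mesh, mech, sys$fields, sys$params,
                                 coupling_config(sigma = 0), feedback = FALSE,
                                 duration = 5, dt = 0.05, record_every = 100L,
                                 seed = 1)
  # L changed, fields stayed finite and non-negative
  expect_false(isTRUE(all.equal(traj$L[nrow(traj$L), 1], sys$geom$L[1])))
  expect_true(all(is.finite(traj$final_fields)))
  expect_true(all(traj$final_fields >= 0))
})

test_that("relaxation times are read off trajectories as documented", {
  fake <- function(dev) {
    structure(list(times = seq_along(dev) - 1,
                   ell_domain = matrix(1 + dev, ncol = 1),
                   ell_domain_o = 1, perturbed_cells = 1L,
                   config = coupling_config()), class = "fold_trajectory")
  }
  # leaves the 5% band at t=2, back inside at t=5
  expect_equal(tau_relaxation(fake(c(0, .02, .2, .3, .1, .01, .01))), 5)
  # never leaves
  expect_true(is.na(tau_relaxation(fake(rep(0.01, 6)))))
  # never returns
  expect_true(is.na(tau_relaxation(fake(c(0, .2, .3, .4, .5, .6)))))
  # settle mode: approach to the trajectory's own plateau
  expect_equal(tau_relaxation(fake(c(0, .02, .30, .20, .12, .11, .10)),
                              mode = "settle"), 4)
  # settle mode is finite even when the band around ell_o is never re-entered
  expect_equal(tau_relaxation(fake(c(0, .3, .2, .15, .15, .15)),
                              mode = "settle"), 3)
})
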