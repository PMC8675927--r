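test_that("cytosolic pool closes the mass budget", {
  g <- reference_geometry()
  p <- polarity_params()
  f <- membrane_field(g$a, g$ell, g$b, n_nodes = 64L)
  expect_equal(unname(cytosolic_concentration(f, p, g$psi)),
               c(p$A_total, p$P_total, p$B_total))

  # uniform field holding the whole pool on the membrane -> zero cytosol
  f$conc[, 1] <- p$A_total / g$psi
  expect_equal(cytosolic_concentration(f, p, g$psi)[["A"]], 0)

  # random field vs an independent midpoint-quadrature oracle
  set.seed(3)
  f$conc[] <- matrix(runif(64 * 3, 0, 50), 64, 3)
  ds <- f$L / f$n_nodes
  oracle <- p$P_total - g$psi * sum(f$conc[, 2] * ds) / f$L
  expect_equal(cytosolic_concentration(f, p, g$psi)[["P"]], oracle,
               tolerance = 1e-12)
  expect_error(cytosolic_concentration(f, p, -1), "psi")
})

test_that("reaction rates evaluate the network kinetics nodewise", {
  g <- reference_geometry()
  p <- polarity_params()
  f <- membrane_field(g$a, g$ell, g$b, n_nodes = 16L)
  R0 <- reaction_rates(f, p, c(A = p$A_total, P = p$P_total, B = p$B_total))
  expect_equal(unname(R0[1, ]), c(p$k_on_A * p$A_total, p$k_on_P * p$P_total,
                                  p$k_on_B * p$B_total))
  expect_equal(R0, R0[rep(1, 16), ], ignore_attr = TRUE)

  # pure loss: no association, positive membrane field -> all rates <= 0
  ploss <- polarity_params(k_on_A = 0, k_on_P = 0, k_on_B = 0)
  f$conc[] <- 20
  expect_true(all(reaction_rates(f, ploss, c(A = 1, P = 1, B = 1)) <= 0))

  # single-node scalar hand evaluation
  f1 <- membrane_field(g$a, g$ell, g$b, n_nodes = 1L,
                       A = 100, P = 50, B = 10)
  cy <- c(A = 600, P = 400, B = 900)
  R <- reaction_rates(f1, p, cy)
  expect_equal(R[1, "A"],
               8.58e-4 * (1 + 0.5e-2 * 10) * 600 - 5.40e-3 * 100 -
                 5.80e-4 * 50 * 100)
  expect_equal(R[1, "P"], 4.74e-3 * 400 - 7.30e-3 * 50 - 0.20e-4 * 100^2 * 50)
  expect_equal(R[1, "B"],
               4.29e-3 * 900 - 5.40e-3 * 10 - 0.40e-4 * 100^2 * 10 -
                 0.14e-4 * 50^2 * 10)
})

test_that("FTCS stepping diffuses correctly and conserves mass", {
  g <- reference_geometry()
  off <- polarity_params(k_on_A = 0, k_off_A = 0, k_AB = 0, k_AP = 0,
                         k_on_P = 0, k_off_P = 0, k_PA = 0,
                         k_on_B = 0, k_off_B = 0, k_BA = 0, k_BP = 0)
  # uniform field is a fixed point of pure diffusion
  f <- membrane_field(g$a, g$ell, g$b, n_nodes = 64L, A = 5, P = 7, B = 2)
  f2 <- step_rd(f, off, g$psi, dt = 0.05, n_steps = 50)
  expect_equal(f2$conc, f$conc, tolerance = 1e-14)

  # delta spike: total membrane amount conserved over 1e4 steps, both BCs
  for (bc in c("reflect", "wrap")) {
    fd <- membrane_field(g$a, g$ell, g$b, n_nodes = 64L)
    fd$conc[20, ] <- 100
    mass0 <- colSums(fd$conc) * fd$L / fd$n_nodes
    fd <- step_rd(fd, off, g$psi, dt = 0.05, n_steps = 1e4, boundary = bc)
    expect_equal(colSums(fd$conc) * fd$L / fd$n_nodes, mass0,
                 tolerance = 1e-12)
  }

  # grid refinement: coarse solution approaches a 4x finer reference
  smooth <- function(n) {
    f <- membrane_field(g$a, g$ell, g$b, n_nodes = n)
    f$conc[, 1] <- 10 + 5 * cos(pi * f$s / f$L)   # zero-flux compatible
    f
  }
  Dbig <- polarity_params(k_on_A = 0, k_off_A = 0, k_AB = 0, k_AP = 0,
                          k_on_P = 0, k_off_P = 0, k_PA = 0, k_on_B = 0,
                          k_off_B = 0, k_BA = 0, k_BP = 0, D_A = 5e-3)
  fc <- step_rd(smooth(64), Dbig, g$psi, dt = 0.1, n_steps = 400)
  ff <- step_rd(smooth(256), Dbig, g$psi, dt = 0.00625, n_steps = 6400)
  # compare at coarse cells (fine cell-centred grid nests 4-per-coarse)
  fine_on_coarse <- colMeans(matrix(ff$conc[, 1], nrow = 4))
  expect_lt(max(abs(fc$conc[, 1] - fine_on_coarse)), 0.02)

  # stability guard refuses an unstable step
  expect_error(step_rd(smooth(256), Dbig, g$psi, dt = 0.2), "FTCS")
})

test_that("length-change rescaling preserves membrane amount", {
  g <- reference_geometry()
  set.seed(11)
  f <- membrane_field(g$a, g$ell, g$b, n_nodes = 128L)
  f$conc[] <- matrix(runif(128 * 3, 0, 30), 128, 3)
  expect_equal(rescale_for_length_change(f, f$L)$conc, f$conc)
  expect_equal(rescale_for_length_change(f, f$L / 2)$conc, 2 * f$conc)
  L2 <- 3.731
  f2 <- rescale_for_length_change(f, L2)
  expect_equal(colSums(f2$conc) * L2 / 128, colSums(f$conc) * f$L / 128,
               tolerance = 1e-12)
  expect_equal(f2$L, L2)
  expect_error(rescale_for_length_change(f, -1), "positive")
})

test_that("initial conditions place the pools as documented", {
  g <- reference_geometry()
  p <- polarity_params()
  f <- initial_condition(g$a, g$ell, g$b, p, g$psi, n_nodes = 256L)
  expect_true(all(f$conc[f$s >= g$a / 2, 3] == 0))
  expect_true(all(f$conc[f$s >= g$a, 3] == 0))
  expect_equal(unname(cytosolic_concentration(f, p, g$psi)),
               c(p$A_total, p$P_total, p$B_total) / 2, tolerance = 1e-12)
  fu <- initial_condition(g$a, g$ell, g$b, p, g$psi, style = "uniform",
                          n_nodes = 256L)
  expect_equal(unname(apply(fu$conc, 2, stats::var)), c(0, 0, 0))
})

test_that("the polarity system converges to a single-peak polarized profile", {
  ss <- ref_steady_state(128L)
  expect_true(attr(ss, "converged"))
  pk <- bazooka_peak_position(ss)
  n <- ss$n_nodes
  # aPKC maximal in the apical region, Par-1 basal of the Bazooka peak
  expect_lt(ss$s[which.max(ss$conc[, 1])], ss$a)
  expect_gt(ss$s[which.max(ss$conc[, 2])], pk$s_star)
  # B has a single interior peak
  B <- ss$conc[, 3]
  interior_max <- which(B > c(B[1], B[-n]) & B >= c(B[-1], B[n]))
  expect_length(interior_max[B[interior_max] > 0.1 * max(B)], 1L)
  # already-steady profile converges within one check interval
  again <- integrate_to_steady_state(ss, polarity_params(),
                                     reference_geometry()$psi, dt = 0.1,
                                     tol = 1e-7, check_every = 500L)
  expect_true(attr(again, "converged"))
  expect_lte(attr(again, "steps"), 500L)
})

test_that("peak location follows the documented grid and tie conventions", {
  g <- reference_geometry()
  f <- membrane_field(g$a, g$ell, g$b, n_nodes = 64L)
  f$conc[23, 3] <- 5
  pk <- bazooka_peak_position(f)
  expect_equal(pk$node, 23L)
  expect_equal(pk$s_star, (23 - 0.5) * f$L / 64)
  expect_equal(pk$ell_domain, pk$s_star)
  expect_equal(pk$junction_depth, pk$s_star - g$a)
  # exact tie -> first (apical-most) node
  f$conc[40, 3] <- 5
  expect_equal(bazooka_peak_position(f)$node, 23L)
  f$conc[, 3] <- 0
  expect_error(bazooka_peak_position(f), "undefined peak")
})

test_that("mass conservation closes at every step of a reactive run", {
  g <- reference_geometry()
  p <- polarity_params()
  f <- initial_condition(g$a, g$ell, g$b, p, g$psi, n_nodes = 64L)
  for (i in 1:50) {
    f <- step_rd(f, p, g$psi, dt = 0.1)
    cy <- cytosolic_concentration(f, p, g$psi)
    expect_equal(g$psi * mean(f$conc[, 1]) + cy[["A"]], p$A_total,
                 tolerance = 1e-12)
    expect_equal(g$psi * mean(f$conc[, 2]) + cy[["P"]], p$P_total,
                 tolerance = 1e-12)
    expect_equal(g$psi * mean(f$conc[, 3]) + cy[["B"]], p$B_total,
                 tolerance = 1e-12)
  }
})
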