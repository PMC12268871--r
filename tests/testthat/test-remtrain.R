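# REM / reg-REM gradients against quadrature + finite-difference oracles,
# the kappa heuristic, and trainer behaviour.

# dense 1D grid over the pair distance; fine enough that the quadrature
# error is well below the 1e-3 comparison tolerance
oracle_grid <- seq(0.05, 5, by = 0.002)

test_that("the KL gradient vanishes for identical ensembles and scales with beta", {
  m <- two_bead_model(C = -2)
  ens <- grid_ensemble(-2, m, 310, oracle_grid)
  g0 <- kl_gradient(ens, ens, m$topology, m$params, temperature = 310)
  expect_equal(unname(g0), 0)
  # doubling beta (halving T) doubles the gradient for fixed ensembles
  ens_b <- grid_ensemble(-1, m, 310, oracle_grid)
  g1 <- kl_gradient(ens, ens_b, m$topology, m$params, temperature = 310)
  g2 <- kl_gradient(ens, ens_b, m$topology, m$params, temperature = 155)
  expect_equal(unname(g2), 2 * unname(g1), tolerance = 1e-12)
  expect_error(kl_gradient(NULL, ens, m$topology, m$params))
})

test_that("the KL gradient matches the quadrature derivative of D_KL", {
  m <- two_bead_model(C = -2.5, R_att = 0.8, q = c(0.3, -0.3))
  Tk <- 310
  C_ref <- -3.2; C_mod <- -2.5
  aa <- grid_ensemble(C_ref, m, Tk, oracle_grid)
  cg <- grid_ensemble(C_mod, m, Tk, oracle_grid)
  got <- kl_gradient(aa, cg, m$topology, set_theta(m$params, C_mod), Tk)
  h <- 1e-5
  num <- (oracle_dkl(C_ref, C_mod + h, m, Tk, oracle_grid) -
          oracle_dkl(C_ref, C_mod - h, m, Tk, oracle_grid)) / (2 * h)
  expect_equal(unname(got), num, tolerance = 1e-3 * abs(num))
})

test_that("the mean-binding-energy gradient matches its finite-difference oracle", {
  m <- two_bead_model(C = -2.5, R_att = 0.8, q = c(0.3, -0.3))
  Tk <- 310
  C_mod <- -2.5
  cg <- grid_ensemble(C_mod, m, Tk, oracle_grid)
  params <- set_theta(m$params, C_mod)
  got <- grad_mean_vbind(cg, m$topology, params, temperature = Tk)
  vbar <- function(C) {
    oracle_average(function(R) oracle_pair_energy(R, C, m), C, m, Tk,
                   oracle_grid)
  }
  h <- 1e-4
  num <- (vbar(C_mod + h) - vbar(C_mod - h)) / (2 * h)
  expect_equal(unname(got), num, tolerance = 1e-3 * abs(num))
})

test_that("a zero-fluctuation ensemble reduces the estimator to <dV/dC>", {
  m <- two_bead_model(C = -2)
  co <- array(rep(two_bead_coords(0.93), 10), dim = c(2, 3, 10))
  ens <- cg_ensemble(co)
  got <- grad_mean_vbind(ens, m$topology, m$params, temperature = 310)
  expect_equal(unname(got),
               unname(du_dtheta(two_bead_coords(0.93), m$topology, m$params)),
               tolerance = 1e-12)
})

test_that("the estimator is invariant to a constant shift of V_bind", {
  fx <- make_dimer_reference(seed = 14, n_frames = 50)
  stats <- regcg:::ensemble_stats(fx$ensemble, fx$topology, fx$params)
  g0 <- grad_mean_vbind(fx$ensemble, fx$topology, fx$params, 310,
                        stats = stats)
  stats2 <- stats
  stats2$V_bind <- stats$V_bind + 7.3
  g1 <- grad_mean_vbind(fx$ensemble, fx$topology, fx$params, 310,
                        stats = stats2)
  expect_equal(g1, g0, tolerance = 1e-9)
})

test_that("the regularized gradient matches the full-loss oracle", {
  m <- two_bead_model(C = -2.5, R_att = 0.8, q = c(0.3, -0.3))
  Tk <- 310
  C_ref <- -3.2; C_mod <- -2.5
  kap <- 0.1 / 4.184; V0 <- -6
  aa <- grid_ensemble(C_ref, m, Tk, oracle_grid)
  cg <- grid_ensemble(C_mod, m, Tk, oracle_grid)
  params <- set_theta(m$params, C_mod)
  cfg <- reg_config(kappa_reg = kap, V0 = V0)
  got <- regrem_gradient(aa, cg, m$topology, params, cfg, Tk)
  loss <- function(C) {
    vbar <- oracle_average(function(R) oracle_pair_energy(R, C, m), C, m,
                           Tk, oracle_grid)
    oracle_dkl(C_ref, C, m, Tk, oracle_grid) + kap * (V0 - vbar)^2
  }
  h <- 1e-4
  num <- (loss(C_mod + h) - loss(C_mod - h)) / (2 * h)
  expect_equal(as.numeric(got), num, tolerance = 1e-3 * abs(num))
})

test_that("kappa_reg = 0 reproduces the plain KL gradient bitwise", {
  fx <- make_dimer_reference(seed = 15, n_frames = 40)
  cg <- cg_ensemble(fx$ensemble$coords[, , 1:20])
  aa <- cg_ensemble(fx$ensemble$coords[, , 21:40])
  cfg0 <- reg_config(kappa_reg = 0)
  g_reg <- regrem_gradient(aa, cg, fx$topology, fx$params, cfg0, 310)
  g_kl <- kl_gradient(aa, cg, fx$topology, fx$params, 310)
  expect_identical(as.numeric(g_reg), as.numeric(g_kl))
})

test_that("the regularization term vanishes when V_bar hits the target", {
  fx <- make_dimer_reference(seed = 16, n_frames = 40)
  cg <- cg_ensemble(fx$ensemble$coords[, , 1:20])
  aa <- cg_ensemble(fx$ensemble$coords[, , 21:40])
  stats <- regcg:::ensemble_stats(cg, fx$topology, fx$params)
  v_bar <- mean(stats$V_bind)
  cfg <- reg_config(kappa_reg = 0.5, V0 = v_bar)
  g_reg <- regrem_gradient(aa, cg, fx$topology, fx$params, cfg, 310)
  g_kl <- kl_gradient(aa, cg, fx$topology, fx$params, 310)
  expect_equal(as.numeric(g_reg), as.numeric(g_kl), tolerance = 1e-10)
})

test_that("the kappa heuristic balances KL and regularization gradients", {
  # <dV/dC> = 1 nm^-1 at 310 K gives kappa ~ 0.1/4.184 (kJ/mol)^-2
  k310 <- kappa_heuristic(1.0, 310)
  expect_lt(abs(k310 - 0.1 / 4.184) / (0.1 / 4.184), 0.05)
  # inverse proportionality in the gradient scale
  expect_equal(kappa_heuristic(2.0, 310), k310 / 2)
  # linear in beta: doubling T halves kappa
  expect_equal(kappa_heuristic(1.0, 620), k310 / 2)
  expect_error(kappa_heuristic(0, 310), "> 0")
})

test_that("training records are complete and seed-reproducible", {
  fx <- make_dimer_reference(seed = 17, n_frames = 200)
  p0 <- set_theta(fx$params, rep(0, 5))
  st <- sim_settings(temperature = 310, wall_radius = 1.1)
  cfg <- reg_config(kappa_reg = 0.1 / 4.184, V0 = -25, n_iterations = 4,
                    steps_per_iter = 5000, stride = 50, seed = 9)
  f1 <- train_regrem(fx$topology, p0, fx$ensemble, cfg, st, start = fx$native)
  f2 <- train_regrem(fx$topology, p0, fx$ensemble, cfg, st, start = fx$native)
  expect_identical(f1$theta_history, f2$theta_history)
  expect_equal(nrow(f1$history), 4)
  expect_true(all(c("iteration", "V_bar", "rmsd", "grad_kl_norm",
                    "grad_reg_norm", "frac_unbound") %in% names(f1$history)))
  expect_true(all(is.finite(f1$history$V_bar)))
  # theta moves towards attraction from the zero start
  expect_lt(mean(get_theta(f1$params)), 0)
  pw <- converged_params(f1, window = 2)
  expect_equal(unname(get_theta(pw)),
               unname(colMeans(utils::tail(f1$theta_history, 2))))
})
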