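# Langevin engine: determinism, thermostat accuracy, energy conservation,
# and the RMSD / distance-distribution analyses.

inert_params <- function() {
  cg_params(data.frame(type_i = "X", type_j = "X", A = 0, R_rep = 0.1,
                       C = 0, R_att = 1, trainable = FALSE, b_term = FALSE))
}

tether_topology <- function(k = 500, r0 = 0, m_heavy = 1e9, m_light = 50) {
  cg_topology(
    data.frame(bead_id = 0:1, monomer_id = 0, type = "X", charge = 0,
               mass = c(m_heavy, m_light)),
    data.frame(bead_i = 0, bead_j = 1, k = k, r0 = r0))
}

test_that("a system at equilibrium with zero noise stays put", {
  topo <- tether_topology(k = 500, r0 = 0.5, m_heavy = 100, m_light = 100)
  run <- simulate_cg(topo, inert_params(), two_bead_coords(0.5),
                     sim_settings(dt_fs = 5, temperature = 0, friction = 0,
                                  n_steps = 1000, stride = 100, seed = 1),
                     init_vel = FALSE)
  expect_equal(get_frame(run$ensemble, n_frames(run$ensemble)),
               two_bead_coords(0.5), tolerance = 1e-12)
})

test_that("sampling a harmonic well reproduces equipartition", {
  # light bead tethered (r0 = 0) to an effectively fixed heavy bead:
  # an isotropic well, <x^2> per component = kB T / k
  topo <- tether_topology(k = 500)
  run <- simulate_cg(topo, inert_params(), two_bead_coords(0.05),
                     sim_settings(dt_fs = 5, temperature = 310, friction = 1,
                                  n_steps = 4e5, stride = 20, seed = 3))
  dx <- run$ensemble$coords[2, 1, ] - run$ensemble$coords[1, 1, ]
  x2 <- mean(dx^2)
  expected <- 0.0083145 * 310 / 500
  se <- sd(dx^2) / sqrt(length(dx) / 20)   # generous correlation allowance
  expect_lt(abs(x2 - expected), 3 * se + 0.02 * expected)
})

test_that("the same seed reproduces the trajectory bit for bit", {
  m <- two_bead_model(C = -3)
  st <- sim_settings(n_steps = 3000, stride = 30, seed = 42,
                     wall_radius = 1.5)
  r1 <- simulate_cg(m$topology, m$params, two_bead_coords(0.8), st)
  r2 <- simulate_cg(m$topology, m$params, two_bead_coords(0.8), st)
  expect_identical(r1$ensemble$coords, r2$ensemble$coords)
  expect_identical(r1$V_bind, r2$V_bind)
  r3 <- simulate_cg(m$topology, m$params, two_bead_coords(0.8),
                    sim_settings(n_steps = 3000, stride = 30, seed = 43,
                                 wall_radius = 1.5))
  expect_false(identical(r1$ensemble$coords, r3$ensemble$coords))
})

test_that("the zero-friction integrator conserves energy", {
  topo <- tether_topology(k = 500, r0 = 0.5, m_heavy = 100, m_light = 100)
  run <- simulate_cg(topo, inert_params(), two_bead_coords(0.62),
                     sim_settings(dt_fs = 1, temperature = 0, friction = 0,
                                  n_steps = 1e4, stride = 10, seed = 1),
                     init_vel = FALSE)
  drift <- diff(range(run$E_total)) / abs(mean(run$E_total))
  expect_lt(drift, 1e-4)
})

test_that("the thermostat holds the kinetic temperature of a 10-bead system", {
  fx <- make_dimer_reference(seed = 4, n_frames = 10)
  run <- simulate_cg(fx$topology, fx$params, fx$native,
                     sim_settings(dt_fs = 15, temperature = 310, friction = 1,
                                  n_steps = 1e6, stride = 100, seed = 9,
                                  wall_radius = 1.5))
  expect_lt(abs(mean(run$T_kin) - 310) / 310, 0.03)
})

test_that("a diverging model aborts with a diagnostic", {
  # absurd time step on a stiff spring blows up
  topo <- tether_topology(k = 1e5, r0 = 0.5, m_heavy = 1, m_light = 1)
  expect_error(
    simulate_cg(topo, inert_params(), two_bead_coords(0.9),
                sim_settings(dt_fs = 500, temperature = 310, n_steps = 5000,
                             stride = 10, seed = 1)),
    "diverged")
})

test_that("RMSD is zero for identical and rigidly moved structures", {
  fx <- make_dimer_reference(seed = 5, n_frames = 3)
  ref <- fx$native
  expect_equal(rmsd_traj(cg_ensemble(ref), ref), 0, tolerance = 1e-12)
  shifted <- sweep(ref, 2, c(1, -2, 0.5), "+")
  expect_equal(rmsd_traj(cg_ensemble(shifted), ref), 0, tolerance = 1e-10)
  th <- 0.9
  Ry <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  expect_equal(rmsd_traj(cg_ensemble(ref %*% t(Ry)), ref), 0,
               tolerance = 1e-10)
})

test_that("RMSD matches a brute-force rotation-grid oracle", {
  set.seed(7)
  a <- matrix(rnorm(9, sd = 0.5), 3, 3)
  b <- a + matrix(rnorm(9, sd = 0.15), 3, 3)
  got <- rmsd_traj(cg_ensemble(b), a)
  # dense grid over Euler angles, centred structures
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  ang <- seq(0, 2 * pi, length.out = 73)[-73]
  half <- seq(0, pi, length.out = 37)
  best <- Inf
  for (p in ang) for (t in half) for (s in ang) {
    Rz1 <- rbind(c(cos(p), -sin(p), 0), c(sin(p), cos(p), 0), c(0, 0, 1))
    Ry <- rbind(c(cos(t), 0, sin(t)), c(0, 1, 0), c(-sin(t), 0, cos(t)))
    Rz2 <- rbind(c(cos(s), -sin(s), 0), c(sin(s), cos(s), 0), c(0, 0, 1))
    fit <- bc %*% t(Rz1 %*% Ry %*% Rz2)
    best <- min(best, sqrt(mean(rowSums((fit - ac)^2))))
  }
  expect_lt(got, best + 1e-12)              # optimal beats any grid point
  expect_lt(abs(got - best) / got, 0.02)    # and the grid gets close
})

test_that("RMSD agrees with the bio3d superposition", {
  fx <- make_dimer_reference(seed = 6, n_frames = 20)
  got <- rmsd_traj(fx$ensemble, fx$native)
  ref_xyz <- as.numeric(t(fx$native))
  other <- vapply(seq_len(20), function(f) {
    mob <- as.numeric(t(get_frame(fx$ensemble, f)))
    bio3d::rmsd(ref_xyz, mob, fit = TRUE)
  }, 0)
  # bio3d::rmsd rounds its result to 3 decimals
  expect_equal(got, other, tolerance = 0.02)
})

test_that("distance distributions are normalised and peak where expected", {
  fx <- make_dimer_reference(seed = 8, n_frames = 2)
  # frozen native pair distance for the facing T1:T1 pair is the gap
  ens <- cg_ensemble(fx$native)
  rdf <- compute_rdf(ens, fx$topology, c("T1", "T1"), bin_width = 0.02)
  expect_equal(sum(rdf$p * rdf$bin_width), 1, tolerance = 1e-12)
  expect_equal(sum(rdf$p > 0), 1)                    # single occupied bin
  expect_equal(rdf$r[which.max(rdf$p)], 0.81, tolerance = 0.011)
  # uniform random points: p(R) grows ~ R^2 at small R
  set.seed(1)
  n <- 60
  co <- array(runif(n * 3 * 40, -1, 1), dim = c(n, 3, 40))
  topo <- cg_topology(data.frame(bead_id = 0:(n - 1),
                                 monomer_id = 0:(n - 1), type = "U",
                                 charge = 0, mass = 1))
  r2 <- compute_rdf(cg_ensemble(co), topo, c("U", "U"), bin_width = 0.1,
                    r_max = 4)
  small <- r2$r <= 0.9
  fitq <- lm(log(r2$p[small] + 1e-12) ~ log(r2$r[small]))
  expect_equal(unname(coef(fitq)[2]), 2, tolerance = 0.25)
  expect_error(compute_rdf(ens, fx$topology, c("Z1", "Z2")), "not present")
})
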