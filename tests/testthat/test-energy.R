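# Pair potential terms, total energy breakdown, forces and parameter
# gradients of the CG model.

test_that("screened electrostatics matches the analytic form and cutoff", {
  expect_equal(u_elec(1.3, 0, 1), 0)
  expect_equal(u_elec(1, 1, 1, eps_r = 17.5, kappa_D = 1.274),
               138.935458 / 17.5 * exp(-1.274))
  expect_equal(u_elec(2.5000001, 1, 1), 0)   # just beyond the 2.5 nm cutoff
  expect_equal(u_elec(2.4999, 1, 1) > 0, TRUE)
  expect_error(u_elec(0, 1, 1), "must be > 0")
  expect_error(u_elec(-0.1, 1, 1), "must be > 0")
})

test_that("soft repulsion is continuous at R_rep and diverges at contact", {
  A <- 41.84; B <- 25104 * 1e-4  # 6 kcal/mol A^4 in kJ/mol nm^4
  expect_equal(u_rep(1.0, A, 1.0, B), B)          # bracket vanishes at R_rep
  expect_equal(u_rep(0.5, A, 1.0, B), A * (1 + cos(pi / 2)) + B / 0.5^4)
  expect_equal(u_rep(0.5, A, 1.0, B), A + 16 * B)
  eps <- 1e-9
  expect_equal(u_rep(1.0 - eps, A, 1.0, B), u_rep(1.0 + eps, A, 1.0, B),
               tolerance = 1e-6)
  expect_gt(u_rep(1e-4, A, 1.0, B), 1e10)         # B/R^4 divergence
  expect_error(u_rep(0, A, 1, B), "must be > 0")
})

test_that("Gaussian attraction has the right peak, tail and linearity", {
  sig <- 0.2
  expect_equal(u_att(0.8, -3, 0.8, sigma = sig), -3 / (sig * sqrt(2 * pi)))
  peak <- abs(u_att(0.8, -3, 0.8, sigma = sig))
  expect_lt(abs(u_att(0.8 + 6 * sig, -3, 0.8, sigma = sig)) / peak, 1e-7)
  # linear in C: u(2C) = 2 u(C)
  expect_equal(u_att(0.93, -4, 0.8), 2 * u_att(0.93, -2, 0.8))
  expect_error(u_att(1, -3, 0.8, sigma = 0), "sigma")
})

test_that("total energy sums terms, restricts V_bind to inter-monomer", {
  m <- two_bead_model(q = c(0.5, -0.5))
  e <- total_energy(two_bead_coords(0.8), m$topology, m$params)
  expect_identical(e[["U_total"]],
                   e[["U_bond"]] + e[["U_elec"]] + e[["U_rep"]] + e[["U_att"]])
  expect_equal(e[["V_bind"]], e[["U_elec"]] + e[["U_rep"]] + e[["U_att"]])
  # beyond cutoff: all nonbonded terms vanish
  far <- total_energy(two_bead_coords(2.6), m$topology, m$params)
  expect_equal(unname(far[c("U_elec", "U_rep", "U_att", "V_bind")]),
               rep(0, 4))
  # single monomer alone: only bonded energy
  topo1 <- cg_topology(
    data.frame(bead_id = 0:1, monomer_id = 0, type = "X",
               charge = 0.5, mass = 100),
    data.frame(bead_i = 0, bead_j = 1, k = 100, r0 = 0.4))
  e1 <- total_energy(two_bead_coords(0.5), topo1, m$params)
  expect_equal(e1[["U_bond"]], 0.5 * 100 * 0.1^2)
  expect_equal(unname(e1[c("U_elec", "U_rep", "U_att", "V_bind")]), rep(0, 4))
  expect_error(total_energy(matrix(0, 3, 3), m$topology, m$params),
               "mismatch")
})

test_that("three-bead energy equals the hand pair sum", {
  topo <- cg_topology(
    data.frame(bead_id = 0:2, monomer_id = c(0, 1, 2), type = "X",
               charge = c(0.4, -0.3, 0.2), mass = 100))
  pr <- data.frame(type_i = "X", type_j = "X", A = 30, R_rep = 0.7,
                   C = -2.5, R_att = 0.9, trainable = FALSE, b_term = TRUE)
  params <- cg_params(pr)
  co <- rbind(c(0, 0, 0), c(0.85, 0.1, 0), c(0.3, 0.9, 0.2))
  e <- total_energy(co, topo, params)
  hand <- 0
  for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
    R <- sqrt(sum((co[p[1], ] - co[p[2], ])^2))
    q <- topo$beads$charge
    hand <- hand + u_elec(R, q[p[1]], q[p[2]]) + u_rep(R, 30, 0.7) +
      u_att(R, -2.5, 0.9)
  }
  expect_equal(e[["U_total"]], hand, tolerance = 1e-10)
})

test_that("forces match central finite differences of the energy", {
  m <- two_bead_model(q = c(0.4, -0.4), C = -3)
  topo <- m$topology
  topo$springs <- data.frame(bead_i = integer(), bead_j = integer(),
                             k = numeric(), r0 = numeric())
  co <- rbind(c(0.02, -0.05, 0.01), c(0.7, 0.25, -0.1))
  f <- cg_forces(co, topo, m$params)
  h <- 1e-6
  for (i in 1:2) for (d in 1:3) {
    cp <- co; cp[i, d] <- cp[i, d] + h
    cm <- co; cm[i, d] <- cm[i, d] - h
    num <- -(total_energy(cp, topo, m$params)[["U_total"]] -
             total_energy(cm, topo, m$params)[["U_total"]]) / (2 * h)
    expect_equal(f[i, d], num, tolerance = 1e-6 * max(1, abs(num)))
  }
  # Newton's third law on an isolated pair
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-12)
  expect_error(cg_forces(rbind(c(0, 0, 0), c(0, 0, 0)), topo, m$params),
               "overlapping")
})

test_that("harmonic spring at its rest length exerts no force", {
  topo <- cg_topology(
    data.frame(bead_id = 0:1, monomer_id = 0, type = "X", charge = 0,
               mass = 100),
    data.frame(bead_i = 0, bead_j = 1, k = 500, r0 = 0.5))
  pr <- data.frame(type_i = "X", type_j = "X", A = 0, R_rep = 0.1, C = 0,
                   R_att = 1, trainable = FALSE, b_term = FALSE)
  f <- cg_forces(two_bead_coords(0.5), topo, cg_params(pr))
  expect_equal(max(abs(f)), 0)
})

test_that("dU/dtheta is the Gaussian factor and matches finite differences", {
  m <- two_bead_model(C = -3, R_att = 0.8)
  g <- du_dtheta(two_bead_coords(0.8), m$topology, m$params)
  expect_equal(unname(g), 1 / (0.2 * sqrt(2 * pi)))
  co <- two_bead_coords(0.93)
  g2 <- du_dtheta(co, m$topology, m$params)
  h <- 1e-4
  num <- (total_energy(co, m$topology, set_theta(m$params, -3 + h))[["U_total"]] -
          total_energy(co, m$topology, set_theta(m$params, -3 - h))[["U_total"]]) / (2 * h)
  expect_equal(unname(g2), num, tolerance = 1e-8)
})

test_that("trainable pairs never in range get zero gradient", {
  topo <- cg_topology(
    data.frame(bead_id = 0:1, monomer_id = 0:1, type = c("X", "Y"),
               charge = 0, mass = 100))
  pr <- data.frame(type_i = c("X", "X", "Y"), type_j = c("X", "Y", "Y"),
                   A = 10, R_rep = 0.5, C = c(-1, -1, -1), R_att = 0.8,
                   trainable = TRUE, b_term = TRUE)
  g <- du_dtheta(two_bead_coords(0.8), topo, cg_params(pr))
  expect_equal(length(g), 3)
  expect_equal(unname(g[c("X:X", "Y:Y")]), c(0, 0))  # types not paired
  expect_gt(g[["X:Y"]], 0)
})

test_that("V_bind is invariant under rigid motion of the whole complex", {
  fx <- make_dimer_reference(seed = 3, n_frames = 5)
  co <- fx$native
  e0 <- total_energy(co, fx$topology, fx$params)
  th <- 0.71
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  co2 <- sweep(co %*% t(Rz), 2, c(0.3, -1.2, 0.5), "+")
  e2 <- total_energy(co2, fx$topology, fx$params)
  expect_equal(e2[["V_bind"]], e0[["V_bind"]], tolerance = 1e-12)
  expect_equal(e2[["U_total"]], e0[["U_total"]], tolerance = 1e-12)
})

test_that("designated-pair V_bind excludes other monomer pairs", {
  tr <- make_trimer_lattice(seed = 2, n_frames = 5)
  co <- tr$native
  e_all <- total_energy(co, tr$topology, tr$params)
  e01 <- total_energy(co, tr$topology, tr$params, bind_pair = c(0, 1))
  e02 <- total_energy(co, tr$topology, tr$params, bind_pair = c(0, 2))
  e12 <- total_energy(co, tr$topology, tr$params, bind_pair = c(1, 2))
  expect_equal(e01[["V_bind"]] + e02[["V_bind"]] + e12[["V_bind"]],
               e_all[["V_bind"]], tolerance = 1e-10)
  expect_lt(e01[["V_bind"]], 0)
})
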