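# Shared builders for small test systems and the quadrature oracles.

# two beads in two monomers with a single trainable Gaussian attraction
two_bead_model <- function(A = 41.84, R_rep = 0.6, C = -3, R_att = 0.8,
                           sigma = 0.2, B = 0.0025104, q = c(0, 0),
                           cutoff = 2.5, b_term = TRUE, mass = 100) {
  topo <- cg_topology(
    data.frame(bead_id = 0:1, monomer_id = 0:1, type = c("X", "X"),
               charge = q, mass = mass))
  pr <- data.frame(type_i = "X", type_j = "X", A = A, R_rep = R_rep,
                   C = C, R_att = R_att, trainable = TRUE, b_term = b_term)
  params <- cg_params(pr, sigma = sigma, B = B, cutoff = cutoff)
  list(topology = topo, params = params)
}

# place the two beads a distance R apart along x
two_bead_coords <- function(R) rbind(c(0, 0, 0), c(R, 0, 0))

# pair energy evaluated directly from the analytic forms (independent of
# the package's energy path)
oracle_pair_energy <- function(R, C, m) {
  p <- m$params$pairs
  q <- m$topology$beads$charge
  ue <- 138.935458 * q[1] * q[2] / (m$params$eps_r * R) *
    exp(-m$params$kappa_D * R)
  ur <- ifelse(R < p$R_rep, p$A * (1 + cos(pi * R / p$R_rep)), 0)
  if (isTRUE(p$b_term)) ur <- ur + m$params$B / R^4
  ua <- C / (m$params$sigma * sqrt(2 * pi)) *
    exp(-(R - p$R_att)^2 / (2 * m$params$sigma^2))
  out <- ue + ur + ua
  out[R > m$params$cutoff] <- 0
  out
}

# 1D Boltzmann quadrature over the pair distance for the two-bead toy:
# returns <f(R)> under p(R) ~ exp(-beta U(R)) on a dense grid
oracle_average <- function(f, C, m, temperature, grid) {
  U <- oracle_pair_energy(grid, C, m)
  w <- exp(-U / (0.0083145 * temperature))
  w <- w / sum(w)
  sum(f(grid) * w)
}

# D_KL(ref || model) over the 1D grid, both distributions Boltzmann
oracle_dkl <- function(C_ref, C_model, m, temperature, grid) {
  beta <- 1 / (0.0083145 * temperature)
  pref <- exp(-beta * oracle_pair_energy(grid, C_ref, m))
  pref <- pref / sum(pref)
  pmod <- exp(-beta * oracle_pair_energy(grid, C_model, m))
  pmod <- pmod / sum(pmod)
  sum(pref * log(pref / pmod))
}

# weighted "dense-sample" ensemble on the grid: one frame per grid point,
# Boltzmann frame weights
grid_ensemble <- function(C, m, temperature, grid) {
  U <- oracle_pair_energy(grid, C, m)
  w <- exp(-U / (0.0083145 * temperature))
  co <- array(0, dim = c(2, 3, length(grid)))
  for (i in seq_along(grid)) co[, , i] <- two_bead_coords(grid[i])
  cg_ensemble(co, weights = w)
}

# exhaustive minimum-chi2 contiguous partition (oracle for edcg_partition)
exhaustive_partition <- function(subspace, n_beads) {
  n <- subspace$n_particles
  best <- NULL; best_chi <- Inf
  cuts <- utils::combn(n - 1, n_beads - 1)
  if (n_beads == 1) cuts <- matrix(numeric(0), nrow = 0, ncol = 1)
  for (ci in seq_len(ncol(cuts))) {
    b <- c(cuts[, ci], n)
    starts <- c(1, utils::head(b, -1) + 1)
    groups <- Map(function(a, z) a:z, starts, b)
    chi <- edcg_residual(mapping_spec(groups), subspace)
    if (chi < best_chi - 1e-15) { best_chi <- chi; best <- groups }
  }
  list(groups = best, chi2 = best_chi)
}
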