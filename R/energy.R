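#' Pair potential terms
#'
#' Scalar (vectorised over `R`) forms of the three nonbonded terms. All
#' energies in kJ/mol, distances in nm.
#'
#' `u_elec` is the Debye-screened Coulomb interaction
#' `ke * Q_I Q_J / (eps_r R) * exp(-kappa_D R)` with the Coulomb constant
#' `ke = 138.935458 kJ mol^-1 nm e^-2`, truncated to zero beyond the cutoff.
#'
#' `u_rep` is a soft cosine repulsion `A * H(R_rep - R) * (1 + cos(pi R /
#' R_rep))` (the Heaviside factor `H` taken as 1 at `R = R_rep`, where the
#' bracket vanishes anyway) plus an always-active `B / R^4` core that keeps
#' the potential bounded below for opposite-charge pairs.
#'
#' `u_att` is a Gaussian well `C / (sigma sqrt(2 pi)) * exp(-(R - R_att)^2 /
#' (2 sigma^2))`; attraction corresponds to `C < 0`.
#'
#' @param R pair distance(s), nm; must be > 0
#' @param Q_I,Q_J bead charges, e
#' @param eps_r,kappa_D,cutoff,A,R_rep,B,C,R_att,sigma see [cg_params]
#' @return energy (kJ/mol), zero beyond `cutoff`
#' @export
u_elec <- function(R, Q_I, Q_J, eps_r = 17.5, kappa_D = 1.274, cutoff = 2.5) {
  if (any(R <= 0)) stop("pair distance must be > 0")
  u <- ke_coul * Q_I * Q_J / (eps_r * R) * exp(-kappa_D * R)
  u[R > cutoff] <- 0
  u
}

#' @rdname u_elec
#' @export
u_rep <- function(R, A, R_rep, B = 6 * kcal * 1e-4, cutoff = 2.5) {
  if (any(R <= 0)) stop("pair distance must be > 0")
  u <- ifelse(R < R_rep, A * (1 + cos(pi * R / R_rep)), 0) + B / R^4
  u[R > cutoff] <- 0
  u
}

#' @rdname u_elec
#' @export
u_att <- function(R, C, R_att, sigma = 0.2, cutoff = 2.5) {
  if (sigma <= 0) stop("sigma must be > 0")
  u <- C / (sigma * sqrt(2 * pi)) * exp(-(R - R_att)^2 / (2 * sigma^2))
  u[R > cutoff] <- 0
  u
}

# resolve a designated binding monomer pair to the (va, vb) ints the core uses
bind_pair_int <- function(bind_pair) {
  if (is.null(bind_pair)) return(c(-1L, -1L))
  if (length(bind_pair) != 2) stop("bind_pair must be two monomer ids")
  as.integer(bind_pair)
}

#' Total CG energy breakdown
#'
#' Sums the harmonic intramonomer springs (`U_bond`) and, over all
#' inter-monomer pairs within the cutoff, screened electrostatics (`U_elec`),
#' soft repulsion (`U_rep`) and Gaussian attraction (`U_att`). `V_bind` is
#' the inter-monomer nonbonded energy, optionally restricted to one
#' designated monomer pair; it never contains bonded or intra-monomer terms.
#'
#' @param coords `n x 3` coordinate matrix (nm) or a [cg_ensemble] frame
#' @param topology a [cg_topology]
#' @param params a [cg_params]
#' @param bind_pair `NULL` (all inter-monomer pairs) or two monomer ids
#' @return named numeric vector `U_bond, U_elec, U_rep, U_att, U_total, V_bind`
#' @export
total_energy <- function(coords, topology, params, bind_pair = NULL) {
  sys <- build_system(topology, params)
  vp <- bind_pair_int(bind_pair)
  cpp_energy(as.matrix(coords), sys, vp[1], vp[2])
}

#' Forces on all beads
#'
#' Negative gradient of the total CG energy; forces are truncated (with the
#' energy) at the cutoff.
#'
#' @inheritParams total_energy
#' @return `n x 3` matrix of forces, kJ mol^-1 nm^-1
#' @export
cg_forces <- function(coords, topology, params) {
  sys <- build_system(topology, params)
  cpp_forces(as.matrix(coords), sys)
}

#' Parameter gradient dU/dtheta
#'
#' Derivative of the total CG energy with respect to each trainable Gaussian
#' amplitude `C_IJ`: the Gaussian factor of the attraction well summed over
#' all in-range inter-monomer pairs of the matching type pair. Because theta
#' enters the energy only through intermolecular terms, this equals
#' `dV_bind/dtheta` when `V_bind` spans all inter-monomer pairs.
#'
#' @inheritParams total_energy
#' @return numeric vector over trainable parameters (kJ mol^-1 nm)^-1 *
#'   kJ/mol, i.e. nm^-1
#' @export
du_dtheta <- function(coords, topology, params, bind_pair = NULL) {
  sys <- build_system(topology, params)
  if (sys$n_theta == 0) return(numeric(0))
  vp <- bind_pair_int(bind_pair)
  coords <- as.matrix(coords)
  fr <- array(coords, dim = c(dim(coords), 1))
  st <- cpp_frame_stats(fr, sys, sys$n_theta, vp[1], vp[2])
  setNames(as.numeric(st$g_full[, 1]), names(get_theta(params)))
}

# Batched per-frame statistics for an ensemble: V_bind, U_total and both
# gradient variants (full U and designated-pair V_bind).
ensemble_stats <- function(ensemble, topology, params, bind_pair = NULL,
                           sys = NULL) {
  if (is.null(sys)) sys <- build_system(topology, params)
  vp <- bind_pair_int(bind_pair)
  cpp_frame_stats(ensemble$coords, sys, sys$n_theta, vp[1], vp[2])
}
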