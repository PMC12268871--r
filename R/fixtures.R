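# Synthetic reference generators. Each fixture builds a ground-truth CG
# model (topology + parameters with known theta*), samples a reference
# ensemble from it with the package's own Langevin engine, and ships the
# ground truth in a sidecar list so recovery tests can compare against it
# after the fact. The three fixtures emulate the three binding regimes of
# interest: a strongly bound dimer, a lattice-like multimer trained on a
# designated pair, and a weakly bound chain pair with frayable termini.

# zigzag chain monomer: beads stacked along z with a small lateral offset
chain_coords <- function(n, x0, spacing = 0.5, wobble = 0.08) {
  z <- (seq_len(n) - (n + 1) / 2) * spacing
  y <- wobble * (-1)^(seq_len(n))
  cbind(x = rep(x0, n), y = y, z = z)
}

all_pair_rows <- function(types) {
  n <- length(types)
  ij <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  data.frame(type_i = types[ij[, 1]], type_j = types[ij[, 2]],
             stringsAsFactors = FALSE)
}

fully_connected_springs <- function(coords, bead_ids, k) {
  n <- nrow(coords)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    out[[length(out) + 1]] <- data.frame(
      bead_i = bead_ids[i], bead_j = bead_ids[j], k = k,
      r0 = sqrt(sum((coords[i, ] - coords[j, ])^2)))
  }
  do.call(rbind, out)
}

# sample a reference ensemble from a ground-truth model, discarding burn-in
sample_reference <- function(topology, params, native, temperature, seed,
                             n_frames, stride = 50L, wall_radius = 2.5,
                             burn_frames = 100L, bind_pair = NULL) {
  st <- sim_settings(dt_fs = 15, temperature = temperature, friction = 1,
                     n_steps = (n_frames + burn_frames) * stride,
                     stride = stride, seed = seed, wall_radius = wall_radius)
  run <- simulate_cg(topology, params, native, st, bind_pair = bind_pair)
  keep <- (burn_frames + 1):n_frames(run$ensemble)
  list(ensemble = cg_ensemble(run$ensemble$coords[, , keep, drop = FALSE]),
       V_bind = run$V_bind[keep], settings = st)
}

#' Synthetic bound-dimer reference
#'
#' Two rigid-ish monomers (fully connected heteroelastic springs) of
#' `beads_per_monomer` beads each, facing each other across a 0.8 nm binding
#' gap. Bead types are shared between the monomers; the Gaussian attractions
#' of the facing like-type pairs carry the ground-truth amplitudes
#' `theta_star` and are the trainable parameters. The reference ensemble is
#' sampled from this ground-truth model at `temperature` and stays bound
#' throughout (a warning is raised otherwise).
#'
#' @param seed integer seed (the fixture is deterministic given the seed)
#' @param n_frames reference frames after burn-in (default 2000)
#' @param beads_per_monomer default 5
#' @param temperature K (default 310)
#' @param theta_star ground-truth facing-pair amplitudes, kJ mol^-1 nm
#'   (length `beads_per_monomer`); the default depths put the mean binding
#'   energy in the strongly bound regime (about -40 kJ/mol)
#' @param k_star ground-truth spring constant, kJ mol^-1 nm^-2
#' @param gap binding gap, nm
#' @param wall_radius reflecting wall radius, nm
#' @param bound_threshold reference frames with `V_bind` above this raise
#'   the unbound-reference warning (kJ/mol)
#' @param cross_strength fixed (non-trainable) amplitudes of the
#'   cross-rung attractions at sequence separation 1 and 2, kJ mol^-1 nm;
#'   these give the interface orientational specificity (without them all
#'   binding wells are parallel to the binding axis and rigid-body twist
#'   and slide of the complex are nearly free)
#' @return list: `topology`, `params` (theta = theta_star), `ensemble`,
#'   `native` (bound start structure), `V_bind` (per reference frame),
#'   `settings`, `ground_truth` (list `theta_star`, `k_star`, `v_bar_ref`)
#' @export
make_dimer_reference <- function(seed = 1L, n_frames = 4000L,
                                 beads_per_monomer = 5L, temperature = 310,
                                 theta_star = NULL, k_star = 3000,
                                 gap = 0.8, wall_radius = 1.1,
                                 bound_threshold = -5,
                                 cross_strength = c(-0.5, -0.2)) {
  if (n_frames < 1) stop("n_frames must be >= 1 (empty ensemble)")
  bpm <- as.integer(beads_per_monomer)
  if (is.null(theta_star)) {
    mid <- (bpm + 1) / 2
    theta_star <- -(3.0 + 1.0 * exp(-(seq_len(bpm) - mid)^2 / 2))
  }
  if (length(theta_star) != bpm)
    stop("theta_star must have one entry per bead type")
  types <- sprintf("T%d", seq_len(bpm))
  qs <- 0.25 * (-1)^(seq_len(bpm) + 1)
  # compact "contact plate": centre bead plus a ring of arm beads in the
  # interface plane; a rotated or slid monomer loses all facing wells at
  # once, giving the bound pose orientational specificity
  arm <- 0.55
  ang <- 2 * pi * (seq_len(bpm - 1) - 1) / (bpm - 1)
  yz <- rbind(c(0, 0), cbind(arm * cos(ang), arm * sin(ang)))
  m1 <- cbind(x = rep(-gap / 2, bpm), y = yz[, 1], z = yz[, 2])
  m2 <- cbind(x = rep(+gap / 2, bpm), y = yz[, 1], z = yz[, 2])
  native <- rbind(m1, m2)
  beads <- data.frame(bead_id = 0:(2 * bpm - 1),
                      monomer_id = rep(0:1, each = bpm),
                      type = rep(types, 2), charge = rep(qs, 2),
                      mass = 110)
  springs <- rbind(fully_connected_springs(m1, 0:(bpm - 1), k_star),
                   fully_connected_springs(m2, bpm:(2 * bpm - 1), k_star))
  topo <- cg_topology(beads, springs)

  pr <- all_pair_rows(types)
  pr$A <- mapply(function(a, b) assign_A(qs[match(a, types)], qs[match(b, types)]),
                 pr$type_i, pr$type_j)
  # native inter-monomer distance per type pair (symmetric across monomers)
  nd <- function(a, b) {
    i <- match(a, types); j <- match(b, types)
    min(sqrt(sum((m1[i, ] - m2[j, ])^2)), sqrt(sum((m1[j, ] - m2[i, ])^2)))
  }
  pr$R_att <- pmin(mapply(nd, pr$type_i, pr$type_j), 2.4)
  # shape complementarity: facing like-type pairs can approach to the
  # binding gap, unlike-type pairs carry a wider soft wall just inside
  # their native separation, so slid or twisted poses are sterically
  # penalised without extra attraction depth
  pr$R_rep <- ifelse(pr$type_i == pr$type_j, 0.6,
                     pmin(0.95 * pr$R_att, 1.2))
  # weak fixed cross attractions between nearby unlike types pin registration
  pr$C <- ifelse(pr$type_i == pr$type_j, 0,
                 ifelse(pr$R_att < 1.2, cross_strength[1],
                        ifelse(pr$R_att < 1.6, cross_strength[2], 0)))
  pr$trainable <- pr$type_i == pr$type_j
  pr$b_term <- TRUE
  params <- cg_params(pr)
  params <- set_theta(params, theta_star)

  ref <- sample_reference(topo, params, native, temperature, seed, n_frames,
                          wall_radius = wall_radius)
  if (mean(ref$V_bind > bound_threshold) > 0.05)
    warning("dimer reference is not consistently bound; ",
            "the overfitting demonstration needs a bound reference")
  list(topology = topo, params = params, ensemble = ref$ensemble,
       native = native, V_bind = ref$V_bind, settings = ref$settings,
       ground_truth = list(theta_star = theta_star, k_star = k_star,
                           v_bar_ref = mean(ref$V_bind)))
}

#' Synthetic weakly bound chain-pair (duplex analog)
#'
#' Two parallel chains with one attraction "rung" per bead pair; the
#' terminal rungs are weaker than the central ones, so long bound-state runs
#' fray at the ends first and simulations at elevated temperature show
#' unbind/rebind cycles.
#'
#' @inheritParams make_dimer_reference
#' @param n_rungs beads per strand (default 4)
#' @param temperature K (default 300)
#' @param theta_star per-rung amplitudes; default weak regime (mean binding
#'   energy about -16 kJ/mol) with 60% strength at the termini
#' @param cross_strength fixed cross-rung amplitude at sequence separation 1
#'   (kJ mol^-1 nm; weaker than the dimer's so the strands can fray)
#' @return as [make_dimer_reference]
#' @export
make_weak_duplex <- function(seed = 1L, n_frames = 2000L, n_rungs = 4L,
                             temperature = 300, theta_star = NULL,
                             k_star = 800, gap = 0.8, wall_radius = 2.0,
                             cross_strength = -1) {
  if (n_frames < 1) stop("n_frames must be >= 1 (empty ensemble)")
  nr <- as.integer(n_rungs)
  if (is.null(theta_star)) {
    theta_star <- rep(-2.6, nr)
    theta_star[c(1, nr)] <- -1.6
  }
  if (length(theta_star) != nr) stop("theta_star must have one entry per rung")
  types <- sprintf("R%d", seq_len(nr))
  qs <- rep(-0.2, nr)
  m1 <- chain_coords(nr, -gap / 2)
  m2 <- chain_coords(nr, +gap / 2)
  native <- rbind(m1, m2)
  beads <- data.frame(bead_id = 0:(2 * nr - 1),
                      monomer_id = rep(0:1, each = nr),
                      type = rep(types, 2), charge = rep(qs, 2), mass = 80)
  springs <- rbind(fully_connected_springs(m1, 0:(nr - 1), k_star),
                   fully_connected_springs(m2, nr:(2 * nr - 1), k_star))
  topo <- cg_topology(beads, springs)
  pr <- all_pair_rows(types)
  pr$A <- 41.84
  pr$R_rep <- 0.6
  nd <- function(a, b) {
    i <- match(a, types); j <- match(b, types)
    min(sqrt(sum((m1[i, ] - m2[j, ])^2)), sqrt(sum((m1[j, ] - m2[i, ])^2)))
  }
  pr$R_att <- pmin(mapply(nd, pr$type_i, pr$type_j), 2.4)
  sep <- abs(match(pr$type_i, types) - match(pr$type_j, types))
  pr$C <- ifelse(sep == 1, cross_strength, 0)
  pr$trainable <- pr$type_i == pr$type_j
  pr$b_term <- TRUE
  params <- cg_params(pr)
  params <- set_theta(params, theta_star)
  ref <- sample_reference(topo, params, native, temperature, seed, n_frames,
                          wall_radius = wall_radius)
  list(topology = topo, params = params, ensemble = ref$ensemble,
       native = native, V_bind = ref$V_bind, settings = ref$settings,
       ground_truth = list(theta_star = theta_star, k_star = k_star,
                           v_bar_ref = mean(ref$V_bind)))
}

#' Synthetic lattice-like trimer (multimer analog)
#'
#' Three identical monomers at the vertices of a triangle, all sharing one
#' bead-type set and one parameter table, for exercising multimer-mode
#' training: gradients and the regularized binding energy act on one
#' designated monomer pair while the updated amplitudes are shared by all
#' monomers.
#'
#' @inheritParams make_dimer_reference
#' @param beads_per_monomer default 4
#' @param ring_radius distance of each monomer centre from the origin, nm
#' @param theta_star per-type amplitudes (facing like-type pairs); default
#'   puts the designated-pair mean binding energy in the strongly bound
#'   lattice regime (about -45 kJ/mol)
#' @return as [make_dimer_reference], plus `bind_pair = c(0, 1)`
#' @export
make_trimer_lattice <- function(seed = 1L, n_frames = 2000L,
                                beads_per_monomer = 4L, temperature = 310,
                                theta_star = NULL, k_star = 1000,
                                ring_radius = 0.65, wall_radius = 2.5) {
  if (n_frames < 1) stop("n_frames must be >= 1 (empty ensemble)")
  bpm <- as.integer(beads_per_monomer)
  if (is.null(theta_star)) theta_star <- rep(-5.5, bpm)
  if (length(theta_star) != bpm)
    stop("theta_star must have one entry per bead type")
  types <- sprintf("T%d", seq_len(bpm))
  qs <- 0.2 * (-1)^(seq_len(bpm) + 1)
  local <- chain_coords(bpm, 0, spacing = 0.45, wobble = 0.06)
  coords <- list(); mono <- integer(0)
  for (m in 0:2) {
    ang <- 2 * pi * m / 3
    centre <- c(ring_radius * cos(ang), ring_radius * sin(ang), 0)
    coords[[m + 1]] <- sweep(local, 2, centre, "+")
    mono <- c(mono, rep(m, bpm))
  }
  native <- do.call(rbind, coords)
  n <- nrow(native)
  beads <- data.frame(bead_id = 0:(n - 1), monomer_id = mono,
                      type = rep(types, 3), charge = rep(qs, 3), mass = 120)
  springs <- do.call(rbind, lapply(0:2, function(m)
    fully_connected_springs(coords[[m + 1]], (m * bpm):((m + 1) * bpm - 1),
                            k_star)))
  topo <- cg_topology(beads, springs)
  pr <- all_pair_rows(types)
  pr$A <- 25 * kcal               # multimer-mode constant repulsion level
  # R_rep from per-type gyration-style radii: half the mean distance of a
  # bead from its monomer centre, symmetrised over the pair
  rg <- sqrt(rowSums(sweep(local, 2, colMeans(local))^2))
  rg_t <- setNames(pmax(rg, 0.25), types)
  pr$R_rep <- 0.5 * (rg_t[pr$type_i] + rg_t[pr$type_j])
  # multimer rule: attraction radius at the minimum mean inter-monomer
  # distance of the type pair in the native lattice
  nd <- function(a, b) {
    i <- match(a, types); j <- match(b, types)
    d <- Inf
    for (ma in 0:1) for (mb in (ma + 1):2) {
      pa <- coords[[ma + 1]]; pb <- coords[[mb + 1]]
      d <- min(d, sqrt(sum((pa[i, ] - pb[j, ])^2)),
               sqrt(sum((pa[j, ] - pb[i, ])^2)))
    }
    d
  }
  pr$R_att <- pmin(mapply(nd, pr$type_i, pr$type_j), 2.4)
  sep <- abs(match(pr$type_i, types) - match(pr$type_j, types))
  pr$C <- ifelse(sep == 1, -2, 0)
  pr$trainable <- pr$type_i == pr$type_j
  pr$b_term <- TRUE
  params <- cg_params(pr)
  params <- set_theta(params, theta_star)
  ref <- sample_reference(topo, params, native, temperature, seed, n_frames,
                          wall_radius = wall_radius, bind_pair = c(0, 1))
  list(topology = topo, params = params, ensemble = ref$ensemble,
       native = native, V_bind = ref$V_bind, settings = ref$settings,
       bind_pair = c(0L, 1L),
       ground_truth = list(theta_star = theta_star, k_star = k_star,
                           v_bar_ref = mean(ref$V_bind)))
}

#' Pseudo-fine-grained chain with known mapping
#'
#' Generates a bead-level chain trajectory from known heterogeneous springs,
#' then realises each bead as a tight cluster of `factor` fine particles
#' (fixed offsets plus small per-frame jitter). Essential-dynamics
#' partitioning of the fine trajectory should recover the generating cluster
#' boundaries, and heteroelastic-network fitting of the mapped trajectory
#' the generating spring constants.
#'
#' @param seed integer seed
#' @param n_frames bead-level frames (default 2000)
#' @param n_beads chain length (default 4)
#' @param factor fine particles per bead (>= 1; 1 reproduces the bead
#'   trajectory exactly)
#' @param k_star consecutive-spring constants, length `n_beads - 1`
#'   (default two stiffness classes c(300, 900, 300) for a 4-bead chain)
#' @param spacing bead spacing, nm
#' @param cluster_r cluster radius of the fine particles, nm
#' @param jitter per-frame fine-particle jitter (sd, nm)
#' @param temperature K
#' @param bead_charge,bead_mass per-bead totals, split equally over members
#' @return list: `fine_ensemble`, `mapping` ([mapping_spec]),
#'   `fine_charges`, `fine_masses`, `bead_ensemble`, `topology` (bead-level,
#'   with the generating springs), `ground_truth` (list `k_star`,
#'   `boundaries`)
#' @export
make_fine_chain <- function(seed = 1L, n_frames = 2000L, n_beads = 4L,
                            factor = 3L, k_star = NULL, spacing = 0.5,
                            cluster_r = 0.05, jitter = 0.01,
                            temperature = 310, bead_charge = 0.2,
                            bead_mass = 60) {
  nb <- as.integer(n_beads); f <- as.integer(factor)
  if (f < 1) stop("factor must be >= 1")
  if (is.null(k_star)) {
    k_star <- rep(300, nb - 1)
    if (nb >= 3) k_star[seq(2, nb - 1, by = 2)] <- 900
  }
  if (length(k_star) != nb - 1)
    stop("k_star must have one entry per consecutive bond")
  native <- chain_coords(nb, 0, spacing = spacing, wobble = 0.05)
  beads <- data.frame(bead_id = 0:(nb - 1), monomer_id = 0,
                      type = sprintf("B%d", seq_len(nb)),
                      charge = bead_charge, mass = bead_mass)
  springs <- data.frame(bead_i = 0:(nb - 2), bead_j = 1:(nb - 1), k = k_star,
                        r0 = sqrt(rowSums((native[-1, , drop = FALSE] -
                                           native[-nb, , drop = FALSE])^2)))
  topo <- cg_topology(beads, springs)
  # nonbonded table is inert (single monomer) but must cover the types
  pr <- all_pair_rows(beads$type)
  pr$A <- 0; pr$R_rep <- 0.1; pr$C <- 0; pr$R_att <- 1
  pr$trainable <- FALSE; pr$b_term <- FALSE
  params <- cg_params(pr)
  st <- sim_settings(dt_fs = 15, temperature = temperature, friction = 1,
                     n_steps = (n_frames + 100) * 20L, stride = 20L,
                     seed = seed, wall_radius = 0)
  run <- simulate_cg(topo, params, native, st)
  keep <- 101:n_frames(run$ensemble)
  bead_co <- run$ensemble$coords[, , keep, drop = FALSE]
  F <- dim(bead_co)[3]
  if (f == 1) {
    fine_co <- bead_co
  } else {
    # deterministic cluster offsets on a small sphere + per-frame jitter
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed + 7L)
    offs <- matrix(rnorm(nb * f * 3), ncol = 3)
    offs <- offs / sqrt(rowSums(offs^2)) * cluster_r
    fine_co <- array(0, dim = c(nb * f, 3, F))
    noise <- array(rnorm(nb * f * 3 * F, sd = jitter), dim = c(nb * f, 3, F))
    for (t in seq_len(F)) {
      base <- bead_co[rep(seq_len(nb), each = f), , t]
      fine_co[, , t] <- base + offs + noise[, , t]
    }
  }
  groups <- split(seq_len(nb * f), rep(seq_len(nb), each = f))
  list(fine_ensemble = cg_ensemble(fine_co),
       mapping = mapping_spec(unname(groups), weights = "mass"),
       fine_charges = rep(bead_charge / f, nb * f),
       fine_masses = rep(bead_mass / f, nb * f),
       bead_ensemble = cg_ensemble(bead_co),
       topology = topo,
       ground_truth = list(k_star = k_star,
                           boundaries = cumsum(rep(f, nb))))
}

#' Count unbind/rebind cycles in a binding-energy trace
#'
#' Two-threshold (hysteresis) counting: the complex must first rise above
#' `unbound_at` and then fall below `bound_at` to complete one cycle.
#'
#' @param v_bind per-frame binding energy, kJ/mol
#' @param bound_at bound-state threshold, kJ/mol (default -8)
#' @param unbound_at unbound threshold, kJ/mol (default -1)
#' @return integer number of completed unbind-rebind cycles
#' @export
count_rebind_cycles <- function(v_bind, bound_at = -8, unbound_at = -1) {
  state <- v_bind[1] < bound_at
  cycles <- 0L
  unbound_seen <- FALSE
  for (v in v_bind) {
    if (state) {
      if (v > unbound_at) { state <- FALSE; unbound_seen <- TRUE }
    } else {
      if (v < bound_at) {
        state <- TRUE
        if (unbound_seen) cycles <- cycles + 1L
      }
    }
  }
  cycles
}
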