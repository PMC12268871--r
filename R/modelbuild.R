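# Rule-based construction of the fixed nonbonded constants: repulsion radii
# from distance distributions, repulsion heights from charge signs, and the
# multimer-mode variants.

#' Pair rule set
#'
#' @param mode `"standard"` (charge-sign A levels, RDF-based radii) or
#'   `"multimer"` (constant A = 25 kcal/mol, gyration-radius repulsion radii,
#'   minimum mean inter-monomer distance for the attraction radius)
#' @param A_unit base repulsion level, kJ/mol (default 10 kcal/mol = 41.84);
#'   assignments are multiples of this level
#' @param A_multimer multimer-mode constant, kJ/mol (default 25 kcal/mol)
#' @param rdf_threshold threshold fraction of the peak density for the
#'   repulsion-radius rule (default 0.05), in (0, 1)
#' @param gyration_radii named per-type gyration radii, nm (multimer mode)
#' @return object of class `pair_ruleset`
#' @export
pair_ruleset <- function(mode = c("standard", "multimer"),
                         A_unit = 10 * kcal, A_multimer = 25 * kcal,
                         rdf_threshold = 0.05, gyration_radii = NULL) {
  mode <- match.arg(mode)
  stopifnot(rdf_threshold > 0, rdf_threshold < 1, A_unit > 0, A_multimer > 0)
  structure(list(mode = mode, A_unit = A_unit, A_multimer = A_multimer,
                 rdf_threshold = rdf_threshold,
                 gyration_radii = gyration_radii),
            class = "pair_ruleset")
}

# first local maximum of the 3-bin moving-average smoothed density that
# rises above noise_floor * max
find_first_peak <- function(rdf, noise_floor = 0.1) {
  p <- rdf$p
  if (length(p) >= 3) {
    ps <- stats::filter(p, rep(1 / 3, 3), sides = 2)
    ps[is.na(ps)] <- p[is.na(ps)]
    ps <- as.numeric(ps)
  } else ps <- p
  floor_v <- noise_floor * max(ps)
  for (i in seq_along(ps)) {
    if (ps[i] <= floor_v) next
    left <- if (i == 1) -Inf else ps[i - 1]
    right <- if (i == length(ps)) -Inf else ps[i + 1]
    if (ps[i] >= left && ps[i] >= right) return(list(index = i, p = ps))
  }
  NULL
}

#' Repulsion radius from a distance distribution
#'
#' The largest bin centre that is still smaller than the radius of the first
#' peak of the distribution and at which the density does not exceed
#' `threshold * p_max` (`p_max` taken at the first peak after 3-bin
#' smoothing).
#'
#' @param rdf a `cg_rdf` from [compute_rdf]
#' @param threshold fraction of the peak density (default 0.05)
#' @param pair optional pair label used in error messages
#' @return repulsion radius, nm
#' @export
determine_R_rep <- function(rdf, threshold = 0.05, pair = NULL) {
  lbl <- if (is.null(pair)) paste(rdf$type_pair, collapse = ":")
         else paste(pair, collapse = ":")
  pk <- find_first_peak(rdf)
  if (is.null(pk)) stop("no detectable first peak in RDF for pair ", lbl)
  pmax_v <- pk$p[pk$index]
  below <- seq_len(pk$index - 1)
  if (!length(below)) stop("no bins below the first peak for pair ", lbl)
  ok <- below[pk$p[below] <= threshold * pmax_v]
  if (!length(ok))
    stop("all bins below the first peak exceed ", threshold,
         " * p_max for pair ", lbl)
  rdf$r[max(ok)]
}

#' Repulsion height from bead charges
#'
#' Standard mode, in multiples of the base level (10 kcal/mol): like-sign
#' pairs (zero charge counts as matching either sign) get one level;
#' strongly opposite pairs (`Q_I * Q_J < -1` e^2) get ten levels
#' (100 kcal/mol); intermediate opposite-sign pairs (`-1 <= Q_I*Q_J < 0`)
#' interpolate linearly between those anchors by `|Q_I*Q_J|` and round up to
#' the next level. Multimer mode returns the constant 25 kcal/mol.
#' Symmetric in its arguments.
#'
#' @param Q_I,Q_J bead charges, e
#' @param ruleset a [pair_ruleset]
#' @return A, kJ/mol
#' @export
assign_A <- function(Q_I, Q_J, ruleset = pair_ruleset()) {
  stopifnot(is.finite(Q_I), is.finite(Q_J))
  if (ruleset$mode == "multimer") return(ruleset$A_multimer)
  prod <- Q_I * Q_J
  if (prod >= 0) return(ruleset$A_unit)        # like signs or a zero charge
  if (prod < -1) return(10 * ruleset$A_unit)
  levels_interp <- 1 + 9 * abs(prod)           # 1 level at 0-, 10 levels at -1
  ceiling(levels_interp - 1e-9) * ruleset$A_unit
}

#' Attraction radius from reference data
#'
#' Standard mode: the first-peak radius of the pair distance distribution.
#' Multimer mode: the minimum over monomer pairs of the mean inter-monomer
#' distance for the type pair.
#'
#' @param ensemble reference [cg_ensemble]
#' @param topology a [cg_topology]
#' @param type_pair two type labels
#' @param mode `"standard"` or `"multimer"`
#' @param bin_width RDF bin width for standard mode, nm
#' @return attraction radius, nm
#' @export
determine_R_att <- function(ensemble, topology, type_pair,
                            mode = c("standard", "multimer"),
                            bin_width = 0.02) {
  mode <- match.arg(mode)
  if (mode == "standard") {
    rdf <- compute_rdf(ensemble, topology, type_pair, bin_width = bin_width)
    pk <- find_first_peak(rdf)
    if (is.null(pk)) stop("no detectable first peak in RDF for pair ",
                          paste(type_pair, collapse = ":"))
    return(rdf$r[pk$index])
  }
  b <- topology$beads[order(topology$beads$bead_id), ]
  monos <- sort(unique(b$monomer_id))
  if (length(monos) < 2) stop("multimer mode needs at least two monomers")
  co <- ensemble$coords
  best <- Inf
  for (a in seq_along(monos)) for (bb in seq_along(monos)) {
    if (bb <= a) next
    ii <- which(b$type == type_pair[1] & b$monomer_id == monos[a])
    jj <- which(b$type == type_pair[2] & b$monomer_id == monos[bb])
    ii2 <- which(b$type == type_pair[2] & b$monomer_id == monos[a])
    jj2 <- which(b$type == type_pair[1] & b$monomer_id == monos[bb])
    pairs <- rbind(expand.grid(i = ii, j = jj), expand.grid(i = ii2, j = jj2))
    pairs <- unique(pairs[pairs$i != pairs$j, ])
    if (!nrow(pairs)) next
    dsum <- 0
    F <- dim(co)[3]
    for (f in seq_len(F)) {
      m <- co[, , f]
      dsum <- dsum + mean(sqrt(rowSums((m[pairs$i, , drop = FALSE] -
                                        m[pairs$j, , drop = FALSE])^2)))
    }
    best <- min(best, dsum / F)
  }
  if (!is.finite(best)) stop("no inter-monomer pairs for type pair ",
                             paste(type_pair, collapse = ":"))
  best
}

#' Build a full nonbonded parameter table from reference data
#'
#' Applies the rules for every bead type pair of the topology: `A` from
#' charges ([assign_A]; per-bead-type charge taken from the first bead of
#' each type), `R_rep` from the distance distribution (standard mode,
#' [determine_R_rep]) or the per-type gyration radii (multimer mode), and
#' `R_att` from [determine_R_att]. All `C` start at 0 and are flagged
#' trainable.
#'
#' @param ensemble reference [cg_ensemble]
#' @param topology a [cg_topology]
#' @param ruleset a [pair_ruleset]
#' @param bin_width RDF bin width, nm
#' @param ... globals passed to [cg_params] (`sigma`, `B`, `eps_r`,
#'   `kappa_D`, `cutoff`)
#' @return a [cg_params]
#' @export
build_params <- function(ensemble, topology, ruleset = pair_ruleset(),
                         bin_width = 0.02, ...) {
  b <- topology$beads[order(topology$beads$bead_id), ]
  types <- sort(unique(b$type))
  qtype <- vapply(types, function(tp) b$charge[b$type == tp][1], 0)
  rows <- list()
  for (i in seq_along(types)) for (j in i:length(types)) {
    ti <- types[i]; tj <- types[j]
    mode <- ruleset$mode
    A <- assign_A(qtype[[ti]], qtype[[tj]], ruleset)
    if (mode == "multimer") {
      if (is.null(ruleset$gyration_radii))
        stop("multimer mode requires per-type gyration radii")
      R_rep <- 0.5 * (ruleset$gyration_radii[[ti]] +
                      ruleset$gyration_radii[[tj]])
      R_att <- determine_R_att(ensemble, topology, c(ti, tj), "multimer")
    } else {
      rdf <- compute_rdf(ensemble, topology, c(ti, tj), bin_width = bin_width)
      R_rep <- determine_R_rep(rdf, ruleset$rdf_threshold, pair = c(ti, tj))
      R_att <- determine_R_att(ensemble, topology, c(ti, tj), "standard",
                               bin_width = bin_width)
    }
    rows[[length(rows) + 1]] <- data.frame(
      type_i = ti, type_j = tj, A = A, R_rep = R_rep, C = 0, R_att = R_att,
      trainable = TRUE, b_term = TRUE)
  }
  cg_params(do.call(rbind, rows), ...)
}
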