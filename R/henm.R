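# Heteroelastic network fitting: iterative update of intramonomer spring
# constants toward reference mean squared pair distances.

#' Mean squared pair distances over an ensemble
#'
#' @param ensemble a [cg_ensemble] with at least 2 frames (1 allowed for
#'   static references)
#' @param pairs data.frame (or 2-column matrix) of 0-based bead pairs
#'   `bead_i`, `bead_j`
#' @param center subtract the squared mean distance, i.e. return the mean
#'   squared distance fluctuation `<R^2> - <R>^2` (default FALSE: raw
#'   `<R^2>`)
#' @return numeric vector of per-pair mean squared distances, nm^2
#' @export
spring_msd <- function(ensemble, pairs, center = FALSE) {
  if (n_frames(ensemble) < 1) stop("empty ensemble")
  pairs <- as.data.frame(pairs)
  co <- ensemble$coords
  F <- dim(co)[3]
  vapply(seq_len(nrow(pairs)), function(p) {
    i <- pairs$bead_i[p] + 1L; j <- pairs$bead_j[p] + 1L
    d2 <- colSums((co[i, , , drop = TRUE] - co[j, , , drop = TRUE])^2)
    if (F == 1) d2 <- sum((co[i, , 1] - co[j, , 1])^2)
    out <- frame_mean(d2, ensemble$weights)
    if (center) out <- out - frame_mean(sqrt(d2), ensemble$weights)^2
    out
  }, 0)
}

#' One heteroelastic-network update step
#'
#' Updates every spring's compliance: `1/k <- 1/k - gamma * (<R^2>_CG -
#' <R^2>_ref)`. Springs whose CG fluctuations exceed the reference are
#' stiffened. `k` is clamped to `[k_min, k_max]`; an update that would drive
#' the compliance non-positive clamps at `k_max`.
#'
#' @param k current spring constants, kJ mol^-1 nm^-2
#' @param msd_cg measured CG mean squared distances, nm^2
#' @param msd_ref reference mean squared distances, nm^2
#' @param gamma learning rate on the compliance, (kJ/mol)^-1; default
#'   `0.3 * beta` at `temperature` (a damped Newton step, since
#'   d<R^2>/d(1/k) is of order kB*T)
#' @param temperature K (used only for the default gamma)
#' @param k_min,k_max clamp bounds, kJ mol^-1 nm^-2
#' @param max_rel_step per-iteration clamp on |delta(1/k)| / (1/k)
#' @return updated spring constant vector
#' @export
henm_update <- function(k, msd_cg, msd_ref, gamma = NULL, temperature = 310,
                        k_min = 1, k_max = 1e5, max_rel_step = 0.2) {
  if (is.null(gamma)) gamma <- 0.3 * beta_kJ(temperature)
  inv <- 1 / k
  step <- gamma * (msd_cg - msd_ref)
  step <- pmin(pmax(step, -max_rel_step * inv), max_rel_step * inv)
  inv_new <- inv - step
  k_new <- ifelse(inv_new <= 0, k_max, 1 / inv_new)
  pmin(pmax(k_new, k_min), k_max)
}

#' Build a heteroelastic spring network from a reference ensemble
#'
#' Connects every intramonomer bead pair whose reference mean distance is
#' below `r_enm`; rest lengths are set to the reference mean distances and
#' all spring constants to `k_init`.
#'
#' @param topology a [cg_topology] (its spring table is replaced)
#' @param reference reference [cg_ensemble]
#' @param r_enm connection cutoff, nm (default 2.0)
#' @param k_init initial spring constant, kJ mol^-1 nm^-2 (default 500)
#' @return a [cg_topology] with the new spring network
#' @export
build_spring_network <- function(topology, reference, r_enm = 2.0,
                                 k_init = 500) {
  b <- topology$beads[order(topology$beads$bead_id), ]
  n <- nrow(b)
  co <- reference$coords
  F <- dim(co)[3]
  si <- sj <- integer(0); r0 <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (b$monomer_id[i] != b$monomer_id[j]) next
    dmean <- mean(sqrt(colSums((co[i, , , drop = TRUE] -
                                co[j, , , drop = TRUE])^2)))
    if (F == 1) dmean <- sqrt(sum((co[i, , 1] - co[j, , 1])^2))
    if (dmean < r_enm) {
      si <- c(si, b$bead_id[i]); sj <- c(sj, b$bead_id[j])
      r0 <- c(r0, dmean)
    }
  }
  if (!length(si)) stop("no spring pairs within r_enm = ", r_enm, " nm")
  cg_topology(topology$beads,
              data.frame(bead_i = si, bead_j = sj, k = k_init, r0 = r0))
}

#' Iterative heteroelastic-network fit
#'
#' Alternates Langevin sampling of the current spring network with
#' compliance updates ([henm_update]) until the worst relative mismatch of
#' the matched distance statistic drops below `tol` or `max_iter` is
#' reached. Nonbonded parameters do not enter (springs are intramonomer,
#' nonbonded terms inter-monomer), so the fit samples the bonded network
#' alone.
#'
#' By default the matched statistic is the mean squared distance
#' *fluctuation* `<R^2> - <R>^2` per spring. Rest lengths are set from the
#' reference mean distances, which already contain the entropic stretch of
#' the reference model; matching raw `<R^2>` therefore has its fixed point
#' at systematically stiffened constants (the raw second moment is
#' dominated by the mean rather than by the fluctuations the elastic
#' network is meant to reproduce). `statistic = "raw"` remains available
#' for pre-centred references.
#'
#' @param topology a [cg_topology] whose springs are the network to fit
#'   (e.g. from [build_spring_network])
#' @param reference reference [cg_ensemble] defining the target fluctuations
#' @param settings a [sim_settings] for the per-iteration sampling runs
#' @param gamma,k_min,k_max,max_rel_step see [henm_update]
#' @param tol convergence tolerance on max relative MSD mismatch (default 0.05)
#' @param max_iter iteration cap (default 30)
#' @param start start coordinates for the sampling runs (default: reference
#'   mean structure)
#' @param statistic `"fluctuation"` (default) or `"raw"`; see Details
#' @return list of class `henm_fit`: `topology` (fitted), `converged`,
#'   `history` (data.frame iteration, max_rel_err), `k_history` (matrix)
#' @export
henm_fit <- function(topology, reference, settings, gamma = NULL,
                     k_min = 1, k_max = 1e5, max_rel_step = 0.2,
                     tol = 0.05, max_iter = 30, start = NULL,
                     statistic = c("fluctuation", "raw")) {
  statistic <- match.arg(statistic)
  centre <- statistic == "fluctuation"
  if (!nrow(topology$springs)) stop("topology has no springs to fit")
  pairs <- topology$springs[, c("bead_i", "bead_j")]
  msd_ref <- spring_msd(reference, pairs, center = centre)
  if (statistic == "raw" && any(msd_ref <= 0))
    stop("reference mean squared distances must be > 0")
  if (any(msd_ref < 0)) stop("reference distance fluctuations must be >= 0")
  if (is.null(start)) start <- apply(reference$coords, c(1, 2), mean)
  # empty nonbonded parameter set: sampling the bonded network only
  types <- unique(topology$beads$type)
  pr <- data.frame(type_i = types[1], type_j = types[1], A = 0, R_rep = 0.1,
                   C = 0, R_att = 1, trainable = FALSE, b_term = FALSE)
  if (length(types) > 1) {
    cmb <- t(combn(types, 2))
    pr <- rbind(pr, data.frame(type_i = c(cmb[, 1], types[-1]),
                               type_j = c(cmb[, 2], types[-1]),
                               A = 0, R_rep = 0.1, C = 0, R_att = 1,
                               trainable = FALSE, b_term = FALSE))
  }
  params0 <- cg_params(pr)
  topo <- topology
  hist_err <- numeric(0)
  k_hist <- matrix(NA_real_, nrow = 0, ncol = nrow(pairs))
  best_topo <- topo; best_err <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    st <- settings
    st$seed <- as.integer((settings$seed + it * 7919) %% .Machine$integer.max)
    run <- simulate_cg(topo, params0, start, st)
    msd_cg <- spring_msd(run$ensemble, pairs, center = centre)
    err <- max(abs(msd_cg - msd_ref) / pmax(msd_ref, 1e-12))
    hist_err <- c(hist_err, err)
    k_hist <- rbind(k_hist, topo$springs$k)
    if (err < best_err) { best_err <- err; best_topo <- topo }
    if (err < tol) { converged <- TRUE; break }
    topo$springs$k <- henm_update(topo$springs$k, msd_cg, msd_ref,
                                  gamma = gamma,
                                  temperature = settings$temperature,
                                  k_min = k_min, k_max = k_max,
                                  max_rel_step = max_rel_step)
  }
  if (!converged)
    warning("hENM fit did not reach tol = ", tol, " within ", max_iter,
            " iterations (best max rel. error ", signif(best_err, 3), ")")
  structure(list(topology = if (converged) topo else best_topo,
                 converged = converged,
                 history = data.frame(iteration = seq_along(hist_err),
                                      max_rel_err = hist_err),
                 k_history = k_hist),
            class = "henm_fit")
}

#' @export
print.henm_fit <- function(x, ...) {
  cat("hENM fit:", nrow(x$history), "iterations,",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(final max rel. MSD error %.3g)\n", tail(x$history$max_rel_err, 1)))
  invisible(x)
}
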