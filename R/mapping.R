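#' Mapping specification
#'
#' Partition of fine particles into beads. Beads are contiguous sequence
#' segments (the essential-dynamics coarse-graining convention); each fine
#' particle belongs to exactly one bead.
#'
#' @param groups list of integer vectors of fine-particle indices (1-based),
#'   disjoint, contiguous and covering `1:n`
#' @param weights `"mass"` (mass-weighted bead positions, default) or
#'   `"uniform"`
#' @return object of class `mapping_spec`
#' @export
mapping_spec <- function(groups, weights = c("mass", "uniform")) {
  weights <- match.arg(weights)
  if (!length(groups)) stop("mapping needs at least one bead")
  all_idx <- as.integer(unlist(groups))
  n <- length(all_idx)
  if (any(vapply(groups, length, 0L) == 0)) stop("empty bead in mapping")
  if (anyDuplicated(all_idx) || !identical(sort(all_idx), 1:n))
    stop("bead index sets must be disjoint and cover all particles")
  for (g in groups)
    if (!identical(as.integer(g), as.integer(min(g):max(g))))
      stop("bead index sets must be contiguous segments")
  structure(list(groups = lapply(groups, as.integer), weights = weights,
                 n_beads = length(groups), n_particles = n),
            class = "mapping_spec")
}

#' @export
print.mapping_spec <- function(x, ...) {
  cat("Mapping:", x$n_particles, "fine particles ->", x$n_beads, "beads (",
      x$weights, "weights )\n")
  invisible(x)
}

# iterative least-squares alignment of all frames to their mean structure
align_frames <- function(coords, n_iter = 3) {
  F <- dim(coords)[3]
  ref <- coords[, , 1]
  for (it in seq_len(n_iter)) {
    for (f in seq_len(F)) coords[, , f] <- superpose(coords[, , f], ref)
    ref <- apply(coords, c(1, 2), mean)
  }
  list(coords = coords, mean = ref)
}

#' Principal component subspace of a fine ensemble
#'
#' Frames are least-squares superposed onto their mean structure, then the
#' 3n x 3n covariance of the coordinate fluctuations is diagonalised.
#' Components are orthonormal and sorted by decreasing variance.
#'
#' @param ensemble a [cg_ensemble] with at least 2 frames
#' @param n_components number of components to retain, or `NULL` to use
#'   `variance_fraction`
#' @param variance_fraction retain the smallest number of components
#'   capturing at least this fraction of total variance (default 0.9)
#' @param align least-squares superpose frames onto the mean structure
#'   before the covariance (default TRUE; disable for pre-aligned or
#'   synthetic displacement data)
#' @return object of class `pc_subspace`: `mean` (n x 3), `vectors`
#'   (3n x K, particle-major: rows are x1,y1,z1,x2,...), `variances` (K),
#'   `total_variance`, `n_particles`
#' @export
pca_subspace <- function(ensemble, n_components = NULL,
                         variance_fraction = 0.9, align = TRUE) {
  d <- dim(ensemble$coords)
  n <- d[1]; F <- d[3]
  if (F < 2) stop("need at least 2 frames for a PC subspace")
  co <- if (align) align_frames(ensemble$coords)$coords else ensemble$coords
  X <- t(apply(co, 3, function(m) as.numeric(t(m))))  # F x 3n
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  cov <- crossprod(Xc) / (F - 1)
  eg <- eigen(cov, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  total <- sum(vals)
  if (is.null(n_components)) {
    if (total == 0) {
      n_components <- 1L
    } else {
      cs <- cumsum(vals) / total
      n_components <- which(cs >= variance_fraction)[1]
    }
  } else {
    if (n_components > F - 1)
      stop("fewer independent frames than requested components")
    if (n_components > 3 * n)
      stop("more components than degrees of freedom")
  }
  n_components <- as.integer(n_components)
  structure(list(mean = matrix(mu, ncol = 3, byrow = TRUE),
                 vectors = eg$vectors[, seq_len(n_components), drop = FALSE],
                 variances = vals[seq_len(n_components)],
                 total_variance = total, n_particles = n),
            class = "pc_subspace")
}

#' @export
print.pc_subspace <- function(x, ...) {
  cat("PC subspace:", length(x$variances), "components over",
      x$n_particles, "particles;",
      sprintf("%.1f%% of total variance\n",
              if (x$total_variance > 0)
                100 * sum(x$variances) / x$total_variance else 100))
  invisible(x)
}

# pairwise fluctuation mismatch in the retained subspace:
# d[i, j] = sum_k lambda_k |v_k(i) - v_k(j)|^2
# (equals <|dr_i^PC - dr_j^PC|^2> because PC amplitudes are uncorrelated
# with variances lambda_k)
pc_pair_mismatch <- function(subspace) {
  n <- subspace$n_particles
  K <- length(subspace$variances)
  D <- matrix(0, n, n)
  for (k in seq_len(K)) {
    vk <- matrix(subspace$vectors[, k], ncol = 3, byrow = TRUE)  # n x 3
    G <- vk %*% t(vk)
    sq <- diag(G)
    D <- D + subspace$variances[k] * (outer(sq, sq, "+") - 2 * G)
  }
  D
}

#' Essential-dynamics residual of a partition
#'
#' chi^2 = 1/(3 N_beads) * sum over beads of the summed mean squared
#' differences of the PC-subspace fluctuations of all unordered particle
#' pairs within the bead. Evaluated in closed form from the retained
#' component variances (the frame average and the variance form are
#' algebraically identical for projected fluctuations).
#'
#' @param spec a [mapping_spec]
#' @param subspace a [pc_subspace]
#' @return chi^2 in nm^2 (non-negative)
#' @export
edcg_residual <- function(spec, subspace) {
  if (spec$n_particles != subspace$n_particles)
    stop("mapping and subspace particle counts differ")
  D <- pc_pair_mismatch(subspace)
  tot <- 0
  for (g in spec$groups) {
    if (length(g) > 1) tot <- tot + sum(D[g, g]) / 2
  }
  tot / (3 * spec$n_beads)
}

#' Optimal contiguous EDCG partition
#'
#' Finds the contiguous partition of the chain into `n_beads` segments
#' minimising the essential-dynamics residual. Exact dynamic programming
#' over boundary placements (O(n^2 B)); ties broken toward the
#' lexicographically smallest boundary vector. A seeded simulated-annealing
#' refinement (`method = "anneal"`) is available for very long chains where
#' the quadratic precomputation is unwanted.
#'
#' @param subspace a [pc_subspace]
#' @param n_beads number of beads (1..n_particles)
#' @param weights weight scheme recorded in the returned [mapping_spec]
#' @param method `"exact"` (default) or `"anneal"`
#' @param seed seed for the annealing fallback
#' @param n_anneal annealing sweeps
#' @return a [mapping_spec] with attribute `chi2`
#' @export
edcg_partition <- function(subspace, n_beads, weights = "mass",
                           method = c("exact", "anneal"), seed = 1L,
                           n_anneal = 2000L) {
  method <- match.arg(method)
  n <- subspace$n_particles
  if (n_beads < 1) stop("n_beads must be >= 1")
  if (n_beads > n) stop("n_beads cannot exceed the particle count")
  D <- pc_pair_mismatch(subspace)
  # segment cost S[a, b] = sum_{a <= i < j <= b} D[i, j]
  seg_cost <- matrix(0, n, n)
  for (a in seq_len(n)) {
    acc <- 0
    if (a < n) for (b in (a + 1):n) {
      acc <- acc + sum(D[a:(b - 1), b])
      seg_cost[a, b] <- acc
    }
  }
  if (method == "anneal") {
    groups <- anneal_partition(seg_cost, n_beads, seed, n_anneal)
  } else {
    # suffix DP: g[b, j] = min cost of partitioning j..n into b segments
    INF <- Inf
    g <- matrix(INF, n_beads, n + 1)
    g[1, 1:n] <- seg_cost[cbind(1:n, n)]
    if (n_beads > 1) for (b in 2:n_beads) {
      for (j in 1:(n - b + 1)) {
        ends <- j:(n - b + 1)
        vals <- seg_cost[cbind(rep(j, length(ends)), ends)] + g[b - 1, ends + 1]
        g[b, j] <- min(vals)
      }
    }
    # front-to-back reconstruction; earliest feasible boundary on ties gives
    # the lexicographically smallest boundary vector
    groups <- vector("list", n_beads)
    j <- 1L
    for (b in n_beads:1) {
      if (b == 1) { groups[[n_beads]] <- j:n; break }
      ends <- j:(n - b + 1)
      vals <- seg_cost[cbind(rep(j, length(ends)), ends)] + g[b - 1, ends + 1]
      tol <- 1e-12 * max(1, abs(g[b, j]))
      e <- ends[which(vals <= g[b, j] + tol)[1]]
      groups[[n_beads - b + 1]] <- j:e
      j <- e + 1L
    }
  }
  spec <- mapping_spec(groups, weights = weights)
  attr(spec, "chi2") <- {
    tot <- 0
    for (g2 in spec$groups) if (length(g2) > 1)
      tot <- tot + seg_cost[min(g2), max(g2)]
    tot / (3 * n_beads)
  }
  spec
}

# seeded boundary annealing over contiguous partitions
anneal_partition <- function(seg_cost, n_beads, seed, n_sweeps) {
  n <- nrow(seg_cost)
  part_cost <- function(bounds) {  # bounds: segment end indices, length n_beads
    starts <- c(1L, head(bounds, -1) + 1L)
    sum(seg_cost[cbind(starts, bounds)])
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bounds <- sort(sample(1:(n - 1), n_beads - 1))
  bounds <- c(bounds, n)
  cur <- part_cost(bounds)
  best <- bounds; best_cost <- cur
  temp0 <- max(cur, 1e-8)
  for (s in seq_len(n_sweeps)) {
    temp <- temp0 * (1 - s / n_sweeps) + 1e-10
    k <- sample(n_beads - 1, 1)
    prop <- bounds
    prop[k] <- bounds[k] + sample(c(-1L, 1L), 1)
    lo <- if (k == 1) 1L else bounds[k - 1] + 1L
    if (prop[k] < lo || prop[k] >= bounds[k + 1]) next
    pc <- part_cost(prop)
    if (pc <= cur || runif(1) < exp((cur - pc) / temp)) {
      bounds <- prop; cur <- pc
      if (cur < best_cost) { best <- bounds; best_cost <- cur }
    }
  }
  starts <- c(1L, head(best, -1) + 1L)
  Map(function(a, b) a:b, starts, best)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Apply a mapping to a fine ensemble
#'
#' Bead positions are the (mass- or uniformly) weighted means of member
#' particles; bead charges and masses are the sums over members, so total
#' charge and mass are conserved exactly.
#'
#' @param ensemble fine-grained [cg_ensemble]
#' @param spec a [mapping_spec]
#' @param fine_charges,fine_masses per fine particle (e, u)
#' @return list: `ensemble` (mapped [cg_ensemble]), `charges`, `masses`
#' @export
apply_mapping <- function(ensemble, spec, fine_charges, fine_masses) {
  d <- dim(ensemble$coords)
  if (spec$n_particles != d[1]) stop("mapping does not cover the fine system")
  if (length(fine_charges) != d[1] || length(fine_masses) != d[1])
    stop("fine charge/mass vectors must match particle count")
  nb <- spec$n_beads
  W <- matrix(0, nb, d[1])
  for (b in seq_len(nb)) {
    g <- spec$groups[[b]]
    w <- if (spec$weights == "mass") fine_masses[g] else rep(1, length(g))
    W[b, g] <- w / sum(w)
  }
  out <- array(0, dim = c(nb, 3, d[3]))
  for (f in seq_len(d[3])) out[, , f] <- W %*% ensemble$coords[, , f]
  list(ensemble = cg_ensemble(out, weights = ensemble$weights),
       charges = as.numeric(vapply(spec$groups, function(g) sum(fine_charges[g]), 0)),
       masses = as.numeric(vapply(spec$groups, function(g) sum(fine_masses[g]), 0)))
}

#' Read / write a mapping file
#'
#' Two tab-separated columns `fine_index bead_id`, both 0-based.
#'
#' @param path file path
#' @param weights weight scheme for the returned spec
#' @return `read_mapping` returns a [mapping_spec]
#' @export
read_mapping <- function(path, weights = "mass") {
  tab <- read.table(path, header = TRUE, sep = "\t")
  if (!all(c("fine_index", "bead_id") %in% names(tab)))
    stop("mapping file must have columns fine_index, bead_id")
  o <- order(tab$fine_index)
  ids <- tab$bead_id[o]
  groups <- split(seq_along(ids), ids)
  mapping_spec(unname(groups), weights = weights)
}

#' @rdname read_mapping
#' @param spec a [mapping_spec]
#' @export
write_mapping <- function(spec, path) {
  rows <- do.call(rbind, lapply(seq_along(spec$groups), function(b)
    data.frame(fine_index = spec$groups[[b]] - 1L, bead_id = b - 1L)))
  rows <- rows[order(rows$fine_index), ]
  write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
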