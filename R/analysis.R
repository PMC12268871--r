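# Structural analysis: optimal superposition, RMSD, distance distributions.

# Kabsch rotation: proper rotation minimising RMSD of (moving -> target)
# after centring. Returns the rotated+translated moving coordinates.
superpose <- function(moving, target) {
  cm <- colMeans(moving); ct <- colMeans(target)
  A <- sweep(moving, 2, cm); B <- sweep(target, 2, ct)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  sweep(A %*% t(R), 2, ct, "+")
}

#' Per-frame RMSD to a reference structure
#'
#' Least-squares superposition (optimal translation and proper rotation,
#' Kabsch algorithm) of each frame onto the reference, then the
#' root-mean-square deviation over beads.
#'
#' @param ensemble a [cg_ensemble]
#' @param reference `n x 3` reference coordinates (nm)
#' @return numeric vector of per-frame RMSD values, nm
#' @export
rmsd_traj <- function(ensemble, reference) {
  reference <- as.matrix(reference)
  d <- dim(ensemble$coords)
  if (d[1] != nrow(reference))
    stop("bead count mismatch between ensemble and reference")
  vapply(seq_len(d[3]), function(f) {
    fit <- superpose(ensemble$coords[, , f], reference)
    sqrt(mean(rowSums((fit - reference)^2)))
  }, 0)
}

#' Radial distribution estimate for a type pair
#'
#' Normalised histogram of inter-monomer pair distances for the given bead
#' type pair: a probability density p(R) over half-open bins [lo, hi) with
#' `sum(p * bin_width) = 1`. The recorded `p_max` and bin centres feed the
#' repulsion-radius rule ([determine_R_rep]).
#'
#' @param ensemble a [cg_ensemble]
#' @param topology a [cg_topology]
#' @param type_pair character vector of two type labels
#' @param bin_width histogram bin width, nm (default 0.02)
#' @param r_max histogram upper edge, nm (default 4)
#' @param intra_monomer include intra-monomer pairs too (default FALSE)
#' @return object of class `cg_rdf`: `r` (bin centres), `p` (density),
#'   `p_max`, `bin_width`
#' @export
compute_rdf <- function(ensemble, topology, type_pair, bin_width = 0.02,
                        r_max = 4, intra_monomer = FALSE) {
  stopifnot(length(type_pair) == 2)
  b <- topology$beads[order(topology$beads$bead_id), ]
  ii <- which(b$type == type_pair[1])
  jj <- which(b$type == type_pair[2])
  if (!length(ii) || !length(jj))
    stop("type not present in topology: ",
         paste(setdiff(type_pair, b$type), collapse = ", "))
  pairs <- expand.grid(i = ii, j = jj)
  if (type_pair[1] == type_pair[2]) pairs <- pairs[pairs$i < pairs$j, ]
  if (!intra_monomer)
    pairs <- pairs[b$monomer_id[pairs$i] != b$monomer_id[pairs$j], ]
  if (!nrow(pairs)) stop("no pairs for type pair ",
                         paste(type_pair, collapse = ":"))
  co <- ensemble$coords
  F <- dim(co)[3]
  dists <- numeric(nrow(pairs) * F)
  for (f in seq_len(F)) {
    m <- co[, , f]
    dvec <- sqrt(rowSums((m[pairs$i, , drop = FALSE] -
                          m[pairs$j, , drop = FALSE])^2))
    dists[((f - 1) * nrow(pairs) + 1):(f * nrow(pairs))] <- dvec
  }
  breaks <- seq(0, r_max, by = bin_width)
  if (max(dists) >= r_max)
    breaks <- seq(0, max(dists) + bin_width, by = bin_width)
  # half-open [lo, hi) binning
  idx <- pmin(floor(dists / bin_width) + 1L, length(breaks) - 1L)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  p <- counts / (sum(counts) * bin_width)
  structure(list(r = breaks[-length(breaks)] + bin_width / 2, p = p,
                 p_max = max(p), bin_width = bin_width,
                 type_pair = type_pair),
            class = "cg_rdf")
}

#' @export
print.cg_rdf <- function(x, ...) {
  cat("RDF", paste(x$type_pair, collapse = ":"), "-", length(x$r), "bins,",
      sprintf("p_max = %.3f at r = %.3f nm\n", x$p_max, x$r[which.max(x$p)]))
  invisible(x)
}

#' @export
plot.cg_rdf <- function(x, ...) {
  plot(x$r, x$p, type = "h", xlab = "R (nm)", ylab = "p(R) (1/nm)",
       main = paste("distance distribution", paste(x$type_pair, collapse = ":")),
       ...)
  invisible(x)
}
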