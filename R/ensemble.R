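#' Coordinate ensemble
#'
#' An ordered set of frames of bead (or fine-particle) coordinates in nm,
#' stored as an `n x 3 x n_frames` array. Optional per-frame weights turn
#' ensemble averages into weighted averages (used e.g. for quadrature-grid
#' ensembles in the gradient oracles); optional box is pass-through metadata.
#'
#' @param coords `n x 3 x F` array, or `n x 3` matrix (single frame), or a
#'   list of `n x 3` matrices
#' @param weights optional non-negative per-frame weights (normalised to sum 1)
#' @param box optional box metadata (not used by the open-boundary engine)
#' @return object of class `cg_ensemble`
#' @export
cg_ensemble <- function(coords, weights = NULL, box = NULL) {
  if (is.list(coords)) {
    if (!length(coords)) stop("ensemble must contain at least one frame")
    coords <- array(unlist(coords),
                    dim = c(nrow(coords[[1]]), 3, length(coords)))
  }
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1))
  d <- dim(coords)
  if (length(d) != 3 || d[2] != 3)
    stop("coords must be an n x 3 x n_frames array")
  if (d[3] < 1) stop("ensemble must contain at least one frame")
  if (!is.null(weights)) {
    if (length(weights) != d[3]) stop("weights length must equal frame count")
    if (any(weights < 0) || sum(weights) <= 0) stop("weights must be >= 0, sum > 0")
    weights <- weights / sum(weights)
  }
  structure(list(coords = coords, weights = weights, box = box),
            class = "cg_ensemble")
}

#' @rdname cg_ensemble
#' @param x a `cg_ensemble`
#' @export
n_frames <- function(x) dim(x$coords)[3]

#' @rdname cg_ensemble
#' @param i frame index
#' @export
get_frame <- function(x, i) {
  m <- x$coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' @export
print.cg_ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat("CG ensemble:", d[3], "frames x", d[1], "particles",
      if (!is.null(x$weights)) "(weighted)" else "", "\n")
  invisible(x)
}

# weighted (or plain) frame average of a per-frame vector/matrix
frame_mean <- function(values, weights = NULL) {
  if (is.null(weights)) {
    if (is.matrix(values)) rowMeans(values) else mean(values)
  } else {
    if (is.matrix(values)) as.numeric(values %*% weights) else sum(values * weights)
  }
}

#' Read a trajectory file
#'
#' Multi-frame XYZ (canonical dialect: coordinates in nm, comment line free
#' text) or PDB (single- or multi-MODEL; PDB coordinates are in Angstrom and
#' are divided by 10). PDB files are parsed with the bio3d package.
#'
#' @param path file path
#' @param format `"xyz"` or `"pdb"`; default guesses from the extension
#' @return a [cg_ensemble]
#' @export
read_trajectory <- function(path, format = c("auto", "xyz", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    xyz <- pdb$xyz             # frames x 3n, Angstrom
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    n <- ncol(xyz) / 3
    F <- nrow(xyz)
    coords <- array(0, dim = c(n, 3, F))
    for (f in seq_len(F))
      coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10
    return(cg_ensemble(coords))
  }
  read_xyz(path)
}

#' Read / write multi-frame XYZ (coordinates in nm)
#'
#' @param path file path
#' @return `read_xyz` returns a [cg_ensemble] with an `labels` attribute
#'   carrying the per-particle symbols
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no frames in trajectory file: ", path)
  frames <- list()
  labels <- NULL
  pos <- 1L
  fidx <- 0L
  while (pos <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    fidx <- fidx + 1L
    if (is.na(n) || n < 1)
      stop("parse error at frame ", fidx, ": bad particle count line")
    if (pos + 1L + n > length(lines))
      stop("parse error at frame ", fidx, ": truncated frame")
    block <- lines[(pos + 2L):(pos + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    if (any(lengths(parts) < 4))
      stop("parse error at frame ", fidx, ": ragged coordinate line")
    m <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                ncol = 3, byrow = TRUE)
    if (anyNA(m)) stop("parse error at frame ", fidx, ": non-numeric coordinate")
    if (is.null(labels)) labels <- vapply(parts, `[`, "", 1)
    if (nrow(m) != length(labels))
      stop("parse error at frame ", fidx, ": particle count changed")
    frames[[fidx]] <- m
    pos <- pos + 2L + n
  }
  ens <- cg_ensemble(frames)
  attr(ens, "labels") <- labels
  ens
}

#' @rdname read_xyz
#' @param ensemble a [cg_ensemble]
#' @param labels per-particle symbols (default "C")
#' @param comments per-frame comment lines (default `step=<i>`)
#' @export
write_xyz <- function(ensemble, path, labels = NULL, comments = NULL) {
  d <- dim(ensemble$coords)
  n <- d[1]; F <- d[3]
  if (is.null(labels)) labels <- attr(ensemble, "labels")
  if (is.null(labels)) labels <- rep("C", n)
  if (is.null(comments)) comments <- sprintf("step=%d", seq_len(F) - 1L)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(F)) {
    writeLines(c(as.character(n), comments[f]), con)
    m <- ensemble$coords[, , f]
    writeLines(sprintf("%s %.8f %.8f %.8f", labels, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}
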