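#' Coarse-grained topology
#'
#' A CG topology holds the bead table (bead id, monomer membership, bead
#' type, charge, mass) and the intramonomer harmonic springs of the
#' heteroelastic network. Bead charges are sums of the fine-grained charges
#' mapped into each bead; springs never cross monomer boundaries (the bonded
#' term describes intramonomer interactions only).
#'
#' @param beads data.frame with columns `bead_id` (integer, 0-based,
#'   contiguous), `monomer_id` (integer), `type` (character label),
#'   `charge` (e), `mass` (u)
#' @param springs data.frame with columns `bead_i`, `bead_j` (0-based bead
#'   ids), `k` (kJ mol^-1 nm^-2), `r0` (nm); may have zero rows
#' @return object of class `cg_topology`
#' @export
cg_topology <- function(beads, springs = NULL) {
  beads <- as.data.frame(beads)
  need <- c("bead_id", "monomer_id", "type", "charge", "mass")
  if (!all(need %in% names(beads)))
    stop("beads table must have columns: ", paste(need, collapse = ", "))
  if (is.null(springs) || nrow(as.data.frame(springs)) == 0) {
    springs <- data.frame(bead_i = integer(), bead_j = integer(),
                          k = numeric(), r0 = numeric())
  }
  springs <- as.data.frame(springs)
  sneed <- c("bead_i", "bead_j", "k", "r0")
  if (!all(sneed %in% names(springs)))
    stop("springs table must have columns: ", paste(sneed, collapse = ", "))
  beads$bead_id <- as.integer(beads$bead_id)
  beads$monomer_id <- as.integer(beads$monomer_id)
  beads$type <- as.character(beads$type)
  topo <- structure(list(beads = beads, springs = springs),
                    class = "cg_topology")
  validate_topology(topo)
  topo
}

#' @rdname cg_topology
#' @param x a `cg_topology`
#' @export
validate_topology <- function(x) {
  b <- x$beads; s <- x$springs
  n <- nrow(b)
  if (n < 1) stop("topology has no beads")
  if (anyDuplicated(b$bead_id) || !identical(sort(b$bead_id), 0:(n - 1L)))
    stop("bead_ids must be unique and contiguous from 0")
  if (any(b$mass <= 0)) stop("all bead masses must be > 0")
  if (nrow(s)) {
    if (any(s$k <= 0)) stop("all spring constants must be > 0")
    if (any(s$bead_i < 0 | s$bead_i >= n | s$bead_j < 0 | s$bead_j >= n))
      stop("spring bead index out of range")
    mono <- b$monomer_id[order(b$bead_id)]
    if (any(mono[s$bead_i + 1L] != mono[s$bead_j + 1L]))
      stop("springs must connect beads of the same monomer")
    if (any(s$bead_i == s$bead_j)) stop("spring connects a bead to itself")
  }
  invisible(x)
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("CG topology:", nrow(x$beads), "beads,",
      length(unique(x$beads$monomer_id)), "monomer(s),",
      nrow(x$springs), "springs\n")
  cat("  types:", paste(unique(x$beads$type), collapse = " "), "\n")
  cat(sprintf("  total charge %+.3f e, total mass %.1f u\n",
              sum(x$beads$charge), sum(x$beads$mass)))
  invisible(x)
}

n_beads <- function(topology) nrow(topology$beads)

#' Read / write a CG topology file
#'
#' Plain-text tab-separated format with a `#BEADS` section
#' (`bead_id monomer_id type charge_e mass_u`) and a `#SPRINGS` section
#' (`bead_i bead_j k_kJ_nm2 r0_nm`). Bead indices are 0-based.
#'
#' @param path file path
#' @return `read_topology` returns a [cg_topology]
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  lines <- readLines(path)
  ib <- grep("^#BEADS", lines)
  is_ <- grep("^#SPRINGS", lines)
  if (length(ib) != 1) stop("topology file must contain one #BEADS section")
  send <- if (length(is_)) is_ - 1L else length(lines)
  bead_lines <- lines[(ib + 1L):send]
  bead_lines <- bead_lines[nzchar(trimws(bead_lines))]
  beads <- read.table(text = bead_lines, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  names(beads) <- sub("^charge_e$", "charge", names(beads))
  names(beads) <- sub("^mass_u$", "mass", names(beads))
  springs <- NULL
  if (length(is_) && is_ < length(lines)) {
    spring_lines <- lines[(is_ + 1L):length(lines)]
    spring_lines <- spring_lines[nzchar(trimws(spring_lines))]
    if (length(spring_lines) > 1) {
      springs <- read.table(text = spring_lines, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
      names(springs) <- sub("^k_kJ_nm2$", "k", names(springs))
      names(springs) <- sub("^r0_nm$", "r0", names(springs))
    }
  }
  cg_topology(beads, springs)
}

#' @rdname read_topology
#' @param topology a [cg_topology]
#' @export
write_topology <- function(topology, path) {
  validate_topology(topology)
  b <- topology$beads[, c("bead_id", "monomer_id", "type", "charge", "mass")]
  names(b) <- c("bead_id", "monomer_id", "type", "charge_e", "mass_u")
  s <- topology$springs
  names(s) <- c("bead_i", "bead_j", "k_kJ_nm2", "r0_nm")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#BEADS", con)
  write.table(b, con, sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines("#SPRINGS", con)
  write.table(s, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
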