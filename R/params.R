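#' Nonbonded parameter set
#'
#' Per type-pair constants of the CG nonbonded potential: screened
#' electrostatics (global dielectric `eps_r` and inverse Debye length
#' `kappa_D`), soft cosine repulsion of height `A` inside radius `R_rep`
#' plus an always-repulsive `B/R^4` core, and a Gaussian attraction well of
#' signed amplitude `C` (kJ mol^-1 nm; the well depth is `C/(sigma*sqrt(2*pi))`,
#' attraction means `C < 0`) centred at `R_att` with global width `sigma`.
#' The `C` entries flagged `trainable` form the parameter vector theta learned
#' by the REM trainer; `b_term` switches the `B/R^4` core per pair.
#'
#' The pair table is stored for unordered type pairs and is symmetric by
#' construction: `(I,J)` and `(J,I)` refer to the same row.
#'
#' @param pairs data.frame with columns `type_i`, `type_j`, `A` (kJ/mol),
#'   `R_rep` (nm), `C` (kJ mol^-1 nm), `R_att` (nm), and optionally
#'   `trainable` (logical, default FALSE) and `b_term` (logical, default TRUE)
#' @param sigma Gaussian well width, nm (default 0.2)
#' @param B repulsive core constant, kJ mol^-1 nm^4 (default 6 kcal/mol A^4
#'   = 0.0025104 kJ mol^-1 nm^4)
#' @param eps_r relative dielectric constant (default 17.5)
#' @param kappa_D inverse Debye screening length, nm^-1 (default 1.274)
#' @param cutoff nonbonded cutoff, nm (default 2.5); energies and forces are
#'   truncated sharply at the cutoff and not shifted
#' @return object of class `cg_params`
#' @export
cg_params <- function(pairs, sigma = 0.2, B = 6 * kcal * 1e-4,
                      eps_r = 17.5, kappa_D = 1.274, cutoff = 2.5) {
  pairs <- as.data.frame(pairs)
  need <- c("type_i", "type_j", "A", "R_rep", "C", "R_att")
  if (!all(need %in% names(pairs)))
    stop("pairs table must have columns: ", paste(need, collapse = ", "))
  if (is.null(pairs$trainable)) pairs$trainable <- FALSE
  if (is.null(pairs$b_term)) pairs$b_term <- TRUE
  pairs$type_i <- as.character(pairs$type_i)
  pairs$type_j <- as.character(pairs$type_j)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  if (anyDuplicated(key(pairs$type_i, pairs$type_j)))
    stop("duplicate type pair in parameter table")
  p <- structure(list(pairs = pairs, sigma = sigma, B = B, eps_r = eps_r,
                      kappa_D = kappa_D, cutoff = cutoff),
                 class = "cg_params")
  validate_params(p)
  p
}

#' @rdname cg_params
#' @param x a `cg_params`
#' @export
validate_params <- function(x) {
  if (x$sigma <= 0) stop("sigma must be > 0")
  if (x$cutoff <= 0) stop("cutoff must be > 0")
  if (x$eps_r <= 0) stop("eps_r must be > 0")
  if (any(x$pairs$R_rep <= 0)) stop("all R_rep must be > 0")
  if (any(x$pairs$A < 0)) stop("A must be >= 0")
  invisible(x)
}

#' @export
print.cg_params <- function(x, ...) {
  cat("CG nonbonded parameters:", nrow(x$pairs), "type pairs,",
      sum(x$pairs$trainable), "trainable C entries\n")
  cat(sprintf("  globals: sigma=%.3g nm, B=%.4g kJ/mol nm^4, eps_r=%.3g, kappa_D=%.4g nm^-1, cutoff=%.3g nm\n",
              x$sigma, x$B, x$eps_r, x$kappa_D, x$cutoff))
  invisible(x)
}

#' Get / set the trainable parameter vector theta
#'
#' theta is the vector of `C` amplitudes flagged trainable, in the row order
#' of the pair table.
#'
#' @param params a [cg_params]
#' @return `get_theta`: named numeric vector (names `type_i:type_j`)
#' @export
get_theta <- function(params) {
  tr <- params$pairs$trainable
  setNames(params$pairs$C[tr],
           paste(params$pairs$type_i[tr], params$pairs$type_j[tr], sep = ":"))
}

#' @rdname get_theta
#' @param theta numeric vector, length = number of trainable entries
#' @export
set_theta <- function(params, theta) {
  tr <- params$pairs$trainable
  if (length(theta) != sum(tr))
    stop("theta length ", length(theta), " != ", sum(tr), " trainable entries")
  params$pairs$C[tr] <- as.numeric(theta)
  params
}

# Flattened system list consumed by the compiled core: per-bead type indices,
# ntype x ntype parameter matrices, spring arrays. theta slots are assigned in
# trainable-row order, matching get_theta()/set_theta().
build_system <- function(topology, params) {
  validate_topology(topology)
  validate_params(params)
  b <- topology$beads[order(topology$beads$bead_id), ]
  types <- sort(unique(b$type))
  ptypes <- unique(c(params$pairs$type_i, params$pairs$type_j))
  missing_t <- setdiff(types, ptypes)
  tidx <- match(b$type, types) - 1L
  nt <- length(types)
  A <- matrix(0, nt, nt); Rr <- matrix(1, nt, nt)
  C <- matrix(0, nt, nt); Ra <- matrix(1, nt, nt)
  bu <- matrix(0L, nt, nt); th <- matrix(-1L, nt, nt)
  seen <- matrix(FALSE, nt, nt)
  slot <- -1L
  for (r in seq_len(nrow(params$pairs))) {
    row <- params$pairs[r, ]
    if (row$trainable) slot <- slot + 1L
    i <- match(row$type_i, types); j <- match(row$type_j, types)
    if (is.na(i) || is.na(j)) next  # pair involves a type absent from topology
    A[i, j] <- A[j, i] <- row$A
    Rr[i, j] <- Rr[j, i] <- row$R_rep
    C[i, j] <- C[j, i] <- row$C
    Ra[i, j] <- Ra[j, i] <- row$R_att
    bu[i, j] <- bu[j, i] <- as.integer(row$b_term)
    if (row$trainable) th[i, j] <- th[j, i] <- slot
    seen[i, j] <- seen[j, i] <- TRUE
  }
  if (length(missing_t))
    stop("topology types without parameters: ", paste(missing_t, collapse = ", "))
  # every inter-monomer type pair that can occur must be parameterised
  mono <- b$monomer_id
  for (i in seq_len(nt)) for (j in i:nt) {
    ti <- which(tidx + 1L == i); tj <- which(tidx + 1L == j)
    cross <- any(outer(mono[ti], mono[tj], "!="))
    if (cross && !seen[i, j])
      stop("no parameters for inter-monomer type pair ",
           types[i], ":", types[j])
  }
  list(mono = as.integer(b$monomer_id), tidx = tidx, charge = b$charge,
       A = A, R_rep = Rr, C = C, R_att = Ra, b_use = bu, theta_idx = th,
       sigma = params$sigma, B = params$B, eps_r = params$eps_r,
       kappa_D = params$kappa_D, cutoff = params$cutoff,
       spring_i = as.integer(topology$springs$bead_i),
       spring_j = as.integer(topology$springs$bead_j),
       spring_k = topology$springs$k, spring_r0 = topology$springs$r0,
       mass = b$mass, n_theta = sum(params$pairs$trainable))
}

#' Read / write a nonbonded parameter file
#'
#' Tab-separated type-pair table (`type_i type_j A_kJ R_rep_nm C_kJ_nm
#' R_att_nm trainable b_term`) preceded by `#GLOBAL key value` header lines
#' for `sigma_nm`, `B_kJ_nm4`, `eps_r`, `kappa_D_nm`, `cutoff_nm`. An `A_kcal`
#' column or a `B_kcal_A4` global is accepted and converted at 4.184 (the
#' conversion is reported via `message()`).
#'
#' @param path file path
#' @return `read_params` returns a [cg_params]
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path)
  gl <- grep("^#GLOBAL\\s", lines, value = TRUE)
  gparse <- strsplit(trimws(sub("^#GLOBAL\\s+", "", gl)), "\\s+")
  globals <- setNames(vapply(gparse, function(z) as.numeric(z[2]), 0),
                      vapply(gparse, `[`, "", 1))
  gneed <- c("sigma_nm", "eps_r", "kappa_D_nm", "cutoff_nm")
  for (g in gneed) if (!g %in% names(globals))
    stop("missing global in parameter file: ", sub("_nm$", "", g))
  if ("B_kcal_A4" %in% names(globals)) {
    B <- globals[["B_kcal_A4"]] * kcal * 1e-4
    message("converted B from kcal/mol A^4 to kJ/mol nm^4 (x 4.184e-4)")
  } else if ("B_kJ_nm4" %in% names(globals)) {
    B <- globals[["B_kJ_nm4"]]
  } else stop("missing global in parameter file: B")
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  tab <- read.table(text = body, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if ("A_kcal" %in% names(tab)) {
    tab$A <- tab$A_kcal * kcal
    tab$A_kcal <- NULL
    message("converted A from kcal/mol to kJ/mol (x 4.184)")
  }
  names(tab) <- sub("^A_kJ$", "A", names(tab))
  names(tab) <- sub("^R_rep_nm$", "R_rep", names(tab))
  names(tab) <- sub("^C_kJ_nm$", "C", names(tab))
  names(tab) <- sub("^R_att_nm$", "R_att", names(tab))
  known <- c("type_i", "type_j", "A", "R_rep", "C", "R_att", "trainable", "b_term")
  bad <- setdiff(names(tab), known)
  if (length(bad)) stop("unknown column in parameter file: ", paste(bad, collapse = ", "))
  cg_params(tab, sigma = globals[["sigma_nm"]], B = B,
            eps_r = globals[["eps_r"]], kappa_D = globals[["kappa_D_nm"]],
            cutoff = globals[["cutoff_nm"]])
}

#' @rdname read_params
#' @param params a [cg_params]
#' @export
write_params <- function(params, path) {
  validate_params(params)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# regcg nonbonded parameters",
               sprintf("#GLOBAL sigma_nm %.10g", params$sigma),
               sprintf("#GLOBAL B_kJ_nm4 %.10g", params$B),
               sprintf("#GLOBAL eps_r %.10g", params$eps_r),
               sprintf("#GLOBAL kappa_D_nm %.10g", params$kappa_D),
               sprintf("#GLOBAL cutoff_nm %.10g", params$cutoff)), con)
  tab <- params$pairs[, c("type_i", "type_j", "A", "R_rep", "C", "R_att",
                          "trainable", "b_term")]
  names(tab) <- c("type_i", "type_j", "A_kJ", "R_rep_nm", "C_kJ_nm",
                  "R_att_nm", "trainable", "b_term")
  write.table(format(tab, digits = 10, trim = TRUE, scientific = FALSE),
              con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
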