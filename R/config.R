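# Run configuration (YAML) and reproducibility manifests.

config_schema <- list(
  paths = c("topology", "params", "reference", "output_dir"),
  sim = c("dt_fs", "temperature", "friction", "n_steps", "stride", "seed",
          "wall_radius"),
  train = c("kappa_reg", "kappa_reg_kcal2", "V0", "gamma", "n_iterations",
            "steps_per_iter", "stride", "seed", "bind_pair", "max_step",
            "v_tol", "v_window"),
  logging = c("verbosity")
)

#' Read a training/simulation run configuration
#'
#' YAML with sections `paths`, `sim`, `train`, `logging`; unknown sections
#' or keys are rejected by name. `train.kappa_reg_kcal2` (a regularization
#' strength quoted in (kcal/mol)^-2) is converted to (kJ/mol)^-2 by
#' 1/4.184^2 and reported. Referenced input files must exist.
#'
#' @param path YAML file path
#' @param check_paths verify that referenced files exist (default TRUE)
#' @return list with elements `paths`, `sim` ([sim_settings]), `train`
#'   ([reg_config]), `logging`
#' @export
read_config <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  bad_sec <- setdiff(names(cfg), names(config_schema))
  if (length(bad_sec)) stop("unknown config section: ",
                            paste(bad_sec, collapse = ", "))
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
    if (length(bad)) stop("unknown key in section '", sec, "': ",
                          paste(bad, collapse = ", "))
  }
  paths <- cfg$paths
  if (check_paths && !is.null(paths)) {
    for (k in c("topology", "params", "reference")) {
      if (!is.null(paths[[k]]) && !file.exists(paths[[k]]))
        stop("configured ", k, " file does not exist: ", paths[[k]])
    }
  }
  sim <- NULL
  if (!is.null(cfg$sim)) sim <- do.call(sim_settings, cfg$sim)
  train <- NULL
  if (!is.null(cfg$train)) {
    tr <- cfg$train
    if (!is.null(tr[["kappa_reg_kcal2"]])) {
      if (!is.null(tr[["kappa_reg"]]))
        stop("give kappa_reg or kappa_reg_kcal2, not both")
      kcal2 <- tr[["kappa_reg_kcal2"]]
      tr[["kappa_reg"]] <- kcal2 / kcal^2
      message(sprintf("converted kappa_reg from (kcal/mol)^-2: %.6g -> %.6g (kJ/mol)^-2",
                      kcal2, tr[["kappa_reg"]]))
      tr[["kappa_reg_kcal2"]] <- NULL
    }
    train <- do.call(reg_config, tr)
  }
  list(paths = paths, sim = sim, train = train,
       logging = if (is.null(cfg$logging)) list(verbosity = 1) else cfg$logging)
}

#' Write a reproducibility manifest
#'
#' Records the seed, package version, R version and an MD5 of the config
#' file — enough to reproduce a run bit-for-bit.
#'
#' @param path output path
#' @param seed integer seed of the run
#' @param config_path optional config file to fingerprint
#' @param extra optional named list of extra fields
#' @export
write_manifest <- function(path, seed, config_path = NULL, extra = NULL) {
  lines <- c(paste0("package\tregcg ", as.character(utils::packageVersion("regcg"))),
             paste0("r_version\t", R.version.string),
             paste0("seed\t", seed))
  if (!is.null(config_path) && file.exists(config_path))
    lines <- c(lines, paste0("config_md5\t",
                             unname(tools::md5sum(config_path))))
  for (k in names(extra)) lines <- c(lines, paste0(k, "\t", extra[[k]]))
  writeLines(lines, path)
  invisible(path)
}
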