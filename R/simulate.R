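#' Langevin dynamics settings
#'
#' @param dt_fs time step in fs (default 15, the standard CG step here)
#' @param temperature K (default 310)
#' @param friction Langevin friction, ps^-1 (default 1)
#' @param n_steps number of integration steps
#' @param stride record a frame every `stride` steps
#' @param seed integer RNG seed (the engine is bit-reproducible given the seed)
#' @param wall_radius optional spherical reflecting wall about the origin, nm
#'   (0 disables); keeps dissociated monomers within sampling range so
#'   rebinding stays observable in open-boundary runs
#' @return object of class `sim_settings`
#' @export
sim_settings <- function(dt_fs = 15, temperature = 310, friction = 1,
                         n_steps = 10000L, stride = 50L, seed = 1L,
                         wall_radius = 0) {
  stopifnot(dt_fs > 0, temperature >= 0, n_steps >= 1, stride >= 1,
            friction >= 0, wall_radius >= 0)
  structure(list(dt_fs = dt_fs, temperature = temperature,
                 friction = friction, n_steps = as.integer(n_steps),
                 stride = as.integer(stride), seed = as.integer(seed),
                 wall_radius = wall_radius),
            class = "sim_settings")
}

#' Run Langevin dynamics on a CG model
#'
#' BAOAB-splitting Langevin integrator. With zero friction (and/or zero
#' temperature) the stochastic step degenerates and the scheme reduces to
#' velocity Verlet, which is used by the energy-conservation checks.
#' Per-frame potential energy, kinetic energy and the inter-monomer binding
#' energy `V_bind` are recorded alongside the coordinates; the `V_bind`
#' record is what the reg-REM estimators consume.
#'
#' @param topology a [cg_topology]
#' @param params a [cg_params]
#' @param coords `n x 3` start coordinates (nm)
#' @param settings a [sim_settings]
#' @param bind_pair `NULL` or two monomer ids restricting `V_bind`
#' @param init_vel draw Maxwell-Boltzmann start velocities (default TRUE;
#'   FALSE starts at rest)
#' @return list of class `cg_run`: `ensemble` ([cg_ensemble]), per-frame
#'   `V_bind`, `U_total`, `E_kin`, `E_total`, `T_kin` (K), and `x_final`
#' @export
simulate_cg <- function(topology, params, coords, settings,
                        bind_pair = NULL, init_vel = TRUE) {
  sys <- build_system(topology, params)
  coords <- as.matrix(coords)
  if (nrow(coords) != length(sys$mono))
    stop("start coordinates do not match topology bead count")
  e0 <- cpp_energy(coords, sys, -1L, -1L)
  if (!is.finite(e0[["U_total"]])) stop("non-finite starting energy")
  vp <- bind_pair_int(bind_pair)
  dt_ps <- settings$dt_fs * 1e-3
  res <- cpp_run_langevin(coords, sys, sys$mass, dt_ps,
                          settings$temperature, settings$friction,
                          settings$n_steps, settings$stride, settings$seed,
                          settings$wall_radius, vp[1], vp[2], init_vel)
  if (res$status > 0)
    stop("simulation diverged (non-finite energy/forces) near recorded frame ",
         res$status)
  n <- nrow(coords)
  structure(list(ensemble = cg_ensemble(res$frames),
                 V_bind = res$V_bind, U_total = res$U_total,
                 E_kin = res$E_kin, E_total = res$E_total,
                 T_kin = 2 * res$E_kin / (3 * n * kB_kJ),
                 x_final = res$x_final, settings = settings),
            class = "cg_run")
}

#' @export
print.cg_run <- function(x, ...) {
  cat("CG run:", n_frames(x$ensemble), "recorded frames\n")
  cat(sprintf("  <U_total> = %.3f kJ/mol, <V_bind> = %.3f kJ/mol, <T_kin> = %.1f K\n",
              mean(x$U_total), mean(x$V_bind), mean(x$T_kin)))
  invisible(x)
}

#' Write a run's trajectory and energy table
#'
#' Writes the multi-frame XYZ trajectory plus a tab-separated per-frame
#' energy table (`frame U_total V_bind T_kin`).
#'
#' @param run a `cg_run` from [simulate_cg]
#' @param xyz_path,energy_path output paths
#' @export
write_run <- function(run, xyz_path, energy_path) {
  write_xyz(run$ensemble, xyz_path)
  tab <- data.frame(frame = seq_along(run$U_total) - 1L,
                    U_total = run$U_total, V_bind = run$V_bind,
                    T_kin = run$T_kin)
  write.table(tab, energy_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(xyz_path)
}
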