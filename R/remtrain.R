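# Relative entropy minimization (REM) trainer and its regularized variant
# (reg-REM). theta is the vector of trainable Gaussian attraction amplitudes
# C_IJ; all gradients are with respect to theta.

#' Training configuration for (reg-)REM
#'
#' @param kappa_reg regularization strength, (kJ/mol)^-2; 0 reduces exactly
#'   to standard REM
#' @param V0 target mean binding energy, kJ/mol
#' @param gamma learning rate, kJ^2 mol^-2 nm^2 (theta has units
#'   kJ mol^-1 nm, the loss gradient (kJ mol^-1 nm)^-1)
#' @param n_iterations number of training iterations
#' @param steps_per_iter CG integration steps per iteration
#' @param stride recording stride within each iteration's run
#' @param seed base seed; each iteration derives its own sub-seed
#' @param bind_pair `NULL` (all inter-monomer interactions) or two monomer
#'   ids designating the pair whose interaction defines `V_bind` and the
#'   regularization (multimer mode: updated theta is shared by all monomers)
#' @param max_step per-iteration cap on max |delta theta|, kJ mol^-1 nm
#' @param v_tol,v_window optional early stop: stop when |mean V_bind - V0| <
#'   `v_tol` over a window of `v_window` iterations (`v_tol = NULL` disables)
#' @return object of class `reg_config`
#' @export
reg_config <- function(kappa_reg = 0.1 / kcal, V0 = -25, gamma = 1.5,
                       n_iterations = 150L, steps_per_iter = 50000L,
                       stride = 50L, seed = 1L, bind_pair = NULL,
                       max_step = 1, v_tol = NULL, v_window = 20L) {
  stopifnot(kappa_reg >= 0, n_iterations >= 1, gamma > 0, max_step > 0)
  structure(list(kappa_reg = kappa_reg, V0 = V0, gamma = gamma,
                 n_iterations = as.integer(n_iterations),
                 steps_per_iter = as.integer(steps_per_iter),
                 stride = as.integer(stride), seed = as.integer(seed),
                 bind_pair = bind_pair, max_step = max_step,
                 v_tol = v_tol, v_window = as.integer(v_window)),
            class = "reg_config")
}

# ensemble-averaged dU/dtheta (full-system gradient), weighted if the
# ensemble carries frame weights
mean_grad_full <- function(ensemble, topology, params, bind_pair = NULL,
                           sys = NULL) {
  st <- ensemble_stats(ensemble, topology, params, bind_pair, sys = sys)
  frame_mean(st$g_full, ensemble$weights)
}

#' Kullback-Leibler divergence gradient (standard REM)
#'
#' `grad = beta * (<dU/dtheta>_ref - <dU/dtheta>_CG)`: the difference of the
#' ensemble-averaged parameter gradients of the CG energy over the mapped
#' reference ensemble and the CG-model ensemble, scaled by `beta = 1/(kB T)`.
#'
#' @param aa_ensemble mapped reference [cg_ensemble]
#' @param cg_ensemble CG-model [cg_ensemble]
#' @param topology a [cg_topology]
#' @param params a [cg_params] with trainable entries flagged
#' @param temperature K
#' @return gradient vector over theta, (kJ/mol)^-1 nm^-1 scale
#' @export
kl_gradient <- function(aa_ensemble, cg_ensemble, topology, params,
                        temperature = 310) {
  if (n_frames(aa_ensemble) < 1 || n_frames(cg_ensemble) < 1)
    stop("both ensembles must be nonempty")
  beta <- beta_kJ(temperature)
  g_aa <- mean_grad_full(aa_ensemble, topology, params)
  g_cg <- mean_grad_full(cg_ensemble, topology, params)
  beta * (g_aa - g_cg)
}

#' Gradient of the mean binding energy (covariance estimator)
#'
#' Fluctuation formula for `d<V_bind>/dtheta` over the CG ensemble:
#' `<dV_bind/dtheta> - beta <V_bind * dU/dtheta> + beta <dU/dtheta> <V_bind>`.
#' The last two terms form a covariance, so the estimator only needs the
#' per-frame binding energy and parameter gradients recorded during
#' sampling. In a zero-fluctuation ensemble the covariance part cancels and
#' the estimator reduces to `<dV_bind/dtheta>` exactly.
#'
#' @param cg_ensemble CG-model [cg_ensemble]
#' @param topology,params,temperature as in [kl_gradient]
#' @param bind_pair `NULL` or two monomer ids restricting `V_bind` (and its
#'   own gradient) to a designated pair
#' @param stats optional precomputed [ensemble_stats] result
#' @return gradient vector over theta (dimensionless, nm^-1 scale)
#' @export
grad_mean_vbind <- function(cg_ensemble, topology, params, temperature = 310,
                            bind_pair = NULL, stats = NULL) {
  if (is.null(stats))
    stats <- ensemble_stats(cg_ensemble, topology, params, bind_pair)
  if (is.null(stats$V_bind) || is.null(stats$g_full))
    stop("per-frame V_bind and dU/dtheta records are required")
  beta <- beta_kJ(temperature)
  w <- cg_ensemble$weights
  vb <- stats$V_bind
  g_bind_mean <- frame_mean(stats$g_bind, w)
  g_full_mean <- frame_mean(stats$g_full, w)
  vb_mean <- frame_mean(vb, w)
  cross <- frame_mean(sweep(stats$g_full, 2, vb, "*"), w)
  g_bind_mean - beta * cross + beta * g_full_mean * vb_mean
}

#' Regularized REM gradient
#'
#' `grad = kl_gradient - 2 kappa (V0 - Vbar) * grad_mean_vbind`, with `Vbar`
#' the ensemble-mean binding energy. At `kappa_reg = 0` the result is the
#' standard REM gradient, bitwise.
#'
#' @inheritParams kl_gradient
#' @param config a [reg_config] (supplies `kappa_reg`, `V0`, `bind_pair`)
#' @return gradient vector over theta; attributes `V_bar`, `kl`, `reg` carry
#'   the mean binding energy and the two gradient components
#' @export
regrem_gradient <- function(aa_ensemble, cg_ensemble, topology, params,
                            config, temperature = 310) {
  kl <- kl_gradient(aa_ensemble, cg_ensemble, topology, params, temperature)
  reg <- 0 * kl
  v_bar <- NA_real_
  if (config$kappa_reg > 0) {
    stats <- ensemble_stats(cg_ensemble, topology, params, config$bind_pair)
    v_bar <- frame_mean(stats$V_bind, cg_ensemble$weights)
    gmv <- grad_mean_vbind(cg_ensemble, topology, params, temperature,
                           config$bind_pair, stats = stats)
    reg <- -2 * config$kappa_reg * (config$V0 - v_bar) * gmv
  }
  out <- kl + reg
  attr(out, "V_bar") <- v_bar
  attr(out, "kl") <- kl
  attr(out, "reg") <- reg
  out
}

#' Regularization-strength heuristic
#'
#' Balances a KL-divergence gradient of `0.5 beta nm^-1` against the
#' regularization gradient at a binding-energy error of 1 kcal/mol:
#' `0.5 beta nm^-1 = 2 kappa * (kcal/mol) * <dV_bind/dtheta>`, i.e.
#' `kappa = 0.25 beta / (mean_grad_vbind * 4.184)` in (kJ/mol)^-2.
#'
#' @param mean_grad_vbind typical magnitude of `<dV_bind/dtheta>`, nm^-1
#'   (about 1 for Gaussian-well amplitudes)
#' @param temperature K
#' @return kappa in (kJ/mol)^-2
#' @export
kappa_heuristic <- function(mean_grad_vbind, temperature = 310) {
  if (mean_grad_vbind <= 0) stop("mean_grad_vbind must be > 0")
  0.25 * beta_kJ(temperature) / (mean_grad_vbind * kcal)
}

#' Train CG attraction amplitudes by (reg-)REM
#'
#' Gradient descent on theta (Gaussian attraction amplitudes `C_IJ`). Each
#' iteration runs a fresh Langevin simulation of the current model from the
#' native (mapped reference mean or supplied) structure, evaluates the KL
#' gradient against the reference ensemble and, for `kappa_reg > 0`, the
#' regularization gradient from the recorded per-frame binding energies, and
#' takes a capped plain gradient-descent step. The reference-side average
#' `<dU/dtheta>_ref` is theta-independent for Gaussian amplitudes and is
#' precomputed once (exact caching).
#'
#' @param topology a [cg_topology]
#' @param params a [cg_params]; its trainable `C` entries are the start theta
#' @param aa_ensemble mapped reference [cg_ensemble]
#' @param config a [reg_config]
#' @param settings a [sim_settings] template for the per-iteration runs
#'   (`n_steps`, `stride`, `seed` are overridden from `config`)
#' @param start native start structure (default: first reference frame)
#' @param unbound_threshold frames with `V_bind` above this (kJ/mol) count
#'   as unbound in the logged unbound fraction (default -1)
#' @param verbose print per-iteration progress every 25 iterations
#' @return object of class `regcg_train`: `params` (final), `history`
#'   (data.frame: iteration, V_bar, rmsd, grad_kl_norm, grad_reg_norm,
#'   frac_unbound), `theta_history` (matrix), `config`
#' @export
train_regrem <- function(topology, params, aa_ensemble, config, settings,
                         start = NULL, unbound_threshold = -1,
                         verbose = FALSE) {
  validate_topology(topology); validate_params(params)
  if (n_frames(aa_ensemble) < 1) stop("reference ensemble is empty")
  if (sum(params$pairs$trainable) == 0) stop("no trainable parameters flagged")
  beta <- beta_kJ(settings$temperature)
  if (is.null(start)) start <- get_frame(aa_ensemble, 1)
  start <- as.matrix(start)

  # AA-side mean gradient: dU/dC is theta-independent, cache once
  g_aa <- mean_grad_full(aa_ensemble, topology, params)

  theta <- get_theta(params)
  nth <- length(theta)
  hist <- data.frame(iteration = integer(), V_bar = numeric(),
                     rmsd = numeric(), grad_kl_norm = numeric(),
                     grad_reg_norm = numeric(), frac_unbound = numeric())
  theta_hist <- matrix(NA_real_, nrow = 0, ncol = nth,
                       dimnames = list(NULL, names(theta)))
  vb_means <- numeric(0)
  last_step <- rep(0, nth)

  for (it in seq_len(config$n_iterations)) {
    params <- set_theta(params, theta)
    st <- settings
    st$n_steps <- config$steps_per_iter
    st$stride <- config$stride
    st$seed <- as.integer((config$seed + it * 104729) %% .Machine$integer.max)
    run <- tryCatch(
      simulate_cg(topology, params, start, st, bind_pair = config$bind_pair),
      error = function(e) e)
    gamma_it <- config$gamma
    if (inherits(run, "error")) {
      # blow-up: redo the last update at half step from the previous theta,
      # retry once, else abort (history so far is in the condition message)
      if (nrow(theta_hist) == 0)
        stop("simulation blew up at iteration 1: ", conditionMessage(run))
      theta <- theta_hist[nrow(theta_hist), ] - last_step / 2
      params <- set_theta(params, theta)
      gamma_it <- gamma_it / 2
      run <- tryCatch(
        simulate_cg(topology, params, start, st, bind_pair = config$bind_pair),
        error = function(e) e)
      if (inherits(run, "error"))
        stop("simulation blew up at iteration ", it, " after step halving: ",
             conditionMessage(run))
    }
    sys <- build_system(topology, params)
    stats <- ensemble_stats(run$ensemble, topology, params, config$bind_pair,
                            sys = sys)
    g_cg <- frame_mean(stats$g_full, NULL)
    kl <- beta * (g_aa - g_cg)
    v_bar <- mean(stats$V_bind)
    reg <- 0 * kl
    if (config$kappa_reg > 0) {
      gmv <- grad_mean_vbind(run$ensemble, topology, params,
                             settings$temperature, config$bind_pair,
                             stats = stats)
      reg <- -2 * config$kappa_reg * (config$V0 - v_bar) * gmv
    }
    grad <- kl + reg
    step <- gamma_it * grad
    mx <- max(abs(step))
    if (mx > config$max_step) step <- step * (config$max_step / mx)
    rms <- mean(rmsd_traj(run$ensemble, start))
    hist <- rbind(hist, data.frame(
      iteration = it, V_bar = v_bar, rmsd = rms,
      grad_kl_norm = sqrt(sum(kl^2)), grad_reg_norm = sqrt(sum(reg^2)),
      frac_unbound = mean(stats$V_bind > unbound_threshold)))
    theta_hist <- rbind(theta_hist, theta)
    vb_means <- c(vb_means, v_bar)
    last_step <- step
    theta <- theta - step
    if (verbose && it %% 25 == 0)
      message(sprintf("iter %4d  V_bar %8.2f  rmsd %6.3f  |kl| %8.3g  |reg| %8.3g",
                      it, v_bar, rms, sqrt(sum(kl^2)), sqrt(sum(reg^2))))
    if (!is.null(config$v_tol) && it >= config$v_window) {
      win <- tail(vb_means, config$v_window)
      if (abs(mean(win) - config$V0) < config$v_tol) break
    }
  }
  params <- set_theta(params, theta)
  rownames(theta_hist) <- NULL
  structure(list(params = params, history = hist,
                 theta_history = theta_hist, config = config,
                 topology = topology, start = start),
            class = "regcg_train")
}

#' Converged model from a training record
#'
#' The per-iteration theta iterates fluctuate with the sampling noise of the
#' per-iteration gradient estimates; the converged model is taken as the
#' mean theta over the final window (analogous to picking a converged model
#' among the late iterations).
#'
#' @param fit a `regcg_train`
#' @param window number of final iterations to average (default 20)
#' @return a [cg_params] with theta set to the final-window mean
#' @export
converged_params <- function(fit, window = 20) {
  nh <- nrow(fit$theta_history)
  window <- min(window, nh)
  thw <- colMeans(fit$theta_history[(nh - window + 1):nh, , drop = FALSE])
  set_theta(fit$params, thw)
}

#' @export
print.regcg_train <- function(x, ...) {
  h <- x$history
  win <- tail(h, min(20, nrow(h)))
  cat("reg-REM training:", nrow(h), "iterations,",
      ncol(x$theta_history), "trainable parameters\n")
  cat(sprintf("  kappa = %.4g (kJ/mol)^-2, V0 = %.4g kJ/mol\n",
              x$config$kappa_reg, x$config$V0))
  cat(sprintf("  final-window mean V_bind = %.2f kJ/mol, mean RMSD = %.3f nm\n",
              mean(win$V_bar), mean(win$rmsd)))
  invisible(x)
}

#' Plot a training record
#'
#' Two panels: mean binding energy per iteration (with the `V0` target) and
#' mean RMSD to the native structure per iteration.
#'
#' @param x a `regcg_train`
#' @param ... passed to `plot`
#' @export
plot.regcg_train <- function(x, ...) {
  h <- x$history
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(h$iteration, h$V_bar, type = "l", xlab = "iteration",
       ylab = "mean V_bind (kJ/mol)", ...)
  if (x$config$kappa_reg > 0)
    abline(h = x$config$V0, col = "red", lty = 2)
  plot(h$iteration, h$rmsd * 10, type = "l", xlab = "iteration",
       ylab = "mean RMSD (A)", ...)
  invisible(x)
}

#' Write a training log
#'
#' Tab-separated per-iteration table (iteration, V_bar, rmsd, gradient
#' norms, unbound fraction), directly plottable.
#'
#' @param fit a `regcg_train`
#' @param path output path
#' @export
write_train_log <- function(fit, path) {
  write.table(fit$history, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
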