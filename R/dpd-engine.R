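#' Soft conservative pair force (reference implementation)
#'
#' \eqn{F^C_{ij} = a_{ij}(1 - r_{ij}/r_C)\hat r_{ij}} for
#' \eqn{r_{ij} < r_C}, zero beyond the cutoff. The force acts on bead i
#' and is antisymmetric under index swap. Distances use the minimum-image
#' convention when a box is given. This pure-R form is the reference the
#' compiled engine is tested against.
#'
#' @param ri,rj Positions of beads i and j (length-3).
#' @param a_ij Maximum repulsion between the two bead types.
#' @param box Periodic box lengths, or `NULL` for open boundaries.
#' @param rC Cutoff distance (1 in reduced units).
#' @return Length-3 force vector on bead i.
#' @export
#' @examples
#' conservative_force(c(0, 0, 0), c(0.5, 0, 0), 100)  # magnitude 50
conservative_force <- function(ri, rj, a_ij, box = NULL, rC = 1) {
  d <- ri - rj
  if (!is.null(box)) d <- d - box * round(d / box)
  r <- sqrt(sum(d^2))
  if (r >= rC) return(c(0, 0, 0))
  if (r < 1e-12) {
    warning("coincident beads: using fallback direction (1, 0, 0)")
    return(a_ij * c(1, 0, 0))
  }
  a_ij * (1 - r / rC) * d / r
}

#' Random and dissipative pair forces (reference implementation)
#'
#' The thermostat pair of forces: random
#' \eqn{F^R = \sigma(1 - r/r_C)\,\theta\,\Delta t^{-1/2}\hat r} with
#' \eqn{\theta} a unit-variance Gaussian shared by the (i, j) and (j, i)
#' directions, and dissipative
#' \eqn{F^D = -\gamma(1 - r/r_C)^2(\hat r\cdot v_{ij})\hat r}. Their
#' amplitudes are tied by \eqn{\sigma^2 = 2\gamma k_BT}.
#'
#' @param ri,rj Bead positions.
#' @param vij Relative velocity `v_i - v_j`.
#' @param model A [default_interaction_model()].
#' @param dt Time step (the random force carries the
#'   \eqn{\Delta t^{-1/2}} factor).
#' @param theta The shared Gaussian variate; drawn if missing.
#' @param box Periodic box lengths or `NULL`.
#' @return List with `random` and `dissipative` length-3 forces on bead i.
#' @export
random_dissipative_forces <- function(ri, rj, vij, model, dt,
                                      theta = stats::rnorm(1), box = NULL) {
  if (dt <= 0) stop("dt must be positive")
  d <- ri - rj
  if (!is.null(box)) d <- d - box * round(d / box)
  r <- sqrt(sum(d^2))
  if (r >= model$rC) return(list(random = c(0, 0, 0), dissipative = c(0, 0, 0)))
  e <- d / r
  w <- 1 - r / model$rC
  list(
    random = model$sigma * w * theta / sqrt(dt) * e,
    dissipative = -model$gamma * w^2 * sum(e * vij) * e
  )
}

#' Harmonic bond force and energy (reference implementation)
#'
#' \eqn{u = \tfrac12 k (r - r_0)^2}; the force on bead i has magnitude
#' \eqn{k|r - r_0|} and restores the equilibrium length.
#'
#' @param ri,rj Bead positions.
#' @param k_bond Force constant (kBT/rC^2).
#' @param r0 Equilibrium length (rC).
#' @param box Periodic box lengths or `NULL`.
#' @return Length-3 force on bead i.
#' @export
bond_force <- function(ri, rj, k_bond, r0, box = NULL) {
  d <- ri - rj
  if (!is.null(box)) d <- d - box * round(d / box)
  r <- sqrt(sum(d^2))
  if (r < 1e-12) stop("coincident bonded beads")
  -k_bond * (r - r0) * d / r
}

#' @rdname bond_force
#' @export
bond_energy <- function(ri, rj, k_bond, r0, box = NULL) {
  d <- ri - rj
  if (!is.null(box)) d <- d - box * round(d / box)
  0.5 * k_bond * (sqrt(sum(d^2)) - r0)^2
}

#' Angle-bending force and energy (reference implementation)
#'
#' \eqn{u = \tfrac12 k (1 - \cos(\theta - \theta_0))} over the triple
#' (i, j, k) with j central. The three forces sum to zero and exert no
#' net torque. Near-colinear geometries are regularized by bounding
#' \eqn{\sin\theta} away from zero.
#'
#' @param ri,rj,rk Bead positions (j central).
#' @param k_angle Force constant (kBT).
#' @param theta0 Equilibrium angle in degrees.
#' @param box Periodic box lengths or `NULL`.
#' @return `angle_force()`: 3 x 3 matrix with rows = forces on i, j, k;
#'   `angle_energy()`: scalar energy.
#' @export
angle_force <- function(ri, rj, rk, k_angle, theta0, box = NULL) {
  mi <- function(d) if (is.null(box)) d else d - box * round(d / box)
  r1 <- mi(ri - rj); r2 <- mi(rk - rj)
  n1 <- sqrt(sum(r1^2)); n2 <- sqrt(sum(r2^2))
  if (n1 < 1e-12 || n2 < 1e-12) stop("degenerate angle geometry")
  cth <- max(-1, min(1, sum(r1 * r2) / (n1 * n2)))
  th <- acos(cth)
  s <- max(sqrt(1 - cth^2), 1e-8)
  dUdth <- 0.5 * k_angle * sin(th - theta0 * pi / 180)
  pref <- dUdth / s
  fi <- pref * (r2 / (n1 * n2) - cth * r1 / n1^2)
  fk <- pref * (r1 / (n1 * n2) - cth * r2 / n2^2)
  rbind(i = fi, j = -(fi + fk), k = fk)
}

#' @rdname angle_force
#' @export
angle_energy <- function(ri, rj, rk, k_angle, theta0, box = NULL) {
  mi <- function(d) if (is.null(box)) d else d - box * round(d / box)
  r1 <- mi(ri - rj); r2 <- mi(rk - rj)
  cth <- max(-1, min(1, sum(r1 * r2) / sqrt(sum(r1^2) * sum(r2^2))))
  0.5 * k_angle * (1 - cos(acos(cth) - theta0 * pi / 180))
}

#' Integrator settings
#'
#' The engine uses the modified velocity-Verlet scheme standard for DPD:
#' positions advance with the current force, velocities are predicted
#' with factor `lambda` before the new force (whose dissipative part
#' depends on velocities) is evaluated, then corrected with the mean of
#' old and new forces.
#'
#' @param dt Reduced time step (default 0.02; the stiff bond constant
#'   512 makes the common 0.04 marginal).
#' @param n_steps Number of integration steps.
#' @param lambda Velocity-prediction parameter (default 0.65).
#' @param gamma Dissipation strength; the noise strength is always
#'   derived as \eqn{\sigma = \sqrt{2\gamma k_BT}}.
#' @param seed Integer seed for the thermostat noise stream.
#' @return Object of class `dpd_integrator_settings`.
#' @export
integrator_settings <- function(dt = 0.02, n_steps = 1000L, lambda = 0.65,
                                gamma = 4.5, seed = 1L) {
  if (dt <= 0) stop("dt must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  if (n_steps < 0) stop("n_steps must be non-negative")
  structure(list(dt = dt, n_steps = as.integer(n_steps), lambda = lambda,
                 gamma = gamma, sigma = sqrt(2 * gamma), seed = as.integer(seed)),
            class = "dpd_integrator_settings")
}

#' Anisotropic barostat settings
#'
#' Berendsen-style pressure coupling applied independently to the x and z
#' box lengths (the axes perpendicular to the tube); the y length is
#' never rescaled. Each coupled axis is scaled by
#' \eqn{\mu = [1 - \kappa(\Delta t/\tau_p)(P_0 - P_{\alpha\alpha})]^{1/3}}
#' toward the set-point, with mobile positions mapped affinely and the
#' frozen tube translated rigidly so its diameter is preserved.
#'
#' @param target_p_perp Reduced pressure set-point for the perpendicular
#'   components; obtain from [calibrate_pressure()] so NPT reproduces the
#'   reduced density 3.
#' @param coupling_time Relaxation constant \eqn{\tau_p} (default 10
#'   reduced time units).
#' @param compressibility Effective compressibility prefactor
#'   \eqn{\kappa} (default 0.016, the DPD-water value at density 3).
#' @return Object of class `dpd_barostat_settings`.
#' @export
barostat_settings <- function(target_p_perp, coupling_time = 10,
                              compressibility = 0.016) {
  if (coupling_time <= 0) stop("coupling_time must be positive")
  structure(list(target_p_perp = target_p_perp,
                 coupling_time = coupling_time,
                 compressibility = compressibility,
                 fixed_axes = "y"),
            class = "dpd_barostat_settings")
}

#' Integrate a configuration forward in time
#'
#' Runs `settings$n_steps` modified velocity-Verlet DPD steps with the
#' pairwise thermostat; when `barostat` is given the x and z box lengths
#' are coupled to the pressure set-point each step. Frames (positions,
#' velocities, box, time) are stored every `sample_every` steps plus the
#' initial and final states; per-`log_every`-step reports carry kinetic
#' temperature, the pressure-tensor diagonal, box lengths, and the total
#' mobile momentum. Runs with the same configuration and seed are
#' identical.
#'
#' @param config A [build_system()] configuration.
#' @param settings An [integrator_settings()].
#' @param model A [default_interaction_model()]; its `gamma`/`sigma` are
#'   taken from `settings`.
#' @param barostat A [barostat_settings()] or `NULL` for NVT.
#' @param sample_every Frame interval in steps (0 stores only the first
#'   and final frames).
#' @param log_every Report interval in steps.
#' @return Object of class `dpd_trajectory`: list with `frames`, `log`
#'   (data frame), per-bead metadata (`type`, `mol_id`, `frozen`),
#'   `tube`, `n_lipids`, `settings`, `final` (a `dpd_config` continuing
#'   the run).
#' @export
dpd_run <- function(config, settings, model = default_interaction_model(settings$gamma),
                    barostat = NULL, sample_every = 0L, log_every = 100L) {
  stopifnot(inherits(config, "dpd_config"),
            inherits(settings, "dpd_integrator_settings"))
  a <- model$a[bead_types()$name, bead_types()$name]
  res <- .dpd_run_cpp(
    config$pos, config$vel, config$type_id, config$frozen, config$box, a,
    config$bonds, config$bond_k, config$bond_r0,
    config$angles, config$angle_k, config$angle_theta0,
    settings$dt, settings$n_steps, settings$lambda,
    settings$gamma, sqrt(2 * settings$gamma * model$kBT), settings$seed,
    !is.null(barostat),
    if (is.null(barostat)) 0 else barostat$target_p_perp,
    if (is.null(barostat)) 1 else barostat$coupling_time,
    if (is.null(barostat)) 0 else barostat$compressibility,
    as.integer(sample_every), as.integer(log_every), 0)
  if (res$n_coincident > 0)
    warning(sprintf("%d coincident bead pair(s) met the fallback direction",
                    res$n_coincident))
  final <- config
  lastf <- res$frames[[length(res$frames)]]
  final$pos <- lastf$pos
  final$vel <- lastf$vel
  final$box <- lastf$box
  if (!is.null(config$tube)) {
    fro <- config$frozen
    final$tube$center <- c(mean(lastf$pos[fro, 1]), config$tube$center[2],
                           mean(lastf$pos[fro, 3]))
  }
  structure(list(
    frames = res$frames, log = res$log,
    type = config$type, type_id = config$type_id, mol_id = config$mol_id,
    frozen = config$frozen, tube = final$tube, n_lipids = config$n_lipids,
    settings = settings, barostat = barostat, final = final,
    seed = settings$seed
  ), class = "dpd_trajectory")
}

#' @export
print.dpd_trajectory <- function(x, ...) {
  nb <- if (length(x$frames)) nrow(x$frames[[1]]$pos) else 0
  cat(sprintf("DPD trajectory: %d frames, %d beads, %d lipids\n",
              length(x$frames), nb, x$n_lipids))
  if (nrow(x$log))
    cat(sprintf("  final T = %.3f kBT, box %.2f x %.2f x %.2f rC\n",
                utils::tail(x$log$temperature, 1),
                utils::tail(x$log$Lx, 1), utils::tail(x$log$Ly, 1),
                utils::tail(x$log$Lz, 1)))
  invisible(x)
}

#' Advance a configuration by a single step
#'
#' Convenience wrapper around [dpd_run()] with `n_steps = 1`.
#'
#' @inheritParams dpd_run
#' @return List with `config` (the advanced `dpd_config`) and `report`
#'   (one-row data frame of diagnostics).
#' @export
dpd_step <- function(config, settings, model = default_interaction_model(settings$gamma),
                     barostat = NULL) {
  s1 <- settings
  s1$n_steps <- 1L
  traj <- dpd_run(config, s1, model, barostat, sample_every = 1L, log_every = 1L)
  list(config = traj$final, report = utils::tail(traj$log, 1))
}

#' Run until the free-lipid count equilibrates
#'
#' Integrates in chunks and stops once [detect_equilibration()] flags a
#' plateau of the free-lipid count (lipids neither adsorbed nor in a
#' surface-attached cluster), or when `max_steps` is reached. Chunks
#' continue bit-exactly from the previous state with per-chunk seeds
#' derived from `settings$seed`.
#'
#' @inheritParams dpd_run
#' @param chunk_steps Steps per chunk between equilibration checks.
#' @param max_steps Hard step budget.
#' @param cutoff Adsorption distance cutoff passed to the free-lipid
#'   count (rC).
#' @return A `dpd_trajectory` covering all chunks, with attribute
#'   `equilibrated` (logical) and `equilibration_frame`.
#' @export
dpd_run_until_equilibrated <- function(config, settings,
                                       model = default_interaction_model(settings$gamma),
                                       barostat = NULL, sample_every = 200L,
                                       chunk_steps = 2000L, max_steps = 50000L,
                                       cutoff = 1.06) {
  frames <- list()
  logs <- list()
  cfg <- config
  done <- 0L
  eq_frame <- NA_integer_
  equilibrated <- FALSE
  chunk <- 0L
  traj <- NULL
  while (done < max_steps) {
    chunk <- chunk + 1L
    s <- settings
    s$n_steps <- as.integer(min(chunk_steps, max_steps - done))
    s$seed <- as.integer((settings$seed + 7919L * chunk) %% .Machine$integer.max)
    traj <- dpd_run(cfg, s, model, barostat, sample_every = sample_every,
                    log_every = max(1L, sample_every))
    drop_first <- length(frames) > 0  # first frame repeats the previous state
    add <- if (drop_first) traj$frames[-1] else traj$frames
    add <- lapply(add, function(f) { f$time <- f$time + done * settings$dt; f })
    frames <- c(frames, add)
    logs[[chunk]] <- transform(traj$log, time = time + done * settings$dt)
    cfg <- traj$final
    done <- done + s$n_steps
    full <- traj
    full$frames <- frames
    full$log <- do.call(rbind, logs)
    free <- free_lipid_count(full, cutoff = cutoff)
    eq <- detect_equilibration(free)
    if (!is.na(eq)) { equilibrated <- TRUE; eq_frame <- eq; break }
  }
  out <- traj
  out$frames <- frames
  out$log <- do.call(rbind, logs)
  attr(out, "equilibrated") <- equilibrated
  attr(out, "equilibration_frame") <- eq_frame
  out
}

#' Calibrate the pressure set-point for NPT runs
#'
#' Runs a short pure-water NVT simulation at reduced density 3 and
#' returns the mean virial pressure, to be used as the perpendicular
#' pressure set-point so that NPT reproduces density 3. For DPD water the
#' result is close to the literature excess-pressure estimate
#' \eqn{\rho k_BT + 0.101\,a\rho^2}.
#'
#' @param model A [default_interaction_model()].
#' @param n_beads Number of water beads in the calibration box.
#' @param n_steps Integration steps (the first fifth is discarded as
#'   burn-in).
#' @param dt Time step.
#' @param seed Seed.
#' @return Mean reduced virial pressure (scalar).
#' @export
calibrate_pressure <- function(model = default_interaction_model(),
                               n_beads = 750L, n_steps = 4000L, dt = 0.02,
                               seed = 1L) {
  spec <- system_spec(substrate = NULL, n_lipids = 0, n_water_beads = n_beads,
                      Ly = (n_beads / 3)^(1 / 3), seed = seed)
  cfg <- build_system(spec)
  st <- integrator_settings(dt = dt, n_steps = n_steps, gamma = model$gamma,
                            seed = seed)
  traj <- dpd_run(cfg, st, model, sample_every = 0L, log_every = 20L)
  lg <- traj$log[traj$log$time > n_steps * dt / 5, ]
  mean((lg$Pxx + lg$Pyy + lg$Pzz) / 3)
}
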