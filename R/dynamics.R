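#' Integrate the system forward in time
#'
#' Langevin dynamics (BAOAB splitting of velocity Verlet) for translational
#' degrees of freedom and torque-driven rotational Langevin dynamics for the
#' membrane orientation axes, with an optional weak Berendsen-style coupling
#' of the in-plane box toward zero lateral tension (the isothermal-isobaric
#' ensemble for a tensionless membrane patch). Fully reproducible under a
#' fixed seed.
#'
#' @param sys an `escrt_system`.
#' @param n_steps number of timesteps.
#' @param dt timestep in tau (defaults to `sys$params$dt`).
#' @param seed integer seed for the thermostat noise stream.
#' @param thermostat logical; `FALSE` gives NVE dynamics.
#' @param barostat logical; couple the in-plane box to zero lateral tension.
#' @param sample_every store a frame every this many steps (0 = none).
#' @param log_every record tension/area/temperature/energy every this many
#'   steps (0 = none).
#' @return the advanced system, with attributes-free extra fields:
#'   `$last_frames` (list of sampled frames), `$last_log` (matrix with
#'   columns time, tension, area, temperature, energy).
#' @export
integrate_system <- function(sys, n_steps, dt = NULL, seed = 1,
                             thermostat = TRUE, barostat = FALSE,
                             sample_every = 0, log_every = 0) {
  if (is.null(dt)) dt <- sys$params$dt
  stopifnot(dt > 0, n_steps >= 1)
  out <- cpp_integrate(as_state(sys), cpp_params(sys$params),
                       as.integer(n_steps), dt, thermostat, barostat,
                       as.integer(sample_every), as.numeric(seed),
                       as.integer(log_every))
  if (!identical(out$status, "ok")) {
    stop("dynamics aborted (", out$status, ") at step ", out$diverged_at,
         ", t = ", sys$time + out$diverged_at * dt,
         " tau; diagnostic state attached", call. = FALSE)
  }
  sc <- out$box[1] / sys$box[1]
  sys$pos <- out$pos; sys$axis <- out$axis
  sys$vel <- out$vel; sys$avel <- out$avel
  sys$box <- out$box
  sys$time <- sys$time + n_steps * dt
  sys$last_frames <- out$frames
  sys$last_log <- out$log
  sys$strain <- out$strain
  invisible(sc)
  sys
}

#' Energy minimization (FIRE)
#'
#' Relaxes the configuration with the FIRE algorithm; per-iteration bead
#' displacement is capped at `max_disp`. Membrane axes are relaxed by
#' steepest descent on the torques. Beads with `frozen = TRUE` do not move.
#'
#' @param sys an `escrt_system`.
#' @param max_iter iteration budget.
#' @param ftol convergence threshold on the maximum force (kBT/sigma).
#' @param max_disp displacement cap per iteration (sigma).
#' @param frozen logical vector (length = bead count) of beads to hold fixed.
#' @return the relaxed system; attributes `energy`, `fmax`, `converged` in
#'   `sys$minimize_info`.
#' @export
minimize_system <- function(sys, max_iter = 5000, ftol = 1e-4, max_disp = 0.05,
                            frozen = NULL) {
  if (is.null(frozen)) frozen <- rep(FALSE, n_beads(sys))
  out <- cpp_minimize(as_state(sys), cpp_params(sys$params),
                      as.integer(max_iter), ftol, max_disp, frozen)
  sys$pos <- out$pos; sys$axis <- out$axis
  sys$minimize_info <- list(energy = out$energy, fmax = out$fmax,
                            iterations = out$iterations,
                            converged = out$converged)
  sys
}

#' Candidate interaction pairs (neighbor list)
#'
#' Returns the Verlet pair list the engine would use at the given cutoff and
#' skin: a superset of all interacting non-excluded pairs. Exposed for
#' verification against a brute-force pair enumeration.
#'
#' @param sys an `escrt_system`.
#' @param cutoff interaction cutoff (defaults to the largest cutoff in use).
#' @param skin Verlet skin.
#' @return two-column integer matrix of bead index pairs (i < j).
#' @export
neighbor_pairs <- function(sys, cutoff = NULL, skin = sys$params$skin) {
  p <- sys$params
  if (is.null(cutoff)) cutoff <- max(p$rc_mm, p$rc_bm, p$rc_bb, p$rmin_rep)
  rc <- cutoff + skin
  pos <- sys$pos; box <- sys$box
  n <- nrow(pos)
  ex <- sys$bonds[, 1:2, drop = FALSE]
  exset <- if (nrow(ex)) paste(pmin(ex[, 1], ex[, 2]), pmax(ex[, 1], ex[, 2])) else character(0)
  out <- matrix(0L, 0, 2)
  res <- list()
  for (i in seq_len(n - 1)) {
    dx <- pos[(i + 1):n, 1] - pos[i, 1]
    dy <- pos[(i + 1):n, 2] - pos[i, 2]
    dz <- pos[(i + 1):n, 3] - pos[i, 3]
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    j <- which(dx^2 + dy^2 + dz^2 < rc^2) + i
    if (length(j)) res[[length(res) + 1]] <- cbind(i, j)
  }
  if (length(res)) {
    out <- do.call(rbind, res)
    if (length(exset)) {
      keep <- !(paste(out[, 1], out[, 2]) %in% exset)
      out <- out[keep, , drop = FALSE]
    }
  }
  colnames(out) <- c("i", "j")
  out
}

#' Equilibrate a flat membrane patch
#'
#' Convenience wrapper: thermostatted, barostatted dynamics with momentum
#' reset, returning the equilibrated system.
#'
#' @param sys an `escrt_system`.
#' @param n_steps equilibration steps.
#' @param seed RNG seed.
#' @param ... passed to [integrate_system()].
#' @return the equilibrated system.
#' @export
equilibrate <- function(sys, n_steps = 10000, seed = 1, ...) {
  sys <- integrate_system(sys, n_steps, seed = seed, thermostat = TRUE,
                          barostat = TRUE, ...)
  zero_momentum(sys)
}
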