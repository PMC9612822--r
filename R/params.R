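#' Default simulation parameters
#'
#' Returns the full parameter set of the model in MD units (lengths in sigma,
#' energies in kBT, times in tau). Every value can be overridden by name.
#'
#' Membrane: `eps_mm` sets the depth of the one-particle-thick pair potential,
#' `mu` is the rigidity-control exponent multiplying the orientation penalty
#' (the default is calibrated so the fluctuation-spectrum estimator returns
#' kappa close to 20 kBT; `mu = 5` is the rigid ~40 kBT preset), `zeta`
#' shapes the smoothly truncated attractive tail, and `rc_mm` is the cutoff.
#'
#' Filaments: `k1`, `k2`, `k3` are the bond stiffnesses of the Flat Spiral,
#' Wide Helix and Tight Helix in kBT/sigma^2; `eps_bm` is the strength of the
#' short-ranged attraction between filament membrane-binding beads and
#' membrane beads, `eps_bb` the weak lateral attraction between binding beads
#' of different subunits, and `eps_cm` the cargo-membrane adhesion.
#'
#' Dynamics: `kT` temperature, `dt` timestep, `gamma`/`gamma_r`
#' translational/rotational Langevin damping (per tau), `baro_coupling` the
#' weak in-plane coupling toward zero lateral tension.
#'
#' @param ... named overrides of any default.
#' @return an object of class `escrt_params` (a named list).
#' @export
default_params <- function(...) {
  p <- list(
    # thermodynamics / integration
    kT = 1.0, dt = 0.01, gamma = 1.0, gamma_r = 1.0, mass = 1.0, inertia = 1.0,
    # membrane pair potential
    eps_mm = 4.34, mu = 3.0, zeta = 4.0,
    rmin_mm = 2^(1/6), rc_mm = 2.6,
    # filament-membrane adhesion (must stay below the membrane cohesion
    # scale or filaments extract beads from the sheet)
    eps_bm = 3.5, rmin_bm = 2^(1/6), rc_bm = 1.8,
    # filament-filament lateral attraction (binding beads)
    eps_bb = 2.0, rmin_bb = 2^(1/6), rc_bb = 2.0,
    # cargo-membrane adhesion (0 = volume exclusion only); kept below the
    # spontaneous-engulfment threshold so wrapping is filament-driven
    eps_cm = 4.0, rmin_cm = 2^(1/6), rc_cm = 1.8,
    # generic excluded volume
    eps_rep = 1.0, rmin_rep = 1.0,
    cargo_radius = 5.0,
    # filament bond stiffnesses (kBT/sigma^2)
    k1 = 128, k2 = 128, k3 = 128,
    # neighbor list / integrator safeguards
    skin = 0.4, max_step = 0.5,
    # barostat
    baro_coupling = 2e-3, baro_every = 10L
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  validate_params(p)
  structure(p, class = "escrt_params")
}

validate_params <- function(p) {
  stopifnot(p$kT > 0, p$dt > 0, p$gamma >= 0, p$gamma_r >= 0,
            p$eps_mm > 0, p$mu >= 0,
            p$k1 >= 0, p$k2 >= 0, p$k3 >= 0,
            p$eps_bm >= 0, p$eps_bb >= 0, p$eps_cm >= 0,
            p$rc_mm > p$rmin_mm, p$rc_bm > p$rmin_bm, p$rc_bb > p$rmin_bb,
            p$cargo_radius > 0)
  invisible(p)
}

#' @export
print.escrt_params <- function(x, ...) {
  cat("escrtsim parameters (MD units):\n")
  cat(sprintf("  membrane: eps_mm = %.3g kBT, mu = %.3g, zeta = %.3g, rc = %.3g sigma\n",
              x$eps_mm, x$mu, x$zeta, x$rc_mm))
  cat(sprintf("  adhesion: filament-membrane %.3g, lateral %.3g, cargo %.3g kBT\n",
              x$eps_bm, x$eps_bb, x$eps_cm))
  cat(sprintf("  stiffness: k1 = %g, k2 = %g, k3 = %g kBT/sigma^2\n",
              x$k1, x$k2, x$k3))
  cat(sprintf("  dynamics: kT = %g, dt = %g tau, gamma = %g/tau\n",
              x$kT, x$dt, x$gamma))
  invisible(x)
}

# subset passed to the C++ kernels
cpp_params <- function(p) {
  p[c("kT", "gamma", "gamma_r", "mass", "inertia",
      "eps_mm", "mu", "zeta", "rmin_mm", "rc_mm",
      "eps_bm", "rmin_bm", "rc_bm",
      "eps_bb", "rmin_bb", "rc_bb",
      "eps_cm", "rmin_cm", "rc_cm",
      "eps_rep", "rmin_rep", "cargo_radius",
      "skin", "baro_coupling", "baro_every", "max_step")]
}
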