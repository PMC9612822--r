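## Desk-scale demonstration presets: a reduced version of the full staged
## remodelling pathway that runs in minutes on one CPU. Geometry is scaled to
## half the production radii; kinetic rates are proportionally faster (the
## deformation distances shrink with the scale, so the quasi-static regime is
## reached at higher nominal rates). Severed subunits are removed from the
## box in these presets: at this system size the nascent vesicle is only a
## few subunit volumes large, and retained monomers crowd it in a way they do
## not at production scale.

#' Desk-scale demonstration system
#'
#' A small periodic membrane patch at default parameters with (optionally) a
#' single adhesive cargo sphere at the box centre, pre-equilibrated with the
#' thermostat and the zero-tension barostat.
#'
#' @param seed RNG seed.
#' @param cargo include the cargo sphere.
#' @param nx patch dimension (beads per side).
#' @param cargo_radius cargo radius (sigma).
#' @param cargo_adhesion cargo-membrane adhesion (kBT).
#' @param t_equil pre-equilibration time (tau).
#' @return an `escrt_system`.
#' @export
desk_demo_system <- function(seed = 1, cargo = TRUE, nx = 24,
                             cargo_radius = 2.5, cargo_adhesion = 4,
                             t_equil = 80) {
  p <- default_params(cargo_radius = cargo_radius)
  sys <- build_flat_patch(nx, nx, params = p)
  sys <- equilibrate(sys, round(t_equil / p$dt), seed = derive_seed(seed, 99L))
  if (cargo) sys <- add_cargo(sys, radius = cargo_radius,
                              adhesion = cargo_adhesion)
  sys
}

#' Desk-scale staged remodelling schedule
#'
#' The full filament-exchange sequence at half-scale geometry: spiral
#' recruitment (flat), Wide Helix recruitment (buckle), spiral severing,
#' Tight Helix recruitment, Wide Helix severing, constriction (tubule),
#' Tight Helix disassembly and final relaxation (scission with cargo).
#'
#' @param scale geometry scale relative to production radii.
#' @param n_spiral,n_wide,n_tight subunit counts.
#' @param r_constriction_nm_tau constriction rate (nm of target radius per
#'   tau); the desk default is eight times the production rate, matching the
#'   halved geometry.
#' @param R_final_nm final Tight Helix target radius, in (unscaled) nm.
#' @param disassembly_mode,disassembly_rate final disassembly protocol.
#' @param t_stage equilibration stage length (tau).
#' @param t_final final relaxation (tau).
#' @return a [protocol_schedule()].
#' @export
desk_demo_schedule <- function(scale = 0.5, n_spiral = 24, n_wide = 40,
                               n_tight = 24,
                               r_constriction_nm_tau = 0.0168,
                               R_final_nm = 5.7,
                               disassembly_mode = "sequential_bottom",
                               disassembly_rate = 0.05,
                               t_stage = 120, t_final = 250) {
  protocol_schedule(
    list(action = "equilibrate", duration = t_stage / 2),
    list(action = "recruit", species = "flat_spiral", n_subunits = n_spiral,
         scale = scale),
    # the spiral needs time to flatten the cargo's spontaneous partial wrap
    list(action = "equilibrate", duration = t_stage * 5 / 3),
    list(action = "recruit", species = "wide_helix", n_subunits = n_wide,
         scale = scale),
    list(action = "equilibrate", duration = t_stage * 4 / 3,
         measure_theta = TRUE),
    list(action = "sever_filament", filament = "flat_spiral", remove = TRUE),
    list(action = "equilibrate", duration = t_stage * 4 / 3),
    list(action = "recruit", species = "tight_helix", n_subunits = n_tight,
         scale = scale),
    list(action = "equilibrate", duration = t_stage * 2 / 3),
    list(action = "sever_filament", filament = "wide_helix", remove = TRUE),
    list(action = "equilibrate", duration = t_stage * 2 / 3),
    list(action = "constrict", filament = "tight_helix",
         rate_nm_tau = r_constriction_nm_tau, R_final_nm = R_final_nm,
         scale = scale),
    list(action = "equilibrate", duration = t_stage / 3),
    list(action = "disassemble", filament = "tight_helix",
         mode = disassembly_mode, rate = disassembly_rate, remove = TRUE),
    list(action = "equilibrate", duration = t_final)
  )
}
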