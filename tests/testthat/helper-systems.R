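# shared fixtures built in code

# a standalone filament in vacuum (huge box, no membrane)
free_filament_system <- function(geom, n_subunits, k, params = default_params()) {
  fil <- build_filament(geom, n_subunits, k)
  sys <- new_system(fil$pos, fil$type, box = c(500, 500, 500), params = params)
  sys$fil <- rep(1L, nrow(fil$pos))
  bonds <- fil$bonds
  bonds[, "fil"] <- 1
  sys$bonds <- bonds
  sys$filaments[[1]] <- list(species = "test", geometry = geom, k = k,
                             n_subunits = n_subunits,
                             beads = seq_len(nrow(fil$pos)),
                             active = rep(TRUE, n_subunits))
  sys
}

# small mixed system: membrane patch + short filament + cargo, for
# force-consistency and ledger tests
mixed_test_system <- function(seed = 1) {
  p <- default_params(cargo_radius = 2)
  sys <- build_flat_patch(10, 10, spacing = 1.1, params = p)
  g <- filament_geometry(radius = 4, pitch = 0, tilt = 0)
  fil <- build_filament(g, 5, k = 64, species = "flat_spiral")
  sys <- add_filament(sys, fil, z_bind = 1.1)
  sys <- add_cargo(sys, radius = 2, adhesion = 4)
  set.seed(seed)
  sys$pos <- sys$pos + matrix(rnorm(nrow(sys$pos) * 3, 0, 0.02), ncol = 3)
  sys
}

# total potential energy via the engine (for finite differences)
total_energy <- function(sys) energy_report(sys)$total

# brute-force all-pairs reference energy
brute_energy <- function(sys) {
  st <- escrtsim:::as_state(sys)
  escrtsim:::cpp_compute_brute(st, escrtsim:::cpp_params(sys$params))$total
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), 1e-12), tol)
}
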