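#' Simulation system container
#'
#' An `escrt_system` bundles membrane beads, filaments, cargo, velocities,
#' the periodic box (periodic in x and y, open along z) and the parameter
#' set. Bead types: 1 membrane, 2 filament membrane-binding, 3 filament back,
#' 4 cargo.
#'
#' @param pos N x 3 matrix of bead positions (sigma).
#' @param type integer vector of bead types.
#' @param box in-plane box lengths and a nominal z extent, `c(Lx, Ly, Lz)`.
#' @param params an [default_params()] object.
#' @param axis optional N x 3 matrix of unit orientation axes (membrane
#'   beads); defaults to (0, 0, 1).
#' @return an object of class `escrt_system`.
#' @export
new_system <- function(pos, type, box, params = default_params(), axis = NULL) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  stopifnot(ncol(pos) == 3, length(type) == n, length(box) == 3)
  if (is.null(axis)) axis <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  check_axes(axis[type == 1L, , drop = FALSE])
  sys <- structure(list(
    pos = unname(pos), axis = unname(as.matrix(axis)),
    vel = matrix(0, n, 3), avel = matrix(0, n, 3),
    type = as.integer(type), fil = rep(0L, n), adh = rep(1, n),
    bonds = matrix(numeric(0), 0, 6,
                   dimnames = list(NULL, c("i", "j", "r0", "k", "fil", "spair"))),
    box = as.numeric(box), time = 0,
    params = params,
    filaments = list(), cargo = NULL
  ), class = "escrt_system")
  sys
}

check_axes <- function(axis, tol = 1e-9) {
  if (!nrow(axis)) return(invisible(TRUE))
  nrm <- sqrt(rowSums(axis^2))
  if (any(abs(nrm - 1) > tol))
    stop("orientation axes must be unit vectors (max |norm - 1| = ",
         format(max(abs(nrm - 1))), ")")
  invisible(TRUE)
}

n_beads <- function(sys) nrow(sys$pos)

# state list handed to the C++ kernels
as_state <- function(sys) {
  list(pos = sys$pos, axis = sys$axis, vel = sys$vel, avel = sys$avel,
       type = sys$type, fil = sys$fil, adh = sys$adh,
       bonds = sys$bonds[, 1:4, drop = FALSE], box = sys$box)
}

#' @export
print.escrt_system <- function(x, ...) {
  nt <- table(factor(x$type, levels = 1:4,
                     labels = c("membrane", "binding", "back", "cargo")))
  cat("escrt_system:", n_beads(x), "beads (",
      paste(sprintf("%s %d", names(nt), nt), collapse = ", "), ")\n")
  cat(sprintf("  box %.2f x %.2f sigma (periodic in-plane), t = %.1f tau\n",
              x$box[1], x$box[2], x$time))
  if (length(x$filaments))
    for (f in x$filaments)
      cat(sprintf("  filament '%s': %d subunits (%d active), R = %.2f sigma, k = %g\n",
                  f$species, f$n_subunits, sum(f$active),
                  f$geometry$radius, f$k))
  if (!is.null(x$cargo))
    cat(sprintf("  cargo: %d bead(s), radius %.1f sigma, adhesion %g kBT\n",
                length(x$cargo$beads), x$cargo$radius, x$cargo$adhesion))
  cat(sprintf("  kappa control mu = %g, eps_mm = %g\n",
              x$params$mu, x$params$eps_mm))
  invisible(x)
}

#' Total potential energy decomposition
#'
#' Evaluates all interaction terms of the current configuration and returns
#' the energy ledger: membrane-membrane, filament bonds, filament-membrane
#' adhesion, filament-filament, cargo-membrane adhesion and cargo excluded
#' volume, together with per-bead energies (pair energies split half to each
#' partner).
#'
#' @param sys an `escrt_system`.
#' @return list with `total`, named `ledger`, `per_bead`, `forces`, `torques`
#'   and in-plane virial components.
#' @export
energy_report <- function(sys) {
  cpp_compute(as_state(sys), cpp_params(sys$params))
}

#' Measured in-plane tension of the current configuration
#'
#' Computes the lateral (frame) tension from the 2D virial, in kBT/sigma^2.
#' Kinetic contributions use the stored velocities.
#'
#' @param sys an `escrt_system`.
#' @return scalar tension.
#' @export
lateral_tension <- function(sys) {
  rep_ <- energy_report(sys)
  kin2d <- sum(sys$params$mass * (sys$vel[, 1]^2 + sys$vel[, 2]^2))
  A <- sys$box[1] * sys$box[2]
  -(kin2d + rep_$virial_xx + rep_$virial_yy) / (2 * A)
}

#' Remove centre-of-mass drift
#'
#' Subtracts the centre-of-mass velocity so the total linear momentum is zero.
#'
#' @param sys an `escrt_system`.
#' @return the system with zero net momentum.
#' @export
zero_momentum <- function(sys) {
  sys$vel <- sweep(sys$vel, 2, colMeans(sys$vel))
  sys
}

# indices of membrane beads
membrane_beads <- function(sys) which(sys$type == 1L)
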