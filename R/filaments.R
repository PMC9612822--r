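#' Filament geometry specification
#'
#' Encodes the target shape of a filament: an arc (pitch 0) or helix of
#' radius `radius`, with `pitch` of rise per full turn, subunits spaced
#' `spacing` apart along the contour, and the membrane-binding face tilted by
#' `tilt` degrees. Tilt is the angle between the binding-face direction and
#' the inward membrane normal: 0 means the face points straight down (Flat
#' Spiral), 90 means it points radially outward (helices).
#'
#' The three-bead subunit triad is an isoceles triangle in the plane normal
#' to the local tangent: two membrane-binding beads `triad_width` apart,
#' displaced `triad_drop` toward the binding face, and one back bead
#' `triad_rise` away from it.
#'
#' @param radius target radius in sigma (> 0).
#' @param pitch rise per turn in sigma (>= 0).
#' @param tilt binding-face tilt in degrees, between -90 and 90.
#' @param spacing subunit spacing along the contour in sigma (> 0).
#' @param handedness +1 or -1.
#' @param triad_width,triad_drop,triad_rise triad dimensions in sigma.
#' @return an object of class `filament_geometry`.
#' @export
filament_geometry <- function(radius, pitch = 0, tilt = 0, spacing = 1,
                              handedness = 1,
                              triad_width = 1, triad_drop = 0.4,
                              triad_rise = 0.6) {
  stopifnot(radius > 0, spacing > 0, pitch >= 0,
            tilt >= -90, tilt <= 90, handedness %in% c(-1, 1))
  if (triad_width <= 0 || (triad_drop + triad_rise) <= 0)
    stop("degenerate subunit triad: zero-area triangle")
  structure(list(radius = radius, pitch = pitch, tilt = tilt,
                 spacing = spacing, handedness = handedness,
                 triad_width = triad_width, triad_drop = triad_drop,
                 triad_rise = triad_rise),
            class = "filament_geometry")
}

#' Filament species presets
#'
#' The three model species: a Flat Spiral with target radius R1 = 19.4 nm,
#' binding face down, stiffness `k1`; a Wide Helix with a smaller radius R2,
#' binding face outward, stiffness `k2`; and a Tight Helix that starts at R2
#' and is constricted toward R3, stiffness `k3`. Radii can be scaled down for
#' reduced desk-scale systems with `scale`.
#'
#' @param species one of `"flat_spiral"`, `"wide_helix"`, `"tight_helix"`.
#' @param params parameter set supplying k1, k2, k3.
#' @param scale multiplies the preset radii and pitch (reduced-size systems).
#' @param units unit system for the nm -> sigma mapping.
#' @return list with `geometry`, `k` and `species`.
#' @export
species_preset <- function(species = c("flat_spiral", "wide_helix", "tight_helix"),
                           params = default_params(), scale = 1,
                           units = md_units()) {
  species <- match.arg(species)
  R1 <- convert_units(19.4, "nm", "sigma", units)   # Flat Spiral target radius
  R2 <- 0.85 * R1                                   # close to, but below, R1
  switch(species,
    flat_spiral = list(species = species, k = params$k1,
      geometry = filament_geometry(radius = R1 * scale, pitch = 0, tilt = 0)),
    wide_helix = list(species = species, k = params$k2,
      geometry = filament_geometry(radius = R2 * scale, pitch = 4.5 * scale,
                                   tilt = 90)),
    tight_helix = list(species = species, k = params$k3,
      geometry = filament_geometry(radius = R2 * scale, pitch = 4.5 * scale,
                                   tilt = 90)))
}

# local frames along the arc/helix; returns centroids and unit frame vectors
backbone_frames <- function(geom, n_subunits) {
  R <- geom$radius; p <- geom$pitch; s <- geom$spacing; h <- geom$handedness
  cpt <- p / (2 * pi)                       # rise per radian
  dtheta <- s / sqrt(R^2 + cpt^2)
  theta <- (seq_len(n_subunits) - 1) * dtheta * h
  z <- (seq_len(n_subunits) - 1) * dtheta * cpt
  centroid <- cbind(R * cos(theta), R * sin(theta), z)
  u <- cbind(cos(theta), sin(theta), 0)     # radial outward
  tang <- cbind(-R * sin(theta) * h, R * cos(theta) * h, cpt * h)
  tang <- tang / sqrt(rowSums(tang^2))
  tilt <- geom$tilt * pi / 180
  b <- sin(tilt) * u                         # binding direction
  b[, 3] <- b[, 3] - cos(tilt)
  # orthogonalise against the tangent (pitched helices at tilt < 90)
  b <- b - tang * rowSums(b * tang)
  b <- b / sqrt(rowSums(b^2))
  side <- cbind(b[, 2] * tang[, 3] - b[, 3] * tang[, 2],
                b[, 3] * tang[, 1] - b[, 1] * tang[, 3],
                b[, 1] * tang[, 2] - b[, 2] * tang[, 1])
  side <- side / sqrt(rowSums(side^2))
  list(centroid = centroid, tangent = tang, binding = b, side = side,
       theta = theta)
}

#' Ideal backbone bead positions of a filament
#'
#' Places subunit triads on a circular arc (pitch 0) or helix of the target
#' radius, with the binding-bead pair oriented by the tilt convention (down
#' for tilt 0, outward for tilt 90). The helix axis is the z-axis through the
#' origin.
#'
#' @param geom a [filament_geometry()].
#' @param n_subunits number of subunits (>= 2).
#' @return list with per-role position matrices `b1`, `b2`, `back` (the two
#'   membrane-binding beads and the back bead) and `centroid`.
#' @export
ideal_backbone <- function(geom, n_subunits) {
  stopifnot(n_subunits >= 2)
  if (geom$pitch == 0 &&
      (n_subunits - 1) * geom$spacing > 2 * pi * geom$radius)
    stop("arc length ", (n_subunits - 1) * geom$spacing,
         " sigma exceeds the full circle 2*pi*R = ",
         round(2 * pi * geom$radius, 2),
         " sigma at pitch 0: subunits would overlap")
  fr <- backbone_frames(geom, n_subunits)
  w2 <- geom$triad_width / 2
  b1 <- fr$centroid + geom$triad_drop * fr$binding + w2 * fr$side
  b2 <- fr$centroid + geom$triad_drop * fr$binding - w2 * fr$side
  back <- fr$centroid - geom$triad_rise * fr$binding
  list(b1 = b1, b2 = b2, back = back, centroid = fr$centroid)
}

#' Solve the nine inter-subunit bond rest lengths for a target geometry
#'
#' The rest lengths are the Euclidean bead-bead distances between the triads
#' of two consecutive subunits on the ideal backbone; by the screw symmetry of
#' the helix one consecutive pair determines all of them. Row r, column c of
#' the returned matrix is the bond between bead role r of subunit k and bead
#' role c of subunit k+1 (roles ordered binding-1, binding-2, back).
#'
#' @param geom a [filament_geometry()].
#' @return a 3 x 3 matrix of positive rest lengths (sigma).
#' @export
solve_rest_lengths <- function(geom) {
  bb <- ideal_backbone_pair(geom)
  roles1 <- rbind(bb$b1[1, ], bb$b2[1, ], bb$back[1, ])
  roles2 <- rbind(bb$b1[2, ], bb$b2[2, ], bb$back[2, ])
  d <- matrix(0, 3, 3, dimnames = list(c("b1", "b2", "back"),
                                       c("b1", "b2", "back")))
  for (r in 1:3) for (c in 1:3)
    d[r, c] <- sqrt(sum((roles1[r, ] - roles2[c, ])^2))
  stopifnot(all(d > 0))
  d
}

# two consecutive triads without the arc-length overlap guard (constriction
# may pass through radii where a full-length filament would not fit a circle)
ideal_backbone_pair <- function(geom) {
  fr <- backbone_frames(geom, 2)
  w2 <- geom$triad_width / 2
  list(b1 = fr$centroid + geom$triad_drop * fr$binding + w2 * fr$side,
       b2 = fr$centroid + geom$triad_drop * fr$binding - w2 * fr$side,
       back = fr$centroid - geom$triad_rise * fr$binding)
}

# intra-subunit rest lengths (rigid triangle)
triad_rest_lengths <- function(geom) {
  w <- geom$triad_width
  hh <- geom$triad_drop + geom$triad_rise
  c(b1_b2 = w, b1_back = sqrt((w / 2)^2 + hh^2), b2_back = sqrt((w / 2)^2 + hh^2))
}

#' Build a filament at its ideal configuration
#'
#' Returns a standalone filament whose internal bond energy is zero: beads on
#' the ideal backbone, intra-subunit rigid-triangle bonds, and 9 harmonic
#' bonds between every consecutive subunit pair with rest lengths from
#' [solve_rest_lengths()].
#'
#' @param geom a [filament_geometry()].
#' @param n_subunits number of subunits (>= 2).
#' @param k inter-subunit bond stiffness (kBT/sigma^2, >= 0).
#' @param species species label.
#' @param k_triad intra-subunit bond stiffness (rigid triangle).
#' @return an object of class `escrt_filament`.
#' @export
build_filament <- function(geom, n_subunits, k, species = "filament",
                           k_triad = 500) {
  stopifnot(k >= 0)
  if (n_subunits < 2) stop("a filament needs at least 2 subunits")
  bb <- ideal_backbone(geom, n_subunits)
  n <- n_subunits
  pos <- matrix(0, 3 * n, 3)
  for (s in seq_len(n)) {
    pos[3 * s - 2, ] <- bb$b1[s, ]
    pos[3 * s - 1, ] <- bb$b2[s, ]
    pos[3 * s, ]     <- bb$back[s, ]
  }
  type <- rep(c(2L, 2L, 3L), n)
  tri <- triad_rest_lengths(geom)
  bonds <- list()
  for (s in seq_len(n)) {
    i0 <- 3 * (s - 1)
    bonds[[length(bonds) + 1]] <- cbind(
      i = i0 + c(1, 1, 2), j = i0 + c(2, 3, 3),
      r0 = unname(tri), k = k_triad, fil = NA, spair = 0)
  }
  rl <- solve_rest_lengths(geom)
  for (s in seq_len(n - 1)) {
    a0 <- 3 * (s - 1); b0 <- 3 * s
    rows <- expand.grid(r = 1:3, c = 1:3)
    bonds[[length(bonds) + 1]] <- cbind(
      i = a0 + rows$r, j = b0 + rows$c,
      r0 = rl[cbind(rows$r, rows$c)], k = k, fil = NA, spair = s)
  }
  bonds <- do.call(rbind, bonds)
  colnames(bonds) <- c("i", "j", "r0", "k", "fil", "spair")
  structure(list(pos = pos, type = type, bonds = bonds,
                 n_subunits = n, geometry = geom, k = k, species = species,
                 active = rep(TRUE, n)),
            class = "escrt_filament")
}

#' @export
print.escrt_filament <- function(x, ...) {
  cat(sprintf("escrt_filament '%s': %d subunits, R = %.2f sigma, pitch %.2f, tilt %g deg, k = %g kBT/sigma^2\n",
              x$species, x$n_subunits, x$geometry$radius, x$geometry$pitch,
              x$geometry$tilt, x$k))
  invisible(x)
}

#' Add a filament to a system
#'
#' Inserts a standalone filament at a rigid-body placement: translated by
#' `center` (x, y) and `z_shift`, optionally rotated about its helix axis by
#' `phase` (radians). No overlap relaxation is performed here; see
#' [recruit_filament()] for the protocol-level insertion.
#'
#' @param sys an `escrt_system`.
#' @param fil an `escrt_filament`.
#' @param center in-plane position of the helix axis (defaults to box centre).
#' @param z_shift vertical offset applied to the filament (its lowest binding
#'   bead is placed at `z_bind` above the local membrane plane when `z_bind`
#'   is given instead).
#' @param z_bind target height of the lowest binding bead above the membrane
#'   mid-plane (overrides `z_shift` when non-NULL).
#' @param phase rotation about the helix axis, radians.
#' @return the system with the filament appended (its index in
#'   `sys$filaments` is `attr(, "filament_id")` of the return value).
#' @export
add_filament <- function(sys, fil, center = NULL, z_shift = 0, z_bind = NULL,
                         phase = 0) {
  if (is.null(center)) center <- sys$box[1:2] / 2
  pos <- fil$pos
  if (phase != 0) {
    rot <- matrix(c(cos(phase), sin(phase), 0,
                    -sin(phase), cos(phase), 0, 0, 0, 1), 3, 3)
    pos <- pos %*% rot
  }
  if (!is.null(z_bind)) {
    # reference height: the local membrane surface under the filament's
    # footprint (annulus around its ring radius), so recruitment onto an
    # already-deformed membrane does not thread the filament through it
    memsel <- sys$type == 1L
    zmem <- 0
    if (any(memsel)) {
      mp <- sys$pos[memsel, , drop = FALSE]
      rr <- sqrt((mp[, 1] - center[1])^2 + (mp[, 2] - center[2])^2)
      R <- fil$geometry$radius
      ring <- abs(rr - R) < 2
      zmem <- if (any(ring)) stats::quantile(mp[ring, 3], 0.9)
              else stats::median(mp[, 3])
    }
    low <- min(pos[fil$type == 2L, 3])
    z_shift <- zmem + z_bind - low
  }
  pos[, 1] <- pos[, 1] + center[1]
  pos[, 2] <- pos[, 2] + center[2]
  pos[, 3] <- pos[, 3] + z_shift
  off <- n_beads(sys)
  fid <- length(sys$filaments) + 1L
  bonds <- fil$bonds
  bonds[, "i"] <- bonds[, "i"] + off
  bonds[, "j"] <- bonds[, "j"] + off
  bonds[, "fil"] <- fid
  sys$pos <- rbind(sys$pos, pos)
  sys$axis <- rbind(sys$axis, matrix(rep(c(0, 0, 1), each = nrow(pos)),
                                     nrow(pos), 3))
  sys$vel <- rbind(sys$vel, matrix(0, nrow(pos), 3))
  sys$avel <- rbind(sys$avel, matrix(0, nrow(pos), 3))
  sys$type <- c(sys$type, fil$type)
  sys$fil <- c(sys$fil, rep(fid, nrow(pos)))
  sys$adh <- c(sys$adh, rep(1, nrow(pos)))
  sys$bonds <- rbind(sys$bonds, bonds)
  meta <- list(species = fil$species, geometry = fil$geometry, k = fil$k,
               n_subunits = fil$n_subunits,
               beads = off + seq_len(nrow(pos)),
               active = rep(TRUE, fil$n_subunits))
  sys$filaments[[fid]] <- meta
  attr(sys, "filament_id") <- fid
  sys
}

# bead indices (in the system) of one subunit of a filament
subunit_beads <- function(sys, fil_id, s) {
  f <- sys$filaments[[fil_id]]
  f$beads[(3 * (s - 1) + 1):(3 * s)]
}

#' Update the target geometry of a filament in place
#'
#' Replaces the rest lengths of all remaining inter-subunit bonds of the
#' filament with those solved for the new target radius; stiffness is
#' unchanged. Used by the protocol engine to constrict the Tight Helix at a
#' fixed rate.
#'
#' @param sys an `escrt_system`.
#' @param fil_id filament index.
#' @param R_new new target radius (sigma, > 0).
#' @return the updated system.
#' @export
update_target_geometry <- function(sys, fil_id, R_new) {
  stopifnot(R_new > 0)
  f <- sys$filaments[[fil_id]]
  g <- f$geometry
  if (R_new == g$radius) return(sys)
  g$radius <- R_new
  rl <- solve_rest_lengths(g)
  rows <- which(!is.na(sys$bonds[, "fil"]) & sys$bonds[, "fil"] == fil_id &
                  sys$bonds[, "spair"] > 0)
  if (length(rows)) {
    # bonds were laid down in expand.grid(r = 1:3, c = 1:3) order per pair
    role <- rep(rl[cbind(rep(1:3, 3), rep(1:3, each = 3))],
                length.out = length(rows))
    sys$bonds[rows, "r0"] <- role
  }
  sys$filaments[[fil_id]]$geometry <- g
  sys
}

#' Sever subunits of a filament
#'
#' Removes every inter-subunit bond touching the named subunits and, unless
#' `retain_adhesion` is set, switches off their membrane and lateral
#' attraction so they become purely volume-excluded diffusing particles.
#' Intra-subunit triangle bonds are kept (a severed subunit stays one rigid
#' particle). With `remove = TRUE` the severed subunits are deleted from the
#' simulation box instead of being left to diffuse. Other filaments and the
#' membrane are untouched either way.
#'
#' @param sys an `escrt_system`.
#' @param fil_id filament index.
#' @param subunits integer subunit indices to sever.
#' @param retain_adhesion keep the membrane attraction of severed subunits.
#' @param remove delete the severed subunits' beads from the box.
#' @return the updated system.
#' @export
sever_subunits <- function(sys, fil_id, subunits, retain_adhesion = FALSE,
                           remove = FALSE) {
  f <- sys$filaments[[fil_id]]
  subunits <- subunits[f$active[subunits]]
  if (!length(subunits)) return(sys)
  pairs <- unique(c(subunits - 1L, subunits))
  pairs <- pairs[pairs >= 1L & pairs <= f$n_subunits - 1L]
  drop <- !is.na(sys$bonds[, "fil"]) & sys$bonds[, "fil"] == fil_id &
    sys$bonds[, "spair"] %in% pairs
  sys$bonds <- sys$bonds[!drop, , drop = FALSE]
  if (!retain_adhesion)
    for (s in subunits) sys$adh[subunit_beads(sys, fil_id, s)] <- 0
  sys$filaments[[fil_id]]$active[subunits] <- FALSE
  if (remove) {
    gone <- unlist(lapply(subunits, function(s)
      subunit_beads(sys, fil_id, s)))
    sys <- delete_beads(sys, gone)
  }
  sys
}

# delete beads and remap all indices (bonds, filament bead lists, cargo)
delete_beads <- function(sys, idx) {
  idx <- sort(unique(idx))
  keep <- setdiff(seq_len(n_beads(sys)), idx)
  remap <- integer(n_beads(sys))
  remap[keep] <- seq_along(keep)
  dropb <- sys$bonds[, "i"] %in% idx | sys$bonds[, "j"] %in% idx
  sys$bonds <- sys$bonds[!dropb, , drop = FALSE]
  sys$bonds[, "i"] <- remap[sys$bonds[, "i"]]
  sys$bonds[, "j"] <- remap[sys$bonds[, "j"]]
  for (m in c("pos", "axis", "vel", "avel"))
    sys[[m]] <- sys[[m]][keep, , drop = FALSE]
  for (m in c("type", "fil", "adh"))
    sys[[m]] <- sys[[m]][keep]
  for (i in seq_along(sys$filaments)) {
    b <- sys$filaments[[i]]$beads
    # deleted subunits keep a zero placeholder so subunit numbering is stable
    nb <- integer(length(b))
    live <- b > 0L & !(b %in% idx)
    nb[live] <- remap[b[live]]
    sys$filaments[[i]]$beads <- nb
  }
  if (!is.null(sys$cargo))
    sys$cargo$beads <- remap[sys$cargo$beads]
  sys
}

#' Create and place cargo
#'
#' Either one large adhesive sphere or several small spheres. Cargo beads
#' interact with the membrane through a short-ranged attraction of strength
#' `adhesion` (0 = volume exclusion only) acting between the cargo surface
#' and membrane beads.
#'
#' @param sys an `escrt_system`.
#' @param radius cargo radius in sigma (> 0).
#' @param adhesion cargo-membrane adhesion strength in kBT.
#' @param n number of cargo spheres (1 = single large cargo).
#' @param center in-plane placement (defaults to box centre).
#' @param gap initial gap between cargo surface and membrane plane.
#' @return the updated system.
#' @export
add_cargo <- function(sys, radius = sys$params$cargo_radius, adhesion = sys$params$eps_cm,
                      n = 1, center = NULL, gap = 0.3) {
  stopifnot(radius > 0, n >= 1)
  if (is.null(center)) center <- sys$box[1:2] / 2
  zmem <- stats::median(sys$pos[sys$type == 1L, 3])
  z <- zmem + radius + sys$params$rmin_cm + gap - 0.5
  if (n == 1) {
    pos <- matrix(c(center, z), 1, 3)
  } else {
    ang <- 2 * pi * (seq_len(n) - 1) / n
    ring <- 2.2 * radius
    pos <- cbind(center[1] + ring * cos(ang), center[2] + ring * sin(ang), z)
  }
  off <- n_beads(sys)
  sys$pos <- rbind(sys$pos, pos)
  sys$axis <- rbind(sys$axis, matrix(rep(c(0, 0, 1), each = n), n, 3))
  sys$vel <- rbind(sys$vel, matrix(0, n, 3))
  sys$avel <- rbind(sys$avel, matrix(0, n, 3))
  sys$type <- c(sys$type, rep(4L, n))
  sys$fil <- c(sys$fil, rep(0L, n))
  sys$adh <- c(sys$adh, rep(1, n))
  sys$params$cargo_radius <- radius
  sys$params$eps_cm <- adhesion
  sys$cargo <- list(mode = if (n == 1) "single" else "multi",
                    radius = radius, adhesion = adhesion,
                    beads = off + seq_len(n))
  sys
}
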