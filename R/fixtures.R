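#' Synthetic analysis snapshots
#'
#' Analytically constructed membrane configurations used as fixtures for the
#' observable estimators: a flat sheet, a capped cylinder (tubule), a cone of
#' given half-angle, a flat plane plus a detached closed vesicle, and a flat
#' lattice with circular pores punched out. Each snapshot carries positions,
#' outward orientation axes, a box, and a `periodic` flag.
#'
#' @param case one of `"flat"`, `"cone"`, `"cylinder"`, `"plane_vesicle"`,
#'   `"pore_lattice"`.
#' @param n lattice dimension of the base sheet.
#' @param spacing lattice spacing (sigma).
#' @param half_angle cone half-angle in degrees (case `"cone"`).
#' @param depth deformation depth in sigma (cone and cylinder).
#' @param tube_radius cylinder radius (sigma).
#' @param vesicle_radius radius of the detached vesicle (sigma).
#' @param pore_centers matrix of in-plane pore centres (one row each), or
#'   NULL for a single centred pore.
#' @param pore_radius pore radius in sigma.
#' @return snapshot list with `pos`, `axis`, `box`, `periodic`, and
#'   case-specific extras (e.g. `cargo_pos`, `vesicle_beads`).
#' @export
synthetic_snapshot <- function(case = c("flat", "cone", "cylinder",
                                        "plane_vesicle", "pore_lattice"),
                               n = 30, spacing = 1.15, half_angle = 45,
                               depth = 14, tube_radius = 4,
                               vesicle_radius = 4,
                               pore_centers = NULL, pore_radius = 2) {
  case <- match.arg(case)
  dy <- spacing * sqrt(3) / 2
  ix <- rep(seq_len(n) - 1L, times = n)
  iy <- rep(seq_len(n) - 1L, each = n)
  x <- (ix + 0.5 * (iy %% 2)) * spacing
  y <- iy * dy
  box <- c(n * spacing, n * dy, 4 * depth + 20)
  ctr <- box[1:2] / 2
  pos <- cbind(x, y, 0)
  axis <- matrix(rep(c(0, 0, 1), each = nrow(pos)), ncol = 3)
  out <- list(box = box, periodic = TRUE)

  if (case == "flat") {
    out$pos <- pos; out$axis <- axis
    return(out)
  }
  if (case == "cone") {
    # indentation: cone apex at depth below the plane, slope set by the
    # half-angle (angle between cone wall and the vertical axis)
    alpha <- half_angle * pi / 180
    rmax <- depth * tan(alpha)
    r <- sqrt((pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2)
    inside <- r < rmax
    pos[inside, 3] <- -(rmax - r[inside]) / tan(alpha)
    # outward (upper-side) normal of the cone wall
    ur <- cbind((pos[, 1] - ctr[1]) / pmax(r, 1e-9),
                (pos[, 2] - ctr[2]) / pmax(r, 1e-9))
    wall <- inside & r > 1e-6
    axis[wall, 1] <- -cos(alpha) * ur[wall, 1]
    axis[wall, 2] <- -cos(alpha) * ur[wall, 2]
    axis[wall, 3] <- sin(alpha)
    out$pos <- pos; out$axis <- axis
    return(out)
  }
  if (case == "cylinder") {
    # vertical tube of radius tube_radius descending from the plane, capped
    # by a hemispherical tip
    r <- sqrt((pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2)
    keep <- r >= tube_radius
    plane_pos <- pos[keep, , drop = FALSE]
    plane_axis <- axis[keep, , drop = FALSE]
    nz <- ceiling(depth / spacing)
    nphi <- max(8, round(2 * pi * tube_radius / spacing))
    phi <- rep(2 * pi * (seq_len(nphi) - 1) / nphi, times = nz)
    zz <- rep(-spacing * seq_len(nz), each = nphi)
    tube_pos <- cbind(ctr[1] + tube_radius * cos(phi),
                      ctr[2] + tube_radius * sin(phi), zz)
    tube_axis <- cbind(-cos(phi), -sin(phi), 0) # outward = into the tube? no:
    # upper-side surface normal of the invagination points inward
    cap <- cbind(ctr[1], ctr[2], -spacing * nz - tube_radius / 2)
    out$pos <- rbind(plane_pos, tube_pos, cap)
    out$axis <- rbind(plane_axis, tube_axis, c(0, 0, 1))
    return(out)
  }
  if (case == "plane_vesicle") {
    zv <- -3 * vesicle_radius
    npts <- max(60, round(4 * pi * vesicle_radius^2 / (spacing^2 * 0.9)))
    gold <- pi * (3 - sqrt(5))
    k <- seq_len(npts)
    zs <- 1 - 2 * (k - 0.5) / npts
    rs <- sqrt(pmax(0, 1 - zs^2))
    th <- gold * k
    ves <- cbind(ctr[1] + vesicle_radius * rs * cos(th),
                 ctr[2] + vesicle_radius * rs * sin(th),
                 zv + vesicle_radius * zs)
    ves_axis <- (ves - matrix(c(ctr[1], ctr[2], zv), npts, 3, byrow = TRUE)) /
      vesicle_radius
    out$pos <- rbind(pos, ves)
    out$axis <- rbind(axis, ves_axis)
    out$vesicle_beads <- nrow(pos) + seq_len(npts)
    out$cargo_pos <- c(ctr, zv)
    return(out)
  }
  # pore_lattice
  if (is.null(pore_centers)) pore_centers <- matrix(ctr, 1, 2)
  keep <- rep(TRUE, nrow(pos))
  for (r in seq_len(nrow(pore_centers)))
    keep <- keep & (sqrt((pos[, 1] - pore_centers[r, 1])^2 +
                           (pos[, 2] - pore_centers[r, 2])^2) > pore_radius)
  out$pos <- pos[keep, , drop = FALSE]
  out$axis <- axis[keep, , drop = FALSE]
  out$pore_centers <- pore_centers
  out
}
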