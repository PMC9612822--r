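## Observables: deformation angle, connectivity, scission/pore detection,
## energy profiles, copolymer stability, subunit partitioning.

# extract membrane positions/axes/box from an escrt_system or a frame list
as_snapshot <- function(x) {
  if (inherits(x, "escrt_system"))
    return(list(pos = x$pos[x$type == 1L, , drop = FALSE],
                axis = x$axis[x$type == 1L, , drop = FALSE],
                box = x$box, periodic = TRUE))
  if (is.list(x) && !is.null(x$pos))
    return(list(pos = x$pos, axis = x$axis, box = x$box,
                periodic = isTRUE(x$periodic) || is.null(x$periodic)))
  stop("cannot interpret snapshot")
}

#' Membrane deformation angle
#'
#' The angle between the vertical axis (the normal of the original flat
#' membrane plane) and the membrane surface normal at half depth of the
#' deformation. The reference plane height is the mean height of the
#' peripheral beads (the outer 20% by in-plane distance from the deformation
#' centre); depth is the distance from that plane to the lowest bead. Beads
#' within a slab of `slab` sigma around half depth contribute their
#' orientation axes; the reported angle is the mean per-bead angle between
#' axis and vertical, so a flat sheet gives 0, a cylindrical tubule wall 90,
#' and a cone of half-angle alpha gives 90 - alpha. Membranes whose depth is
#' below `noise_floor` (thermal roughness) are reported as flat, theta = 0.
#'
#' @param x an `escrt_system` or a snapshot list with `pos`, `axis`, `box`.
#' @param slab half-depth slab thickness (sigma).
#' @param noise_floor depth below which the membrane counts as flat (sigma).
#' @return deformation angle theta in degrees, in `[0, 90]`.
#' @export
deformation_angle <- function(x, slab = 2, noise_floor = 2) {
  sn <- as_snapshot(x)
  pos <- sn$pos; axis <- sn$axis
  if (is.null(axis)) stop("snapshot carries no orientation axes")
  zmin_i <- which.min(pos[, 3])
  centre <- pos[zmin_i, 1:2]
  dx <- pos[, 1] - centre[1]; dy <- pos[, 2] - centre[2]
  if (sn$periodic) {
    dx <- dx - sn$box[1] * round(dx / sn$box[1])
    dy <- dy - sn$box[2] * round(dy / sn$box[2])
  }
  rin <- sqrt(dx^2 + dy^2)
  peri <- rin >= stats::quantile(rin, 0.8)
  z_ref <- mean(pos[peri, 3])
  depth <- z_ref - min(pos[, 3])
  if (depth < noise_floor) return(0)
  z_half <- z_ref - depth / 2
  in_slab <- abs(pos[, 3] - z_half) <= slab / 2
  if (sum(in_slab) < 10)
    stop("fewer than 10 beads in the half-depth slab (", sum(in_slab), ")")
  ax <- axis[in_slab, , drop = FALSE]
  ang <- acos(pmin(1, abs(ax[, 3]) / sqrt(rowSums(ax^2)))) * 180 / pi
  min(mean(ang), 90)
}

#' Connected components of the membrane proximity graph
#'
#' Builds the graph of membrane beads closer than `cutoff` (with periodic
#' in-plane wrapping) and returns its connected components with deterministic
#' labels: components are numbered by their smallest member bead index.
#'
#' @param x an `escrt_system` or snapshot.
#' @param cutoff proximity cutoff; defaults to the membrane interaction
#'   cutoff.
#' @return list with `membership` (integer vector over membrane beads),
#'   `n_components`, `sizes`, and `edges` (the wrapped-edge flags used by
#'   [detect_scission()]).
#' @export
membrane_components <- function(x, cutoff = NULL) {
  sn <- as_snapshot(x)
  if (is.null(cutoff))
    cutoff <- if (inherits(x, "escrt_system")) x$params$rc_mm else 2.6
  pos <- sn$pos; box <- sn$box
  n <- nrow(pos)
  pairs <- vector("list", n)
  wrapped <- vector("list", n)
  for (i in seq_len(max(n - 1, 0))) {
    dx0 <- pos[(i + 1):n, 1] - pos[i, 1]
    dy0 <- pos[(i + 1):n, 2] - pos[i, 2]
    dz <- pos[(i + 1):n, 3] - pos[i, 3]
    dx <- dx0; dy <- dy0
    if (sn$periodic) {
      dx <- dx - box[1] * round(dx / box[1])
      dy <- dy - box[2] * round(dy / box[2])
    }
    hit <- which(dx^2 + dy^2 + dz^2 < cutoff^2)
    if (length(hit)) {
      pairs[[i]] <- cbind(i, hit + i)
      wrapped[[i]] <- (abs(dx0[hit] - dx[hit]) > 1e-9) |
        (abs(dy0[hit] - dy[hit]) > 1e-9)
    }
  }
  edges <- do.call(rbind, pairs[!vapply(pairs, is.null, TRUE)])
  wflag <- unlist(wrapped)
  g <- igraph::graph_from_edgelist(
    if (is.null(edges)) matrix(0L, 0, 2) else edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - ifelse(is.null(edges), 0, igraph::vcount(g))))
  cmp <- igraph::components(g)
  memb <- cmp$membership[seq_len(n)]
  # deterministic labels: order components by smallest member index
  first <- tapply(seq_len(n), memb, min)
  relab <- rank(first)
  memb <- as.integer(relab[as.character(memb)])
  sizes <- as.integer(table(memb))
  list(membership = memb, n_components = max(memb), sizes = sizes,
       edges = edges, wrapped = wflag)
}

#' Detect membrane scission
#'
#' Scission is called when the membrane splits into at least two components,
#' the component nearest the cargo is disjoint from the component that spans
#' the periodic boundaries (the mother membrane), and the vesicle component
#' is closed: every bead has at least `min_neighbors` neighbours within the
#' cutoff, and the beads cover all directions around the component centroid
#' (an open cup leaves an uncovered cap and is not a vesicle).
#'
#' @param x an `escrt_system` or snapshot.
#' @param cargo_pos cargo position (length-3); taken from the system if
#'   omitted.
#' @param cutoff proximity cutoff.
#' @param min_neighbors closure criterion.
#' @return list with `scission` (logical), `vesicle` (bead indices within the
#'   membrane subset, or NULL) and the component structure.
#' @export
detect_scission <- function(x, cargo_pos = NULL, cutoff = NULL,
                            min_neighbors = 3) {
  sn <- as_snapshot(x)
  if (is.null(cargo_pos) && inherits(x, "escrt_system") && !is.null(x$cargo))
    cargo_pos <- colMeans(x$pos[x$cargo$beads, , drop = FALSE])
  if (is.null(cargo_pos)) stop("cargo position required for scission calls")
  if (is.null(cutoff))
    cutoff <- if (inherits(x, "escrt_system")) x$params$rc_mm else 2.6
  cmp <- membrane_components(x, cutoff)
  out <- list(scission = FALSE, vesicle = NULL, components = cmp)
  if (cmp$n_components < 2) return(out)
  pos <- sn$pos; box <- sn$box
  # Components spanning the periodic boundaries: unwrap each component by a
  # BFS over its proximity edges using minimum-image displacements; if any
  # edge is inconsistent with the unwrapped coordinates the component wraps
  # around the box (percolation test). Compact clusters never span, whatever
  # their raw (unwrapped trajectory) coordinates look like.
  spanning <- integer(0)
  if (!is.null(cmp$edges)) {
    u <- matrix(NA_real_, nrow(pos), 2)
    adj <- vector("list", nrow(pos))
    for (r in seq_len(nrow(cmp$edges))) {
      i <- cmp$edges[r, 1]; j <- cmp$edges[r, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
    for (comp in seq_len(cmp$n_components)) {
      members <- which(cmp$membership == comp)
      root <- members[1]
      u[root, ] <- pos[root, 1:2]
      queue <- root
      while (length(queue)) {
        i <- queue[[1]]; queue <- queue[-1]
        for (j in adj[[i]]) {
          if (!is.na(u[j, 1])) next
          d <- pos[j, 1:2] - pos[i, 1:2]
          d <- d - box[1:2] * round(d / box[1:2])
          u[j, ] <- u[i, ] + d
          queue <- c(queue, j)
        }
      }
      spans <- FALSE
      for (i in members) for (j in adj[[i]]) {
        d <- pos[j, 1:2] - pos[i, 1:2]
        d <- d - box[1:2] * round(d / box[1:2])
        if (any(abs((u[j, ] - u[i, ]) - d) > 0.5 * box[1:2])) { spans <- TRUE; break }
      }
      if (spans) spanning <- c(spanning, comp)
    }
  }
  # component nearest the cargo (min bead distance)
  dx <- pos[, 1] - cargo_pos[1]; dy <- pos[, 2] - cargo_pos[2]
  dx <- dx - box[1] * round(dx / box[1]); dy <- dy - box[2] * round(dy / box[2])
  d2 <- dx^2 + dy^2 + (pos[, 3] - cargo_pos[3])^2
  near_comp <- cmp$membership[which.min(d2)]
  if (near_comp %in% spanning) return(out)
  ves <- which(cmp$membership == near_comp)
  # closure: neighbour count within the vesicle component
  vp <- pos[ves, , drop = FALSE]
  nv <- nrow(vp)
  if (nv < 4) return(out)
  deg <- integer(nv)
  for (i in seq_len(nv)) {
    dxx <- vp[, 1] - vp[i, 1]; dyy <- vp[, 2] - vp[i, 2]; dzz <- vp[, 3] - vp[i, 3]
    dxx <- dxx - box[1] * round(dxx / box[1]); dyy <- dyy - box[2] * round(dyy / box[2])
    deg[i] <- sum(dxx^2 + dyy^2 + dzz^2 < cutoff^2) - 1L
  }
  if (!all(deg >= min_neighbors)) return(out)
  # directional coverage: every probe direction from the centroid must be
  # within 30 degrees of some bead direction
  ctr <- colMeans(vp)
  uu <- sweep(vp, 2, ctr)
  uu <- uu / pmax(sqrt(rowSums(uu^2)), 1e-9)
  k <- seq_len(64)
  zs <- 1 - 2 * (k - 0.5) / 64
  rs <- sqrt(pmax(0, 1 - zs^2))
  th <- pi * (3 - sqrt(5)) * k
  probes <- cbind(rs * cos(th), rs * sin(th), zs)
  cover <- apply(probes %*% t(uu), 1, max)
  if (all(cover >= cos(30 * pi / 180))) {
    out$scission <- TRUE
    out$vesicle <- ves
  }
  out
}

#' Detect membrane pores
#'
#' Pores are rings of under-coordinated membrane beads (neighbour count below
#' `coord_threshold`) forming closed loops that are not on the outer boundary
#' of a non-periodic patch. Under-coordinated beads are clustered by
#' proximity; a cluster is a pore ring if it has at least `min_ring` members
#' and each member touches at least two others in the cluster (a loop). For
#' non-periodic patches, clusters containing beads within `cutoff` of the
#' bounding box of the sheet are discarded as outer boundary.
#'
#' @param x an `escrt_system` or a snapshot; set `periodic = FALSE` in a
#'   snapshot for open patches.
#' @param cutoff neighbour cutoff (defaults to the membrane cutoff).
#' @param coord_threshold beads with fewer neighbours than this are
#'   under-coordinated (triangular lattice interior has 6).
#' @return data.frame with one row per pore: centroid coordinates, ring size
#'   and estimated ring length (perimeter).
#' @export
detect_pores <- function(x, cutoff = NULL, coord_threshold = 5) {
  sn <- as_snapshot(x)
  if (is.null(cutoff))
    cutoff <- if (inherits(x, "escrt_system")) 1.5 * x$params$rmin_mm else 1.7
  pos <- sn$pos; box <- sn$box
  n <- nrow(pos)
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      n_beads = integer(0), ring_length = numeric(0))
  # coordination numbers
  deg <- integer(n)
  adj <- vector("list", n)
  for (i in seq_len(n - 1)) {
    dx <- pos[(i + 1):n, 1] - pos[i, 1]
    dy <- pos[(i + 1):n, 2] - pos[i, 2]
    dz <- pos[(i + 1):n, 3] - pos[i, 3]
    if (sn$periodic) {
      dx <- dx - box[1] * round(dx / box[1])
      dy <- dy - box[2] * round(dy / box[2])
    }
    hit <- which(dx^2 + dy^2 + dz^2 < cutoff^2) + i
    for (j in hit) { adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i) }
  }
  deg <- lengths(adj)
  uc <- which(deg < coord_threshold)
  if (!length(uc)) return(empty)
  if (!sn$periodic) {
    # outer boundary beads of an open patch
    mar <- cutoff
    onb <- pos[uc, 1] < min(pos[, 1]) + mar | pos[uc, 1] > max(pos[, 1]) - mar |
           pos[uc, 2] < min(pos[, 2]) + mar | pos[uc, 2] > max(pos[, 2]) - mar
  } else onb <- rep(FALSE, length(uc))
  # cluster under-coordinated beads by proximity (slightly larger linkage)
  link <- 1.6 * cutoff
  m <- length(uc)
  up <- pos[uc, , drop = FALSE]
  ed <- list()
  for (i in seq_len(max(m - 1, 0))) {
    dx <- up[(i + 1):m, 1] - up[i, 1]
    dy <- up[(i + 1):m, 2] - up[i, 2]
    dz <- up[(i + 1):m, 3] - up[i, 3]
    if (sn$periodic) {
      dx <- dx - box[1] * round(dx / box[1])
      dy <- dy - box[2] * round(dy / box[2])
    }
    hit <- which(dx^2 + dy^2 + dz^2 < link^2)
    if (length(hit)) ed[[length(ed) + 1]] <- cbind(i, hit + i)
  }
  edges <- if (length(ed)) do.call(rbind, ed) else matrix(0L, 0, 2)
  g <- igraph::make_empty_graph(m, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  pores <- empty
  for (cl in unique(memb)) {
    members <- which(memb == cl)
    if (any(onb[members])) next           # outer boundary, not a pore
    if (length(members) < 4) next
    # loop criterion: every member has >= 2 cluster neighbours
    degc <- vapply(members, function(i)
      sum(edges[, 1] == i | edges[, 2] == i), 0L)
    if (any(degc < 2)) next
    mp <- up[members, , drop = FALSE]
    ctr <- colMeans(mp)
    # perimeter estimate: order by angle around the centroid in the local
    # best-fit plane and sum consecutive spacings
    cc <- sweep(mp, 2, ctr)
    pcv <- svd(cc)$v
    xy <- cc %*% pcv[, 1:2]
    o <- order(atan2(xy[, 2], xy[, 1]))
    ring <- mp[o, , drop = FALSE]
    per <- sum(sqrt(rowSums((ring - ring[c(2:nrow(ring), 1), ])^2)))
    pores <- rbind(pores, data.frame(x = ctr[1], y = ctr[2], z = ctr[3],
                                     n_beads = length(members),
                                     ring_length = per))
  }
  pores
}

#' Per-filament membrane binding fraction
#'
#' Fraction of a filament's active membrane-binding beads that lie within the
#' binding attraction cutoff of at least one membrane bead.
#'
#' @param sys an `escrt_system`.
#' @param fil_id filament index.
#' @param cutoff binding cutoff; defaults to `rc_bm`.
#' @return fraction in `[0, 1]` (NA if the filament has no active subunits).
#' @export
binding_fraction <- function(sys, fil_id, cutoff = sys$params$rc_bm) {
  f <- sys$filaments[[fil_id]]
  act <- which(f$active)
  if (!length(act)) return(NA_real_)
  bind <- unlist(lapply(act, function(s) subunit_beads(sys, fil_id, s)[1:2]))
  mem <- sys$pos[sys$type == 1L, , drop = FALSE]
  box <- sys$box
  ok <- vapply(bind, function(b) {
    dx <- mem[, 1] - sys$pos[b, 1]; dy <- mem[, 2] - sys$pos[b, 2]
    dx <- dx - box[1] * round(dx / box[1]); dy <- dy - box[2] * round(dy / box[2])
    any(dx^2 + dy^2 + (mem[, 3] - sys$pos[b, 3])^2 < cutoff^2)
  }, TRUE)
  mean(ok)
}

#' Copolymer stability over a batch of final snapshots
#'
#' The fraction of replicas in which both copolymerising filaments remain
#' attached to the membrane: each filament's binding fraction must be at
#' least `attach_threshold` at the end of the run.
#'
#' @param batch list of final `escrt_system`s, or a list of per-replica
#'   binding-fraction vectors.
#' @param attach_threshold minimum binding fraction counting as attached.
#' @return fraction in `[0, 1]`.
#' @export
copolymer_stability <- function(batch, attach_threshold = 0.5) {
  stopifnot(length(batch) >= 1)
  attached <- vapply(batch, function(b) {
    bf <- if (inherits(b, "escrt_system"))
      vapply(seq_along(b$filaments), function(i) binding_fraction(b, i), 0)
    else as.numeric(b)
    all(bf >= attach_threshold)
  }, TRUE)
  mean(attached)
}

#' Fraction of final-helix subunits in the budded vesicle
#'
#' After a detected scission, the fraction of the filament's subunits whose
#' centroid is nearer to the vesicle membrane component than to the mother
#' component.
#'
#' @param sys an `escrt_system` after scission.
#' @param fil_id filament index (the final, disassembled helix).
#' @param scission result of [detect_scission()]; recomputed if omitted.
#' @return fraction in `[0, 1]`.
#' @export
subunit_partition <- function(sys, fil_id, scission = NULL) {
  if (is.null(scission)) scission <- detect_scission(sys)
  if (!isTRUE(scission$scission))
    stop("subunit_partition called without a detected scission")
  mem_idx <- which(sys$type == 1L)
  mem <- sys$pos[mem_idx, , drop = FALSE]
  ves <- scission$vesicle
  box <- sys$box
  f <- sys$filaments[[fil_id]]
  present <- which(vapply(seq_len(f$n_subunits), function(s)
    all(subunit_beads(sys, fil_id, s) > 0L), TRUE))
  if (!length(present))
    stop("all subunits of filament ", fil_id, " were removed from the box")
  frac <- vapply(present, function(s) {
    ctr <- colMeans(sys$pos[subunit_beads(sys, fil_id, s), , drop = FALSE])
    dx <- mem[, 1] - ctr[1]; dy <- mem[, 2] - ctr[2]
    dx <- dx - box[1] * round(dx / box[1]); dy <- dy - box[2] * round(dy / box[2])
    d2 <- dx^2 + dy^2 + (mem[, 3] - ctr[3])^2
    in_ves <- seq_len(nrow(mem)) %in% ves
    min(d2[in_ves]) < min(d2[!in_ves])
  }, TRUE)
  mean(frac)
}

#' Local potential-energy profile along the neck axis
#'
#' Per-bead membrane energy (membrane pair terms plus the membrane share of
#' filament-membrane and cargo-membrane adhesion), relative to the flat
#' membrane per-bead baseline, binned by height with bin width `bin_width`
#' and averaged over the supplied snapshots.
#'
#' @param snapshots list of `escrt_system`s (e.g. consecutive trajectory
#'   states).
#' @param baseline flat-membrane per-bead energy; computed from the first
#'   snapshot's parameters on a dedicated flat reference if NULL is given a
#'   numeric value is expected.
#' @param bin_width bin width in sigma.
#' @return data.frame with bin centre `z`, mean excess energy per bead, and
#'   bead counts; empty bins are absent (not zero).
#' @export
local_energy_profile <- function(snapshots, baseline, bin_width = 1) {
  stopifnot(length(snapshots) >= 1, is.numeric(baseline))
  acc <- list()
  for (sys in snapshots) {
    repx <- energy_report(sys)
    mem <- sys$type == 1L
    e <- repx$per_bead[mem]
    z <- sys$pos[mem, 3]
    acc[[length(acc) + 1]] <- data.frame(z = z, e = e)
  }
  d <- do.call(rbind, acc)
  bin <- floor(d$z / bin_width)
  agg <- stats::aggregate(d$e, list(bin = bin), mean)
  cnt <- as.integer(table(bin))
  data.frame(z = (agg$bin + 0.5) * bin_width,
             energy = agg$x - baseline,
             n = cnt)
}

#' Flat-membrane per-bead baseline energy
#'
#' Mean per-bead potential energy of an equilibrated flat patch at the given
#' parameters; used as the reference for [local_energy_profile()].
#'
#' @param params parameter set.
#' @param nx patch dimension.
#' @param n_steps equilibration steps.
#' @param seed RNG seed.
#' @return scalar energy per bead (kBT).
#' @export
flat_baseline_energy <- function(params = default_params(), nx = 16,
                                 n_steps = 10000, seed = 1) {
  sys <- build_flat_patch(nx, nx, spacing = 1.18, params = params)
  sys <- integrate_system(sys, n_steps, seed = seed, barostat = TRUE)
  repx <- energy_report(sys)
  mean(repx$per_bead[sys$type == 1L])
}

#' Pore formation energy per unit area
#'
#' Excess system potential energy at pore opening relative to the pre-pore
#' state, divided by the opened pore area, converted to kBT/nm^2.
#'
#' @param delta_energy energy step(s) at pore opening, kBT.
#' @param pore_area opened area(s), nm^2.
#' @return energy per unit area in kBT/nm^2 (vectorised; mean over events).
#' @export
pore_formation_energy <- function(delta_energy, pore_area) {
  if (!length(delta_energy)) stop("no pore events supplied")
  stopifnot(length(delta_energy) == length(pore_area), all(pore_area > 0))
  mean(delta_energy / pore_area)
}

#' Least-squares circle fit
#'
#' Fits a plane through the points (principal components), projects onto it,
#' and performs an algebraic (Kasa) circle fit. Used to measure the relaxed
#' radius of a free filament.
#'
#' @param pts n x 3 matrix of points.
#' @return list with `radius`, `center` (3D) and the in-plane RMS residual.
#' @export
fit_circle <- function(pts) {
  stopifnot(nrow(pts) >= 3)
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2, ctr)
  v <- svd(cc)$v
  xy <- cc %*% v[, 1:2]
  # Kasa: minimise |x^2 + y^2 - 2ax - 2by - c|
  A <- cbind(2 * xy[, 1], 2 * xy[, 2], 1)
  b <- xy[, 1]^2 + xy[, 2]^2
  sol <- qr.solve(A, b)
  r <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
  resid <- sqrt(mean((sqrt((xy[, 1] - sol[1])^2 + (xy[, 2] - sol[2])^2) - r)^2))
  center3 <- ctr + v[, 1] * sol[1] + v[, 2] * sol[2]
  list(radius = unname(r), center = center3, rms = resid)
}
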