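test_that("deformation angle is 0 for flat, 90 for tubule, 90-alpha for cones", {
  flat <- synthetic_snapshot("flat")
  expect_equal(deformation_angle(flat), 0)
  cyl <- synthetic_snapshot("cylinder", depth = 16, tube_radius = 5)
  expect_lt(abs(deformation_angle(cyl) - 90), 2)
  for (alpha in c(30, 45, 60)) {
    cone <- synthetic_snapshot("cone", half_angle = alpha, depth = 12)
    expect_lt(abs(deformation_angle(cone) - (90 - alpha)), 2)
  }
})

test_that("deformation angle is invariant under rigid in-plane motions", {
  cone <- synthetic_snapshot("cone", half_angle = 40, depth = 12)
  th0 <- deformation_angle(cone)
  # translation (periodic wrap)
  tr <- cone
  tr$pos[, 1] <- (tr$pos[, 1] + 7.3) %% tr$box[1]
  tr$pos[, 2] <- (tr$pos[, 2] + 3.1) %% tr$box[2]
  expect_equal(deformation_angle(tr), th0, tolerance = 1e-6)
  # in-plane rotation about the deformation centre (non-periodic analysis ok:
  # rotate positions and axes about the box centre by 90 degrees)
  rot <- cone
  ctr <- cone$box[1:2] / 2
  x <- rot$pos[, 1] - ctr[1]; y <- rot$pos[, 2] - ctr[2]
  rot$pos[, 1] <- -y + ctr[1]; rot$pos[, 2] <- x + ctr[2]
  ax <- rot$axis
  rot$axis[, 1] <- -ax[, 2]; rot$axis[, 2] <- ax[, 1]
  expect_equal(deformation_angle(rot), th0, tolerance = 1e-6)
})

test_that("half-depth slab with too few beads is an error", {
  # sparse deep spike: almost no beads near half depth
  sn <- synthetic_snapshot("flat", n = 12)
  sn$pos[1, 3] <- -40
  expect_error(deformation_angle(sn, noise_floor = 1), "fewer than 10")
})

test_that("connected components match a brute-force flood fill", {
  set.seed(21)
  for (rep in 1:2) {
    # random clustered points: a few blobs, some touching
    n <- 500
    ctrs <- matrix(runif(10 * 2, 5, 45), 10, 2)
    pts <- ctrs[sample(10, n, replace = TRUE), ] +
      matrix(rnorm(n * 2, 0, 1.2), n, 2)
    pos <- cbind(pts %% 50, runif(n, 0, 2))
    snap <- list(pos = pos, axis = NULL, box = c(50, 50, 20), periodic = TRUE)
    cutoff <- 1.8
    got <- membrane_components(snap, cutoff)$membership
    # flood fill oracle
    lab <- integer(n)
    cur <- 0L
    for (s in seq_len(n)) {
      if (lab[s]) next
      cur <- cur + 1L
      queue <- s
      while (length(queue)) {
        i <- queue[[1]]; queue <- queue[-1]
        if (lab[i]) next
        lab[i] <- cur
        dx <- pos[, 1] - pos[i, 1]; dy <- pos[, 2] - pos[i, 2]
        dx <- dx - 50 * round(dx / 50); dy <- dy - 50 * round(dy / 50)
        nb <- which(dx^2 + dy^2 + (pos[, 3] - pos[i, 3])^2 < cutoff^2 & !lab)
        queue <- c(queue, nb)
      }
    }
    # same partition (labels both deterministic smallest-first)
    expect_equal(got, lab)
    # permutation invariance of the partition
    perm <- sample(n)
    snap2 <- list(pos = pos[perm, ], axis = NULL, box = c(50, 50, 20),
                  periodic = TRUE)
    got2 <- membrane_components(snap2, cutoff)$membership
    agree <- vapply(seq_len(n - 1), function(i)
      (got[perm[i]] == got[perm[i + 1]]) == (got2[i] == got2[i + 1]), TRUE)
    expect_true(all(agree))
  }
})

test_that("scission detection requires a detached closed vesicle", {
  flat <- synthetic_snapshot("flat")
  expect_false(detect_scission(flat, cargo_pos = c(15, 15, -5),
                               cutoff = 1.8)$scission)
  pv <- synthetic_snapshot("plane_vesicle", vesicle_radius = 4)
  res <- detect_scission(pv, cargo_pos = pv$cargo_pos, cutoff = 1.8)
  expect_true(res$scission)
  expect_setequal(res$vesicle, pv$vesicle_beads)
  # open cup (half vesicle) is not closed -> no scission
  cup <- pv
  keep <- seq_len(nrow(pv$pos))
  cupbead <- pv$vesicle_beads[pv$pos[pv$vesicle_beads, 3] >
                                pv$cargo_pos[3]]
  keep <- setdiff(keep, cupbead)
  cup$pos <- pv$pos[keep, , drop = FALSE]
  cup$axis <- pv$axis[keep, , drop = FALSE]
  expect_false(detect_scission(cup, cargo_pos = pv$cargo_pos,
                               cutoff = 1.8)$scission)
})

test_that("scission calls are monotone under extra neck-bead deletion", {
  pv <- synthetic_snapshot("plane_vesicle", vesicle_radius = 4)
  res <- detect_scission(pv, cargo_pos = pv$cargo_pos, cutoff = 1.8)
  expect_true(res$scission)
  # delete random plane beads (never un-detaches the vesicle)
  set.seed(3)
  plane <- setdiff(seq_len(nrow(pv$pos)), pv$vesicle_beads)
  drop <- sample(plane, 30)
  keep <- setdiff(seq_len(nrow(pv$pos)), drop)
  pv2 <- pv
  pv2$pos <- pv$pos[keep, , drop = FALSE]
  pv2$axis <- pv$axis[keep, , drop = FALSE]
  expect_true(detect_scission(pv2, cargo_pos = pv$cargo_pos,
                              cutoff = 1.8)$scission)
})

test_that("pore detection finds punched holes and ignores outer boundaries", {
  pristine <- synthetic_snapshot("pore_lattice", pore_radius = 0)
  pristine$periodic <- FALSE
  expect_equal(nrow(detect_pores(pristine, cutoff = 1.7)), 0)
  one <- synthetic_snapshot("pore_lattice", pore_radius = 2)
  one$periodic <- FALSE
  pores <- detect_pores(one, cutoff = 1.7)
  expect_equal(nrow(pores), 1)
  expect_lt(abs(pores$x - one$pore_centers[1, 1]), 1.5)
  expect_lt(abs(pores$y - one$pore_centers[1, 2]), 1.5)
})

test_that("merged punched disks give one pore with a slit-like perimeter", {
  n <- 30; spacing <- 1.15
  ctr <- c(n * spacing / 2, n * spacing * sqrt(3) / 4)
  centers <- rbind(ctr + c(-1.8, 0), ctr + c(1.8, 0))
  slit <- synthetic_snapshot("pore_lattice", pore_centers = centers,
                             pore_radius = 2)
  slit$periodic <- FALSE
  pores <- detect_pores(slit, cutoff = 1.7)
  expect_equal(nrow(pores), 1)
  # stadium-shaped slit: two half-circles of radius ~2 + two straight edges
  expected <- 2 * pi * 2 + 2 * 3.6
  expect_lt(abs(pores$ring_length - expected) / expected, 0.20)
})

test_that("local energy profile is baseline-subtracted arithmetic", {
  flat <- build_flat_patch(10, 10)
  base <- mean(energy_report(flat)$per_bead)
  prof <- local_energy_profile(list(flat), baseline = base)
  expect_true(all(abs(prof$energy) < 1e-9))
  # one bead with +1 kBT excess shifts its bin mean by 1/(beads in bin):
  # emulate by shifting the baseline of a known bin through a direct check
  prof2 <- local_energy_profile(list(flat), baseline = base - 1)
  expect_true(all(abs(prof2$energy - 1) < 1e-9))
})

test_that("copolymer stability is the fraction of doubly-attached replicas", {
  expect_equal(copolymer_stability(list(c(1, 1), c(0.9, 0.8))), 1.0)
  expect_equal(copolymer_stability(list(c(0.1, 1), c(1, 0.2))), 0.0)
  batch <- c(replicate(7, c(0.8, 0.9), simplify = FALSE),
             replicate(3, c(0.3, 0.9), simplify = FALSE))
  expect_equal(copolymer_stability(batch), 0.7)
})

test_that("subunit partition fractions hit the trivial limits", {
  pv <- synthetic_snapshot("plane_vesicle", vesicle_radius = 5)
  # build a fake system wrapping the snapshot plus a filament
  p <- default_params()
  n <- nrow(pv$pos)
  g <- filament_geometry(radius = 2, pitch = 1, tilt = 90)
  fil <- build_filament(g, 4, 64, "tight_helix")
  mk <- function(fil_z) {
    pos <- fil$pos
    pos[, 1] <- pos[, 1] + pv$cargo_pos[1]
    pos[, 2] <- pos[, 2] + pv$cargo_pos[2]
    pos[, 3] <- pos[, 3] + fil_z
    sys <- new_system(rbind(pv$pos, pos), c(rep(1L, n), fil$type),
                      box = pv$box, params = p,
                      axis = rbind(pv$axis, matrix(rep(c(0, 0, 1),
                        each = nrow(pos)), ncol = 3)))
    sys$fil <- c(rep(0L, n), rep(1L, nrow(pos)))
    sys$filaments[[1]] <- list(species = "tight_helix", geometry = g, k = 64,
                               n_subunits = 4,
                               beads = n + seq_len(nrow(pos)),
                               active = rep(FALSE, 4))
    sys$cargo <- list(mode = "single", radius = 2, adhesion = 0,
                      beads = integer(0))
    sys
  }
  inside <- mk(pv$cargo_pos[3])      # subunits inside the vesicle
  sc <- detect_scission(inside, cargo_pos = pv$cargo_pos, cutoff = 1.8)
  expect_equal(subunit_partition(inside, 1, sc), 1.0)
  above <- mk(30)                    # subunits far above the mother plane
  sc2 <- detect_scission(above, cargo_pos = pv$cargo_pos, cutoff = 1.8)
  expect_equal(subunit_partition(above, 1, sc2), 0.0)
  # calling without scission is an error
  flat <- build_flat_patch(8, 8)
  flat$cargo <- list(beads = 1L)
  expect_error(subunit_partition(flat, 1,
                                 list(scission = FALSE)), "without")
})

test_that("pore formation energy is a simple quotient with linear scaling", {
  expect_equal(pore_formation_energy(5, 10), 0.5)
  expect_equal(pore_formation_energy(10, 10), 1.0)
  expect_equal(pore_formation_energy(c(5, 6), c(10, 10)), 0.55)
  expect_error(pore_formation_energy(numeric(0), numeric(0)), "no pore")
})

test_that("circle fit recovers a known circle", {
  th <- seq(0, 1.5 * pi, length.out = 40)
  pts <- cbind(3 + 7 * cos(th), -2 + 7 * sin(th), 5)
  fit <- fit_circle(pts)
  expect_equal(fit$radius, 7, tolerance = 1e-9)
  expect_lt(fit$rms, 1e-9)
})
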