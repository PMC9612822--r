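test_that("backbone becomes collinear in the straight-filament limit", {
  g <- filament_geometry(radius = 1e6, pitch = 0, tilt = 0)
  bb <- ideal_backbone(g, 10)
  ctr <- bb$centroid
  d <- ctr[10, ] - ctr[1, ]
  d <- d / sqrt(sum(d^2))
  dev <- apply(ctr, 1, function(x) {
    v <- x - ctr[1, ]
    sqrt(sum((v - sum(v * d) * d)^2))
  })
  expect_lt(max(dev), 1e-3)
})

test_that("flat spiral triads have level binding beads and equal spacing", {
  R1 <- convert_units(19.4, "nm", "sigma")
  g <- filament_geometry(radius = R1, pitch = 0, tilt = 0)
  bb <- ideal_backbone(g, 12)
  # binding beads all at the same height, below the back beads
  expect_lt(diff(range(c(bb$b1[, 3], bb$b2[, 3]))), 1e-12)
  expect_true(all(bb$back[, 3] > bb$b1[, 3]))
  # consecutive centroid spacing equal
  sp <- sqrt(rowSums((bb$centroid[-1, ] - bb$centroid[-12, ])^2))
  expect_lt(diff(range(sp)), 1e-12)
})

test_that("subunit centroids sit exactly on the helix radius", {
  for (g in list(filament_geometry(5, 0, 0), filament_geometry(8.4, 3, 90),
                 filament_geometry(2.5, 4, 90, handedness = -1))) {
    bb <- ideal_backbone(g, 8)
    r <- sqrt(bb$centroid[, 1]^2 + bb$centroid[, 2]^2)
    expect_lt(max(abs(r - g$radius)), 1e-9)
  }
})

test_that("overlapping arc at pitch zero is flagged", {
  g <- filament_geometry(radius = 2, pitch = 0, tilt = 0)
  expect_error(ideal_backbone(g, 20), "overlap")
})

test_that("rest lengths are mirror-symmetric in the straight limit", {
  g <- filament_geometry(radius = 1e7, pitch = 0, tilt = 0)
  rl <- solve_rest_lengths(g)
  # swapping the two binding-bead roles on both subunits is a symmetry
  expect_equal(rl["b1", "b1"], rl["b2", "b2"], tolerance = 1e-6)
  expect_equal(rl["b1", "b2"], rl["b2", "b1"], tolerance = 1e-6)
  expect_equal(rl["b1", "back"], rl["b2", "back"], tolerance = 1e-6)
  expect_equal(rl["back", "b1"], rl["back", "b2"], tolerance = 1e-6)
})

test_that("shrinking the target radius lengthens outer relative to inner bonds", {
  R <- 10
  rel <- function(R) {
    rl <- solve_rest_lengths(filament_geometry(R, 0, 0))
    rl["b1", "b1"] / rl["b2", "b2"]   # outer edge / inner edge
  }
  r1 <- rel(R); r2 <- rel(R / 2); r3 <- rel(R / 4)
  expect_gt(r2, r1)
  expect_gt(r3, r2)
})

test_that("degenerate triads are rejected", {
  expect_error(filament_geometry(5, triad_width = 0), "degenerate")
  expect_error(filament_geometry(5, triad_drop = 0, triad_rise = 0),
               "degenerate")
})

test_that("a built filament has zero bond energy and the right bond count", {
  g <- filament_geometry(radius = 6, pitch = 0, tilt = 0)
  sys <- free_filament_system(g, 10, k = 64)
  expect_equal(sum(sys$bonds[, "spair"] > 0), 81)  # 9 pairs x 9 bonds
  rep1 <- energy_report(sys)
  expect_lt(abs(rep1$ledger[["bonds"]]), 1e-12)
  expect_error(build_filament(g, 1, 64), "at least 2")
})

test_that("perturbing one bead gives the hand-computed harmonic energy", {
  g <- filament_geometry(radius = 6, pitch = 0, tilt = 0)
  k <- 32
  sys <- free_filament_system(g, 4, k = k)
  # move bead 5 (binding bead 2 of subunit 2) by delta in z
  delta <- 0.07
  target <- 5L
  pos2 <- sys$pos
  pos2[target, 3] <- pos2[target, 3] + delta
  # hand-computed: sum over bonds touching the bead of k_b/2 (|r'| - r0)^2
  bonds <- sys$bonds
  expected <- 0
  for (b in seq_len(nrow(bonds))) {
    if (bonds[b, "i"] != target && bonds[b, "j"] != target) next
    rr <- sqrt(sum((pos2[bonds[b, "i"], ] - pos2[bonds[b, "j"], ])^2))
    expected <- expected + 0.5 * bonds[b, "k"] * (rr - bonds[b, "r0"])^2
  }
  sys$pos <- pos2
  expect_equal(energy_report(sys)$ledger[["bonds"]], unname(expected),
               tolerance = 1e-10)
})

test_that("a free flat spiral relaxes to planarity and target radius", {
  R1 <- convert_units(19.4, "nm", "sigma")
  g <- filament_geometry(radius = R1, pitch = 0, tilt = 0)
  sys <- free_filament_system(g, 10, k = 128)
  set.seed(4)
  sys$pos <- sys$pos + matrix(rnorm(nrow(sys$pos) * 3, 0, 0.1), ncol = 3)
  sys <- minimize_system(sys, max_iter = 20000, ftol = 1e-6)
  # planarity of the backbone: RMS deviation of subunit centroids from their
  # own best-fit plane (the triads themselves span two parallel bead planes,
  # and the rigid body may have tilted during relaxation)
  cents <- t(vapply(1:10, function(s)
    colMeans(sys$pos[(3 * s - 2):(3 * s), ]), numeric(3)))
  cc <- sweep(cents, 2, colMeans(cents))
  oop <- cc %*% svd(cc)$v[, 3]
  expect_lt(sqrt(mean(oop^2)), 0.1)
  ctr <- t(vapply(1:10, function(s)
    colMeans(sys$pos[(3 * s - 2):(3 * s - 1), ]), numeric(3)))
  fit <- fit_circle(ctr)
  expect_lt(abs(fit$radius - R1) / R1, 0.05)
})

test_that("a free helix relaxes to within 5% of its target radius", {
  g <- filament_geometry(radius = 6, pitch = 3, tilt = 90)
  sys <- free_filament_system(g, 20, k = 32)
  set.seed(5)
  sys$pos <- sys$pos + matrix(rnorm(nrow(sys$pos) * 3, 0, 0.08), ncol = 3)
  sys <- minimize_system(sys, max_iter = 20000, ftol = 1e-6)
  ctr <- t(vapply(1:20, function(s)
    colMeans(sys$pos[(3 * s - 2):(3 * s), ]), numeric(3)))
  fit <- fit_circle(ctr)
  expect_lt(abs(fit$radius - 6) / 6, 0.05)
})

test_that("target-radius updates are the identity at the current radius", {
  g <- filament_geometry(radius = 6, pitch = 2, tilt = 90)
  sys <- free_filament_system(g, 6, k = 64)
  r0 <- sys$bonds[, "r0"]
  sys2 <- update_target_geometry(sys, 1, 6)
  expect_identical(sys2$bonds[, "r0"], r0)
  sys3 <- update_target_geometry(sys, 1, 3)
  expect_false(isTRUE(all.equal(sys3$bonds[, "r0"], r0)))
  expect_equal(sys3$filaments[[1]]$geometry$radius, 3)
  # stiffness untouched
  expect_identical(sys3$bonds[, "k"], sys$bonds[, "k"])
})

test_that("linear constriction schedule reaches R_final at the stated time", {
  # rate 2.1e-3 nm/tau from R2 to R_final takes (R2 - R_final)/rate tau
  rate_nm <- 2.1e-3
  R2_nm <- 16.5; Rf_nm <- 5.7
  expected_tau <- (R2_nm - Rf_nm) / rate_nm
  # emulate the protocol engine's per-chunk linear interpolation
  rate_sigma <- convert_units(rate_nm, "nm/tau", "sigma/tau")
  R <- convert_units(R2_nm, "nm", "sigma")
  Rf <- convert_units(Rf_nm, "nm", "sigma")
  chunk_tau <- 2
  n <- 0
  while (R > Rf + 1e-12) { R <- max(Rf, R - rate_sigma * chunk_tau); n <- n + 1 }
  expect_lt(abs(n * chunk_tau - expected_tau), chunk_tau + 1e-9)
})

test_that("severing one filament leaves membrane and other filaments intact", {
  p <- default_params()
  sys <- build_flat_patch(12, 12, params = p)
  g1 <- filament_geometry(radius = 5, pitch = 0, tilt = 0)
  g2 <- filament_geometry(radius = 3.5, pitch = 2, tilt = 90)
  sys <- add_filament(sys, build_filament(g1, 8, 64, "flat_spiral"), z_bind = 1.1)
  sys <- add_filament(sys, build_filament(g2, 8, 64, "wide_helix"), z_bind = 0.9)
  n_mem <- sum(sys$type == 1L)
  bonds_f2 <- sum(sys$bonds[, "fil"] == 2)
  sys <- sever_subunits(sys, 1, 1:8)
  expect_equal(sum(sys$type == 1L), n_mem)
  expect_equal(sum(sys$bonds[, "fil"] == 2), bonds_f2)
  expect_equal(sum(sys$bonds[, "fil"] == 1 & sys$bonds[, "spair"] > 0), 0)
  expect_true(all(sys$adh[sys$filaments[[1]]$beads] == 0))
  # intra-subunit triangles survive (severed subunits stay rigid particles)
  expect_equal(sum(sys$bonds[, "fil"] == 1 & sys$bonds[, "spair"] == 0), 24)
})

test_that("pair interactions are symmetric under particle exchange", {
  p <- default_params()
  set.seed(11)
  mk <- function(types, filv) {
    pos <- matrix(c(0, 0, 0, 1.3, 0.2, 0.1), 2, 3, byrow = TRUE)
    sys <- new_system(pos, types, box = c(50, 50, 50), params = p)
    sys$fil <- filv
    sys
  }
  for (tp in list(c(1L, 2L), c(2L, 2L), c(1L, 3L), c(2L, 3L))) {
    e12 <- energy_report(mk(tp, c(0L, 1L)))$total
    e21 <- energy_report(mk(rev(tp), c(1L, 0L)))$total
    expect_equal(e12, e21, tolerance = 1e-14)
  }
})

test_that("cross-term energies hit their stated minima", {
  p <- default_params()
  # binding bead at the minimum distance from a membrane bead
  sys <- new_system(matrix(c(0, 0, 0, p$rmin_bm, 0, 0), 2, 3, byrow = TRUE),
                    c(1L, 2L), box = c(50, 50, 50), params = p)
  expect_equal(energy_report(sys)$total, -p$eps_bm, tolerance = 1e-12)
  # beyond all cutoffs: zero
  sys$pos[2, 1] <- 10
  expect_equal(energy_report(sys)$total, 0)
})
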