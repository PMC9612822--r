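test_that("NVE dynamics conserves energy at halved timestep", {
  sys <- build_flat_patch(10, 10, params = default_params(mu = 4))
  sys <- integrate_system(sys, 2000, seed = 5, barostat = FALSE) # thermalize
  sys <- integrate_system(sys, 10000, dt = 0.005, seed = 1,
                          thermostat = FALSE, barostat = FALSE,
                          log_every = 250)
  E <- sys$last_log[, "energy"]
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-4)
})

test_that("identical seeds give bit-identical trajectories", {
  sys <- build_flat_patch(8, 8)
  a <- integrate_system(sys, 500, seed = 42, barostat = TRUE)
  b <- integrate_system(sys, 500, seed = 42, barostat = TRUE)
  expect_identical(a$pos, b$pos)
  expect_identical(a$vel, b$vel)
  expect_identical(a$axis, b$axis)
  c2 <- integrate_system(sys, 500, seed = 43, barostat = TRUE)
  expect_false(identical(a$pos, c2$pos))
})

test_that("neighbor list is a superset of interacting pairs and energies agree", {
  sys <- mixed_test_system(seed = 3)
  # brute-force O(N^2) pair list within the cutoff
  p <- sys$params
  rc <- max(p$rc_mm, p$rc_bm, p$rc_bb)
  nl <- neighbor_pairs(sys)
  keynl <- paste(nl[, 1], nl[, 2])
  pos <- sys$pos; box <- sys$box
  n <- nrow(pos)
  ex <- paste(pmin(sys$bonds[, 1], sys$bonds[, 2]),
              pmax(sys$bonds[, 1], sys$bonds[, 2]))
  for (i in seq_len(n - 1)) {
    dx <- pos[(i + 1):n, 1] - pos[i, 1]
    dy <- pos[(i + 1):n, 2] - pos[i, 2]
    dz <- pos[(i + 1):n, 3] - pos[i, 3]
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    js <- which(dx^2 + dy^2 + dz^2 < rc^2) + i
    for (j in js)
      if (!(paste(i, j) %in% ex))
        expect_true(paste(i, j) %in% keynl)
  }
  # engine total with neighbor list equals brute-force total
  expect_rel_equal(total_energy(sys), brute_energy(sys), 1e-12)
})

test_that("an isolated bead has an empty neighbor list", {
  sys <- new_system(matrix(c(5, 5, 5), 1, 3), 1L, box = c(20, 20, 20))
  expect_equal(nrow(neighbor_pairs(sys)), 0)
})

test_that("forces match finite differences of the total energy", {
  sys <- mixed_test_system(seed = 9)
  rep1 <- energy_report(sys)
  h <- 2e-6
  set.seed(10)
  probe <- sample(nrow(sys$pos), 8)
  for (i in probe) for (k in 1:3) {
    sp <- sys; sp$pos[i, k] <- sp$pos[i, k] + h
    sm <- sys; sm$pos[i, k] <- sm$pos[i, k] - h
    fd <- -(total_energy(sp) - total_energy(sm)) / (2 * h)
    expect_lt(abs(rep1$forces[i, k] - fd), 1e-6 * max(1, abs(fd)))
  }
})

test_that("net force on the full system vanishes", {
  sys <- mixed_test_system(seed = 12)
  rep1 <- energy_report(sys)
  expect_lt(max(abs(colSums(rep1$forces))) / nrow(sys$pos), 1e-9)
})

test_that("energy ledger terms sum to the total and per-bead energies to terms", {
  sys <- mixed_test_system(seed = 5)
  rep1 <- energy_report(sys)
  expect_rel_equal(sum(rep1$ledger), rep1$total, 1e-9)
  expect_rel_equal(sum(rep1$per_bead), rep1$total, 1e-9)
  # flat membrane alone: all non-membrane terms zero
  flat <- build_flat_patch(8, 8)
  lf <- energy_report(flat)$ledger
  expect_true(all(lf[names(lf) != "membrane"] == 0))
})

test_that("momentum reset leaves |total momentum| below 1e-6", {
  sys <- build_flat_patch(8, 8)
  sys <- integrate_system(sys, 2000, seed = 8)
  sys <- zero_momentum(sys)
  expect_lt(sqrt(sum(colSums(sys$vel)^2)), 1e-6)
})

test_that("virial lateral tension matches dU/dA on a frozen configuration", {
  sys <- build_flat_patch(12, 12, spacing = 1.15)   # slightly stretched
  set.seed(2)
  sys$pos <- sys$pos + matrix(rnorm(nrow(sys$pos) * 3, 0, 0.01), ncol = 3)
  gamma_vir <- lateral_tension(sys)     # velocities are zero
  # finite difference of U under affine in-plane strain
  e <- 1e-5
  scale_sys <- function(sys, s) {
    sys$pos[, 1] <- sys$pos[, 1] * s
    sys$pos[, 2] <- sys$pos[, 2] * s
    sys$box[1:2] <- sys$box[1:2] * s
    sys
  }
  A <- sys$box[1] * sys$box[2]
  up <- total_energy(scale_sys(sys, 1 + e))
  um <- total_energy(scale_sys(sys, 1 - e))
  dUdA <- (up - um) / (A * ((1 + e)^2 - (1 - e)^2))
  expect_rel_equal(gamma_vir, dUdA, 0.01)
})

test_that("a pre-stretched patch contracts monotonically under the barostat", {
  sys <- build_flat_patch(10, 10, spacing = 1.3)
  area0 <- sys$box[1] * sys$box[2]
  sys <- integrate_system(sys, 8000, seed = 6, barostat = TRUE,
                          log_every = 1000)
  area <- sys$last_log[, "area"]
  expect_true(all(diff(area) < 0))
  expect_lt(area[length(area)], 0.97 * area0)
})

test_that("height-fluctuation spectrum is stationary after thermalization", {
  sys <- build_flat_patch(12, 12)
  sys <- integrate_system(sys, 15000, seed = 4, barostat = TRUE)
  sys <- integrate_system(sys, 30000, seed = 5, barostat = TRUE,
                          sample_every = 600)
  fr <- lapply(sys$last_frames, function(f)
    height_field(f$pos, f$box, n_grid = 12))
  half <- length(fr) %/% 2
  k1 <- estimate_bending_rigidity(fr[1:half], sys$box, q_window = c(0, 1.2))
  k2 <- estimate_bending_rigidity(fr[(half + 1):length(fr)], sys$box,
                                  q_window = c(0, 1.2))
  expect_lt(abs(log(k1$kappa / k2$kappa)), log(2)) # agree within noise
})

test_that("divergent dynamics abort with a diagnostic", {
  sys <- build_flat_patch(8, 8)
  sys$vel[1, ] <- c(500, 0, 0)  # absurd velocity: displacement cap trips
  expect_error(integrate_system(sys, 10, thermostat = FALSE),
               "aborted")
})
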