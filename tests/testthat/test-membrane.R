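test_that("membrane pair energy is zero beyond the cutoff", {
  p <- default_params()
  res <- membrane_pair_interaction(c(0, 0, 0), c(0, 0, 1),
                                   c(p$rc_mm + 0.01, 0, 0), c(0, 0, 1), p)
  expect_identical(res$energy, 0)
  expect_identical(unname(c(res$force_i, res$force_j,
                            res$torque_i, res$torque_j)), rep(0, 12))
})

test_that("aligned pair at the minimum distance sits at the potential minimum", {
  p <- default_params()
  res <- membrane_pair_interaction(c(0, 0, 0), c(0, 0, 1),
                                   c(p$rmin_mm, 0, 0), c(0, 0, 1), p)
  expect_equal(res$energy, -p$eps_mm, tolerance = 1e-12)
  expect_lt(max(abs(c(res$force_i, res$force_j))), 1e-12)
  expect_lt(max(abs(c(res$torque_i, res$torque_j))), 1e-12)
})

test_that("pair forces and torques match finite differences of the energy", {
  p <- default_params()
  set.seed(7)
  h <- 1e-6
  for (rep in 1:12) {
    xi <- runif(3)
    dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
    xj <- xi + dirv * runif(1, 0.95, 2.5)
    ni <- rnorm(3); ni <- ni / sqrt(sum(ni^2))
    nj <- rnorm(3); nj <- nj / sqrt(sum(nj^2))
    base <- membrane_pair_interaction(xi, ni, xj, nj, p)
    for (k in 1:3) {
      xp <- xj; xp[k] <- xp[k] + h
      xm <- xj; xm[k] <- xm[k] - h
      fd <- -(membrane_pair_interaction(xi, ni, xp, nj, p)$energy -
                membrane_pair_interaction(xi, ni, xm, nj, p)$energy) / (2 * h)
      expect_equal(base$force_j[k], fd, tolerance = 1e-5)
    }
    # torque about axis k: dU/dtheta = -tau_k
    for (k in 1:3) {
      e <- c(0, 0, 0); e[k] <- 1
      rot <- function(n, a) n * cos(a) +
        c(e[2] * n[3] - e[3] * n[2], e[3] * n[1] - e[1] * n[3],
          e[1] * n[2] - e[2] * n[1]) * sin(a) + e * sum(e * n) * (1 - cos(a))
      fd <- -(membrane_pair_interaction(xi, rot(ni, h), xj, nj, p)$energy -
                membrane_pair_interaction(xi, rot(ni, -h), xj, nj, p)$energy) / (2 * h)
      expect_equal(base$torque_i[k], fd, tolerance = 1e-5)
    }
    # Newton's third law, exactly
    expect_identical(base$force_i, -base$force_j)
  }
})

test_that("non-unit axes are rejected", {
  expect_error(membrane_pair_interaction(c(0, 0, 0), c(0, 0, 2),
                                         c(1, 0, 0), c(0, 0, 1)),
               "unit")
})

test_that("flat patch construction gives the requested lattice", {
  sys <- build_flat_patch(10, 10)
  expect_equal(nrow(sys$pos), 100)
  expect_true(all(sys$type == 1L))
  expect_equal(sys$axis, matrix(rep(c(0, 0, 1), each = 100), 100, 3))
  expect_error(build_flat_patch(10, 10, spacing = 3.5), "cohere")
  expect_error(build_flat_patch(10, 10, spacing = 0.2), "cohere")
  expect_error(build_flat_patch(2, 10))
})

test_that("equilibrated patch stays one connected sheet and is fluid", {
  sys <- build_flat_patch(12, 12)
  sys <- integrate_system(sys, 10000, seed = 3, barostat = TRUE,
                          sample_every = 500)
  cmp <- membrane_components(sys)
  expect_equal(cmp$n_components, 1)
  # fluidity: in-plane MSD grows linearly in time
  frames <- sys$last_frames
  p0 <- frames[[1]]$pos
  msd <- vapply(frames, function(f)
    mean(rowSums((f$pos[, 1:2] - p0[, 1:2])^2)), 0)
  tt <- vapply(frames, function(f) f$time, 0)
  fit <- stats::lm(msd ~ tt)
  expect_gt(stats::coef(fit)[2], 0)          # diffusing, not frozen
  expect_gt(summary(fit)$r.squared, 0.9)     # linear growth
})

test_that("height field gridding averages bead heights per bin", {
  pos <- rbind(c(0.5, 0.5, 1), c(0.6, 0.5, 3), c(9.5, 9.5, -2))
  h <- height_field(pos, box = c(10, 10, 10), n_grid = 5)
  expect_equal(h[1, 1], 2)    # two beads averaged
  expect_equal(h[5, 5], -2)
  expect_false(anyNA(h))      # empty bins interpolated
})

test_that("spectrum estimator recovers known rigidity within 10%", {
  box <- c(36, 36, 60)
  for (k0 in c(20, 40)) {
    fr <- synthetic_height_frames(250, 32, box, kappa = k0, seed = k0)
    est <- estimate_bending_rigidity(fr, box, q_window = c(0, 0.9))
    expect_lt(abs(est$kappa - k0) / k0, 0.10)
  }
})

test_that("doubling height amplitudes divides the fitted rigidity by 4", {
  box <- c(36, 36, 60)
  fr <- synthetic_height_frames(120, 32, box, kappa = 20, seed = 2)
  fr2 <- lapply(fr, function(h) 2 * h)
  k1 <- estimate_bending_rigidity(fr, box)$kappa
  k2 <- estimate_bending_rigidity(fr2, box)$kappa
  expect_equal(k1 / k2, 4, tolerance = 1e-9)
})

test_that("a q window with fewer than 3 modes is an error", {
  box <- c(36, 36, 60)
  fr <- synthetic_height_frames(5, 32, box, kappa = 20, seed = 1)
  expect_error(estimate_bending_rigidity(fr, box, q_window = c(0, 0.18)),
               "at least 3")
})
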