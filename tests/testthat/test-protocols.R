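test_that("instantaneous disassembly severs every inter-subunit bond at once", {
  g <- filament_geometry(radius = 6, pitch = 2, tilt = 90)
  sys <- free_filament_system(g, 8, k = 64)
  res <- disassemble_filament(sys, 1, "instantaneous")
  expect_equal(sum(res$system$bonds[, "spair"] > 0), 0)
  expect_equal(nrow(res$events), 8)
  expect_true(all(res$events$time == sys$time))
  expect_error(disassemble_filament(res$system, 1, "instantaneous"),
               "not active")
})

test_that("sequential severing events occur at times k/rate", {
  g <- filament_geometry(radius = 6, pitch = 2, tilt = 90)
  sys <- free_filament_system(g, 6, k = 64)
  rate <- 5  # subunits per tau
  res <- disassemble_filament(sys, 1, "sequential_top", rate = rate, seed = 2)
  expect_equal(res$events$time, (1:6) / rate, tolerance = sys$params$dt)
  # top-first: severed in order of decreasing height
  h0 <- vapply(1:6, function(s) mean(sys$pos[(3 * s - 2):(3 * s), 3]), 0)
  expect_equal(res$events$subunit, order(-h0))
  res2 <- disassemble_filament(sys, 1, "sequential_bottom", rate = rate, seed = 2)
  expect_equal(res2$events$subunit, order(h0))
})

test_that("random severing order is seed-reproducible and uniform", {
  g <- filament_geometry(radius = 6, pitch = 2, tilt = 90)
  sys <- free_filament_system(g, 6, k = 64)
  a <- disassemble_filament(sys, 1, "random", rate = 50, seed = 7)
  b <- disassemble_filament(sys, 1, "random", rate = 50, seed = 7)
  expect_identical(a$events$subunit, b$events$subunit)
  # first-severed index is uniform over subunits across seeds
  firsts <- vapply(1:240, function(s)
    disassemble_filament(sys, 1, "random", rate = 50, seed = s)$events$subunit[1],
    0L)
  tab <- table(factor(firsts, levels = 1:6))
  chi <- stats::chisq.test(tab)
  expect_gt(chi$p.value, 0.001)
})

test_that("unknown disassembly mode is an error", {
  g <- filament_geometry(radius = 6, pitch = 2, tilt = 90)
  sys <- free_filament_system(g, 4, k = 64)
  expect_error(disassemble_filament(sys, 1, "sideways"))
  expect_error(disassemble_filament(sys, 1, "random", rate = -1), "positive")
})

test_that("schedule validation catches malformed stages", {
  expect_error(protocol_schedule(list(action = "explode")), "action")
  expect_error(protocol_schedule(list(action = "constrict", rate_nm_tau = 0)),
               "positive")
  sch <- protocol_schedule(list(action = "equilibrate", duration = 5))
  expect_s3_class(sch, "protocol_schedule")
})

test_that("an equilibrate-only schedule on a flat patch stays flat", {
  sys <- build_flat_patch(12, 12)
  sch <- protocol_schedule(list(action = "equilibrate", duration = 30,
                                measure_theta = TRUE))
  res <- run_protocol(sys, sch, seed = 3)
  expect_equal(res$outcome, "flat")
  expect_equal(res$theta, 0)
  expect_true(all(res$events$stage >= 1))
})

test_that("recruitment binds the filament to the membrane", {
  p <- default_params()
  sys <- build_flat_patch(16, 16, params = p)
  sys <- integrate_system(sys, 5000, seed = 1, barostat = TRUE)
  sys <- recruit_filament(sys, "flat_spiral", n_subunits = 12, scale = 0.45)
  fid <- attr(sys, "filament_id")
  sys <- integrate_system(sys, 15000, seed = 2, barostat = TRUE)
  expect_gte(binding_fraction(sys, fid), 0.8)
})

test_that("with zero binding strength the filament does not stay bound", {
  p <- default_params(eps_bm = 0)
  sys <- build_flat_patch(16, 16, params = p)
  sys <- integrate_system(sys, 3000, seed = 1, barostat = TRUE)
  sys <- recruit_filament(sys, "flat_spiral", n_subunits = 12, scale = 0.45)
  fid <- attr(sys, "filament_id")
  sys <- integrate_system(sys, 15000, seed = 2, barostat = TRUE)
  expect_lt(binding_fraction(sys, fid), 0.5)
})

test_that("batch manifests have one row per condition x replica with distinct seeds", {
  grid <- expand.grid(k1 = c(32, 128), k2 = c(32, 128))
  build <- function(row) build_flat_patch(8, 8)
  sched <- function(row) protocol_schedule(list(action = "equilibrate",
                                                duration = 2))
  man <- run_batch(build, sched, grid = grid, n_replicas = 2, seed = 5)
  expect_equal(nrow(man), 8)
  expect_equal(length(unique(man$seed)), 8)
  expect_true(all(c("outcome", "theta", "scission") %in% names(man)))
  # reproducible from the manifest: same seeds -> same outcomes
  man2 <- run_batch(build, sched, grid = grid, n_replicas = 2, seed = 5)
  expect_identical(man$outcome, man2$outcome)
  expect_identical(man$seed, man2$seed)
})
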