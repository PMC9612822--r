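## Staged remodelling protocols: recruitment, equilibration, severing,
## constriction, disassembly; batch execution over replicas and scans.

#' Recruit a pre-assembled filament onto the membrane
#'
#' Inserts the filament at its ideal geometry at a species-appropriate
#' placement -- the Flat Spiral binding-face down just above the membrane,
#' helices coaxial with the existing assembly with their lowest turn at the
#' local membrane surface -- and relaxes the insertion with capped-displacement
#' FIRE steps to remove overlaps before dynamics resumes.
#'
#' @param sys an `escrt_system`.
#' @param species preset name (see [species_preset()]) or a list with
#'   `geometry`, `k`, `species`.
#' @param n_subunits number of subunits.
#' @param scale preset radius scale (reduced systems).
#' @param center in-plane placement; defaults to the box centre (or cargo
#'   position).
#' @param z_bind height of the lowest binding bead above the membrane
#'   mid-plane; defaults per species.
#' @param relax_iter relaxation budget.
#' @param min_gap smallest tolerated non-bonded gap after relaxation (sigma).
#' @return the system with the filament recruited; its index is in
#'   `attr(, "filament_id")`.
#' @export
recruit_filament <- function(sys, species, n_subunits, scale = 1,
                             center = NULL, z_bind = NULL,
                             relax_iter = 6000, min_gap = 0.5) {
  spec <- if (is.character(species))
    species_preset(species, sys$params, scale = scale) else species
  fil <- build_filament(spec$geometry, n_subunits, spec$k,
                        species = spec$species)
  if (is.null(z_bind))
    z_bind <- if (spec$geometry$tilt < 45) 1.1 else 0.9
  phase <- 0.4 * length(sys$filaments)  # interdigitate successive helices
  n_old <- n_beads(sys)
  sys <- add_filament(sys, fil, center = center, z_bind = z_bind,
                      phase = phase)
  fid <- attr(sys, "filament_id")
  sys <- minimize_system(sys, max_iter = relax_iter, ftol = 1,
                         max_disp = 0.05)
  # check residual overlaps between the new filament and the rest
  new_idx <- (n_old + 1):n_beads(sys)
  pr <- neighbor_pairs(sys, cutoff = min_gap, skin = 0)
  if (nrow(pr)) {
    cross <- xor(pr[, 1] %in% new_idx, pr[, 2] %in% new_idx)
    bad <- which(cross)
    for (r in bad) {
      dxv <- sys$pos[pr[r, 1], ] - sys$pos[pr[r, 2], ]
      dxv[1] <- dxv[1] - sys$box[1] * round(dxv[1] / sys$box[1])
      dxv[2] <- dxv[2] - sys$box[2] * round(dxv[2] / sys$box[2])
      if (sqrt(sum(dxv^2)) < min_gap)
        stop("unresolvable overlap after recruitment relaxation (beads ",
             pr[r, 1], ", ", pr[r, 2], ")")
    }
  }
  attr(sys, "filament_id") <- fid
  sys
}

# resolve a filament reference (index or species name) to an index
resolve_filament <- function(sys, ref) {
  if (is.numeric(ref)) return(as.integer(ref))
  hits <- which(vapply(sys$filaments, function(f) f$species == ref, TRUE))
  if (!length(hits)) stop("no filament with species '", ref, "'")
  hits[length(hits)]
}

#' Disassemble a filament
#'
#' Severs the filament's inter-subunit bonds according to one of four
#' protocols: `instantaneous` (all at once), `random` (uniformly random
#' subunit order at the given rate), `sequential_top` / `sequential_bottom`
#' (strictly from the highest / lowest subunit along the helix axis at the
#' given rate). For rate-based modes the k-th severing event occurs at time
#' k/rate, with Langevin dynamics between events.
#'
#' @param sys an `escrt_system`.
#' @param filament filament index or species name.
#' @param mode disassembly protocol.
#' @param rate subunits per tau (ignored for `instantaneous`).
#' @param seed RNG seed (ordering of `random` mode and dynamics noise).
#' @param retain_adhesion severed subunits keep their membrane attraction.
#' @param remove delete severed subunits from the box instead of letting them
#'   diffuse (useful at reduced system size, where trapped monomers crowd the
#'   nascent vesicle far more than at production scale).
#' @param dt timestep; defaults to the parameter set's.
#' @param barostat couple the box during the interleaved dynamics.
#' @return list with `system` and `events` (data.frame: time, subunit).
#' @export
disassemble_filament <- function(sys, filament,
                                 mode = c("instantaneous", "random",
                                          "sequential_top", "sequential_bottom"),
                                 rate = NULL, seed = 1,
                                 retain_adhesion = FALSE, remove = FALSE,
                                 dt = NULL, barostat = TRUE) {
  mode <- match.arg(mode)
  fid <- resolve_filament(sys, filament)
  f <- sys$filaments[[fid]]
  alive <- which(f$active)
  if (!length(alive)) stop("filament ", fid, " is not active")
  if (is.null(dt)) dt <- sys$params$dt
  t0 <- sys$time
  if (mode == "instantaneous") {
    sys <- sever_subunits(sys, fid, alive, retain_adhesion, remove)
    return(list(system = sys,
                events = data.frame(time = t0, subunit = alive)))
  }
  if (is.null(rate) || rate <= 0)
    stop("mode '", mode, "' needs a positive disassembly rate (subunits/tau)")
  order_idx <- switch(mode,
    random = { set.seed(derive_seed(seed, 101L)); sample(alive) },
    # "top"/"bottom" = far/near end relative to the membrane along the helix
    # axis: order by subunit centroid height
    sequential_top = alive[order(-subunit_heights(sys, fid, alive))],
    sequential_bottom = alive[order(subunit_heights(sys, fid, alive))])
  events <- data.frame(time = t0 + seq_along(order_idx) / rate,
                       subunit = order_idx)
  for (k in seq_along(order_idx)) {
    n_steps <- max(1L, round((events$time[k] - sys$time) / dt))
    sys <- integrate_system(sys, n_steps, dt = dt,
                            seed = derive_seed(seed, 200L + k),
                            barostat = barostat)
    sys <- sever_subunits(sys, fid, order_idx[k], retain_adhesion, remove)
  }
  list(system = sys, events = events)
}

subunit_heights <- function(sys, fid, subunits) {
  vapply(subunits, function(s)
    mean(sys$pos[subunit_beads(sys, fid, s), 3]), 0)
}

#' Build a staged remodelling schedule
#'
#' A schedule is an ordered list of stages. Supported actions:
#' \describe{
#'   \item{equilibrate}{`duration` (tau).}
#'   \item{recruit}{`species`, `n_subunits`, optional `scale`.}
#'   \item{sever_filament}{`filament`; instantaneous severing of all bonds.}
#'   \item{constrict}{`filament`, `rate_nm_tau`, `R_final_nm`: linear
#'     interpolation of the target radius at the given rate.}
#'   \item{disassemble}{`filament`, `mode`, `rate` (subunits/tau).}
#' }
#'
#' @param ... stage lists, each with an `action` field.
#' @return object of class `protocol_schedule`.
#' @export
protocol_schedule <- function(...) {
  stages <- list(...)
  ok <- c("equilibrate", "recruit", "sever_filament", "constrict", "disassemble")
  for (s in stages) {
    if (is.null(s$action) || !s$action %in% ok)
      stop("each stage needs an action in: ", paste(ok, collapse = ", "))
    if (s$action == "constrict" &&
        (is.null(s$rate_nm_tau) || s$rate_nm_tau <= 0))
      stop("constrict stage needs a positive rate_nm_tau")
    if (s$action == "disassemble" && !is.null(s$rate) && s$rate <= 0)
      stop("disassembly rate must be positive")
  }
  structure(stages, class = "protocol_schedule")
}

#' The default staged remodelling schedule
#'
#' The full filament-exchange sequence: equilibrate the membrane; recruit the
#' Flat Spiral and equilibrate; recruit the Wide Helix, equilibrate and
#' measure the deformation angle; sever the Flat Spiral; recruit the Tight
#' Helix (at the Wide Helix radius); sever the Wide Helix; constrict the
#' Tight Helix to `R_final_nm` at `r_constriction_nm_tau`; disassemble it;
#' final equilibration and outcome classification.
#'
#' @param scale radius scale for reduced desk-scale systems.
#' @param n_spiral,n_wide,n_tight subunit counts.
#' @param r_constriction_nm_tau constriction rate (nm of target radius / tau).
#' @param R_final_nm final Tight Helix target radius (nm).
#' @param disassembly_mode,disassembly_rate final-helix disassembly protocol.
#' @param t_equil equilibration stage duration (tau).
#' @param t_final final relaxation duration (tau).
#' @return a [protocol_schedule()].
#' @export
default_schedule <- function(scale = 1, n_spiral = 34, n_wide = 40,
                             n_tight = 40,
                             r_constriction_nm_tau = 2.1e-3,
                             R_final_nm = 5.7,
                             disassembly_mode = "instantaneous",
                             disassembly_rate = 0.02,
                             t_equil = 250, t_final = 400) {
  protocol_schedule(
    list(action = "equilibrate", duration = t_equil),
    list(action = "recruit", species = "flat_spiral", n_subunits = n_spiral,
         scale = scale),
    list(action = "equilibrate", duration = t_equil),
    list(action = "recruit", species = "wide_helix", n_subunits = n_wide,
         scale = scale),
    list(action = "equilibrate", duration = t_equil, measure_theta = TRUE),
    list(action = "sever_filament", filament = "flat_spiral"),
    list(action = "equilibrate", duration = t_equil),
    list(action = "recruit", species = "tight_helix", n_subunits = n_tight,
         scale = scale),
    list(action = "equilibrate", duration = t_equil / 2),
    list(action = "sever_filament", filament = "wide_helix"),
    list(action = "constrict", filament = "tight_helix",
         rate_nm_tau = r_constriction_nm_tau, R_final_nm = R_final_nm,
         scale = scale),
    list(action = "disassemble", filament = "tight_helix",
         mode = disassembly_mode, rate = disassembly_rate),
    list(action = "equilibrate", duration = t_final)
  )
}

#' Run a staged protocol
#'
#' Executes the stages in order with per-stage derived RNG streams, records
#' the deformation angle after each equilibration (and specifically wherever
#' `measure_theta` is set), keeps an event log, and classifies the final
#' outcome as one of flat, buckle, tubule, scission, filament_detached or
#' membrane_ruptured.
#'
#' @param sys an `escrt_system` (typically a flat patch, plus cargo if
#'   desired).
#' @param schedule a [protocol_schedule()].
#' @param seed run seed; every stage derives its own stream.
#' @param dt timestep (default from params).
#' @param sample_every frame sampling cadence in steps (0 = none).
#' @param constrict_chunk steps between target-radius updates while
#'   constricting.
#' @param seed_stage_offset added to the stage index when deriving per-stage
#'   seeds, so a schedule executed in slices reproduces the stream of the
#'   same schedule executed in one call.
#' @param verbose print stage progress.
#' @return list with `system`, `events`, `theta` (after the flagged
#'   equilibration), `stage_log` (data.frame) and `outcome`.
#' @export
run_protocol <- function(sys, schedule, seed = 1, dt = NULL,
                         sample_every = 0, constrict_chunk = 200,
                         seed_stage_offset = 0L, verbose = FALSE) {
  stopifnot(inherits(schedule, "protocol_schedule"))
  if (is.null(dt)) dt <- sys$params$dt
  events <- list()
  stage_log <- list()
  theta_marked <- NA_real_
  first_scission <- NA_real_
  frames <- list()
  note <- function(time, stage, what, detail = "")
    events[[length(events) + 1]] <<- data.frame(
      time = time, stage = stage, event = what, detail = detail)
  units <- md_units()
  for (k in seq_along(schedule)) {
    st <- schedule[[k]]
    sseed <- derive_seed(seed, k + seed_stage_offset)
    note(sys$time, k, paste0("begin_", st$action))
    if (st$action == "equilibrate") {
      n_steps <- max(1L, round(st$duration / dt))
      # with cargo present, scission is checked periodically so a transient
      # re-contact of vesicle and mother in a small periodic box cannot mask
      # an achieved scission (efficiency = reaching scission in the budget)
      chunk <- if (!is.null(sys$cargo)) min(n_steps, 2500L) else n_steps
      done <- 0L
      ci <- 0L
      while (done < n_steps) {
        nn <- min(chunk, n_steps - done)
        ci <- ci + 1L
        sys <- integrate_system(sys, nn, dt = dt, seed = derive_seed(sseed, ci),
                                barostat = TRUE, sample_every = sample_every)
        if (sample_every > 0) frames <- c(frames, sys$last_frames)
        done <- done + nn
        if (!is.null(sys$cargo) && is.na(first_scission)) {
          scn <- detect_scission(sys)
          if (isTRUE(scn$scission)) {
            first_scission <- sys$time
            note(sys$time, k, "scission_detected")
          }
        }
      }
      th <- tryCatch(deformation_angle(sys), error = function(e) NA_real_)
      if (isTRUE(st$measure_theta)) theta_marked <- th
      stage_log[[length(stage_log) + 1]] <- data.frame(
        stage = k, action = st$action, time = sys$time, theta = th)
    } else if (st$action == "recruit") {
      sys <- recruit_filament(sys, st$species, st$n_subunits,
                              scale = if (is.null(st$scale)) 1 else st$scale)
      note(sys$time, k, "recruited", st$species)
    } else if (st$action == "sever_filament") {
      fid <- resolve_filament(sys, st$filament)
      sys <- disassemble_filament(sys, fid, "instantaneous",
                                  remove = isTRUE(st$remove))$system
      note(sys$time, k, "severed", as.character(st$filament))
    } else if (st$action == "constrict") {
      fid <- resolve_filament(sys, st$filament)
      scl <- if (is.null(st$scale)) 1 else st$scale
      R_final <- convert_units(st$R_final_nm, "nm", "sigma", units) * scl
      rate <- convert_units(st$rate_nm_tau, "nm/tau", "sigma/tau", units)
      chunk_tau <- constrict_chunk * dt
      ic <- 0L
      while (sys$filaments[[fid]]$geometry$radius > R_final + 1e-9) {
        R_new <- max(R_final,
                     sys$filaments[[fid]]$geometry$radius - rate * chunk_tau)
        sys <- update_target_geometry(sys, fid, R_new)
        ic <- ic + 1L
        sys <- integrate_system(sys, constrict_chunk, dt = dt,
                                seed = derive_seed(sseed, ic),
                                barostat = TRUE)
      }
      note(sys$time, k, "constricted",
           sprintf("R_final=%.2f sigma", R_final))
    } else if (st$action == "disassemble") {
      res <- disassemble_filament(sys, st$filament, st$mode, st$rate,
                                  seed = sseed, remove = isTRUE(st$remove))
      sys <- res$system
      note(sys$time, k, "disassembled",
           paste0(st$filament, ":", st$mode))
    }
    if (verbose)
      message(sprintf("stage %d (%s) done at t = %.0f tau", k, st$action,
                      sys$time))
  }
  outcome <- classify_outcome(sys)
  label <- outcome$outcome
  if (!is.na(first_scission)) label <- "scission"
  note(sys$time, length(schedule), "outcome", label)
  list(system = sys, events = do.call(rbind, events),
       theta = theta_marked,
       stage_log = do.call(rbind, stage_log),
       outcome = label, scission = outcome$scission,
       scission_time = first_scission,
       frames = frames)
}

#' Classify the morphological outcome of a run
#'
#' Order of precedence: scission (detached closed vesicle nearest the cargo);
#' membrane_ruptured (multiple components without a clean vesicle);
#' filament_detached (any active filament with binding fraction below the
#' detachment threshold); otherwise flat / buckle / tubule by the deformation
#' angle (< 10, < 60, >= 60 degrees).
#'
#' @param sys an `escrt_system`.
#' @param detach_threshold binding fraction below which an active filament
#'   counts as detached.
#' @return list with `outcome`, `theta`, `scission` (the [detect_scission()]
#'   record or NULL).
#' @export
classify_outcome <- function(sys, detach_threshold = 0.2) {
  sc <- NULL
  if (!is.null(sys$cargo)) {
    sc <- detect_scission(sys)
    if (isTRUE(sc$scission))
      return(list(outcome = "scission", theta = NA_real_, scission = sc))
  }
  cmp <- membrane_components(sys)
  if (cmp$n_components > 1)
    return(list(outcome = "membrane_ruptured", theta = NA_real_, scission = sc))
  th <- deformation_angle(sys)
  for (i in seq_along(sys$filaments)) {
    f <- sys$filaments[[i]]
    if (any(f$active)) {
      bf <- binding_fraction(sys, i)
      if (!is.na(bf) && bf < detach_threshold)
        return(list(outcome = "filament_detached", theta = th, scission = sc))
    }
  }
  outcome <- if (th < 10) "flat" else if (th < 60) "buckle" else "tubule"
  list(outcome = outcome, theta = th, scission = sc)
}

#' Run a batch of protocol replicas over a parameter grid
#'
#' Executes `build_fn(params_row)` to construct the starting system, then
#' [run_protocol()] with per-replica derived seeds, for every row of the grid
#' times `n_replicas`. Averaging over replicas follows the study design
#' (typically 5 replicas for scission-efficiency scans, 10 for copolymer
#' stability).
#'
#' @param build_fn function(row) returning an `escrt_system`.
#' @param schedule_fn function(row) returning a [protocol_schedule()].
#' @param grid data.frame of scan parameters (one row per condition); a
#'   single empty row for plain replica runs.
#' @param n_replicas replicas per condition.
#' @param seed batch seed; replica seeds are derived deterministically.
#' @return a manifest data.frame: one row per replica with condition
#'   parameters, seed, outcome, theta and scission flag.
#' @export
run_batch <- function(build_fn, schedule_fn, grid = data.frame(.cond = 1),
                      n_replicas = 5, seed = 1) {
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    row <- grid[g, , drop = FALSE]
    for (r in seq_len(n_replicas)) {
      rseed <- derive_seed(seed, g, r)
      sys <- build_fn(row)
      res <- run_protocol(sys, schedule_fn(row), seed = rseed)
      rows[[length(rows) + 1]] <- cbind(
        row, data.frame(replica = r, seed = rseed, outcome = res$outcome,
                        theta = res$theta,
                        scission = identical(res$outcome, "scission"),
                        row.names = NULL))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scission efficiency of a batch
#'
#' Operational definition: the fraction of replicas whose outcome is
#' scission within the schedule's stage budget.
#'
#' @param manifest a [run_batch()] manifest (optionally pre-filtered).
#' @return fraction in `[0, 1]`.
#' @export
scission_efficiency <- function(manifest) mean(manifest$scission)
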