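## Trajectory, config, checkpoint and manifest I/O.
##
## Frames are stored in an extended-XYZ dialect: a bead-count line, a comment
## line with Lattice=..., Time=..., and Properties=species:S:1:pos:R:3:
## axis:R:3[:energy:R:1], then one line per bead. Orientation axes ride along
## as extra columns so standard molecular viewers can read the files.

species_letters <- c("M", "B", "K", "C") # membrane, binding, back, cargo

#' Write frames to an extended-XYZ trajectory file
#'
#' @param frames list of frames (`time`, `box`, `pos`, `axis`, optional
#'   `type`, `energy`) or `escrt_system`s.
#' @param file output path or connection.
#' @param append append to an existing trajectory.
#' @return `file`, invisibly.
#' @export
write_frames <- function(frames, file, append = FALSE) {
  if (inherits(frames, "escrt_system") ||
      (!is.null(frames$pos) && !is.null(frames$box))) frames <- list(frames)
  con <- if (inherits(file, "connection")) file
         else base::file(file, if (append) "a" else "w")
  on.exit(if (!inherits(file, "connection")) close(con))
  for (fr in frames) {
    if (inherits(fr, "escrt_system"))
      fr <- list(time = fr$time, box = fr$box, pos = fr$pos, axis = fr$axis,
                 type = fr$type)
    n <- nrow(fr$pos)
    type <- if (is.null(fr$type)) rep(1L, n) else fr$type
    has_e <- !is.null(fr$energy)
    props <- paste0("species:S:1:pos:R:3:axis:R:3", if (has_e) ":energy:R:1")
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%.8g 0 0 0 %.8g 0 0 0 %.8g" Properties=%s Time=%.8g',
      fr$box[1], fr$box[2], fr$box[3], props, fr$time), con)
    body <- sprintf("%s %.10g %.10g %.10g %.10g %.10g %.10g",
                    species_letters[type],
                    fr$pos[, 1], fr$pos[, 2], fr$pos[, 3],
                    fr$axis[, 1], fr$axis[, 2], fr$axis[, 3])
    if (has_e) body <- paste(body, sprintf("%.10g", fr$energy))
    writeLines(body, con)
  }
  invisible(file)
}

#' Read frames from an extended-XYZ trajectory file
#'
#' @param file path.
#' @return list of frames (`time`, `box`, `pos`, `axis`, `type`, optional
#'   `energy`). A truncated file is an error naming the last complete frame.
#' @export
read_frames <- function(file) {
  lines <- readLines(file)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n))
      stop("malformed frame header at line ", i, ": '", lines[i], "'")
    if (i + 1L + n > length(lines))
      stop("truncated trajectory: frame ", length(frames) + 1L,
           " incomplete; last complete frame is ", length(frames))
    hdr <- lines[i + 1L]
    lat <- regmatches(hdr, regexec('Lattice="([^"]+)"', hdr))[[1]][2]
    if (is.na(lat)) stop("missing Lattice in frame header at line ", i + 1L)
    lv <- as.numeric(strsplit(trimws(lat), "\\s+")[[1]])
    box <- lv[c(1, 5, 9)]
    tm <- regmatches(hdr, regexec("Time=([0-9eE+.-]+)", hdr))[[1]][2]
    tm <- if (is.na(tm)) NA_real_ else as.numeric(tm)
    has_e <- grepl("energy:R:1", hdr, fixed = TRUE)
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    ncol_exp <- 7L + has_e
    bad <- which(lengths(toks) != ncol_exp)
    if (length(bad))
      stop("malformed bead record at line ", i + 1L + bad[1],
           ": expected ", ncol_exp, " fields")
    m <- matrix(unlist(lapply(toks, `[`, -1L)), nrow = n, byrow = TRUE)
    type <- match(vapply(toks, `[`, "", 1L), species_letters)
    fr <- list(time = tm, box = box,
               pos = matrix(as.numeric(m[, 1:3]), n, 3),
               axis = matrix(as.numeric(m[, 4:6]), n, 3),
               type = as.integer(type))
    if (has_e) fr$energy <- as.numeric(m[, 7])
    frames[[length(frames) + 1L]] <- fr
    i <- i + 2L + n
  }
  frames
}

#' Write / read a run configuration
#'
#' Configurations are YAML key trees holding the parameter set (MD units,
#' keys suffixed per [default_params()] conventions), filament/cargo
#' descriptions and the protocol schedule.
#'
#' @param config a list (e.g. `list(params =, filaments =, cargo =,
#'   schedule =, seed =)`).
#' @param file path.
#' @return `read_config` returns the list with `params` restored to an
#'   `escrt_params` object when present.
#' @export
write_config <- function(config, file) {
  cfg <- config
  if (inherits(cfg$params, "escrt_params")) cfg$params <- unclass(cfg$params)
  if (inherits(cfg$schedule, "protocol_schedule"))
    cfg$schedule <- unclass(cfg$schedule)
  yaml::write_yaml(cfg, file)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (!is.null(cfg$params)) cfg$params <- do.call(default_params, cfg$params)
  if (!is.null(cfg$schedule))
    cfg$schedule <- do.call(protocol_schedule, cfg$schedule)
  cfg
}

#' Write / read a full-state checkpoint
#'
#' Checkpoints store the complete `escrt_system` (positions, axes,
#' velocities, angular velocities, bead types, adhesion factors, bonds, box,
#' time, parameters, filament and cargo metadata) as a portable YAML
#' container, sufficient to re-launch the run.
#'
#' @param sys an `escrt_system`.
#' @param file path.
#' @return `read_checkpoint` returns the restored `escrt_system`.
#' @export
write_checkpoint <- function(sys, file) {
  ck <- list(
    pos = as.numeric(sys$pos), axis = as.numeric(sys$axis),
    vel = as.numeric(sys$vel), avel = as.numeric(sys$avel),
    n = n_beads(sys),
    type = as.integer(sys$type), fil = as.integer(sys$fil),
    adh = as.numeric(sys$adh),
    bonds = as.numeric(sys$bonds), n_bonds = nrow(sys$bonds),
    box = sys$box, time = sys$time,
    params = unclass(sys$params),
    filaments = lapply(sys$filaments, function(f) {
      f$geometry <- unclass(f$geometry); f
    }),
    cargo = sys$cargo)
  yaml::write_yaml(ck, file, precision = 15L)
  invisible(file)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(file) {
  ck <- yaml::read_yaml(file)
  n <- ck$n
  params <- do.call(default_params, ck$params)
  sys <- structure(list(
    pos = matrix(ck$pos, n, 3), axis = matrix(ck$axis, n, 3),
    vel = matrix(ck$vel, n, 3), avel = matrix(ck$avel, n, 3),
    type = as.integer(ck$type), fil = as.integer(ck$fil),
    adh = as.numeric(ck$adh),
    bonds = matrix(ck$bonds, ck$n_bonds, 6,
                   dimnames = list(NULL, c("i", "j", "r0", "k", "fil", "spair"))),
    box = as.numeric(ck$box), time = ck$time,
    params = params,
    filaments = lapply(ck$filaments, function(f) {
      f$geometry <- do.call(filament_geometry, f$geometry)
      f$beads <- as.integer(unlist(f$beads))
      f$active <- as.logical(unlist(f$active))
      f
    }),
    cargo = if (!is.null(ck$cargo)) {
      cg <- ck$cargo; cg$beads <- as.integer(unlist(cg$beads)); cg
    }), class = "escrt_system")
  sys
}

#' Write / read a batch manifest
#'
#' Manifests are comma-delimited tables with a header, one row per replica
#' (seed, scan parameters, outcome, theta, scission flag), from which every
#' batch statistic can be recomputed.
#'
#' @param manifest a data.frame (from [run_batch()]).
#' @param file path.
#' @return `read_manifest` returns the data.frame.
#' @export
write_manifest <- function(manifest, file) {
  utils::write.csv(manifest, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' Export a filament bond table
#'
#' Writes the system's bond list (1-based bead indices, rest length,
#' stiffness, filament id, subunit-pair id) as a simple whitespace-delimited
#' text table.
#'
#' @param sys an `escrt_system`.
#' @param file path.
#' @export
write_bonds <- function(sys, file) {
  utils::write.table(sys$bonds, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
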