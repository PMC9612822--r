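#' One-particle-thick membrane pair interaction
#'
#' Evaluates the orientation-dependent pair potential between two membrane
#' beads: a repulsive 2-4 core below the minimum-energy distance plus a
#' smoothly truncated cos^(2 zeta) attractive tail, modulated by an alignment
#' factor linear in the axes' mutual orientation relative to the separation
#' vector, with `mu` multiplying the orientation penalty (zero spontaneous
#' curvature). Energy is exactly -eps_mm for a pair at the minimum distance
#' with parallel axes perpendicular to the separation; energy and forces
#' vanish smoothly at the cutoff `rc_mm`.
#'
#' @param pos_i,pos_j bead positions (length-3).
#' @param axis_i,axis_j unit orientation axes (length-3).
#' @param params an [default_params()] object.
#' @return list with `energy`, `force_i`, `force_j`, `torque_i`, `torque_j`.
#' @export
membrane_pair_interaction <- function(pos_i, axis_i, pos_j, axis_j,
                                      params = default_params()) {
  check_axes(rbind(axis_i, axis_j))
  cpp_pair_membrane(as.numeric(pos_i), as.numeric(axis_i),
                    as.numeric(pos_j), as.numeric(axis_j),
                    cpp_params(params))
}

#' Build a flat membrane patch
#'
#' Constructs a triangular-lattice sheet of membrane beads in the z = 0
#' mid-plane with all orientation axes along +z, inside a periodic in-plane
#' box sized to the lattice. `ny` must be even for the lattice to tile the
#' periodic box. The default spacing is close to the tension-free bead
#' spacing; the in-plane barostat removes the residual tension during
#' equilibration.
#'
#' @param nx,ny beads per row / number of rows (both >= 4, `ny` even).
#' @param spacing lattice constant in sigma; must lie inside the attractive
#'   well of the membrane potential or the sheet would not cohere.
#' @param params an [default_params()] object.
#' @param zbox nominal open z extent stored in the box vector.
#' @return an `escrt_system` containing `nx * ny` membrane beads.
#' @export
build_flat_patch <- function(nx, ny, spacing = 1.05, params = default_params(),
                             zbox = 60) {
  stopifnot(nx >= 4, ny >= 4)
  if (ny %% 2 != 0) stop("ny must be even for a periodic triangular lattice")
  if (spacing < 0.85 * params$rmin_mm || spacing > params$rc_mm)
    stop("spacing ", spacing, " lies outside the attractive well [",
         round(params$rmin_mm, 3), ", ", round(params$rc_mm, 3),
         "]; the sheet would not cohere")
  dy <- spacing * sqrt(3) / 2
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  x <- (ix + 0.5 * (iy %% 2)) * spacing
  y <- iy * dy
  pos <- cbind(x, y, 0)
  box <- c(nx * spacing, ny * dy, zbox)
  new_system(pos, rep(1L, nx * ny), box, params)
}

#' Grid a membrane frame into a height field
#'
#' Bins membrane-bead heights on a uniform `n_grid` x `n_grid` in-plane grid
#' (bin size close to the lattice spacing) and averages z per bin; empty bins
#' are filled by linear (here: local neighbourhood mean) interpolation.
#'
#' @param pos membrane bead positions (N x 3) or an `escrt_system`.
#' @param box box vector `c(Lx, Ly, Lz)`; taken from the system if omitted.
#' @param n_grid grid dimension.
#' @return an `n_grid` x `n_grid` matrix of heights.
#' @export
height_field <- function(pos, box = NULL, n_grid = 32) {
  if (inherits(pos, "escrt_system")) {
    box <- pos$box
    pos <- pos$pos[pos$type == 1L, , drop = FALSE]
  }
  stopifnot(!is.null(box))
  gx <- floor(((pos[, 1] %% box[1]) / box[1]) * n_grid) + 1L
  gy <- floor(((pos[, 2] %% box[2]) / box[2]) * n_grid) + 1L
  gx[gx > n_grid] <- n_grid
  gy[gy > n_grid] <- n_grid
  h <- matrix(NA_real_, n_grid, n_grid)
  cnt <- matrix(0L, n_grid, n_grid)
  sums <- matrix(0, n_grid, n_grid)
  for (k in seq_len(nrow(pos))) {
    sums[gx[k], gy[k]] <- sums[gx[k], gy[k]] + pos[k, 3]
    cnt[gx[k], gy[k]] <- cnt[gx[k], gy[k]] + 1L
  }
  h[cnt > 0] <- sums[cnt > 0] / cnt[cnt > 0]
  # fill empty bins from periodic 8-neighbourhood means, iterating if needed
  while (anyNA(h)) {
    idx <- which(is.na(h), arr.ind = TRUE)
    filled <- FALSE
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      ii <- ((i - 2):(i)) %% n_grid + 1L
      jj <- ((j - 2):(j)) %% n_grid + 1L
      nb <- h[ii, jj]
      if (any(!is.na(nb))) {
        h[i, j] <- mean(nb, na.rm = TRUE)
        filled <- TRUE
      }
    }
    if (!filled) { h[is.na(h)] <- 0; break }
  }
  h
}

#' Estimate membrane bending rigidity from the height-fluctuation spectrum
#'
#' Fits the thermal undulation spectrum `<|h_q|^2> = kT / (A kappa q^4)` over
#' a low-q window, where `h_q` is the discrete Fourier transform of the
#' gridded height field divided by the number of grid points and `A` the
#' projected area. The fit is performed in log space, i.e. `log kappa` is the
#' mean of `log(kT / (A q^4 <|h_q|^2>))` over the window, which weights every
#' mode equally. With `include_tension = TRUE` a `Sigma q^2` term is fitted
#' alongside (linear regression of `1/(A S q^2 / kT)` on `q^2`) and the
#' curvature coefficient is reported.
#'
#' @param height_frames list of height-field matrices (all the same size).
#' @param box box vector; only the in-plane extents are used.
#' @param q_window `c(q_lo, q_hi)` in 1/sigma; modes with `q_lo <= |q| <= q_hi`
#'   enter the fit (at least 3 required).
#' @param kT thermal energy (MD units).
#' @param include_tension also fit a residual-tension term.
#' @return list with `kappa` (kBT), number of modes and frames used, and the
#'   per-mode spectrum.
#' @export
estimate_bending_rigidity <- function(height_frames, box,
                                      q_window = c(0, 0.9), kT = 1,
                                      include_tension = FALSE) {
  stopifnot(length(height_frames) >= 2)
  n <- nrow(height_frames[[1]])
  A <- box[1] * box[2]
  kx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) # FFT frequency order
  qx <- 2 * pi * kx / box[1]
  qy <- 2 * pi * kx / box[2]
  Q <- sqrt(outer(qx^2, qy^2, `+`))
  S <- matrix(0, n, n)
  for (h in height_frames) {
    H <- stats::fft(h - mean(h)) / (n * n)
    S <- S + Mod(H)^2
  }
  S <- S / length(height_frames)
  sel <- Q >= max(q_window[1], 1e-9) & Q <= q_window[2] & Q > 0
  # drop the redundant Hermitian half so each physical mode counts once
  half <- outer(seq_len(n), seq_len(n),
                function(i, j) (kx[i] > 0) | (kx[i] == 0 & kx[j] > 0))
  sel <- sel & half
  if (sum(sel) < 3)
    stop("q window [", q_window[1], ", ", q_window[2], "] contains only ",
         sum(sel), " modes; at least 3 required")
  q <- Q[sel]; s <- S[sel]
  if (include_tension) {
    # 1/S = (A/kT) (kappa q^4 + Sigma q^2)  =>  kT/(A S q^2) = kappa q^2 + Sigma
    y <- kT / (A * s * q^2)
    fit <- stats::lm(y ~ I(q^2))
    kappa <- unname(stats::coef(fit)[2])
    sigma_t <- unname(stats::coef(fit)[1])
  } else {
    kappa <- exp(mean(log(kT / (A * s * q^4))))
    sigma_t <- NA_real_
  }
  list(kappa = kappa, tension = sigma_t, n_modes = sum(sel),
       n_frames = length(height_frames),
       spectrum = data.frame(q = q, S = s))
}

#' Generate synthetic height-field frames with known rigidity
#'
#' Draws independent Gaussian Fourier modes with variance
#' `<|h_q|^2> = kT / (A kappa q^4)` and returns real-space height fields.
#' Used as the generate-and-recover oracle for the spectrum estimator and as
#' a test fixture.
#'
#' @param n_frames number of frames.
#' @param n_grid grid dimension.
#' @param box box vector.
#' @param kappa bending rigidity (kBT).
#' @param kT thermal energy.
#' @param seed RNG seed.
#' @param amplitude_scale multiplies all height amplitudes (spectrum scales
#'   with its square).
#' @return list of `n_grid` x `n_grid` height matrices.
#' @export
synthetic_height_frames <- function(n_frames, n_grid, box, kappa, kT = 1,
                                    seed = 1, amplitude_scale = 1) {
  set.seed(seed)
  n <- n_grid
  A <- box[1] * box[2]
  kx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  qx <- 2 * pi * kx / box[1]
  qy <- 2 * pi * kx / box[2]
  Q <- sqrt(outer(qx^2, qy^2, `+`))
  sd_mode <- matrix(0, n, n)
  nz <- Q > 0
  sd_mode[nz] <- sqrt(kT / (A * kappa * Q[nz]^4))
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    # complex modes with total variance sd_mode^2, Hermitian-symmetrised
    re <- matrix(stats::rnorm(n * n, 0, sd_mode / sqrt(2)), n, n)
    im <- matrix(stats::rnorm(n * n, 0, sd_mode / sqrt(2)), n, n)
    H <- complex(real = re, imaginary = im)
    dim(H) <- c(n, n)
    conj_idx <- function(i) c(1L, n:2L)[i]
    Hc <- H
    for (i in seq_len(n)) for (j in seq_len(n))
      Hc[i, j] <- (H[i, j] + Conj(H[conj_idx(i), conj_idx(j)])) / sqrt(2)
    h <- Re(stats::fft(Hc, inverse = TRUE))
    frames[[f]] <- h * amplitude_scale
  }
  frames
}
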