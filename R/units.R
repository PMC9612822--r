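#' Simulation unit system
#'
#' All internal computation uses reduced MD units: length sigma, energy kBT,
#' time tau, bead mass 1. Conversions to physical units happen only at I/O
#' boundaries. The physical length mapping is sigma = 2.3 nm; the tau-to-
#' seconds mapping is deliberately left undefined, so times and rates are
#' reported per tau (rates in nm/tau).
#'
#' @param sigma_nm physical length of one MD length unit, in nanometres.
#' @return an object of class `md_units`.
#' @export
md_units <- function(sigma_nm = 2.3) {
  stopifnot(is.numeric(sigma_nm), length(sigma_nm) == 1L, sigma_nm > 0)
  structure(list(sigma_nm = sigma_nm), class = "md_units")
}

#' @export
print.md_units <- function(x, ...) {
  cat("MD unit system: sigma =", x$sigma_nm,
      "nm; energy in kBT; time in tau (unmapped)\n")
  invisible(x)
}

# Parse a unit tag into a dimension vector (length, energy, time exponents)
# and a scale factor to the internal MD unit of the same dimension.
# Supported base tags: sigma, nm, kT, tau. Compound tags use "/" and "^n",
# e.g. "nm/tau", "kT/sigma^2", "kT/nm^2".
parse_unit <- function(tag, units) {
  base <- function(b) {
    switch(b,
      sigma = list(dim = c(L = 1, E = 0, T = 0), scale = 1),
      nm    = list(dim = c(L = 1, E = 0, T = 0), scale = 1 / units$sigma_nm),
      kT    = list(dim = c(L = 0, E = 1, T = 0), scale = 1),
      tau   = list(dim = c(L = 0, E = 0, T = 1), scale = 1),
      stop("unknown unit tag: '", b, "'", call. = FALSE))
  }
  tag <- gsub("\\s", "", tag)
  parts <- strsplit(tag, "/", fixed = TRUE)[[1]]
  if (!length(parts) || any(!nzchar(parts)))
    stop("malformed unit tag: '", tag, "'", call. = FALSE)
  dim <- c(L = 0, E = 0, T = 0)
  scale <- 1
  for (k in seq_along(parts)) {
    piece <- parts[k]
    pow <- 1
    if (grepl("^", piece, fixed = TRUE)) {
      bits <- strsplit(piece, "^", fixed = TRUE)[[1]]
      piece <- bits[1]
      pow <- as.numeric(bits[2])
      if (is.na(pow)) stop("malformed exponent in unit tag: '", tag, "'", call. = FALSE)
    }
    b <- base(piece)
    sgn <- if (k == 1) 1 else -1   # first part numerator, rest denominators
    dim <- dim + sgn * pow * b$dim
    scale <- scale * b$scale^(sgn * pow)
  }
  list(dim = dim, scale = scale)
}

#' Convert a value between unit tags
#'
#' Supported base tags are `"sigma"`, `"nm"`, `"kT"` and `"tau"`; compound
#' tags combine them with `/` and `^`, e.g. `"nm/tau"` or `"kT/sigma^2"`.
#' Conversion between tags of different physical dimension is an error.
#'
#' @param x numeric vector of values.
#' @param from,to unit tags.
#' @param units an [md_units()] object.
#' @return numeric vector in the target units.
#' @examples
#' convert_units(1, "sigma", "nm")    # 2.3
#' convert_units(19.4, "nm", "sigma") # 19.4 / 2.3
#' @export
convert_units <- function(x, from, to, units = md_units()) {
  uf <- parse_unit(from, units)
  ut <- parse_unit(to, units)
  if (!isTRUE(all.equal(uf$dim, ut$dim)))
    stop("incompatible dimensions: '", from, "' has dimension (",
         paste(sprintf("%s^%g", names(uf$dim), uf$dim), collapse = " "),
         ") but '", to, "' has (",
         paste(sprintf("%s^%g", names(ut$dim), ut$dim), collapse = " "), ")",
         call. = FALSE)
  x * uf$scale / ut$scale
}

#' Derive a child random seed
#'
#' One user-level seed drives a whole run; per-stage and per-replica streams
#' are split off deterministically so that adding analysis calls or replicas
#' never perturbs the dynamics of the others. The derivation is a small
#' integer hash; results are in `[1, 2^31 - 2]`.
#'
#' @param seed parent seed (integer-like).
#' @param ... further integer-like stream labels (stage index, replica index).
#' @return a positive integer seed.
#' @export
derive_seed <- function(seed, ...) {
  labs <- c(seed, unlist(list(...)))
  h <- 0
  m <- 2147483647  # 2^31 - 1 (prime)
  for (v in labs) {
    h <- (h * 48271 + (as.numeric(v) %% m) + 11) %% m
    h <- (h * 16807 + 7) %% m
  }
  as.integer(h %% (m - 1) + 1)
}
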