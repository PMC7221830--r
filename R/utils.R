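# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a child seed from a base seed and a stream index (stays < 2^31)
#' @noRd
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %%
               2147483629)
}

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bondi van der Waals radii (Angstrom), frozen so occupancy descriptors are
# bit-stable across sessions.
VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98
)

vdw_radius <- function(elem) {
  r <- VDW_RADII[elem]
  r[is.na(r)] <- 1.70
  unname(r)
}

# Average atomic masses for molecular-weight windows in the decoy filter.
ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904
)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
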