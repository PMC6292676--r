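# Mutual information and the generalized correlation coefficient.

# Columns scaled to unit standard deviation. MI is invariant under
# per-variable rescaling, but the max-norm k-NN estimate is not when the
# marginals live on very different scales; standardizing first restores the
# invariance in practice (and is a no-op statistically).
standardize_columns <- function(x) {
  s <- apply(x, 2, sd)
  sweep(x, 2, s, "/")
}

# Deterministic tie-breaking jitter: k-NN estimators assume continuous
# distributions, so exactly repeated values (finite-precision trajectories)
# are perturbed by an amount ~1e-10 of each column's range, drawn from a
# seeded local RNG that never touches the caller's RNG state.
add_tie_jitter <- function(x, seed, scale = 1e-10) {
  rng <- local_rng_state(seed)
  on.exit(restore_rng_state(rng))
  rng_range <- apply(x, 2, function(col) diff(range(col)))
  rng_range[rng_range == 0] <- 1
  x + matrix(runif(length(x), -0.5, 0.5), nrow(x), ncol(x)) *
    rep(rng_range * scale, each = nrow(x))
}

local_rng_state <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  old
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' k-nearest-neighbour mutual information
#'
#' Kraskov (algorithm 1) estimate of the mutual information between two
#' continuous multivariate samples, using the max-norm in the joint space.
#' The estimate is in nats and is clamped at 0 (the estimator can go
#' slightly negative for independent data). Exactly tied coordinates are
#' broken by a deterministic seeded jitter of about 1e-10 of each
#' coordinate's range, so results are reproducible bit-for-bit.
#'
#' @param x,y Numeric matrices with one row per sample (vectors are treated
#'   as single-column matrices). Row counts must match and exceed `k + 1`.
#' @param k Neighbour count (default 6).
#' @param jitter_seed Seed for the tie-breaking jitter (default 42).
#' @return Mutual information in nats (scalar, >= 0).
#' @references Kraskov, Stoegbauer & Grassberger (2004) Phys. Rev. E 69,
#'   066138.
#' @export
mutual_information_knn <- function(x, y, k = 6, jitter_seed = 42) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) abort("x and y must have equal sample counts")
  if (nrow(x) < k + 2) abort("need at least k + 2 samples")
  if (any(apply(x, 2, sd) == 0) || any(apply(y, 2, sd) == 0)) {
    abort("degenerate input: a coordinate has zero variance")
  }
  if (ncol(x) == ncol(y) && isTRUE(all.equal(unname(x), unname(y),
                                             tolerance = 0))) {
    abort("degenerate input: y is an exact copy of x (MI unbounded)")
  }
  xj <- add_tie_jitter(standardize_columns(x), jitter_seed)
  yj <- add_tie_jitter(standardize_columns(y), jitter_seed + 1)
  max(0, .ksg_mi_cpp(xj, yj, as.integer(k)))
}

#' Generalized correlation coefficient from mutual information
#'
#' The Lange-Grubmueller transform maps a mutual information `I` between two
#' d-dimensional variables onto a correlation-like coefficient
#' `r_MI = sqrt(1 - exp(-2 I / d))` in `[0, 1]`. For jointly Gaussian
#' d-dimensional variables with per-dimension correlation rho (isotropic),
#' `r_MI = |rho|` exactly, which is the basis of the estimator checks used
#' throughout this package.
#'
#' @param mi Mutual information in nats (>= 0; vectorized).
#' @param d Dimensionality of each variable (default 3, atomic displacement
#'   vectors).
#' @return `r_MI` in `[0, 1]`.
#' @references Lange & Grubmueller (2006) Proteins 62, 1053-1061.
#' @export
gc_coefficient <- function(mi, d = 3) {
  if (any(mi < 0, na.rm = TRUE)) abort("mi must be non-negative (clamp first)")
  if (d < 1) abort("d must be >= 1")
  sqrt(1 - exp(-2 * mi / d))
}

#' Closed-form Gaussian mutual information
#'
#' MI in nats between two isotropic d-dimensional jointly Gaussian variables
#' with per-dimension correlation `rho`: `-(d/2) log(1 - rho^2)`. Used as an
#' independent oracle for the k-NN estimator.
#'
#' @param rho Per-dimension correlation in (-1, 1).
#' @param d Dimensionality (default 3).
#' @return MI in nats.
#' @export
gaussian_mi <- function(rho, d = 3) {
  stopifnot(all(abs(rho) < 1))
  -(d / 2) * log(1 - rho^2)
}
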