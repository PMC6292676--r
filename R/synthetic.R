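# Synthetic trajectories and fixtures with known ground truth.
#
# The generators draw from models whose statistics are known exactly, so
# every analysis stage can be tested without a deposited MD trajectory:
#  * block-correlated Gaussian fluctuations emulate coupled-domain motions;
#  * a two-plateau sigmoid distance trace emulates a conformational
#    transition between a pre-activated and an activated state;
#  * a minimal Asp/Lys structure gives an exact salt-bridge geometry.
# All randomness flows from the single seed in the call; generators are
# bit-reproducible and never touch the caller's RNG state.

#' Synthetic trajectory with block-correlated Gaussian fluctuations
#'
#' Generates a Cα-only pseudo-protein whose per-frame displacements are
#' drawn from a stationary multivariate Gaussian with a block (domain-wise)
#' correlation structure: `intra_cor` within each block and the requested
#' correlation between blocks, identically and independently on x, y and z
#' (isotropic). Under isotropy the generalized correlation of a residue pair
#' equals the per-dimension correlation exactly in the population limit,
#' which makes the generator a quantitative oracle for [gc_matrix()].
#'
#' @param blocks Named integer vector of residues per block,
#'   e.g. `c(A = 5, B = 5)`.
#' @param inter_cor Between-block per-dimension correlation: a single
#'   number for all block pairs, or a symmetric nblocks x nblocks matrix
#'   (diagonal ignored).
#' @param intra_cor Within-block correlation between distinct residues
#'   (default 0.9).
#' @param amplitude Fluctuation standard deviation per coordinate, Angstrom
#'   (default 1).
#' @param n_frames Number of frames (default 3000).
#' @param seed Seed for all randomness.
#' @param dt Frame spacing in ns (default 1).
#' @param spacing Distance between consecutive mean Cα positions, Angstrom
#'   (default 10).
#' @return An `mdtrajectory`; `attr(, "ground_truth")` holds the block
#'   labels, the implied residue-residue correlation matrix and the call
#'   parameters.
#' @export
make_block_trajectory <- function(blocks, inter_cor, intra_cor = 0.9,
                                  amplitude = 1.0, n_frames = 3000,
                                  seed = 1, dt = 1, spacing = 10) {
  stopifnot(length(blocks) >= 1, all(blocks >= 1), !is.null(names(blocks)))
  nb <- length(blocks)
  if (is.matrix(inter_cor)) {
    stopifnot(nrow(inter_cor) == nb, ncol(inter_cor) == nb,
              max(abs(inter_cor - t(inter_cor))) < 1e-12)
    ic <- inter_cor
  } else {
    stopifnot(length(inter_cor) == 1)
    ic <- matrix(inter_cor, nb, nb)
  }
  n <- sum(blocks)
  block_of <- rep(seq_len(nb), blocks)
  r <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      r[i, j] <- if (i == j) {
        1
      } else if (block_of[i] == block_of[j]) {
        intra_cor
      } else {
        ic[block_of[i], block_of[j]]
      }
    }
  }
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort(sprintf(
      "requested correlation structure is not positive semi-definite (min eigenvalue %.3g)",
      min(ev)
    ))
  }
  ch <- chol(r + diag(1e-12, n))

  rng <- local_rng_state(seed)
  on.exit(restore_rng_state(rng))
  disp <- lapply(1:3, function(ax) {
    (matrix(rnorm(n_frames * n), n_frames, n) %*% ch) * amplitude
  })

  top <- calpha_topology(n, spacing = spacing)
  base <- as.vector(t(top$xyz))
  xyz <- matrix(base, n_frames, 3 * n, byrow = TRUE)
  for (ax in 1:3) {
    xyz[, seq(ax, 3 * n, by = 3)] <-
      xyz[, seq(ax, 3 * n, by = 3), drop = FALSE] + disp[[ax]]
  }
  out <- trajectory(top, xyz, dt = dt)
  attr(out, "superposed") <- TRUE  # displacements are drawn in a fixed frame
  attr(out, "ground_truth") <- list(
    kind = "block_gaussian",
    blocks = blocks,
    block_of = stats::setNames(names(blocks)[block_of], top$atoms$resno),
    residue_cor = r,
    inter_cor = ic,
    intra_cor = intra_cor,
    amplitude = amplitude,
    n_frames = n_frames,
    seed = seed
  )
  out
}

# Cα-only pseudo-protein topology along a gently kinked line.
calpha_topology <- function(n, spacing = 10, chain = "A") {
  t <- seq_len(n)
  xyz <- cbind(
    spacing * t,
    2 * sin(t / 3),
    2 * cos(t / 5)
  )
  atoms <- tibble::tibble(
    eleno = t, elety = "CA", alt = NA_character_,
    resid = "ALA", chain = chain, resno = t, insert = "",
    het = FALSE, occ = 1, elem = "C"
  )
  new_mdstruct(atoms, xyz, source = "synthetic")
}

#' Synthetic two-plateau transition trajectory
#'
#' Generates a minimal two-residue Cα trajectory whose inter-residue
#' distance follows a sigmoidal switch between two plateaus with additive
#' Gaussian noise:
#' `d(t) = v1 + (v2 - v1) / (1 + exp(-steepness (t/F - midpoint))) + eps`.
#' The defaults mirror an activation-like event in which a monitored
#' distance relaxes from about 19.4 to about 8 Angstrom roughly halfway
#' through the observation window.
#'
#' @param v1,v2 Plateau values in Angstrom (defaults 19.4 and 8.0).
#' @param midpoint Switch midpoint as a fraction of the trajectory
#'   (0 < midpoint < 1, default 0.5).
#' @param steepness Dimensionless switch steepness (default 20; the
#'   10-90% width is about `4.4 / steepness` of the trajectory).
#' @param noise_sd Additive Gaussian noise on the distance, Angstrom
#'   (default 0.5).
#' @param n_frames Number of frames (default 4000).
#' @param seed Seed for the noise.
#' @param dt Frame spacing in ns (default 1).
#' @return An `mdtrajectory` of two Cα atoms (residues 1 and 2);
#'   `attr(, "ground_truth")` holds the noiseless curve and the parameters.
#' @export
make_transition_trajectory <- function(v1 = 19.4, v2 = 8.0, midpoint = 0.5,
                                       steepness = 20, noise_sd = 0.5,
                                       n_frames = 4000, seed = 1, dt = 1) {
  stopifnot(midpoint > 0, midpoint < 1, noise_sd >= 0, n_frames >= 2)
  t_frac <- (seq_len(n_frames) - 0.5) / n_frames
  clean <- v1 + (v2 - v1) / (1 + exp(-steepness * (t_frac - midpoint)))
  rng <- local_rng_state(seed)
  on.exit(restore_rng_state(rng))
  noisy <- clean + rnorm(n_frames, sd = noise_sd)

  top <- calpha_topology(2, spacing = 10)
  top$xyz <- rbind(c(0, 0, 0), c(v1, 0, 0))
  xyz <- matrix(0, n_frames, 6)
  xyz[, 4] <- noisy
  out <- trajectory(top, xyz, dt = dt)
  attr(out, "ground_truth") <- list(
    kind = "sigmoid_transition",
    v1 = v1, v2 = v2, midpoint = midpoint, steepness = steepness,
    noise_sd = noise_sd, n_frames = n_frames, seed = seed,
    clean = clean
  )
  out
}

#' Fit a sigmoidal transition to a distance series
#'
#' Least-squares refit of the two-plateau logistic model used by
#' [make_transition_trajectory()], giving plateau estimates and the
#' change-point (midpoint) location. Uses Levenberg-Marquardt with starting
#' values taken from the first/last deciles of the series.
#'
#' @param series A `distance_series` tibble (or any tibble with `frame` and
#'   `distance` columns).
#' @return A one-row tibble with `v1`, `v2`, `midpoint`, `steepness` and
#'   the residual standard deviation `sigma`.
#' @export
fit_transition <- function(series) {
  f <- nrow(series)
  df <- data.frame(t_frac = (series$frame - 0.5) / f, d = series$distance)
  q <- floor(f / 10)
  start <- list(
    v1 = mean(df$d[seq_len(max(q, 2))]),
    v2 = mean(df$d[seq(f - max(q, 2) + 1, f)]),
    m = 0.5, s = 10
  )
  fit <- minpack.lm::nlsLM(
    d ~ v1 + (v2 - v1) / (1 + exp(-s * (t_frac - m))),
    data = df, start = start,
    lower = c(v1 = -Inf, v2 = -Inf, m = 0.01, s = 0.1),
    upper = c(v1 = Inf, v2 = Inf, m = 0.99, s = 1000),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- as.list(stats::coef(fit))
  tibble::tibble(
    v1 = p$v1, v2 = p$v2, midpoint = p$m, steepness = p$s,
    sigma = stats::sigma(fit)
  )
}

#' Minimal salt-bridge fixture structure
#'
#' Builds a two-residue Asp/Lys structure whose side-chain COM-COM distance
#' (carboxylate oxygens vs. ammonium nitrogen) equals `distance` exactly:
#' OD1/OD2 sit symmetrically about the origin and NZ sits at
#' `(distance, 0, 0)`.
#'
#' @param distance Requested COM-COM distance, Angstrom (>= 0).
#' @return An `mdstruct` carrying the side-chain atoms needed by
#'   [salt_bridge_series()].
#' @export
make_salt_bridge_fixture <- function(distance) {
  stopifnot(distance >= 0)
  atoms <- tibble::tibble(
    eleno = 1:8,
    elety = c("CA", "CB", "CG", "OD1", "OD2", "CA", "CE", "NZ"),
    alt = NA_character_,
    resid = c(rep("ASP", 5), rep("LYS", 3)),
    chain = "A",
    resno = c(rep(1L, 5), rep(2L, 3)),
    insert = "",
    het = FALSE, occ = 1,
    elem = c("C", "C", "C", "O", "O", "C", "C", "N")
  )
  xyz <- rbind(
    c(-3.0, 0.0, 0.0),   # ASP CA
    c(-2.0, 0.5, 0.0),   # ASP CB
    c(-1.0, 0.0, 0.0),   # ASP CG
    c(0.0, 1.0, 0.0),    # ASP OD1
    c(0.0, -1.0, 0.0),   # ASP OD2  -> O-group COM at origin
    c(distance + 3.0, 0.0, 0.0),  # LYS CA
    c(distance + 1.5, 0.0, 0.0),  # LYS CE
    c(distance, 0.0, 0.0)         # LYS NZ   -> N-group COM at (distance,0,0)
  )
  new_mdstruct(atoms, xyz, source = "synthetic")
}

#' Write a generator's ground truth as JSON
#'
#' @param traj A trajectory produced by a generator in this package.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(traj, path) {
  gt <- attr(traj, "ground_truth")
  if (is.null(gt)) abort("trajectory carries no ground-truth record")
  gt$residue_cor <- NULL  # matrices are re-derivable from blocks + cors
  gt$clean <- NULL
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
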