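# Essential dynamics: PCA of the Cα covariance matrix.

#' Principal component analysis of Cα fluctuations (essential dynamics)
#'
#' Builds the 3N x 3N covariance matrix of the mean-centered Cα coordinates
#' of a superposed trajectory and diagonalizes it. Each eigenvector
#' (principal component, PC) carries an eigenvalue equal to the mean-square
#' fluctuation of the trajectory along it; the motion along PC1 is the
#' system's essential dynamics. The covariance uses the population (1/F)
#' normalization. Eigenvector signs follow a fixed convention — the
#' largest-magnitude component of each mode is positive — so outputs are
#' reproducible.
#'
#' @param traj A superposed `mdtrajectory` (see [superpose()]).
#' @param sel Atom indices to analyze; defaults to all protein Cα atoms.
#'   At least 2 atoms and 2 frames are required.
#' @return An object of class `ed_pca`: `values` (eigenvalues, Angstrom^2,
#'   descending, clamped at 0), `vectors` (3N x n orthonormal matrix),
#'   `mean` (3N mean coordinates), `projections` (F x n, Angstrom), `resno`,
#'   `sel`, `times`.
#' @export
ed_pca <- function(traj, sel = NULL) {
  stopifnot(inherits(traj, "mdtrajectory"))
  sel <- sel %||% protein_ca_indices(traj$topology)
  if (length(sel) < 2) abort("PCA needs at least 2 atoms")
  if (n_frames(traj) < 2) abort("PCA needs more than one frame")
  cols <- xyz_cols(sel)
  x <- traj$xyz[, cols, drop = FALSE]
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  f <- nrow(xc)
  cov <- crossprod(xc) / f
  eig <- eigen(cov, symmetric = TRUE)
  vals <- eig$values
  if (any(vals < -1e-8 * max(abs(vals), 1))) {
    warn("covariance matrix has significantly negative eigenvalues")
  }
  vals <- pmax(vals, 0)
  vecs <- eig$vectors
  # sign convention: largest-|component| of each mode positive
  for (m in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, m]))
    if (vecs[i, m] < 0) vecs[, m] <- -vecs[, m]
  }
  structure(
    list(
      values = vals,
      vectors = vecs,
      mean = mu,
      projections = xc %*% vecs,
      resno = traj$topology$atoms$resno[sel],
      sel = sel,
      times = traj$times
    ),
    class = "ed_pca"
  )
}

#' @export
print.ed_pca <- function(x, ...) {
  tot <- sum(x$values)
  cat(
    "<ed_pca> ", length(x$sel), " atoms, ", nrow(x$projections), " frames; ",
    "PC1 ", sprintf("%.1f%%", 100 * x$values[1] / max(tot, .Machine$double.eps)),
    ", PC1+PC2 ",
    sprintf(
      "%.1f%%",
      100 * sum(x$values[1:min(2, length(x$values))]) /
        max(tot, .Machine$double.eps)
    ),
    " of total fluctuation\n",
    sep = ""
  )
  invisible(x)
}

#' Project frames onto principal components
#'
#' @param traj An `mdtrajectory` over the same atoms (superposed consistently
#'   with the PCA input).
#' @param result An `ed_pca`.
#' @param n_modes Number of leading modes to project onto (default 2,
#'   i.e. the PC1/PC2 essential subspace).
#' @return A tibble with columns `frame`, `time_ns` and `PC1 ... PCn`
#'   (Angstrom).
#' @export
project_frames <- function(traj, result, n_modes = 2) {
  stopifnot(inherits(result, "ed_pca"))
  if (n_modes > ncol(result$vectors)) abort("n_modes exceeds available modes")
  cols <- xyz_cols(result$sel)
  if (max(cols) > ncol(traj$xyz)) abort("trajectory does not cover PCA atoms")
  xc <- sweep(traj$xyz[, cols, drop = FALSE], 2, result$mean)
  proj <- xc %*% result$vectors[, seq_len(n_modes), drop = FALSE]
  colnames(proj) <- paste0("PC", seq_len(n_modes))
  dplyr::bind_cols(
    tibble::tibble(frame = seq_len(n_frames(traj)), time_ns = traj$times),
    tibble::as_tibble(proj)
  )
}

#' Per-residue displacement vectors of a principal component
#'
#' Splits one eigenvector into per-residue 3-vectors (the porcupine-plot
#' quantity): the displacement in Angstrom per unit projection along that
#' mode. Because eigenvectors are unit length, the squared magnitudes sum
#' to 1.
#'
#' @param result An `ed_pca`.
#' @param mode Mode index (1 = PC1).
#' @return A tibble with columns `resno`, `dx`, `dy`, `dz`, `magnitude`.
#' @export
mode_displacements <- function(result, mode = 1) {
  stopifnot(inherits(result, "ed_pca"))
  if (mode < 1 || mode > ncol(result$vectors)) abort("mode index out of range")
  v <- matrix(result$vectors[, mode], ncol = 3, byrow = TRUE)
  tibble::tibble(
    resno = result$resno,
    dx = v[, 1], dy = v[, 2], dz = v[, 3],
    magnitude = sqrt(rowSums(v^2))
  )
}

#' @describeIn ed_pca Tidy eigenvalue spectrum: one row per mode with
#'   `eigenvalue` (Angstrom^2) and cumulative variance fractions.
#' @param x,object An `ed_pca`.
#' @param ... Unused.
#' @method tidy ed_pca
#' @export
tidy.ed_pca <- function(x, ...) {
  tot <- sum(x$values)
  tibble::tibble(
    mode = seq_along(x$values),
    eigenvalue = x$values,
    prop_var = x$values / max(tot, .Machine$double.eps),
    cum_var = cumsum(x$values) / max(tot, .Machine$double.eps)
  )
}

#' @describeIn ed_pca One-row model summary.
#' @method glance ed_pca
#' @export
glance.ed_pca <- function(x, ...) {
  tot <- sum(x$values)
  tibble::tibble(
    n_atoms = length(x$sel),
    n_frames = nrow(x$projections),
    total_fluctuation = tot,
    pc1_frac = x$values[1] / max(tot, .Machine$double.eps),
    pc12_frac = sum(x$values[1:min(2, length(x$values))]) /
      max(tot, .Machine$double.eps)
  )
}

#' @describeIn ed_pca Scatter of the PC1/PC2 projections colored by time.
#' @method autoplot ed_pca
#' @export
autoplot.ed_pca <- function(object, ...) {
  df <- tibble::tibble(
    PC1 = object$projections[, 1],
    PC2 = object$projections[, min(2, ncol(object$projections))],
    time_ns = object$times
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$time_ns)) +
    ggplot2::geom_path(alpha = 0.4) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "PC1 (Å)", y = "PC2 (Å)", colour = "time (ns)",
      title = "Essential-dynamics projection"
    ) +
    ggplot2::theme_minimal()
}
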