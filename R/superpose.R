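# Least-squares superposition of trajectory frames onto a reference.

#' Superpose a trajectory onto a reference structure
#'
#' Removes global rotation and translation by least-squares (Kabsch) fitting
#' every frame onto the reference coordinates over a fit selection. This is
#' required before covariance-based analyses ([ed_pca()], [gc_matrix()]),
#' which operate on internal fluctuations only.
#'
#' @param traj An `mdtrajectory`.
#' @param reference An `mdstruct` with the same atoms; defaults to the
#'   trajectory's own topology.
#' @param fit_sel Atom indices used for the fit; defaults to all protein Cα
#'   atoms. At least 3 atoms are required.
#' @return The fitted `mdtrajectory`; per-frame RMSD over the fit selection
#'   (Angstrom) is stored in `attr(, "rmsd")`.
#' @export
superpose <- function(traj, reference = NULL, fit_sel = NULL) {
  stopifnot(inherits(traj, "mdtrajectory"))
  reference <- reference %||% traj$topology
  fit_sel <- fit_sel %||% protein_ca_indices(traj$topology)
  if (length(fit_sel) < 3) abort("need at least 3 atoms to superpose")
  cols <- xyz_cols(fit_sel)
  fixed <- as.vector(t(reference$xyz))
  fitted <- bio3d::fit.xyz(
    fixed = fixed, mobile = traj$xyz,
    fixed.inds = cols, mobile.inds = cols
  )
  if (!is.matrix(fitted)) fitted <- matrix(fitted, nrow = 1)
  out <- trajectory(traj$topology, fitted, times = traj$times)
  dev <- sweep(fitted[, cols, drop = FALSE], 2, fixed[cols])
  attr(out, "rmsd") <- sqrt(rowSums(dev^2) / length(fit_sel))
  attr(out, "superposed") <- TRUE
  out
}

#' Per-frame RMSD against a reference
#'
#' @param traj An `mdtrajectory`.
#' @param reference An `mdstruct`; defaults to the topology.
#' @param sel Atom indices; defaults to protein Cα atoms.
#' @return Numeric vector of per-frame RMSD (Angstrom), without fitting.
#' @export
rmsd_series <- function(traj, reference = NULL, sel = NULL) {
  reference <- reference %||% traj$topology
  sel <- sel %||% protein_ca_indices(traj$topology)
  cols <- xyz_cols(sel)
  ref <- as.vector(t(reference$xyz))[cols]
  dev <- sweep(traj$xyz[, cols, drop = FALSE], 2, ref)
  sqrt(rowSums(dev^2) / length(sel))
}
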