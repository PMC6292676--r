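# Trajectory container: a topology plus an F x 3A coordinate matrix
# (bio3d "xyz" layout: frame rows, x1 y1 z1 x2 y2 z2 ... columns).

#' Construct a trajectory
#'
#' @param topology An `mdstruct` describing the A atoms of every frame.
#' @param xyz Numeric F x 3A matrix of coordinates (Angstrom), one frame per
#'   row, or an A x 3 matrix for a single frame.
#' @param times Frame times in ns, strictly increasing; defaults to
#'   `0, dt, 2 dt, ...`.
#' @param dt Frame spacing in ns used when `times` is missing (default 1).
#' @return An object of class `mdtrajectory` with elements `topology`, `xyz`
#'   and `times`.
#' @export
trajectory <- function(topology, xyz, times = NULL, dt = 1) {
  stopifnot(inherits(topology, "mdstruct"))
  n_atoms <- nrow(topology$atoms)
  if (is.matrix(xyz) && ncol(xyz) == 3 && nrow(xyz) == n_atoms) {
    xyz <- matrix(as.vector(t(xyz)), nrow = 1)
  }
  if (!is.matrix(xyz) || ncol(xyz) != 3 * n_atoms) {
    abort(sprintf(
      "trajectory frames have %s coordinates but topology has %d atoms",
      if (is.matrix(xyz)) ncol(xyz) else "?", n_atoms
    ))
  }
  if (nrow(xyz) < 1) abort("trajectory must contain at least one frame")
  if (is.null(times)) times <- (seq_len(nrow(xyz)) - 1) * dt
  if (length(times) != nrow(xyz) || any(diff(times) <= 0)) {
    abort("frame times must match frame count and increase strictly")
  }
  structure(
    list(topology = topology, xyz = unname(xyz), times = as.numeric(times)),
    class = "mdtrajectory"
  )
}

#' Read a trajectory bound to a topology
#'
#' Reads one or more trajectory files and concatenates their frames in file
#' order. Supported formats: DCD (via bio3d) and multi-model PDB. Every
#' frame's atom count must match the topology.
#'
#' @param topology An `mdstruct` (see [read_structure()]).
#' @param paths Character vector of trajectory file paths.
#' @param dt Frame spacing in ns used to synthesize times (default 1).
#' @param times Optional explicit frame times (ns) for the concatenated set.
#' @return An `mdtrajectory`.
#' @export
read_trajectory <- function(topology, paths, dt = 1, times = NULL) {
  stopifnot(length(paths) >= 1)
  frames <- lapply(paths, function(p) {
    if (!file.exists(p)) abort(paste0("trajectory file not found: ", p))
    ext <- tolower(tools::file_ext(p))
    xyz <- switch(ext,
      dcd = unclass(bio3d::read.dcd(p, verbose = FALSE)),
      pdb = ,
      pdbqt = ,
      ent = {
        m <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
        unclass(m$xyz)
      },
      abort(paste0("unsupported trajectory format: .", ext,
                   " (use DCD or multi-model PDB)"))
    )
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
    xyz
  })
  widths <- vapply(frames, ncol, integer(1))
  if (length(unique(widths)) != 1 ||
      widths[1] != 3 * nrow(topology$atoms)) {
    abort(sprintf(
      "atom-count mismatch: topology has %d atoms; trajectory frames have %s",
      nrow(topology$atoms),
      paste(unique(widths / 3), collapse = ", ")
    ))
  }
  trajectory(topology, do.call(rbind, frames), times = times, dt = dt)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj An `mdtrajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "mdtrajectory"))
  top <- traj$topology
  bio3d::write.pdb(
    file = path,
    xyz = traj$xyz,
    type = ifelse(top$atoms$het & !(top$atoms$resid %in% AMINO3),
                  "HETATM", "ATOM"),
    resno = top$atoms$resno,
    resid = top$atoms$resid,
    eleno = top$atoms$eleno,
    elety = top$atoms$elety,
    chain = top$atoms$chain,
    o = top$atoms$occ,
    b = rep(0, nrow(top$atoms)),
    elesy = top$atoms$elem
  )
  invisible(path)
}

#' Number of frames in a trajectory
#' @param traj An `mdtrajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

# A x 3 coordinates of one frame
frame_coords <- function(traj, frame) {
  matrix(traj$xyz[frame, ], ncol = 3, byrow = TRUE)
}

# F x 3 coordinate block of a single atom
atom_coords <- function(traj, atom) {
  traj$xyz[, (3 * (atom - 1) + 1):(3 * atom), drop = FALSE]
}

# xyz column indices of a set of atom indices (bio3d layout)
xyz_cols <- function(atoms) {
  as.vector(rbind(3 * (atoms - 1) + 1, 3 * (atoms - 1) + 2, 3 * atoms))
}

#' Restrict a trajectory to a frame window
#'
#' Windows are half-open `[start, end)` and may be given either as frame
#' indices or as fractions of the trajectory length (both in `[0, 1]`), e.g.
#' `frame_window(traj, 0.75, 1)` keeps the last quarter of the frames —
#' the usual way to isolate a settled (e.g. activated-state) segment for
#' correlation analysis.
#'
#' @param traj An `mdtrajectory`.
#' @param start,end Window bounds; fractions if both are <= 1.
#' @return An `mdtrajectory` containing the selected frames.
#' @export
frame_window <- function(traj, start, end) {
  f <- n_frames(traj)
  if (start <= 1 && end <= 1) {
    i0 <- floor(start * f) + 1
    i1 <- floor(end * f + 1e-9)
  } else {
    i0 <- start
    i1 <- end - 1
  }
  i0 <- max(1L, as.integer(i0))
  i1 <- min(f, as.integer(i1))
  if (i1 < i0) abort("frame window is empty")
  if (i1 - i0 < 1) warn("frame window has fewer than 2 frames")
  trajectory(
    traj$topology,
    traj$xyz[i0:i1, , drop = FALSE],
    times = traj$times[i0:i1]
  )
}

#' @export
print.mdtrajectory <- function(x, ...) {
  cat(
    "<mdtrajectory> ", n_frames(x), " frames x ", nrow(x$topology$atoms),
    " atoms, t = [", x$times[1], ", ", x$times[n_frames(x)], "] ns\n",
    sep = ""
  )
  invisible(x)
}
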