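# Shared fixtures, all built in code at test time.

# Minimal PDB text with configurable atoms. `atoms` is a data.frame with
# columns: eleno, elety, alt, resid, chain, resno, x, y, z, occ.
write_pdb_text <- function(atoms, path) {
  fmt <- paste0(
    "ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f  0.00          %2s"
  )
  pad_elety <- function(e) {
    # PDB convention: columns 13-16, element right-padded from column 14
    ifelse(nchar(e) >= 4, e, sprintf(" %-3s", e))
  }
  lines <- sprintf(
    fmt, atoms$eleno, pad_elety(atoms$elety),
    ifelse(is.na(atoms$alt), " ", atoms$alt),
    atoms$resid, atoms$chain, atoms$resno,
    atoms$x, atoms$y, atoms$z, atoms$occ,
    substr(trimws(atoms$elety), 1, 1)
  )
  writeLines(c(lines, "END"), path)
  path
}

# One-residue (GLY: N, CA, C) PDB file
one_residue_pdb <- function(path = tempfile(fileext = ".pdb")) {
  atoms <- data.frame(
    eleno = 1:3, elety = c("N", "CA", "C"), alt = NA,
    resid = "GLY", chain = "A", resno = 1,
    x = c(0, 1.458, 2.0), y = c(0, 0, 1.4), z = 0, occ = 1
  )
  write_pdb_text(atoms, path)
}

# Random rigid rotation matrix (seeded by caller)
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2
  ), 3, 3, byrow = TRUE)
}

# Apply a rigid transform to every frame of a trajectory
transform_trajectory <- function(traj, rot = diag(3), shift = c(0, 0, 0)) {
  f <- gctraj::n_frames(traj)
  n <- ncol(traj$xyz) / 3
  xyz <- traj$xyz
  for (fr in seq_len(f)) {
    m <- matrix(xyz[fr, ], ncol = 3, byrow = TRUE)
    m <- m %*% t(rot)
    m <- sweep(m, 2, -shift)
    xyz[fr, ] <- as.vector(t(m))
  }
  out <- gctraj::trajectory(traj$topology, xyz, times = traj$times)
  attributes(out)[setdiff(names(attributes(traj)), names(attributes(out)))] <-
    attributes(traj)[setdiff(names(attributes(traj)), names(attributes(out)))]
  out
}

# Cα-only pseudo-protein structure spanning given residue numbers
calpha_pdb <- function(resno, path = tempfile(fileext = ".pdb"),
                       chain = "A") {
  atoms <- data.frame(
    eleno = seq_along(resno), elety = "CA", alt = NA,
    resid = "ALA", chain = chain, resno = resno,
    x = 3.8 * seq_along(resno),
    y = 2 * sin(seq_along(resno) / 3),
    z = 2 * cos(seq_along(resno) / 5), occ = 1
  )
  write_pdb_text(atoms, path)
}

# Trajectory with explicitly given per-frame coordinate list (A x 3 each)
traj_from_frames <- function(topology, frames, dt = 1) {
  xyz <- do.call(rbind, lapply(frames, function(m) as.vector(t(m))))
  gctraj::trajectory(topology, xyz, dt = dt)
}
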