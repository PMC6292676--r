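make_two_atom_traj <- function(coords_a, coords_b) {
  top <- read_structure(calpha_pdb(1:2))
  frames <- Map(function(a, b) rbind(a, b), coords_a, coords_b)
  traj_from_frames(top, frames)
}

test_that("pair distances reproduce hand geometry and degenerate cases", {
  traj <- make_two_atom_traj(
    list(c(0, 0, 0), c(1, 1, 1)),
    list(c(3, 4, 0), c(1, 1, 1))
  )
  d <- pair_distance_series(traj, 1, 2)
  expect_equal(d$distance, c(5, 0))
  # identical selections give zero every frame
  same <- pair_distance_series(traj, 1, 1)
  expect_equal(same$distance, c(0, 0))
  expect_error(pair_distance_series(traj, integer(0), 2), "empty")
})

test_that("distances are invariant under rigid motions of each frame", {
  set.seed(42)
  top <- read_structure(calpha_pdb(1:5))
  traj <- traj_from_frames(
    top, replicate(4, top$xyz + matrix(rnorm(15), 5, 3), simplify = FALSE)
  )
  moved <- transform_trajectory(traj, random_rotation(), rnorm(3, sd = 20))
  d0 <- pair_distance_series(traj, 1, 4)$distance
  d1 <- pair_distance_series(moved, 1, 4)$distance
  expect_equal(d1, d0, tolerance = 1e-6)
})

test_that("salt-bridge distances use side-chain group COMs", {
  # Asp OD1 (0,0,0), OD2 (0,0,2) -> COM (0,0,1); Lys NZ (3,0,1) -> 3.0 A
  atoms <- data.frame(
    eleno = 1:6,
    elety = c("CA", "CG", "OD1", "OD2", "CA", "NZ"),
    alt = NA,
    resid = c(rep("ASP", 4), "LYS", "LYS"),
    chain = "A", resno = c(1, 1, 1, 1, 2, 2),
    x = c(-2, -1, 0, 0, 5, 3), y = 0, z = c(0, 1, 0, 2, 1, 1), occ = 1
  )
  s <- read_structure(write_pdb_text(atoms, tempfile(fileext = ".pdb")))
  traj <- trajectory(s, s$xyz)
  sb <- salt_bridge_series(traj, acidic = list(chain = "A", resno = 1),
                           basic = list(chain = "A", resno = 2))
  expect_equal(sb$distance, 3.0)
  expect_equal(as.character(sb$strength), "strong")
})

test_that("salt-bridge contracts reject wrong residue types and missing atoms", {
  s <- read_structure(one_residue_pdb())  # GLY
  traj <- trajectory(s, s$xyz)
  expect_error(
    salt_bridge_series(traj, acidic = list(chain = "A", resno = 1),
                       basic = list(chain = "A", resno = 1)),
    "not a valid acidic"
  )
  # Asp missing OD2
  atoms <- data.frame(
    eleno = 1:3, elety = c("CA", "OD1", "NZ"), alt = NA,
    resid = c("ASP", "ASP", "LYS"), chain = "A", resno = c(1, 1, 2),
    x = 0:2, y = 0, z = 0, occ = 1
  )
  s2 <- read_structure(write_pdb_text(atoms, tempfile(fileext = ".pdb")))
  traj2 <- trajectory(s2, s2$xyz)
  expect_error(
    salt_bridge_series(traj2, acidic = list(chain = "A", resno = 1),
                       basic = list(chain = "A", resno = 2)),
    "missing side-chain"
  )
})

test_that("salt-bridge series are consistent under time reversal", {
  fx <- make_salt_bridge_fixture(3)
  xyz <- rbind(
    as.vector(t(fx$xyz)),
    as.vector(t(fx$xyz + 0.5)),
    as.vector(t(fx$xyz + 1.0))
  )
  traj <- trajectory(fx, xyz)
  rev_traj <- trajectory(fx, xyz[3:1, ])
  a <- salt_bridge_series(traj, list(chain = "A", resno = 1),
                          list(chain = "A", resno = 2))
  b <- salt_bridge_series(rev_traj, list(chain = "A", resno = 1),
                          list(chain = "A", resno = 2))
  expect_equal(rev(b$distance), a$distance)
})

test_that("cross-domain salt-bridge scans find engineered pairs only", {
  fx <- make_salt_bridge_fixture(3)
  traj <- trajectory(fx, fx$xyz)
  domains <- resolve_domains(
    list(D1 = list(chain = "A", ranges = list(c(1, 1))),
         D2 = list(chain = "A", ranges = list(c(2, 2)))),
    fx
  )
  hits <- scan_salt_bridges(traj, domains, "D1", "D2")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$acidic_resno, 1)
  expect_equal(hits$basic_resno, 2)
  expect_equal(hits$occupancy, 1)

  far <- make_salt_bridge_fixture(20)
  hits2 <- scan_salt_bridges(trajectory(far, far$xyz),
                             resolve_domains(
                               list(D1 = list(chain = "A", ranges = list(c(1, 1))),
                                    D2 = list(chain = "A", ranges = list(c(2, 2)))),
                               far),
                             "D1", "D2")
  expect_equal(nrow(hits2), 0)
  expect_error(scan_salt_bridges(traj, domains, "D1", "NOPE"), "unknown domain")
})

test_that("occupancy thresholds are boundary-exact", {
  fx <- make_salt_bridge_fixture(3)
  # frame 1 at 3 A (formed), frame 2 pushed to 10 A (broken)
  moved <- fx$xyz
  moved[6:8, 1] <- moved[6:8, 1] + 7
  traj <- trajectory(fx, rbind(as.vector(t(fx$xyz)), as.vector(t(moved))))
  domains <- resolve_domains(
    list(D1 = list(chain = "A", ranges = list(c(1, 1))),
         D2 = list(chain = "A", ranges = list(c(2, 2)))),
    fx
  )
  expect_equal(
    nrow(scan_salt_bridges(traj, domains, "D1", "D2", min_occupancy = 1.0)),
    0
  )
  expect_equal(
    nrow(scan_salt_bridges(traj, domains, "D1", "D2", min_occupancy = 0.5)),
    1
  )
})

test_that("contact series report the nearest partner with low-resno tie-break", {
  atoms <- data.frame(
    eleno = 1:4,
    elety = c("CA", "P", "P", "P"),
    alt = NA,
    resid = c("ALA", "DA", "DA", "DA"),
    chain = c("A", "C", "C", "C"),
    resno = c(1, 11, 12, 13),
    x = c(0, 3, 10, -3), y = 0, z = 0, occ = 1
  )
  s <- read_structure(write_pdb_text(atoms, tempfile(fileext = ".pdb")),
                      require_protein = TRUE)
  traj <- trajectory(s, s$xyz)
  partner <- select_atoms(s, chain = "C")
  cs <- contact_series(traj, list(chain = "A", resno = 1), partner)
  expect_equal(cs$min_distance, 3)
  # residues 11 and 13 both at 3 A: lowest resno wins
  expect_equal(cs$partner_resno, 11)
  # residue against itself is allowed and gives zero
  self <- contact_series(traj, list(chain = "A", resno = 1),
                         select_atoms(s, chain = "A"))
  expect_equal(self$min_distance, 0)
  expect_error(contact_series(traj, list(chain = "A", resno = 1), integer(0)),
               "empty")
})

test_that("moving-average smoothing truncates windows at the ends", {
  top <- read_structure(calpha_pdb(1:2))
  frames <- lapply(c(1, 2, 3, 4, 5), function(d) {
    rbind(c(0, 0, 0), c(d, 0, 0))
  })
  ser <- pair_distance_series(traj_from_frames(top, frames), 1, 2)
  sm <- smooth_series(ser, 3)
  expect_equal(sm$smoothed, c(1.5, 2, 3, 4, 4.5))
  expect_equal(sm$distance, 1:5)  # raw kept
  expect_equal(smooth_series(ser, 1)$smoothed, ser$distance)
  const <- ser
  const$distance <- rep(2, 5)
  expect_equal(smooth_series(const, 5)$smoothed, rep(2, 5))
  expect_error(smooth_series(ser, 2), "odd")
  expect_error(smooth_series(ser, 7), "odd|within")
})
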