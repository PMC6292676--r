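# Brute-force rigid-fit oracle: coarse search over rotations (Euler grid)
# followed by local refinement, centroids matched exactly.
grid_fit_rmsd <- function(mobile, fixed, n_grid = 24) {
  mob_c <- sweep(mobile, 2, colMeans(mobile))
  fix_c <- sweep(fixed, 2, colMeans(fixed))
  rot <- function(a, b, c) {
    rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
                 byrow = TRUE)
    ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
                 byrow = TRUE)
    rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    rz %*% ry %*% rz2
  }
  obj <- function(p) {
    r <- rot(p[1], p[2], p[3])
    sqrt(mean(rowSums((mob_c %*% t(r) - fix_c)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = n_grid)
  best <- Inf
  best_p <- c(0, 0, 0)
  for (a in grid) for (b in grid[grid <= pi]) for (c in grid) {
    v <- obj(c(a, b, c))
    if (v < best) {
      best <- v
      best_p <- c(a, b, c)
    }
  }
  stats::optim(best_p, obj, method = "Nelder-Mead")$value
}

test_that("superposition removes pure rotations and translations exactly", {
  set.seed(5)
  top <- read_structure(calpha_pdb(1:6))
  base <- top$xyz + matrix(rnorm(18), 6, 3)
  top$xyz <- base
  frames <- replicate(5, {
    r <- random_rotation()
    sweep(base %*% t(r), 2, -rnorm(3, sd = 30))
  }, simplify = FALSE)
  traj <- traj_from_frames(top, frames)
  fitted <- superpose(traj)
  expect_lt(max(attr(fitted, "rmsd")), 1e-6)
  expect_error(superpose(traj, fit_sel = 1:2), "at least 3")
})

test_that("least-squares fit matches a brute-force rotation-search oracle", {
  set.seed(8)
  top <- read_structure(calpha_pdb(1:5))
  ref <- top$xyz + matrix(rnorm(15), 5, 3)
  top$xyz <- ref
  mobile <- ref + matrix(rnorm(15, sd = 0.6), 5, 3)
  mobile <- sweep(mobile %*% t(random_rotation()), 2, c(5, -3, 2))
  traj <- traj_from_frames(top, list(mobile))
  fitted <- superpose(traj)
  kabsch_rmsd <- attr(fitted, "rmsd")[1]
  oracle <- grid_fit_rmsd(mobile, ref)
  expect_equal(kabsch_rmsd, oracle, tolerance = 1e-3)
  # the optimal fit can never be beaten
  expect_lte(kabsch_rmsd, oracle + 1e-6)
  # and fitting never increases the RMSD of the raw frame
  raw <- sqrt(mean(rowSums((mobile - ref)^2)))
  expect_lte(kabsch_rmsd, raw + 1e-9)
})

test_that("fit recovers the noise level on large synthetic frames", {
  set.seed(13)
  n <- 500
  top <- read_structure(calpha_pdb(1:n))
  sigma <- 0.5
  frames <- replicate(4, {
    noisy <- top$xyz + matrix(rnorm(3 * n, sd = sigma), n, 3)
    sweep(noisy %*% t(random_rotation()), 2, rnorm(3, sd = 10))
  }, simplify = FALSE)
  fitted <- superpose(traj_from_frames(top, frames))
  # isotropic per-coordinate noise sigma -> per-atom displacement sigma*sqrt(3)
  # (minus ~6/3n lost to the fitted rigid-body dof, negligible at n = 500)
  expect_equal(mean(attr(fitted, "rmsd")), sigma * sqrt(3),
               tolerance = 0.1)
})

test_that("a static trajectory has an all-zero eigenvalue spectrum", {
  top <- read_structure(calpha_pdb(1:4))
  traj <- traj_from_frames(top, list(top$xyz, top$xyz, top$xyz))
  p <- ed_pca(traj)
  expect_equal(p$values, rep(0, 12))
  expect_equal(unname(p$projections), matrix(0, 3, 12))
})

test_that("PCA satisfies trace, centering and orthonormality invariants", {
  set.seed(21)
  top <- read_structure(calpha_pdb(1:6))
  frames <- replicate(40, top$xyz + matrix(rnorm(18), 6, 3), simplify = FALSE)
  traj <- traj_from_frames(top, frames)
  p <- ed_pca(traj)
  x <- traj$xyz
  cov_trace <- sum(apply(sweep(x, 2, colMeans(x)), 2,
                         function(v) mean(v^2)))
  expect_equal(sum(p$values), cov_trace, tolerance = 1e-8)
  expect_lt(max(abs(crossprod(p$vectors) - diag(ncol(p$vectors)))), 1e-6)
  expect_lt(max(abs(colMeans(p$projections))), 1e-10)
})

test_that("PCA recovers a known diagonal covariance at F = 2000", {
  set.seed(31)
  top <- read_structure(calpha_pdb(1:2))
  vars <- c(4, 1, 0.25, 0.04, 0.01, 0.0025)
  x <- sapply(vars, function(v) rnorm(2000, sd = sqrt(v)))
  base <- as.vector(t(top$xyz))
  traj <- trajectory(top, sweep(x, 2, base, "+"))
  p <- ed_pca(traj)
  expect_equal(p$values, sort(vars, decreasing = TRUE), tolerance = 0.15)
})

test_that("projection reproduces stored values and constructed displacements", {
  set.seed(41)
  top <- read_structure(calpha_pdb(1:5))
  frames <- replicate(30, top$xyz + matrix(rnorm(15), 5, 3), simplify = FALSE)
  traj <- traj_from_frames(top, frames)
  p <- ed_pca(traj)
  proj <- project_frames(traj, p, n_modes = 3)
  expect_equal(proj$PC1, p$projections[, 1])
  expect_equal(proj$PC3, p$projections[, 3])
  # the mean structure projects to zero
  mean_traj <- trajectory(top, rbind(p$mean, p$mean))
  expect_lt(max(abs(project_frames(mean_traj, p, 2)[, c("PC1", "PC2")])), 1e-10)
  # a frame displaced +1 A along mode 1 projects to (1, 0, ...)
  disp <- trajectory(top, rbind(p$mean + p$vectors[, 1], p$mean))
  pd <- project_frames(disp, p, 3)
  expect_equal(unlist(pd[1, c("PC1", "PC2", "PC3")]),
               c(PC1 = 1, PC2 = 0, PC3 = 0), tolerance = 1e-10)
  expect_error(project_frames(traj, p, n_modes = 99), "exceeds")
})

test_that("mode displacements split eigenvectors per residue with unit norm", {
  top <- read_structure(calpha_pdb(1:4))
  set.seed(51)
  frames <- replicate(20, top$xyz + matrix(rnorm(12), 4, 3), simplify = FALSE)
  p <- ed_pca(traj_from_frames(top, frames))
  md <- mode_displacements(p, 1)
  expect_equal(nrow(md), 4)
  expect_equal(sum(md$magnitude^2), 1, tolerance = 1e-10)
  expect_error(mode_displacements(p, 13), "out of range")
  # a hinge: only residue 4 moves -> top mode concentrated there
  hinge <- lapply(seq(-2, 2, length.out = 20), function(s) {
    m <- top$xyz
    m[4, 2] <- m[4, 2] + s
    m
  })
  ph <- ed_pca(traj_from_frames(top, hinge))
  mh <- mode_displacements(ph, 1)
  expect_gt(mh$magnitude[4], 0.99)
  expect_lt(max(mh$magnitude[1:3]), 0.01)
})

test_that("eigen-decomposition agrees with an independent PCA implementation", {
  set.seed(71)
  top <- read_structure(calpha_pdb(1:5))
  frames <- replicate(60, top$xyz + matrix(rnorm(15), 5, 3), simplify = FALSE)
  traj <- traj_from_frames(top, frames)
  p <- ed_pca(traj)
  ref <- bio3d::pca.xyz(traj$xyz)
  f <- n_frames(traj)
  # bio3d uses the 1/(F-1) sample covariance; rescale to population terms
  expect_equal(p$values, ref$L * (f - 1) / f, tolerance = 1e-8)
  # leading subspaces coincide (up to sign)
  expect_equal(abs(sum(p$vectors[, 1] * ref$U[, 1])), 1, tolerance = 1e-6)
})

test_that("the spectrum is invariant under mirroring and rigid rotation", {
  set.seed(61)
  top <- read_structure(calpha_pdb(1:5))
  frames <- replicate(25, top$xyz + matrix(rnorm(15), 5, 3), simplify = FALSE)
  traj <- traj_from_frames(top, frames)
  p <- ed_pca(traj)
  # mirror: duplicate frames with displacements negated about the mean
  mu <- matrix(colMeans(traj$xyz), nrow = 1)
  mirrored <- trajectory(top, rbind(traj$xyz,
                                    sweep(-sweep(traj$xyz, 2, mu), 2, mu, "+")))
  pm <- ed_pca(mirrored)
  expect_equal(pm$values, p$values, tolerance = 1e-8)
  # rigid rotation of the whole (superposed) trajectory
  rot <- transform_trajectory(traj, random_rotation(), c(3, 1, -2))
  pr <- ed_pca(rot)
  expect_equal(pr$values, p$values, tolerance = 1e-8)
})
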