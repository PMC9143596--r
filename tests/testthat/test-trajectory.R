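test_that("Kabsch superposition recovers rigid transforms", {
  set.seed(21)
  a <- matrix(rnorm(30), ncol = 3)
  fit <- kabsch_superpose(a, a)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)

  R <- euler_rotation(0.4, 1.1, -0.7)
  b <- a %*% t(R) + matrix(rep(c(5, -3, 2), each = 10), ncol = 3)
  fit2 <- kabsch_superpose(b, a)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-8)
  expect_equal(fit2$transformed, a, tolerance = 1e-8)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-10)

  # mirrored coordinates still yield a proper rotation (det +1)
  mirrored <- a %*% diag(c(-1, 1, 1))
  fit3 <- kabsch_superpose(mirrored, a)
  expect_equal(det(fit3$rotation), 1, tolerance = 1e-10)
  expect_gt(fit3$rmsd, 0)

  expect_error(kabsch_superpose(a[1:2, ], a[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("Kabsch RMSD agrees with the bio3d reference fit", {
  set.seed(33)
  for (k in 1:10) {
    a <- matrix(rnorm(24), ncol = 3)
    b <- matrix(rnorm(24), ncol = 3)
    ours <- kabsch_superpose(a, b)$rmsd
    fitted <- suppressWarnings(
      bio3d::fit.xyz(as.vector(t(b)), as.vector(t(a))))
    ref <- sqrt(mean(colSums(
      matrix((fitted - as.vector(t(b)))^2, nrow = 3))))
    expect_equal(ours, ref, tolerance = 1e-6)
  }
})

test_that("RMSD series is zero for static and rigidly drifting motion", {
  base <- matrix(rnorm(30, sd = 3), ncol = 3)
  static <- array(rep(base, each = 5), c(5, 10, 3))
  traj <- make_traj(static)
  s <- rmsd_series(traj)
  expect_equal(s$rmsd, rep(0, 5), tolerance = 1e-10)
  expect_equal(s$rmsd[1], 0)  # frame-0 reference

  drifting <- gen_trajectory(10, 6, sigma = 0, drift = c(1, 2, 0),
                             seed = 2)$traj
  s2 <- rmsd_series(drifting)
  expect_equal(s2$rmsd, rep(0, 6), tolerance = 1e-8)
  # without superposition the drift is visible
  s3 <- rmsd_series(drifting, superpose = FALSE)
  expect_gt(s3$rmsd[6], 1)
})

test_that("RMSD series equals an independent superpose-then-RMS oracle", {
  sim <- gen_trajectory(12, 8, sigma = 0.4, seed = 14)
  s <- rmsd_series(sim$traj)
  ref <- matrix(sim$traj$coords[1, , ], ncol = 3)
  for (f in seq_len(8)) {
    cur <- matrix(sim$traj$coords[f, , ], ncol = 3)
    fitted <- suppressWarnings(
      bio3d::fit.xyz(as.vector(t(ref)), as.vector(t(cur))))
    oracle <- sqrt(mean(colSums(
      matrix((fitted - as.vector(t(ref)))^2, nrow = 3))))
    expect_equal(s$rmsd[f], oracle, tolerance = 1e-8)
  }
})

test_that("RMSF recovers planted isotropic fluctuations", {
  sim <- gen_trajectory(5, 6000, sigma = 0.5, seed = 8)
  out <- rmsf_per_residue(sim$traj, window = "all",
                          superpose = FALSE)
  # isotropic N(0, 0.5^2) per coordinate -> RMSF = 0.5 * sqrt(3)
  expect_equal(out$rmsf, rep(0.5 * sqrt(3), 5), tolerance = 0.02)

  static <- make_traj(array(rep(matrix(rnorm(30), ncol = 3),
                                each = 4), c(4, 10, 3)))
  expect_equal(rmsf_per_residue(static, window = "all")$rmsf,
               rep(0, 10), tolerance = 1e-10)
})

test_that("RMSF ordering follows planted amplitudes across seeds", {
  for (seed in 1:5) {
    sim <- gen_trajectory(2, 400, sigma = c(0.2, 0.6), seed = seed)
    out <- rmsf_per_residue(sim$traj, window = "all",
                            superpose = FALSE)
    expect_lt(out$rmsf[1], out$rmsf[2])
  }
})

test_that("RMSF uses the trailing window by default", {
  # quiet first half, noisy second half
  quiet <- gen_trajectory(4, 50, sigma = 0.05, seed = 3)$traj
  noisy <- gen_trajectory(4, 50, sigma = 0.8, seed = 4)$traj
  coords <- array(0, c(100, 4, 3))
  coords[1:50, , ] <- quiet$coords
  coords[51:100, , ] <- noisy$coords
  both <- make_traj(coords)
  trailing <- rmsf_per_residue(both, superpose = FALSE)
  full <- rmsf_per_residue(both, window = "all", superpose = FALSE)
  expect_gt(mean(trailing$rmsf), mean(full$rmsf))
  expect_error(rmsf_per_residue(both, window = 5L), "at least 2")
})

test_that("distance series tracks per-frame closest atoms", {
  # static 3-4-5 right triangle: distance is exactly 5
  coords <- array(0, c(3, 3, 3))
  for (f in 1:3) {
    coords[f, 1, ] <- c(0, 0, 0)
    coords[f, 2, ] <- c(3, 4, 0)
    coords[f, 3, ] <- c(0, 0, 0)
  }
  traj <- make_traj(coords)
  d <- distance_series(traj, atom_a = 1, atoms_b = c(2, 3),
                       labels = c("C1", "C2"))
  expect_equal(d$C1, rep(5, 3))
  expect_equal(d$C2, rep(0, 3))   # coincident atoms
  expect_equal(d$closest, rep("C2", 3))

  # planted sliding: closest carbon switches from C1 to C3 at frame 4
  coords2 <- array(0, c(6, 4, 3))
  for (f in 1:6) {
    coords2[f, 1, ] <- c(0, 0, 0)                      # probe
    coords2[f, 2, ] <- c(if (f < 4) 2 else 9, 0, 0)    # C1
    coords2[f, 3, ] <- c(5, 5, 0)                      # C2
    coords2[f, 4, ] <- c(0, if (f < 4) 6 else 1, 0)    # C3
  }
  traj2 <- make_traj(coords2)
  d2 <- distance_series(traj2, 1, c(2, 3, 4),
                        labels = c("C1", "C2", "C3"))
  expect_equal(d2$closest, c("C1", "C1", "C1", "C3", "C3", "C3"))

  expect_error(distance_series(traj, atom_a = c(1, 2), atoms_b = 3),
               "exactly one")
})

test_that("hydrogen bonds require both distance and angle", {
  # linear O-H...O at 2.8 A
  coords <- rbind(c(0, 0, 0),      # donor O
                  c(1.0, 0, 0),    # H
                  c(2.8, 0, 0))    # acceptor O
  donors <- data.frame(donor = 1L, hydrogen = 2L)
  hb <- hydrogen_bonds(coords, donors, acceptors = 3L)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.8)
  expect_equal(hb$angle, 180)

  # same geometry stretched to 3.6 A: rejected by distance
  far <- coords; far[3, 1] <- 3.6
  expect_equal(nrow(hydrogen_bonds(far, donors, 3L)), 0)

  # donor-H-acceptor angle of 60 degrees: rejected by angle alone
  bent <- rbind(c(0, 0, 0), c(1.0, 0, 0),
                c(1.0, 0, 0) + 1.9 * c(-cos(pi / 3), sin(pi / 3), 0))
  d_heavy <- sqrt(sum((bent[3, ] - bent[1, ])^2))
  expect_lt(d_heavy, 3.5)
  expect_equal(nrow(hydrogen_bonds(bent, donors, 3L)), 0)

  expect_error(hydrogen_bonds(coords,
                              data.frame(donor = 1L,
                                         hydrogen = NA_integer_),
                              3L), "hydrogen")
})

test_that("trajectory PDB round trip preserves coordinates and topology", {
  sim <- gen_trajectory(6, 4, sigma = 0.3, seed = 19)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(sim$traj, path)
  back <- read_trajectory_pdb(path)
  expect_equal(dim(back$coords), dim(sim$traj$coords))
  # PDB carries 3 decimals
  expect_equal(back$coords, sim$traj$coords, tolerance = 1e-3)
  expect_equal(back$topology$resno, sim$traj$topology$resno)
  expect_equal(back$dt, sim$traj$dt)
})
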