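test_that("landscape scoring is deterministic and order-independent", {
  wt <- c(`112` = "D", `238` = "S")
  land <- gen_landscape(c(112, 238), wt, wt_energy = -7,
                        additive = data.frame(site = 238, aa = "C",
                                              effect = -1.6),
                        noise_sd = 0.3, seed = 42)
  v <- list(sites = 238L, new_aas = "C")
  a <- land$score(v)
  # independent of query order and global RNG state
  land$score(list(sites = 112L, new_aas = "M"))
  runif(5)
  expect_identical(land$score(v), a)
  # same config, fresh generator: byte-identical
  land2 <- gen_landscape(c(112, 238), wt, wt_energy = -7,
                         additive = data.frame(site = 238, aa = "C",
                                               effect = -1.6),
                         noise_sd = 0.3, seed = 42)
  expect_identical(land2$score(v), a)

  expect_error(land$score(list(sites = 999L, new_aas = "A")),
               "unknown site")
  expect_error(
    gen_landscape(c(112), c(`112` = "D"),
                  additive = data.frame(site = 112, aa = "D",
                                        effect = -1)),
    "WT residue")
})

test_that("noise-free landscape reproduces planted effects exactly", {
  wt <- c(`112` = "D", `119` = "Q", `238` = "S")
  land <- gen_landscape(
    c(112, 119, 238), wt, wt_energy = -7,
    additive = data.frame(site = c(238, 112),
                          aa = c("C", "M"),
                          effect = c(-1.6, -0.9)),
    epistasis = data.frame(site_a = 112, site_b = 238, effect = -0.5,
                           aa_a = "M", aa_b = "F"),
    noise_sd = 0)
  expect_equal(land$score(list(sites = integer(0),
                               new_aas = character(0))), -7)
  expect_equal(land$score(list(sites = 238L, new_aas = "C")), -8.6)
  expect_equal(land$ground_truth$single$label, "S238C")
  expect_equal(land$ground_truth$single$delta_delta_g, -1.6)
  # residue-specific epistasis only fires for that residue pair
  expect_equal(land$score(list(sites = c(112L, 238L),
                               new_aas = c("M", "F"))),
               -7 - 0.9 - 0.5)
  expect_equal(land$score(list(sites = c(112L, 238L),
                               new_aas = c("M", "C"))),
               -7 - 0.9 - 1.6)
  expect_equal(land$ground_truth$double$label, "D112M/S238C")
})

test_that("planted pose clusters are exactly recovered", {
  sim <- gen_pose_set(k_clusters = 3, spread = 0.5, n_poses = 24,
                      seed = 6, separation = 10)
  cl <- cluster_poses(sim$poses, 2.0)
  expect_length(cl, 3)
  for (c1 in cl) {
    expect_length(unique(sim$true_labels[c1$member_index]), 1)
  }
  got <- integer(24)
  for (k in seq_along(cl)) got[cl[[k]]$member_index] <- k
  expect_equal(length(unique(paste(got, sim$true_labels))), 3)

  expect_length(cluster_poses(gen_pose_set(1, 0.5, 8,
                                           seed = 2)$poses, 2.0), 1)
  expect_error(gen_pose_set(3, 5.5, 10, separation = 10),
               "infeasible")
})

test_that("poses planted away from the catalytic probe are rejected", {
  rec <- make_receptor()
  rules <- make_rules()
  # cluster center 30 A from every receptor atom
  sim <- gen_pose_set(1, spread = 0.3, n_poses = 6, seed = 3,
                      centers = list(matrix(rep(c(30, 30, 30),
                                                each = 4),
                                            ncol = 3)))
  for (p in sim$poses) {
    expect_false(pose_filter(p, rec, rules)$accept)
  }
})

test_that("trajectory generator honours sigma and drift", {
  flat <- gen_trajectory(8, 5, sigma = 0, seed = 1)
  expect_equal(rmsd_series(flat$traj)$rmsd, rep(0, 5),
               tolerance = 1e-12)
  # same seed, same bytes
  again <- gen_trajectory(8, 5, sigma = 0.4, seed = 7)
  again2 <- gen_trajectory(8, 5, sigma = 0.4, seed = 7)
  expect_identical(again$traj$coords, again2$traj$coords)
  expect_error(gen_trajectory(4, 5, sigma = -1), "non-negative")
})

test_that("energy-frame generator hits exact means at zero SD", {
  means <- rbind(complex = c(-150, -40, 110, -22),
                 protein = c(-100, -20, 60, -8),
                 ligand = c(-10, -5, 20, -4))
  frames <- gen_energy_frames(means, matrix(0, 3, 4), n = 5, seed = 1)
  s <- summarize_binding(frames)
  delta <- means["complex", ] - means["protein", ] - means["ligand", ]
  expect_equal(s$mean[1:4], unname(delta))
  expect_equal(s$sd, rep(0, 5))
  expect_error(gen_energy_frames(means, matrix(-1, 3, 4)), "negative")
  expect_error(gen_energy_frames(means[1:2, ], matrix(0, 2, 4)),
               "3 x 4")
})

test_that("generators emit the formats the readers consume", {
  # alignment
  path <- withr::local_tempfile(fileext = ".fasta")
  aln <- gen_alignment(n_seqs = 3, n_cols = 25, seed = 2, path = path)
  expect_identical(unname(read_alignment(path, "seq1")$rows),
                   unname(aln$rows))
  # poses: TSV and multi-model PDB
  sim <- gen_pose_set(2, 0.5, 6, seed = 4)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_poses_tsv(sim$poses, tsv)
  back <- read_poses_tsv(tsv)
  expect_length(back, 6)
  expect_equal(back[[3]]$coords, sim$poses[[3]]$coords,
               tolerance = 1e-8)
  expect_equal(back[[3]]$energy, sim$poses[[3]]$energy,
               tolerance = 1e-8)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_poses_pdb(sim$poses, pdb)
  back2 <- read_poses_pdb(pdb)
  expect_length(back2, 6)
  expect_equal(back2[[5]]$coords, sim$poses[[5]]$coords,
               tolerance = 1e-3)
  expect_equal(back2[[5]]$energy, sim$poses[[5]]$energy,
               tolerance = 1e-4)
  expect_equal(back2[[5]]$variant_label,
               sim$poses[[5]]$variant_label)
})

test_that("seed splitting keeps child seeds in 32-bit range", {
  for (s in c(0L, 1L, 999999L, 2147483646L)) {
    cs <- revscreen:::child_seed(s, "landscape:S238C")
    expect_true(cs >= 0 && cs < 2^31)
    expect_identical(cs, revscreen:::child_seed(s, "landscape:S238C"))
  }
  expect_false(identical(revscreen:::child_seed(1L, "a"),
                         revscreen:::child_seed(1L, "b")))
})
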