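test_that("snapshot selection is equidistant over the window", {
  # 2000 frames -> trailing window 1001:2000, 500 equidistant picks
  # spanning both endpoints (gaps of 2, with an occasional 3 because
  # 999 frame steps do not divide evenly into 499 intervals)
  idx <- select_snapshots(2000, 500)
  expect_length(idx, 500)
  expect_equal(idx[1], 1001)
  expect_equal(idx[500], 2000)
  expect_true(all(diff(idx) %in% c(2L, 3L)))

  # window exactly n_select -> identity
  idx2 <- select_snapshots(1000, 500)
  expect_equal(idx2, 501:1000)

  # spacing uniformity over a grid of sizes: gaps differ by <= 1
  for (nf in c(120, 333, 1007)) {
    for (ns in c(7, 50, 99)) {
      got <- select_snapshots(nf, ns, window = "all")
      expect_length(got, ns)
      expect_equal(got, sort(unique(got)))
      expect_true(all(got >= 1 & got <= nf))
      gaps <- diff(got)
      expect_lte(max(gaps) - min(gaps), 1)
    }
  }

  expect_warning(select_snapshots(100, 500), "taking all")
  expect_error(select_snapshots(100, 10, window = integer(0)),
               "window")
})

test_that("Shrake-Rupley SASA matches closed forms and a numerical oracle", {
  # isolated sphere: 4 pi (r + probe)^2
  one <- data.frame(x = 0, y = 0, z = 0, radius = 1.9)
  a1 <- sasa(one, probe = 1.4)
  expect_equal(sum(a1), 4 * pi * 3.3^2, tolerance = 0.01)

  # two distant atoms: additive
  two_far <- data.frame(x = c(0, 100), y = 0, z = 0,
                        radius = c(1.9, 1.5))
  expect_equal(sum(sasa(two_far, probe = 1.4)),
               4 * pi * (3.3^2 + 2.9^2), tolerance = 0.01)

  # overlapping pair vs latitude-band numerical oracle
  for (d in c(2.0, 3.5, 5.0)) {
    atoms <- data.frame(x = c(0, d), y = 0, z = 0,
                        radius = c(1.7, 1.52))
    got <- sum(sasa(atoms, probe = 1.4))
    oracle <- oracle_pair_sasa(c(0, 0, 0), c(d, 0, 0), 1.7, 1.52, 1.4)
    expect_equal(got, oracle, tolerance = 0.02)
  }

  # SASA decreases monotonically as two atoms approach
  areas <- sapply(c(8, 6, 4, 3, 2, 1), function(d) {
    sum(sasa(data.frame(x = c(0, d), y = 0, z = 0, radius = 1.7)))
  })
  expect_true(all(diff(areas) < 0))

  # element radii resolved from the shipped table
  el <- data.frame(x = 0, y = 0, z = 0, elem = "O")
  expect_equal(sum(sasa(el)), 4 * pi * (1.52 + 1.4)^2,
               tolerance = 0.01)
  expect_error(sasa(data.frame(x = 0, y = 0, z = 0, elem = "XX")),
               "no radius")
})

test_that("apolar energy is the linear surface-tension model", {
  expect_equal(apolar_energy(0), 3.84982)
  expect_equal(apolar_energy(100), 6.11760, tolerance = 1e-8)
  # linearity: E(2S) - E(S) = gamma * S
  s <- 137.3
  expect_equal(apolar_energy(2 * s) - apolar_energy(s),
               0.0226778 * s, tolerance = 1e-10)
  # slope by finite difference
  expect_equal((apolar_energy(1000) - apolar_energy(0)) / 1000,
               0.0226778, tolerance = 1e-12)
  expect_error(apolar_energy(-1), "non-negative")
})

test_that("binding energy is the complex-minus-components difference", {
  prot <- c(vdw = -3000, elec = -9000, polar = 2500, apolar = 90)
  lig <- c(vdw = -50, elec = -40, polar = 120, apolar = 25)
  same <- energy_frame(1, prot + lig, prot, lig)
  expect_equal(unname(binding_energy(same)), rep(0, 5))

  planted <- c(vdw = -10, elec = -5, polar = 7, apolar = -2)
  f <- energy_frame(2, prot + lig + planted, prot, lig)
  be <- binding_energy(f)
  expect_equal(be[["total"]], -10)
  expect_equal(unname(be[names(planted)]), unname(planted))

  # independent summation oracle on generated frames
  frames <- gen_energy_frames(
    term_means = rbind(complex = c(-100, -50, 80, -20),
                       protein = c(-80, -40, 60, -10),
                       ligand = c(-5, -3, 10, -4)),
    term_sds = matrix(5, 3, 4), n = 20, seed = 12)
  for (f in frames[1:5]) {
    oracle <- sum(f$complex) - sum(f$protein) - sum(f$ligand)
    expect_equal(binding_energy(f)[["total"]], oracle,
                 tolerance = 1e-12)
  }

  expect_error(energy_frame(1, prot[1:3], prot, lig), "terms")
})

test_that("binding summary gives per-term means and sample SDs", {
  prot <- c(vdw = -100, elec = -50, polar = 40, apolar = -10)
  lig <- c(vdw = -10, elec = -5, polar = 4, apolar = -1)
  const <- lapply(1:5, function(i) {
    energy_frame(i, prot + lig + c(vdw = -20, elec = -8, polar = 12,
                                   apolar = -3), prot, lig)
  })
  s <- summarize_binding(const)
  expect_equal(s$sd, rep(0, 5))
  expect_equal(s$mean[s$term == "total"], -19)
  # total mean equals the sum of term means exactly
  expect_equal(s$mean[s$term == "total"],
               sum(s$mean[s$term != "total"]))
  expect_error(summarize_binding(const[1]), "at least 2")

  # sampling behaviour: Gaussian frames recover parameterized means
  means <- rbind(complex = c(-150, -40, 110, -22),
                 protein = c(-100, -20, 60, -8),
                 ligand = c(-10, -5, 20, -4))
  frames <- gen_energy_frames(means, matrix(10, 3, 4), n = 500,
                              seed = 77)
  s2 <- summarize_binding(frames)
  true_total <- sum(means["complex", ] - means["protein", ] -
                      means["ligand", ])
  sd_total <- sqrt(sum(3 * 10^2 * 4))  # 12 independent terms of sd 10
  expect_lt(abs(s2$mean[s2$term == "total"] - true_total),
            3 * sd_total / sqrt(500))
})

test_that("per-residue deltas subtract the averaged WT profiles", {
  v <- matrix(rep(c(-2, 0, 1), each = 4), nrow = 4)
  colnames(v) <- c("10", "11", "12")
  wt1 <- matrix(rep(c(-1, 0, 1), each = 4), nrow = 4,
                dimnames = list(NULL, c("10", "11", "12")))
  wt2 <- wt1
  d <- per_residue_delta(v, list(wt1, wt2))
  expect_equal(unname(d), c(-1, 0, 0))
  expect_equal(per_residue_delta(wt1, list(wt1, wt2)),
               c(`10` = 0, `11` = 0, `12` = 0))
  bad <- wt1
  colnames(bad) <- c("10", "11", "99")
  expect_error(per_residue_delta(v, list(bad)), "differ")
})

test_that("per-residue decomposition conserves the decomposable total", {
  frames <- gen_energy_frames(
    term_means = rbind(complex = c(-100, -50, 80, -20),
                       protein = c(-80, -40, 60, -10),
                       ligand = c(-5, -3, 10, -4)),
    term_sds = matrix(8, 3, 4), n = 10, seed = 5, n_residues = 7)
  for (f in frames) {
    delta <- binding_energy(f)
    decomposable <- sum(delta[c("vdw", "elec", "polar")])
    expect_equal(sum(f$per_residue), decomposable, tolerance = 1e-9)
    expect_length(f$per_residue, 7)
  }
})

test_that("energy frame TSV round trip preserves all terms", {
  frames <- gen_energy_frames(
    term_means = rbind(complex = c(-100, -50, 80, -20),
                       protein = c(-80, -40, 60, -10),
                       ligand = c(-5, -3, 10, -4)),
    term_sds = matrix(3, 3, 4), n = 6, seed = 9, n_residues = 4)
  main <- withr::local_tempfile(fileext = ".tsv")
  pr <- withr::local_tempfile(fileext = ".tsv")
  write_energy_frames(frames, main, per_residue_path = pr)
  back <- read_energy_frames(main, per_residue_path = pr)
  expect_length(back, 6)
  for (i in seq_along(frames)) {
    expect_equal(back[[i]]$complex, frames[[i]]$complex,
                 tolerance = 1e-8)
    expect_equal(sum(back[[i]]$per_residue),
                 sum(frames[[i]]$per_residue), tolerance = 1e-8)
  }
})
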