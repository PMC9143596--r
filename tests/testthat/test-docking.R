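test_that("pose RMSD matches the direct per-atom formula", {
  p1 <- make_pose(1, c(0, 0, 0), -7)
  expect_equal(pose_rmsd(p1, p1), 0)
  p2 <- make_pose(2, c(3, 0, 0), -7)
  expect_equal(pose_rmsd(p1, p2), 3)
  # brute-force formula on random coordinates
  set.seed(9)
  a <- matrix(rnorm(15), ncol = 3)
  b <- matrix(rnorm(15), ncol = 3)
  direct <- sqrt(sum((a - b)^2) / 5)
  expect_equal(pose_rmsd(a, b), direct, tolerance = 1e-10)
  expect_error(pose_rmsd(a, b[1:3, ]), "differ")
})

test_that("leader clustering forms an energy-ordered partition", {
  dup <- lapply(1:10, function(i) make_pose(i, c(0, 0, 0), -7 + i / 10))
  cl <- cluster_poses(dup, 2.0)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size, 10)
  expect_equal(cl[[1]]$representative, 1)  # lowest energy

  far <- lapply(1:3, function(i) make_pose(i, c(10 * i, 0, 0), -6 - i))
  cl3 <- cluster_poses(far, 2.0)
  expect_length(cl3, 3)
  expect_equal(vapply(cl3, `[[`, numeric(1), "size"), c(1, 1, 1))
  # clusters ordered by representative energy
  expect_equal(vapply(cl3, `[[`, numeric(1), "energy"),
               sort(vapply(far, `[[`, numeric(1), "energy")))

  expect_equal(cluster_poses(list(), 2.0), list())
})

test_that("clustering invariants hold on random pose sets", {
  for (seed in 1:20) {
    sim <- gen_pose_set(k_clusters = 3, spread = 1.4, n_poses = 12,
                        seed = seed, separation = 6)
    cl <- cluster_poses(sim$poses, 2.0)
    all_members <- unlist(lapply(cl, `[[`, "member_index"))
    # partition: every pose in exactly one cluster
    expect_equal(sort(all_members), 1:12)
    for (c1 in cl) {
      e <- vapply(sim$poses[c1$member_index], `[[`, numeric(1),
                  "energy")
      # representative is cluster-minimal in energy
      expect_equal(min(e), c1$energy)
      # all member-representative RMSDs within tolerance
      rep_pose <- sim$poses[[c1$rep_index]]
      for (m in c1$member_index) {
        expect_lte(pose_rmsd(sim$poses[[m]], rep_pose), 2.0)
      }
    }
  }
})

test_that("pose filter applies catalytic distance and subsite contacts", {
  rec <- make_receptor()
  rules <- make_rules()
  # atom 3.9 A from OG, subsites contacted (atoms within 5 A of both)
  ok <- pose(1, rbind(c(3.9, 0, 0), c(4.0, 1.0, 0), c(1.0, 4.0, 0)),
             -7)
  res <- pose_filter(ok, rec, rules)
  expect_true(res$accept)
  expect_length(res$reasons, 0)

  # nearest ligand atom 4.1 A from OG -> catalytic_distance failure
  away <- pose(2, rbind(c(4.1, 0, 0), c(4.5, 1.0, 0), c(1.0, 4.0, 0)),
               -7)
  res2 <- pose_filter(away, rec, rules)
  expect_false(res2$accept)
  expect_true("catalytic_distance" %in% res2$reasons)

  # pose hugging subsite I only -> subsite_II failure
  one_side <- pose(3, rbind(c(3.5, 0, 0), c(4.5, 0, 0)), -7)
  res3 <- pose_filter(one_side, rec, rules)
  expect_false(res3$accept)
  expect_equal(res3$reasons, "subsite_II")

  bad_rules <- default_filter_rules(catalytic_resno = 999)
  expect_error(pose_filter(ok, rec, bad_rules), "not found")
})

test_that("deltaG selection takes the lowest accepted representative", {
  rec <- make_receptor()
  rules <- make_rules()
  good_center <- c(2.0, 2.0, 0)   # passes all rules
  # one accepted cluster with energies {-7.1, -6.8}
  poses <- list(make_pose(1, good_center, -7.1),
                make_pose(2, good_center, -6.8))
  sel <- select_delta_g(poses, rec, rules)
  expect_equal(sel$delta_g, -7.1)
  expect_equal(sel$accepted_pose, "1")

  # two accepted clusters: min rule
  poses2 <- c(poses,
              list(make_pose(3, good_center + c(0, 0, 2.5), -7.5)))
  expect_equal(select_delta_g(poses2, rec, rules)$delta_g, -7.5)

  # global minimum fails the catalytic filter -> next accepted cluster
  bad_center <- c(30, 30, 30)
  poses3 <- list(make_pose(1, bad_center, -9.0),
                 make_pose(2, good_center, -7.2))
  sel3 <- select_delta_g(poses3, rec, rules)
  expect_equal(sel3$delta_g, -7.2)
  expect_equal(sel3$n_accepted_clusters, 1L)

  # nothing accepted -> flagged record with undefined deltaG
  sel4 <- select_delta_g(list(make_pose(1, bad_center, -9.0)), rec,
                         rules)
  expect_true(sel4$flagged)
  expect_true(is.na(sel4$delta_g))

  # invariant to pose input order
  perm <- select_delta_g(rev(poses2), rec, rules)
  expect_equal(perm$delta_g, select_delta_g(poses2, rec, rules)$delta_g)
})

test_that("deltadeltaG is the arithmetic difference from wild type", {
  expect_equal(delta_delta_g(-7.2, -7.2), 0)
  expect_equal(delta_delta_g(-8.0, -7.0), -1.0)
  expect_true(is.na(delta_delta_g(NA, -7.0)))
})

test_that("selection threshold is mean minus sample SD", {
  thr <- selection_threshold(c(1, 1, 1))
  expect_equal(thr$mean, 1)
  expect_equal(thr$sd, 0)
  expect_equal(thr$cutoff, 1)

  thr2 <- selection_threshold(c(0, 2))
  expect_equal(thr2$mean, 1)
  expect_equal(thr2$sd, sqrt(2))
  expect_equal(thr2$cutoff, 1 - sqrt(2))

  # two-pass oracle on 42 values
  set.seed(2)
  v <- rnorm(42, -0.3, 0.8)
  m <- sum(v) / 42
  s <- sqrt(sum((v - m)^2) / 41)
  thr3 <- selection_threshold(v)
  expect_equal(thr3$mean, m, tolerance = 1e-12)
  expect_equal(thr3$sd, s, tolerance = 1e-12)
  expect_equal(thr3$cutoff, m - s, tolerance = 1e-12)
  expect_lte(thr3$cutoff, thr3$mean)

  expect_error(selection_threshold(c(1)), "at least 2")
})

test_that("candidate nomination is strictly below the cutoff", {
  rec <- data.frame(variant_label = c("a", "b", "c"),
                    delta_delta_g = c(-1, 0.5, 0))
  thr <- list(cutoff = 0)
  got <- nominate_candidates(rec, thr)
  expect_equal(got$variant_label, "a")
  # value exactly at the cutoff is excluded
  rec2 <- data.frame(variant_label = c("a", "b"),
                     delta_delta_g = c(0, -0.1))
  expect_equal(nominate_candidates(rec2, thr)$variant_label, "b")
})

test_that("planted single-site improvement is recovered through the screen", {
  wt <- c(`238` = "S", `119` = "Q", `87` = "Y")
  land <- gen_landscape(c(238, 119, 87), wt, wt_energy = -7,
                        additive = data.frame(site = 238, aa = "A",
                                              effect = -1.6),
                        noise_sd = 0.2, seed = 5)
  lib <- alanine_combinatorial(c(238, 119, 87), wt,
                               r_min = 1, r_max = 1)
  recs <- score_library(lib, land$score)
  got <- recs$delta_delta_g[recs$variant_label == "S238A"]
  # recovered within a few noise SDs (two draws enter the difference)
  expect_lt(abs(got - (-1.6)), 3 * 0.2 * sqrt(2))
})
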