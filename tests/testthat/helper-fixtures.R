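# Shared fixture builders; everything is generated in code.

# Minimal receptor atom table: a catalytic serine OG probe plus two
# cleft subsite anchors at configurable positions.
make_receptor <- function(og = c(0, 0, 0),
                          subsite_I = c(5, 0, 0),
                          subsite_II = c(0, 5, 0)) {
  data.frame(
    elety = c("OG", "CB", "CB"),
    resno = c(160L, 87L, 238L),
    resid = c("SER", "TYR", "SER"),
    x = c(og[1], subsite_I[1], subsite_II[1]),
    y = c(og[2], subsite_I[2], subsite_II[2]),
    z = c(og[3], subsite_I[3], subsite_II[3]),
    stringsAsFactors = FALSE
  )
}

make_rules <- function(...) {
  default_filter_rules(subsites = list(subsite_I = 87L,
                                       subsite_II = 238L), ...)
}

# A pose whose atoms sit at `center` plus small fixed offsets.
make_pose <- function(id, center, energy, n_atoms = 4L,
                      variant_label = "WT") {
  offs <- matrix(c(0, 0, 0,
                   0.5, 0, 0,
                   0, 0.5, 0,
                   0, 0, 0.5), ncol = 3, byrow = TRUE)
  offs <- offs[rep_len(seq_len(4L), n_atoms), , drop = FALSE]
  pose(id, sweep(offs, 2, center, "+"), energy, variant_label)
}

# Independent leader-clustering oracle: precomputes the full pairwise
# RMSD matrix, then replays the assignment rule from scratch.
oracle_leader_partition <- function(poses, tol) {
  n <- length(poses)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(mean(rowSums(
        (poses[[i]]$coords - poses[[j]]$coords)^2)))
    }
  }
  e <- vapply(poses, `[[`, numeric(1), "energy")
  ids <- vapply(poses, function(p) as.character(p$pose_id),
                character(1))
  ord <- order(e, ids)
  reps <- integer(0)
  assign <- integer(n)
  for (i in ord) {
    hit <- 0L
    for (k in seq_along(reps)) {
      if (d[i, reps[k]] <= tol) { hit <- k; break }
    }
    if (hit == 0L) {
      reps <- c(reps, i)
      hit <- length(reps)
    }
    assign[i] <- hit
  }
  list(reps = reps, assign = assign)
}

# Rotation matrix from Euler angles (z-y-z convention).
euler_rotation <- function(a, b, g) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0,
                             sin(t), cos(t), 0,
                             0, 0, 1), 3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t),
                             0, 1, 0,
                             -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(g)
}

# Single-CA-per-residue trajectory from an explicit coordinate array.
make_traj <- function(coords, dt = 10) {
  n <- dim(coords)[2]
  trajectory(data.frame(elety = "CA", resno = seq_len(n),
                        resid = "ALA", chain = "A", elem = "C",
                        stringsAsFactors = FALSE),
             coords, dt)
}

# Numerical SASA oracle for a pair of spheres: latitude-band
# integration of each expanded sphere's exposed fraction.
oracle_pair_sasa <- function(p1, p2, r1, r2, probe, n_bands = 4000) {
  expand1 <- r1 + probe; expand2 <- r2 + probe
  one <- function(center, R, other, Ro) {
    # bands of constant polar angle about the center-to-center axis
    d <- sqrt(sum((other - center)^2))
    theta <- (seq_len(n_bands) - 0.5) * pi / n_bands
    ring_area <- 2 * pi * R^2 * sin(theta) * (pi / n_bands)
    # point on band at angle theta from the axis toward `other`
    x <- R * cos(theta)           # along axis
    rho <- R * sin(theta)
    dist2 <- (d - x)^2 + rho^2
    sum(ring_area[dist2 >= Ro^2])
  }
  one(p1, expand1, p2, expand2) + one(p2, expand2, p1, expand1)
}
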