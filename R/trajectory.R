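# Trajectory post-processing: Kabsch superposition, RMSD time series,
# per-residue RMSF over a trailing window, catalytic-distance series
# with closest-carbon labels, and hydrogen-bond geometry.
# Internal units are Angstrom and picoseconds.

#' Construct a trajectory
#'
#' @param topology Atom `data.frame` with columns `elety` (atom name),
#'   `resno`, `resid`, `chain`, `elem`.
#' @param coords Numeric array of dimension `T x N x 3` (frames, atoms,
#'   xyz) in Angstrom.
#' @param dt Time per frame in picoseconds.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(topology, coords, dt = 10) {
  coords <- as.array(coords)
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop("coords must be a T x N x 3 array")
  }
  if (dim(coords)[2] != nrow(topology)) {
    stop("atom count mismatch: topology has ", nrow(topology),
         ", coords have ", dim(coords)[2])
  }
  if (dt <= 0) stop("dt must be positive")
  structure(list(topology = topology, coords = coords, dt = dt),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("trajectory: ", d[1], " frames x ", d[2], " atoms, dt = ",
      x$dt, " ps\n", sep = "")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]

frame_coords <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3)
}

#' Select atom indices from a topology
#'
#' Predicate-style selection: all supplied conditions are ANDed. This is
#' the package's selection surface (e.g. `elety = "CA"` for alpha
#' carbons, `resno = 160, elety = "OG"` for the catalytic serine
#' hydroxyl oxygen).
#'
#' @param topology Atom `data.frame` (or a `trajectory`).
#' @param elety,resno,resid,chain,elem Optional filters; vectors allowed.
#' @return Integer vector of matching atom indices (possibly empty).
#' @export
select_atoms <- function(topology, elety = NULL, resno = NULL,
                         resid = NULL, chain = NULL, elem = NULL) {
  if (inherits(topology, "trajectory")) topology <- topology$topology
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(elety)) keep <- keep & topology$elety %in% elety
  if (!is.null(resno)) keep <- keep & topology$resno %in% resno
  if (!is.null(resid)) keep <- keep & topology$resid %in% resid
  if (!is.null(chain)) keep <- keep & topology$chain %in% chain
  if (!is.null(elem)) keep <- keep & topology$elem %in% elem
  which(keep)
}

#' Kabsch least-squares superposition
#'
#' Optimal rigid-body fit of `mobile` onto `reference`: translation of
#' both centroids to the origin, SVD of the weighted cross-covariance,
#' and a determinant correction guaranteeing a proper rotation
#' (det = +1). Returns the transform and the post-fit RMSD.
#'
#' @param mobile,reference N x 3 coordinate matrices, `N >= 3`.
#' @param weights Optional non-negative per-atom weights.
#' @return List with `rotation` (3 x 3, applied on the right:
#'   `mobile %*% rotation`), `translation` (length 3),
#'   `rmsd` (unweighted post-fit RMSD over the fitted atoms) and
#'   `transformed` (the superposed mobile coordinates).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  A <- as.matrix(mobile); B <- as.matrix(reference)
  if (!identical(dim(A), dim(B))) stop("coordinate dimensions differ")
  n <- nrow(A)
  if (n < 3L) stop("need at least 3 atoms for superposition")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative with positive sum")
  }
  w <- weights / sum(weights)
  ca <- colSums(A * w); cb <- colSums(B * w)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(A0 * w, B0)   # 3 x 3 cross-covariance
  sv <- svd(H)
  if (min(sv$d) < 1e-12 && sum(sv$d > 1e-12) < 2) {
    stop("degenerate geometry: atoms are (nearly) collinear")
  }
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)   # right-multiplication rotation
  fitted <- A0 %*% R
  rmsd <- sqrt(mean(rowSums((fitted - B0)^2)))
  translation <- cb
  list(rotation = R, translation = translation, rmsd = rmsd,
       transformed = sweep(fitted, 2, translation, "+"))
}

#' RMSD time series against a reference frame
#'
#' For each sampled frame, superposes the selected atoms onto the same
#' selection in the reference frame (frame 1 -- the energy-minimized
#' start -- by default) and reports the post-fit RMSD on that selection.
#'
#' @param traj A [trajectory()].
#' @param selection Integer atom indices (default: all atoms; use
#'   [select_atoms()] for backbone or heavy-atom subsets).
#' @param reference_frame Reference frame index (default 1).
#' @param stride Sample every `stride`-th frame (default 1).
#' @param superpose Remove rigid-body motion first (default `TRUE`).
#' @return `data.frame` with `frame`, `time` (ps) and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, selection = NULL, reference_frame = 1L,
                        stride = 1L, superpose = TRUE) {
  if (is.null(selection)) selection <- seq_len(dim(traj$coords)[2])
  if (length(selection) == 0L) stop("empty selection")
  frames <- seq(1L, n_frames(traj), by = stride)
  if (length(frames) == 1L) {
    warning("stride larger than trajectory: single-point series")
  }
  ref <- frame_coords(traj, reference_frame)[selection, , drop = FALSE]
  rmsd <- vapply(frames, function(i) {
    cur <- frame_coords(traj, i)[selection, , drop = FALSE]
    if (superpose) {
      kabsch_superpose(cur, ref)$rmsd
    } else {
      sqrt(mean(rowSums((cur - ref)^2)))
    }
  }, numeric(1))
  data.frame(frame = frames, time = (frames - 1L) * traj$dt,
             rmsd = rmsd)
}

resolve_window <- function(n, window, dt = NULL) {
  if (is.character(window)) {
    if (window == "last_half") {
      return(seq.int(floor(n / 2) + 1L, n))
    }
    if (window == "all") return(seq_len(n))
    stop("unknown window '", window, "'")
  }
  w <- as.integer(window)
  if (length(w) == 0L || any(w < 1L | w > n)) {
    stop("window indices out of range")
  }
  w
}

#' Per-residue RMSF over a trailing window
#'
#' Frames in the analysis window (trailing half by default, matching a
#' converged last-50-ns convention for 100-ns runs) are superposed on
#' the fit selection (alpha carbons by default) of the window-mean
#' structure in two passes; the RMSF of each residue is then the RMS
#' deviation of its representative point (alpha carbon, falling back to
#' the residue centroid) from its window-mean position.
#'
#' @param traj A [trajectory()].
#' @param window `"last_half"`, `"all"`, or an integer frame index
#'   vector (must hold at least 2 frames).
#' @param superpose Remove rigid-body motion first (default `TRUE`).
#' @param fit_selection Atom indices used for the fit (default: alpha
#'   carbons, else all atoms).
#' @return `data.frame` with `resno` and `rmsf` (Angstrom).
#' @export
rmsf_per_residue <- function(traj, window = "last_half",
                             superpose = TRUE, fit_selection = NULL) {
  frames <- resolve_window(n_frames(traj), window)
  if (length(frames) < 2L) stop("window must hold at least 2 frames")
  if (is.null(fit_selection)) {
    fit_selection <- select_atoms(traj, elety = "CA")
    if (length(fit_selection) < 3L) {
      fit_selection <- seq_len(dim(traj$coords)[2])
    }
  }
  stack <- lapply(frames, frame_coords, traj = traj)
  if (superpose) {
    ref <- stack[[1]][fit_selection, , drop = FALSE]
    for (pass in 1:2) {
      stack <- lapply(stack, function(xyz) {
        fit <- kabsch_superpose(xyz[fit_selection, , drop = FALSE], ref)
        center <- colMeans(xyz[fit_selection, , drop = FALSE])
        sweep(sweep(xyz, 2, center) %*% fit$rotation, 2,
              fit$translation, "+")
      })
      ref <- Reduce(`+`, lapply(stack, function(xyz) {
        xyz[fit_selection, , drop = FALSE]
      })) / length(stack)
    }
  }
  resnos <- sort(unique(traj$topology$resno))
  # per-residue representative point per frame: the alpha carbon when
  # unique, else the residue centroid
  big <- array(unlist(stack, use.names = FALSE),
               c(dim(stack[[1]]), length(stack)))  # N x 3 x T
  rmsf <- vapply(resnos, function(rn) {
    idx <- select_atoms(traj, resno = rn, elety = "CA")
    if (length(idx) != 1L) idx <- select_atoms(traj, resno = rn)
    p <- if (length(idx) == 1L) {
      t(big[idx, , ])                        # T x 3
    } else {
      t(apply(big[idx, , , drop = FALSE], c(2, 3), mean))
    }
    mu <- colMeans(p)
    sqrt(mean(rowSums(sweep(p, 2, mu)^2)))
  }, numeric(1))
  data.frame(resno = resnos, rmsf = rmsf)
}

#' Distance time series from one atom to a set of atoms
#'
#' Per-frame Euclidean distances from a single probe atom (e.g. the
#' catalytic serine OG) to each target atom (e.g. the four mid-chain
#' carbonyl carbons C1-C4 of a tetrameric substrate), plus the per-frame
#' label of the closest target -- the quantity used to detect substrate
#' sliding along the cleft.
#'
#' @param traj A [trajectory()].
#' @param atom_a Index of the probe atom (must resolve to exactly one).
#' @param atoms_b Indices of target atoms (at least one).
#' @param labels Optional names for the targets (default `elety` of each).
#' @return `data.frame` with `frame`, `time`, one distance column per
#'   target, and `closest` (label of the per-frame argmin).
#' @export
distance_series <- function(traj, atom_a, atoms_b, labels = NULL) {
  if (length(atom_a) != 1L) {
    stop("atom_a must resolve to exactly one atom (got ",
         length(atom_a), ")")
  }
  if (length(atoms_b) < 1L) stop("atoms_b must resolve to >= 1 atom")
  if (is.null(labels)) labels <- traj$topology$elety[atoms_b]
  frames <- seq_len(n_frames(traj))
  d <- t(vapply(frames, function(i) {
    xyz <- frame_coords(traj, i)
    sqrt(colSums((t(xyz[atoms_b, , drop = FALSE]) -
                    xyz[atom_a, ])^2))
  }, numeric(length(atoms_b))))
  colnames(d) <- labels
  out <- data.frame(frame = frames, time = (frames - 1L) * traj$dt)
  out <- cbind(out, as.data.frame(d))
  out$closest <- labels[apply(d, 1L, which.min)]
  out
}

vec_angle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Hydrogen bonds in one frame by geometric criterion
#'
#' A donor/acceptor pair is reported when the donor-heavy-to-acceptor
#' distance is at most `d_cut` and the donor-H-acceptor angle is at
#' least `angle_cut` (180 degrees = linear).
#'
#' @param coords N x 3 coordinate matrix for the frame.
#' @param donors `data.frame` with integer columns `donor` (heavy-atom
#'   index) and `hydrogen` (attached H index).
#' @param acceptors Integer vector of acceptor heavy-atom indices.
#' @param d_cut Heavy-heavy distance cutoff, Angstrom (default 3.5).
#' @param angle_cut Donor-H-acceptor angle cutoff, degrees (default 120).
#' @return `data.frame` with `donor`, `hydrogen`, `acceptor`,
#'   `distance`, `angle` for each accepted pair.
#' @export
hydrogen_bonds <- function(coords, donors, acceptors, d_cut = 3.5,
                           angle_cut = 120) {
  coords <- as.matrix(coords)
  if (!all(c("donor", "hydrogen") %in% names(donors))) {
    stop("donors must carry 'donor' and 'hydrogen' columns")
  }
  if (anyNA(donors$hydrogen)) {
    stop("donor without an attached hydrogen")
  }
  hits <- list()
  for (i in seq_len(nrow(donors))) {
    d_idx <- donors$donor[i]; h_idx <- donors$hydrogen[i]
    for (a_idx in acceptors) {
      if (a_idx == d_idx) next
      dist <- sqrt(sum((coords[d_idx, ] - coords[a_idx, ])^2))
      if (dist > d_cut) next
      ang <- vec_angle(coords[d_idx, ] - coords[h_idx, ],
                       coords[a_idx, ] - coords[h_idx, ])
      if (ang < angle_cut) next
      hits[[length(hits) + 1L]] <- data.frame(
        donor = d_idx, hydrogen = h_idx, acceptor = a_idx,
        distance = dist, angle = ang)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  }
  do.call(rbind, hits)
}

#' Write a trajectory as multi-model PDB
#'
#' Minimal ATOM/MODEL/ENDMDL records; coordinates in Angstrom.
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  top <- traj$topology
  writeLines(sprintf("REMARK DT %.4f", traj$dt), con)
  for (m in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- frame_coords(traj, m)
    for (i in seq_len(nrow(top))) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, substr(top$elety[i], 1, 4), substr(top$resid[i], 1, 3),
        substr(top$chain[i], 1, 1), top$resno[i],
        xyz[i, 1], xyz[i, 2], xyz[i, 3], top$elem[i]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a trajectory from multi-model PDB
#'
#' Uses `bio3d::read.pdb(multi = TRUE)`; `dt` is taken from a
#' `REMARK DT <ps>` line when present. This is also the adapter point
#' for binary formats: convert externally to multi-model PDB, or build a
#' [trajectory()] directly from any `T x N x 3` array (converting nm to
#' Angstrom on ingestion).
#'
#' @param path PDB path.
#' @param dt Frame spacing in ps (overrides any `REMARK DT`).
#' @return A [trajectory()].
#' @export
read_trajectory_pdb <- function(path, dt = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  if (is.null(dt)) {
    line <- grep("^REMARK DT", readLines(path, n = 5L), value = TRUE)
    dt <- if (length(line)) {
      as.numeric(strsplit(trimws(line[1]), "\\s+")[[1]][3])
    } else 10
  }
  nf <- nrow(pdb$xyz); na <- nrow(pdb$atom)
  coords <- array(NA_real_, c(nf, na, 3))
  for (m in seq_len(nf)) {
    coords[m, , ] <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
  }
  top <- data.frame(elety = pdb$atom$elety, resno = pdb$atom$resno,
                    resid = pdb$atom$resid, chain = pdb$atom$chain,
                    elem = pdb$atom$elesy, stringsAsFactors = FALSE)
  trajectory(top, coords, dt)
}
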