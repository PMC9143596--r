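# MM/PBSA bookkeeping. The vacuum molecular-mechanics terms and the
# Poisson-Boltzmann polar solvation term are engine outputs read from
# tables; the apolar solvation term is recomputable here from a
# Shrake-Rupley SASA with the linear surface-tension model. Energies
# are kJ/mol throughout.

MMPBSA_TERMS <- c("vdw", "elec", "polar", "apolar")
MMPBSA_ENTITIES <- c("complex", "protein", "ligand")

#' Surface-tension coefficient of the apolar solvation model (kJ/(mol A^2))
#' @export
APOLAR_GAMMA <- 0.0226778

#' Offset constant of the apolar solvation model (kJ/mol)
#' @export
APOLAR_CONST <- 3.84982

#' Evenly spaced snapshot selection
#'
#' Picks `n_select` equidistant frame indices spanning the analysis
#' window inclusive of both endpoints. The default window is the
#' trailing half of the trajectory (the converged last 50 ns of a
#' 100-ns run); the default count of 500 matches common end-point
#' free-energy practice. If the window holds fewer than `n_select`
#' frames, all window frames are returned with a warning.
#'
#' @param n_frames Total number of frames.
#' @param n_select Number of snapshots (default 500).
#' @param window `"last_half"`, `"all"`, or an integer index vector.
#' @return Sorted unique integer indices within the window.
#' @export
select_snapshots <- function(n_frames, n_select = 500,
                             window = "last_half") {
  idx <- resolve_window(n_frames, window)
  if (length(idx) == 0L) stop("empty snapshot window")
  if (length(idx) <= n_select) {
    if (length(idx) < n_select) {
      warning("window holds ", length(idx), " < ", n_select,
              " frames; taking all")
    }
    return(idx)
  }
  pick <- round(seq(idx[1], idx[length(idx)], length.out = n_select))
  sort(unique(as.integer(pick)))
}

#' Quasi-uniform sphere points (deterministic golden-section spiral)
#' @param n Number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Each atom's sphere is expanded by the probe radius and sampled with a
#' deterministic quasi-uniform point set; the accessible fraction is the
#' share of points not buried inside any neighbour's expanded sphere,
#' times the expanded-sphere area.
#'
#' @param atoms `data.frame` with `x`, `y`, `z` and either a `radius`
#'   column (Angstrom) or an `elem` column resolved through `radii`.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_sphere_points Sample points per atom (default 960).
#' @param radii Named element -> radius table ([vdw_radii()]).
#' @return Numeric vector of per-atom areas (A^2) with attribute
#'   `total`; `sum()` of the vector equals the total SASA.
#' @export
sasa <- function(atoms, probe = 1.4, n_sphere_points = 960,
                 radii = vdw_radii()) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!is.null(atoms$radius)) {
    r <- atoms$radius
  } else if (!is.null(atoms$elem)) {
    r <- radii[toupper(atoms$elem)]
    if (anyNA(r)) {
      stop("no radius for element(s): ",
           paste(unique(atoms$elem[is.na(r)]), collapse = ", "))
    }
    r <- unname(r)
  } else {
    stop("atoms need a 'radius' or 'elem' column")
  }
  n <- nrow(xyz)
  rr <- r + probe
  pts <- sphere_points(n_sphere_points)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rr + rr[i])^2 & seq_len(n) != i)
    surf <- sweep(pts * rr[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, n_sphere_points)
      for (j in nb) {
        if (!any(free)) break
        dj <- rowSums(sweep(surf[free, , drop = FALSE], 2,
                            xyz[j, ])^2)
        free[free] <- dj >= rr[j]^2
      }
      frac <- mean(free)
    } else {
      frac <- 1
    }
    areas[i] <- frac * 4 * pi * rr[i]^2
  }
  structure(areas, total = sum(areas))
}

#' Apolar (non-polar) solvation energy from SASA
#'
#' Linear surface-tension model: `gamma * SASA + const`, with
#' gamma = 0.0226778 kJ/(mol A^2) and const = 3.84982 kJ/mol.
#'
#' @param sasa_total Total SASA in A^2 (non-negative).
#' @param gamma Surface tension (kJ/(mol A^2)).
#' @param const Offset constant (kJ/mol).
#' @return Apolar solvation energy in kJ/mol.
#' @export
apolar_energy <- function(sasa_total, gamma = APOLAR_GAMMA,
                          const = APOLAR_CONST) {
  if (any(sasa_total < 0)) stop("SASA must be non-negative")
  gamma * sasa_total + const
}

#' Construct a per-snapshot energy frame
#'
#' @param frame_index Snapshot index.
#' @param complex,protein,ligand Named numeric vectors with components
#'   `vdw`, `elec`, `polar`, `apolar` (kJ/mol).
#' @param per_residue Optional named numeric vector: per-residue
#'   contribution to the decomposable binding energy of this snapshot.
#' @return An object of class `energy_frame`.
#' @export
energy_frame <- function(frame_index, complex, protein, ligand,
                         per_residue = NULL) {
  comp <- list(complex = complex, protein = protein, ligand = ligand)
  for (ent in MMPBSA_ENTITIES) {
    v <- comp[[ent]]
    if (!all(MMPBSA_TERMS %in% names(v))) {
      stop(ent, " record must carry terms ",
           paste(MMPBSA_TERMS, collapse = ", "))
    }
    if (!all(is.finite(v[MMPBSA_TERMS]))) {
      stop("non-finite energy term in ", ent)
    }
  }
  structure(list(frame_index = frame_index,
                 complex = complex[MMPBSA_TERMS],
                 protein = protein[MMPBSA_TERMS],
                 ligand = ligand[MMPBSA_TERMS],
                 per_residue = per_residue),
            class = "energy_frame")
}

#' Per-term and total binding energy of one snapshot
#'
#' For each component, Delta = complex - (protein + ligand); the total
#' is the sum of the four Deltas.
#'
#' @param frame An [energy_frame()].
#' @return Named numeric vector: `vdw`, `elec`, `polar`, `apolar`,
#'   `total` (kJ/mol).
#' @export
binding_energy <- function(frame) {
  if (!inherits(frame, "energy_frame")) {
    stop("frame must be an energy_frame")
  }
  delta <- frame$complex - (frame$protein + frame$ligand)
  c(delta, total = sum(delta))
}

#' Binding-energy summary over snapshots
#'
#' Mean and sample standard deviation of each Delta term and of the
#' per-snapshot totals. The mean total equals the sum of the term means
#' exactly (before any rounding).
#'
#' @param frames List of [energy_frame()]s, at least 2.
#' @return Object of class `binding_summary`: `data.frame` with rows
#'   vdw/elec/polar/apolar/total and columns `mean`, `sd`; attribute
#'   `n_snapshots`.
#' @export
summarize_binding <- function(frames) {
  if (length(frames) < 2L) stop("need at least 2 snapshots")
  deltas <- t(vapply(frames, binding_energy,
                     numeric(length(MMPBSA_TERMS) + 1L)))
  out <- data.frame(term = colnames(deltas),
                    mean = colMeans(deltas),
                    sd = apply(deltas, 2, stats::sd),
                    row.names = NULL)
  attr(out, "n_snapshots") <- length(frames)
  class(out) <- c("binding_summary", "data.frame")
  out
}

#' Per-residue binding-energy difference relative to wild type
#'
#' The variant's mean per-residue decomposition profile minus the
#' average of the wild-type replica mean profiles (replicas are averaged
#' at the profile level, not pooled). Negative values are binding-energy
#' gains, positive values losses.
#'
#' @param variant_profiles List of per-snapshot named numeric vectors
#'   (residue -> kJ/mol) for the variant, or a snapshots x residues
#'   matrix.
#' @param wt_profiles List of wild-type replicas, each itself a list of
#'   per-snapshot profiles (or a matrix).
#' @return Named numeric vector: residue -> Delta(DeltaG) in kJ/mol.
#' @export
per_residue_delta <- function(variant_profiles, wt_profiles) {
  mean_profile <- function(p) {
    m <- if (is.matrix(p)) p else do.call(rbind, p)
    colMeans(m)
  }
  v <- mean_profile(variant_profiles)
  wt_means <- lapply(wt_profiles, mean_profile)
  keys <- names(v)
  for (w in wt_means) {
    if (!identical(sort(names(w)), sort(keys))) {
      offenders <- c(setdiff(keys, names(w)), setdiff(names(w), keys))
      stop("residue sets differ between variant and WT profiles: ",
           paste(offenders, collapse = ", "))
    }
  }
  wt_avg <- Reduce(`+`, lapply(wt_means, function(w) w[keys])) /
    length(wt_means)
  v - wt_avg
}

#' Read energy frames from TSV
#'
#' Expected columns: `frame`, `entity` (complex/protein/ligand), `vdw`,
#' `elec`, `polar`, `apolar`. An optional companion per-residue table
#' has columns `frame`, `residue`, `energy`.
#'
#' @param path Energy TSV path.
#' @param per_residue_path Optional per-residue decomposition TSV.
#' @return List of [energy_frame()]s.
#' @export
read_energy_frames <- function(path, per_residue_path = NULL) {
  df <- utils::read.delim(path)
  need <- c("frame", "entity", MMPBSA_TERMS)
  if (!all(need %in% names(df))) {
    stop("energy table must have columns ",
         paste(need, collapse = ", "))
  }
  pr <- NULL
  if (!is.null(per_residue_path)) {
    pr <- utils::read.delim(per_residue_path)
  }
  frames <- lapply(sort(unique(df$frame)), function(fi) {
    sub <- df[df$frame == fi, , drop = FALSE]
    get_ent <- function(ent) {
      row <- sub[sub$entity == ent, , drop = FALSE]
      if (nrow(row) != 1L) {
        stop("frame ", fi, ": need exactly one '", ent, "' record")
      }
      stats::setNames(as.numeric(row[1, MMPBSA_TERMS]), MMPBSA_TERMS)
    }
    res <- NULL
    if (!is.null(pr)) {
      prs <- pr[pr$frame == fi, , drop = FALSE]
      res <- stats::setNames(prs$energy, as.character(prs$residue))
    }
    energy_frame(fi, get_ent("complex"), get_ent("protein"),
                 get_ent("ligand"), per_residue = res)
  })
  frames
}

#' Write energy frames as TSV
#'
#' @param frames List of [energy_frame()]s.
#' @param path Output path for the entity/term table.
#' @param per_residue_path Optional output path for the per-residue
#'   decomposition table.
#' @return `path`, invisibly.
#' @export
write_energy_frames <- function(frames, path,
                                per_residue_path = NULL) {
  rows <- lapply(frames, function(f) {
    do.call(rbind, lapply(MMPBSA_ENTITIES, function(ent) {
      data.frame(frame = f$frame_index, entity = ent,
                 as.list(f[[ent]]), stringsAsFactors = FALSE)
    }))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(per_residue_path)) {
    pr <- do.call(rbind, lapply(frames, function(f) {
      if (is.null(f$per_residue)) return(NULL)
      data.frame(frame = f$frame_index,
                 residue = names(f$per_residue),
                 energy = unname(f$per_residue),
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(pr)) {
      utils::write.table(pr, per_residue_path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}

#' Reported MM/PBSA summaries shipped with the package
#'
#' Published binding free-energy summaries (component means +/- SD and
#' totals, kJ/mol, 500 snapshots each) for wild-type PETase and the
#' Q119F, D112M/S238F and S238C variants, two MD replicas each. Used as
#' a consistency fixture (component means must sum to the total within
#' component rounding) and as realistic parameters for the energy-frame
#' generator.
#'
#' @return `data.frame` with columns `variant`, `replica`, `vdw`,
#'   `vdw_sd`, `elec`, `elec_sd`, `polar`, `polar_sd`, `apolar`,
#'   `apolar_sd`, `total`, `total_sd`.
#' @export
reported_mmpbsa <- function() {
  path <- system.file("extdata", "petase_mmpbsa_reported.tsv",
                      package = "revscreen", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
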