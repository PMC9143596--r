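# Docking-screen post-processing: pose RMSD, energy-ordered leader
# clustering, geometric acceptance filters (catalytic-serine distance
# and cleft-subsite occupancy), per-variant deltaG selection, deltadeltaG
# and the mean-minus-SD nomination threshold.

#' Construct a docking pose
#'
#' @param pose_id Identifier (integer or string); unique within a pose set.
#' @param coords N x 3 matrix of ligand heavy-atom coordinates (Angstrom),
#'   in a fixed atom order shared by all poses of the ligand.
#' @param energy Docking score (kcal/mol) reported by the engine.
#' @param variant_label Label of the enzyme variant the pose was docked to.
#' @return An object of class `pose`.
#' @export
pose <- function(pose_id, coords, energy, variant_label = "WT") {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  if (!all(is.finite(coords))) stop("non-finite pose coordinates")
  if (!is.finite(energy)) stop("non-finite pose energy")
  structure(list(pose_id = pose_id, coords = coords,
                 energy = as.numeric(energy),
                 variant_label = variant_label),
            class = "pose")
}

#' RMSD between two poses
#'
#' Root-mean-square per-atom displacement WITHOUT superposition: docking
#' poses share the receptor frame, so rigid differences are real.
#'
#' @param a,b `pose` objects (or bare N x 3 matrices) with identical atom
#'   count and order.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(a, b) {
  ca <- if (inherits(a, "pose")) a$coords else as.matrix(a)
  cb <- if (inherits(b, "pose")) b$coords else as.matrix(b)
  if (!identical(dim(ca), dim(cb))) {
    stop("pose atom counts differ: ", nrow(ca), " vs ", nrow(cb))
  }
  sqrt(mean(rowSums((ca - cb)^2)))
}

#' Leader clustering of docking poses
#'
#' Poses are visited in ascending energy (ties broken by pose id); each
#' pose joins the first existing cluster whose representative lies within
#' `rmsd_tol`, else opens a new cluster with itself as representative.
#' Representatives are therefore cluster-minimal in energy, and clusters
#' are returned in order of representative energy.
#'
#' @param poses List of `pose` objects.
#' @param rmsd_tol RMSD tolerance in Angstrom (default 2.0).
#' @return List of clusters, each a list with `representative` (pose id),
#'   `rep_index` (index into `poses`), `members` (pose ids),
#'   `member_index`, `size`, `energy` (representative energy).
#' @export
cluster_poses <- function(poses, rmsd_tol = 2.0) {
  if (length(poses) == 0L) return(list())
  energies <- vapply(poses, `[[`, numeric(1), "energy")
  ids <- vapply(poses, function(p) as.character(p$pose_id), character(1))
  visit <- order(energies, ids)
  clusters <- list()
  for (i in visit) {
    placed <- FALSE
    for (k in seq_along(clusters)) {
      rep_idx <- clusters[[k]]$rep_index
      if (pose_rmsd(poses[[i]], poses[[rep_idx]]) <= rmsd_tol) {
        clusters[[k]]$member_index <- c(clusters[[k]]$member_index, i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <-
        list(rep_index = i, member_index = i)
    }
  }
  lapply(clusters, function(cl) {
    list(representative = poses[[cl$rep_index]]$pose_id,
         rep_index = cl$rep_index,
         members = ids[cl$member_index],
         member_index = cl$member_index,
         size = length(cl$member_index),
         energy = energies[cl$rep_index])
  })
}

#' Default pose-acceptance rules
#'
#' The catalytic rule requires a ligand heavy atom within `cutoff`
#' Angstrom of the nucleophile's side-chain oxygen (serine 160 OG for
#' PETase). The cleft rule requires every configured subsite residue set
#' to be contacted (some ligand atom within `contact_cutoff` of some
#' subsite atom), encoding the requirement that the substrate lies along
#' the L-shaped cleft rather than dangling off one end. Subsite residue
#' sets are configuration: the defaults name the two halves of the
#' PETase cleft by residue number.
#'
#' @param catalytic_resno Residue number of the catalytic serine.
#' @param catalytic_atom Atom name of the probe atom (default `"OG"`).
#' @param cutoff Catalytic distance cutoff in Angstrom (default 4.0).
#' @param subsites Named list of integer vectors of receptor residue
#'   numbers, one per subsite.
#' @param contact_cutoff Subsite contact cutoff in Angstrom (default 5.0).
#' @return A rules list consumed by [pose_filter()].
#' @export
default_filter_rules <- function(catalytic_resno = 160,
                                 catalytic_atom = "OG",
                                 cutoff = 4.0,
                                 subsites = list(
                                   subsite_I = c(87, 119, 159, 185),
                                   subsite_II = c(238, 241, 280)
                                 ),
                                 contact_cutoff = 5.0) {
  list(catalytic_resno = catalytic_resno,
       catalytic_atom = catalytic_atom,
       cutoff = cutoff,
       subsites = subsites,
       contact_cutoff = contact_cutoff)
}

receptor_xyz <- function(receptor) {
  if (is.data.frame(receptor)) {
    as.matrix(receptor[, c("x", "y", "z")])
  } else {
    stop("receptor must be an atom data.frame with x/y/z columns")
  }
}

min_cross_distance <- function(a, b) {
  # smallest pairwise distance between two coordinate sets
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

#' Geometric acceptance filter for one pose
#'
#' @param pose A `pose`.
#' @param receptor Receptor atom table: data.frame with columns `elety`
#'   (atom name), `resno`, `x`, `y`, `z` (e.g. `bio3d::read.pdb(...)$atom`).
#' @param rules Rules from [default_filter_rules()].
#' @return List with `accept` (logical) and `reasons` (character vector
#'   naming failed rules: `"catalytic_distance"` and/or subsite names).
#' @export
pose_filter <- function(pose, receptor, rules = default_filter_rules()) {
  lig <- pose$coords
  cat_sel <- receptor$resno == rules$catalytic_resno &
    receptor$elety == rules$catalytic_atom
  if (!any(cat_sel)) {
    stop("catalytic atom ", rules$catalytic_atom, " of residue ",
         rules$catalytic_resno, " not found in receptor")
  }
  cat_xyz <- receptor_xyz(receptor)[cat_sel, , drop = FALSE]
  reasons <- character(0)
  if (min_cross_distance(lig, cat_xyz) >= rules$cutoff) {
    reasons <- c(reasons, "catalytic_distance")
  }
  for (name in names(rules$subsites)) {
    sel <- receptor$resno %in% rules$subsites[[name]]
    if (!any(sel)) {
      stop("subsite ", name, ": no receptor atoms for residues ",
           paste(rules$subsites[[name]], collapse = ", "))
    }
    sub_xyz <- receptor_xyz(receptor)[sel, , drop = FALSE]
    if (min_cross_distance(lig, sub_xyz) > rules$contact_cutoff) {
      reasons <- c(reasons, name)
    }
  }
  list(accept = length(reasons) == 0L, reasons = reasons)
}

#' Accepted binding energy of one variant
#'
#' Clusters the variant's poses, applies the geometric filter to each
#' cluster representative, and returns the lowest representative energy
#' among accepted clusters as the variant's deltaG. If no cluster is
#' accepted the record carries `delta_g = NA` and is flagged.
#'
#' @param poses List of `pose` objects belonging to one variant.
#' @param receptor Receptor atom table (see [pose_filter()]).
#' @param rules Acceptance rules ([default_filter_rules()]).
#' @param rmsd_tol Clustering tolerance in Angstrom (default 2.0).
#' @return List with `variant_label`, `delta_g`, `accepted_pose`,
#'   `n_poses`, `n_clusters`, `n_accepted_clusters`, `flagged`.
#' @export
select_delta_g <- function(poses, receptor,
                           rules = default_filter_rules(),
                           rmsd_tol = 2.0) {
  if (length(poses) == 0L) stop("no poses supplied")
  label <- poses[[1]]$variant_label
  clusters <- cluster_poses(poses, rmsd_tol)
  accepted <- Filter(function(cl) {
    pose_filter(poses[[cl$rep_index]], receptor, rules)$accept
  }, clusters)
  if (length(accepted) == 0L) {
    return(list(variant_label = label, delta_g = NA_real_,
                accepted_pose = NA_character_,
                n_poses = length(poses), n_clusters = length(clusters),
                n_accepted_clusters = 0L, flagged = TRUE))
  }
  energies <- vapply(accepted, `[[`, numeric(1), "energy")
  best <- accepted[[which.min(energies)]]
  list(variant_label = label, delta_g = best$energy,
       accepted_pose = as.character(best$representative),
       n_poses = length(poses), n_clusters = length(clusters),
       n_accepted_clusters = length(accepted), flagged = FALSE)
}

#' Binding-energy difference relative to wild type
#'
#' deltadeltaG = deltaG(variant) - deltaG(WT); negative values predict
#' improved binding. `NA` inputs propagate.
#'
#' @param dg_variant,dg_wt Docking scores in kcal/mol.
#' @return deltadeltaG in kcal/mol.
#' @export
delta_delta_g <- function(dg_variant, dg_wt) {
  dg_variant - dg_wt
}

#' Mean-minus-SD selection threshold
#'
#' Computes the mean and sample standard deviation (n - 1 denominator)
#' of a set of deltadeltaG values; the nomination cutoff is mean - SD.
#'
#' @param values Numeric vector of deltadeltaG values, `n >= 2`
#'   (`NA`s dropped).
#' @return Object of class `selection_threshold`: list with `mean`,
#'   `sd`, `cutoff`, `n`.
#' @export
selection_threshold <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    stop("need at least 2 finite values to form a threshold")
  }
  m <- mean(values)
  s <- stats::sd(values)
  structure(list(mean = m, sd = s, cutoff = m - s, n = length(values)),
            class = "selection_threshold")
}

#' @export
print.selection_threshold <- function(x, ...) {
  cat(sprintf(
    "selection_threshold: mean %.3f - sd %.3f = cutoff %.3f (n = %d)\n",
    x$mean, x$sd, x$cutoff, x$n))
  invisible(x)
}

#' Nominate improved variants below the threshold
#'
#' Selects screen records with deltadeltaG strictly below the cutoff,
#' sorted ascending (most improved first). Records with undefined
#' deltadeltaG are excluded.
#'
#' @param records Data frame of screen records with columns
#'   `variant_label` and `delta_delta_g`.
#' @param threshold A [selection_threshold()].
#' @return The selected rows, ordered by increasing deltadeltaG.
#' @export
nominate_candidates <- function(records, threshold) {
  keep <- !is.na(records$delta_delta_g) &
    records$delta_delta_g < threshold$cutoff
  out <- records[keep, , drop = FALSE]
  out[order(out$delta_delta_g), , drop = FALSE]
}

#' Docking-engine provenance block
#'
#' The engine settings under which pose sets were generated (search grid,
#' genetic-algorithm budget, run count). Recorded in reports for
#' provenance only; nothing in this package executes a docking engine.
#'
#' @param grid_dim Grid box size in Angstrom (x, y, z).
#' @param grid_center Grid box center coordinates.
#' @param grid_spacing Grid spacing in Angstrom.
#' @param ga_population,ga_generations,ga_evaluations Genetic-algorithm
#'   settings.
#' @param n_runs Number of independent docking runs per variant.
#' @return A named list stored verbatim in stage reports.
#' @export
docking_provenance <- function(grid_dim = c(120, 90, 120),
                               grid_center = c(-2.403, 30.711, -18.311),
                               grid_spacing = 0.375,
                               ga_population = 200,
                               ga_generations = 27000,
                               ga_evaluations = 2500000,
                               n_runs = 500) {
  list(grid_dim = grid_dim, grid_center = grid_center,
       grid_spacing = grid_spacing, ga_population = ga_population,
       ga_generations = ga_generations,
       ga_evaluations = ga_evaluations, n_runs = n_runs)
}
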