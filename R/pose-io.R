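# On-disk formats for pose sets and receptors. Poses travel either as a
# long TSV (pose_id, variant_label, energy, atom, x, y, z) or as a
# multi-model PDB with one MODEL per pose and the docking score in a
# REMARK ENERGY record. Receptors are plain PDB read via bio3d.

#' Write a pose set as TSV
#'
#' Long format, one row per atom: `pose_id`, `variant_label`, `energy`,
#' `atom` (1-based index), `x`, `y`, `z`.
#'
#' @param poses List of [pose()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_poses_tsv <- function(poses, path) {
  rows <- lapply(poses, function(p) {
    data.frame(pose_id = as.character(p$pose_id),
               variant_label = p$variant_label,
               energy = p$energy,
               atom = seq_len(nrow(p$coords)),
               x = p$coords[, 1], y = p$coords[, 2], z = p$coords[, 3],
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pose set from TSV
#'
#' @param path Path written by [write_poses_tsv()].
#' @return List of [pose()] objects, in file order of first appearance.
#' @export
read_poses_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = c(
    pose_id = "character", variant_label = "character"))
  ids <- unique(df$pose_id)
  lapply(ids, function(id) {
    sub <- df[df$pose_id == id, , drop = FALSE]
    sub <- sub[order(sub$atom), , drop = FALSE]
    pose(id, as.matrix(sub[, c("x", "y", "z")]), sub$energy[1],
         sub$variant_label[1])
  })
}

#' Write a pose set as multi-model PDB
#'
#' One MODEL per pose; the docking score is carried on a
#' `REMARK ENERGY <pose_id> <energy>` line inside the model. Atoms are
#' written as carbon HETATM-style ATOM records of a `LIG` residue, which
#' is sufficient for clustering/filtering round trips.
#'
#' @param poses List of [pose()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_poses_pdb <- function(poses, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(poses)) {
    p <- poses[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(sprintf("REMARK ENERGY %s %.4f %s",
                       as.character(p$pose_id), p$energy,
                       p$variant_label), con)
    for (i in seq_len(nrow(p$coords))) {
      writeLines(sprintf(
        "ATOM  %5d  C%-2d LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, i %% 100, p$coords[i, 1], p$coords[i, 2], p$coords[i, 3]),
        con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a pose set from multi-model PDB
#'
#' Coordinates are parsed with `bio3d::read.pdb(multi = TRUE)`; pose ids,
#' energies and variant labels come from the `REMARK ENERGY` lines.
#'
#' @param path Path written by [write_poses_pdb()] (or any multi-model
#'   PDB with one `REMARK ENERGY id energy label` line per model).
#' @return List of [pose()] objects.
#' @export
read_poses_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  lines <- grep("^REMARK ENERGY", readLines(path), value = TRUE)
  if (nrow(pdb$xyz) != length(lines)) {
    stop("model count (", nrow(pdb$xyz),
         ") does not match REMARK ENERGY count (", length(lines), ")")
  }
  lapply(seq_len(nrow(pdb$xyz)), function(m) {
    parts <- strsplit(trimws(lines[m]), "\\s+")[[1]]
    coords <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    pose(parts[3], coords, as.numeric(parts[4]),
         if (length(parts) >= 5) parts[5] else "WT")
  })
}

#' Read a receptor atom table from PDB
#'
#' Thin wrapper over `bio3d::read.pdb` returning the atom data.frame
#' (columns include `elety`, `resno`, `resid`, `x`, `y`, `z`, `elesy`)
#' that the pose filter and SASA routines consume.
#'
#' @param path PDB file path.
#' @return Atom `data.frame`.
#' @export
read_receptor <- function(path) {
  bio3d::read.pdb(path, verbose = FALSE)$atom
}

#' Run the docking screen over variant pose sets
#'
#' Applies [select_delta_g()] to each variant's pose list and assembles
#' the screen-record table with deltadeltaG relative to the wild type.
#'
#' @param pose_sets Named list: variant label -> list of [pose()]s. Must
#'   include `"WT"` (or `wt_label`).
#' @param receptor Receptor atom table.
#' @param rules Acceptance rules ([default_filter_rules()]).
#' @param rmsd_tol Clustering tolerance (Angstrom).
#' @param wt_label Label of the wild-type entry (default `"WT"`).
#' @return `data.frame` with columns `variant_label`, `delta_g`,
#'   `delta_delta_g`, `accepted_pose`, `n_poses`, `n_accepted_clusters`,
#'   `flagged`.
#' @export
screen_pose_sets <- function(pose_sets, receptor,
                             rules = default_filter_rules(),
                             rmsd_tol = 2.0, wt_label = "WT") {
  if (!wt_label %in% names(pose_sets)) {
    stop("pose_sets must contain the wild-type entry '", wt_label, "'")
  }
  recs <- lapply(names(pose_sets), function(label) {
    r <- select_delta_g(pose_sets[[label]], receptor, rules, rmsd_tol)
    r$variant_label <- label
    r
  })
  df <- data.frame(
    variant_label = vapply(recs, `[[`, character(1), "variant_label"),
    delta_g = vapply(recs, `[[`, numeric(1), "delta_g"),
    accepted_pose = vapply(recs, `[[`, character(1), "accepted_pose"),
    n_poses = vapply(recs, `[[`, integer(1), "n_poses"),
    n_accepted_clusters = vapply(recs, `[[`, integer(1),
                                 "n_accepted_clusters"),
    flagged = vapply(recs, `[[`, logical(1), "flagged"),
    stringsAsFactors = FALSE
  )
  dg_wt <- df$delta_g[df$variant_label == wt_label]
  df$delta_delta_g <- delta_delta_g(df$delta_g, dg_wt)
  df[, c("variant_label", "delta_g", "delta_delta_g", "accepted_pose",
         "n_poses", "n_accepted_clusters", "flagged")]
}
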