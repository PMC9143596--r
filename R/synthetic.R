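# Synthetic generators: a variant -> binding-energy landscape with
# additive site effects, pairwise epistasis and Gaussian noise; docking
# pose sets with planted cluster structure; trajectories with planted
# per-residue fluctuation amplitudes; and per-snapshot MM/PBSA component
# tables with known means/SDs. One global seed fans out to per-generator
# and per-variant child seeds through a deterministic string-hash
# splitting rule, so generation order never changes results.

# Deterministic string hash (31-polynomial mod a Mersenne prime),
# combined with the user seed; always a valid 32-bit seed.
child_seed <- function(seed, stream) {
  mod <- 2147483647
  h <- seed %% mod
  for (code in utf8ToInt(stream)) {
    h <- (h * 31 + code) %% mod
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Synthetic variant -> binding-energy landscape
#'
#' Builds a deterministic scoring function
#' `deltaG(variant) = wt_energy + sum(additive) + sum(epistasis) + noise`
#' where additive effects are per (site, amino acid), epistasis is a
#' sparse per-site-pair penalty/bonus applied when both sites are
#' substituted, and the noise is one Gaussian draw per variant, keyed to
#' the variant label so that scoring is reproducible and
#' order-independent. The wild type's additive effect is zero at every
#' site by construction.
#'
#' @param sites Integer vector of mutable residue numbers.
#' @param wt_residues Named character vector: WT residue per site.
#' @param wt_energy Wild-type docking score, kcal/mol.
#' @param additive `data.frame` with columns `site`, `aa`, `effect`
#'   (kcal/mol); unlisted (site, aa) pairs have zero effect.
#' @param epistasis Optional `data.frame` with columns `site_a`,
#'   `site_b`, `effect` and optional `aa_a`, `aa_b`; a row without
#'   amino-acid columns (or with `NA`s) applies whenever both sites are
#'   substituted, a row with them only to that residue pair. Generic and
#'   residue-specific terms for the same pair add.
#' @param noise_sd Gaussian noise SD, kcal/mol (0 = noise-free).
#' @param seed Integer seed (with `noise_sd > 0` the same seed gives
#'   byte-identical scores).
#' @return Object of class `landscape`: list with `score` (function
#'   taking a variant -- a list with `sites`/`new_aas` or a library row),
#'   `config`, and `ground_truth` (noise-free best single and double
#'   variants).
#' @export
gen_landscape <- function(sites, wt_residues, wt_energy = -7.0,
                          additive, epistasis = NULL, noise_sd = 0,
                          seed = 1L) {
  sites <- as.integer(sites)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  stopifnot(all(c("site", "aa", "effect") %in% names(additive)))
  wt_at <- function(s) wt_residues[[as.character(s)]]
  for (i in seq_len(nrow(additive))) {
    if (additive$aa[i] == wt_at(additive$site[i])) {
      stop("additive table assigns an effect to the WT residue at site ",
           additive$site[i], " (must be zero by construction)")
    }
  }
  eff_key <- paste(additive$site, additive$aa)
  eff <- stats::setNames(additive$effect, eff_key)
  epi_generic <- NULL
  epi_specific <- NULL
  if (!is.null(epistasis) && nrow(epistasis)) {
    ep <- epistasis
    if (is.null(ep$aa_a)) ep$aa_a <- NA_character_
    if (is.null(ep$aa_b)) ep$aa_b <- NA_character_
    swap <- ep$site_a > ep$site_b
    tmp <- ep[swap, c("site_a", "aa_a")]
    ep[swap, c("site_a", "aa_a")] <- ep[swap, c("site_b", "aa_b")]
    ep[swap, c("site_b", "aa_b")] <- tmp
    gen <- is.na(ep$aa_a) & is.na(ep$aa_b)
    if (any(gen)) {
      epi_generic <- stats::setNames(
        ep$effect[gen], paste(ep$site_a[gen], ep$site_b[gen]))
    }
    if (any(!gen)) {
      epi_specific <- stats::setNames(
        ep$effect[!gen], paste(ep$site_a[!gen], ep$site_b[!gen],
                               ep$aa_a[!gen], ep$aa_b[!gen]))
    }
  }
  true_energy <- function(v_sites, v_aas) {
    e <- wt_energy
    if (length(v_sites)) {
      ord <- order(v_sites)
      v_sites <- v_sites[ord]; v_aas <- v_aas[ord]
      k <- paste(v_sites, v_aas)
      e <- e + sum(eff[k], na.rm = TRUE)
      if (length(v_sites) >= 2L) {
        idx <- utils::combn(seq_along(v_sites), 2L)
        if (!is.null(epi_generic)) {
          pk <- paste(v_sites[idx[1, ]], v_sites[idx[2, ]])
          e <- e + sum(epi_generic[pk], na.rm = TRUE)
        }
        if (!is.null(epi_specific)) {
          sk <- paste(v_sites[idx[1, ]], v_sites[idx[2, ]],
                      v_aas[idx[1, ]], v_aas[idx[2, ]])
          e <- e + sum(epi_specific[sk], na.rm = TRUE)
        }
      }
    }
    e
  }
  score <- function(variant) {
    v_sites <- variant$sites
    v_aas <- variant$new_aas
    if (length(v_sites) && !all(v_sites %in% sites)) {
      stop("variant names unknown site(s): ",
           paste(setdiff(v_sites, sites), collapse = ", "))
    }
    label <- if (length(v_sites)) {
      variant_label(v_sites, vapply(v_sites, wt_at, character(1)),
                    v_aas)
    } else "WT"
    e <- true_energy(v_sites, v_aas)
    if (noise_sd > 0) {
      e <- e + with_seed(child_seed(seed, paste0("landscape:", label)),
                         stats::rnorm(1, 0, noise_sd))
    }
    e
  }
  # Noise-free ground truth: best single substitution by enumeration,
  # best double analytically (per-site best additive effect, corrected
  # pair-by-pair for generic and residue-specific epistasis), so large
  # site sets stay cheap.
  best <- list(single = NULL, double = NULL)
  site_best <- lapply(sites, function(s) {
    aas <- setdiff(standard_aa(), wt_at(s))
    e <- eff[paste(s, aas)]
    e[is.na(e)] <- 0
    k <- which.min(e)
    list(aa = aas[k], effect = unname(e[k]))
  })
  names(site_best) <- as.character(sites)
  e1 <- vapply(site_best, `[[`, numeric(1), "effect")
  k1 <- which.min(e1)
  s1 <- sites[k1]
  best$single <- list(
    label = variant_label(s1, wt_at(s1), site_best[[k1]]$aa),
    sites = s1, new_aas = site_best[[k1]]$aa,
    delta_delta_g = unname(e1[k1]))
  if (length(sites) >= 2L) {
    add_of <- function(s, a) {
      v <- eff[paste(s, a)]
      if (is.na(v)) 0 else unname(v)
    }
    best_e <- Inf
    idx <- utils::combn(seq_along(sites), 2L)
    for (p in seq_len(ncol(idx))) {
      a <- sites[idx[1, p]]; b <- sites[idx[2, p]]
      gen <- if (is.null(epi_generic)) 0 else {
        v <- epi_generic[paste(a, b)]
        if (is.na(v)) 0 else unname(v)
      }
      cand <- list(list(aa_a = site_best[[as.character(a)]]$aa,
                        aa_b = site_best[[as.character(b)]]$aa,
                        extra = 0))
      if (!is.null(epi_specific)) {
        hits <- grep(paste0("^", a, " ", b, " "), names(epi_specific))
        for (h in hits) {
          parts <- strsplit(names(epi_specific)[h], " ")[[1]]
          if (parts[3] == wt_at(a) || parts[4] == wt_at(b)) next
          cand[[length(cand) + 1L]] <-
            list(aa_a = parts[3], aa_b = parts[4],
                 extra = unname(epi_specific[h]))
        }
      }
      for (cn in cand) {
        e <- add_of(a, cn$aa_a) + add_of(b, cn$aa_b) + gen + cn$extra
        if (e < best_e) {
          best_e <- e
          best$double <- list(
            label = variant_label(c(a, b), c(wt_at(a), wt_at(b)),
                                  c(cn$aa_a, cn$aa_b)),
            sites = c(a, b), new_aas = c(cn$aa_a, cn$aa_b),
            delta_delta_g = e)
        }
      }
    }
  }
  structure(
    list(score = score, true_energy = true_energy,
         config = list(sites = sites, wt_residues = wt_residues,
                       wt_energy = wt_energy, additive = additive,
                       epistasis = epistasis, noise_sd = noise_sd,
                       seed = seed),
         ground_truth = best),
    class = "landscape")
}

#' Score a variant library against an energy function
#'
#' Evaluates the scorer for every library member plus the wild type and
#' assembles the screen-record table with deltadeltaG relative to WT.
#' The scorer stands in for a docking engine; any function mapping a
#' variant (list with `sites`, `new_aas`) to kcal/mol works, including
#' `landscape$score`.
#'
#' @param library A `variant_library`.
#' @param scorer Function variant -> deltaG, e.g. `gen_landscape(...)$score`.
#' @return Screen-record `data.frame` with `variant_label`, `r`,
#'   `delta_g`, `delta_delta_g` and list-columns `sites`, `new_aas`.
#' @export
score_library <- function(library, scorer) {
  df <- as.data.frame(library)
  wt_dg <- scorer(list(sites = integer(0), new_aas = character(0)))
  df$delta_g <- vapply(library$variants, scorer, numeric(1))
  df$delta_delta_g <- delta_delta_g(df$delta_g, wt_dg)
  df$variant_label <- df$label
  df[, c("variant_label", "r", "delta_g", "delta_delta_g", "sites",
         "new_aas")]
}

#' Synthetic docking pose set with planted clusters
#'
#' Draws `k_clusters` well-separated cluster centers (or takes them as
#' given) and jitters `n_poses` member poses around them so that every
#' member lies within `spread` (RMSD) of its center. Feasibility
#' requires `spread` below half the minimum center separation, so the
#' planted partition is exactly recoverable at a tolerance between
#' `2 * spread` and `separation - 2 * spread`.
#'
#' @param k_clusters Number of planted clusters.
#' @param spread Maximum member-to-center RMSD, Angstrom.
#' @param n_poses Total number of poses.
#' @param energies Optional numeric vector of pose energies (default:
#'   standard-normal draws around -7).
#' @param seed Integer seed.
#' @param n_atoms Ligand heavy-atom count (default 5).
#' @param centers Optional list of center matrices (`n_atoms x 3`).
#' @param separation Center-to-center RMSD when centers are generated
#'   (default 10).
#' @param variant_label Label attached to the poses.
#' @return List with `poses` (list of [pose()]), `true_labels` (integer
#'   cluster id per pose) and `centers`.
#' @export
gen_pose_set <- function(k_clusters, spread, n_poses, energies = NULL,
                         seed = 1L, n_atoms = 5L, centers = NULL,
                         separation = 10, variant_label = "WT") {
  if (is.null(centers)) {
    if (spread >= separation / 2) {
      stop("infeasible geometry: spread must be < separation / 2")
    }
    base <- with_seed(child_seed(seed, "pose_centers"),
                      matrix(stats::rnorm(n_atoms * 3, sd = 2),
                             ncol = 3))
    centers <- lapply(seq_len(k_clusters), function(k) {
      # rigid translation by k * separation along x: RMSD between
      # centers is exactly their index distance times separation
      base + matrix(rep(c((k - 1L) * separation, 0, 0), each = n_atoms),
                    ncol = 3)
    })
  } else {
    k_clusters <- length(centers)
    n_atoms <- nrow(centers[[1]])
    min_sep <- Inf
    for (i in seq_len(k_clusters - 1L)) {
      for (j in seq(i + 1L, k_clusters)) {
        min_sep <- min(min_sep, pose_rmsd(centers[[i]], centers[[j]]))
      }
    }
    if (k_clusters > 1L && spread >= min_sep / 2) {
      stop("infeasible geometry: spread must be < half the minimum ",
           "center separation (", round(min_sep, 3), ")")
    }
  }
  true_labels <- rep(seq_len(k_clusters), length.out = n_poses)
  if (is.null(energies)) {
    energies <- with_seed(child_seed(seed, "pose_energies"),
                          stats::rnorm(n_poses, -7, 0.5))
  }
  poses <- with_seed(child_seed(seed, "pose_jitter"), {
    lapply(seq_len(n_poses), function(i) {
      jit <- matrix(stats::rnorm(n_atoms * 3), ncol = 3)
      target <- stats::runif(1, 0, 0.95 * spread)
      jit <- jit * target / sqrt(mean(rowSums(jit^2)))
      pose(pose_id = i, coords = centers[[true_labels[i]]] + jit,
           energy = energies[i], variant_label = variant_label)
    })
  })
  list(poses = poses, true_labels = true_labels, centers = centers)
}

#' Synthetic trajectory with planted per-residue fluctuations
#'
#' One alpha-carbon pseudo-atom per residue on a fixed extended-chain
#' scaffold; every frame adds independent Gaussian displacements with
#' per-residue SD `sigma[i]` per coordinate (so the expected RMSF of
#' residue i is `sigma[i] * sqrt(3)`), plus an optional rigid per-frame
#' drift that superposition must remove.
#'
#' @param n_residues Number of residues.
#' @param n_frames Number of frames.
#' @param sigma Per-residue fluctuation SD in Angstrom (recycled).
#' @param dt Frame spacing, ps (default 10).
#' @param drift Optional length-3 per-frame rigid displacement vector.
#' @param seed Integer seed.
#' @return List with `traj` (a [trajectory()]) and `sigma` (the planted
#'   per-residue SDs).
#' @export
gen_trajectory <- function(n_residues, n_frames, sigma, dt = 10,
                           drift = NULL, seed = 1L) {
  sigma <- rep_len(sigma, n_residues)
  if (any(sigma < 0)) stop("sigma must be non-negative")
  base <- cbind(3.8 * seq_len(n_residues),
                2 * sin(seq_len(n_residues) / 3),
                2 * cos(seq_len(n_residues) / 3))
  coords <- array(0, c(n_frames, n_residues, 3))
  noise <- with_seed(child_seed(seed, "trajectory"), {
    array(stats::rnorm(n_frames * n_residues * 3),
          c(n_frames, n_residues, 3))
  })
  for (i in seq_len(n_residues)) {
    noise[, i, ] <- noise[, i, ] * sigma[i]
  }
  for (f in seq_len(n_frames)) {
    shift <- if (is.null(drift)) c(0, 0, 0) else (f - 1) * drift
    coords[f, , ] <- base +
      matrix(noise[f, , ], ncol = 3) +
      matrix(rep(shift, each = n_residues), ncol = 3)
  }
  top <- data.frame(elety = "CA", resno = seq_len(n_residues),
                    resid = "ALA", chain = "A", elem = "C",
                    stringsAsFactors = FALSE)
  list(traj = trajectory(top, coords, dt), sigma = sigma)
}

#' Synthetic MM/PBSA energy frames with known means and SDs
#'
#' Gaussian per-term draws for each entity (complex, protein, ligand).
#' Optionally attaches a per-residue decomposition that sums exactly to
#' each snapshot's decomposable total (vdW + electrostatic + polar
#' deltas), so conservation checks hold by construction.
#'
#' @param term_means 3 x 4 numeric matrix (rows complex/protein/ligand,
#'   columns vdw/elec/polar/apolar), kJ/mol.
#' @param term_sds Matrix of matching shape with non-negative SDs.
#' @param n Number of snapshots (default 500).
#' @param seed Integer seed.
#' @param n_residues If positive, attach an `n_residues`-way per-residue
#'   decomposition.
#' @return List of [energy_frame()]s.
#' @export
gen_energy_frames <- function(term_means, term_sds, n = 500, seed = 1L,
                              n_residues = 0L) {
  term_means <- as.matrix(term_means)
  term_sds <- as.matrix(term_sds)
  if (!identical(dim(term_means), c(3L, 4L)) ||
      !identical(dim(term_sds), c(3L, 4L))) {
    stop("term_means and term_sds must be 3 x 4 ",
         "(complex/protein/ligand x vdw/elec/polar/apolar)")
  }
  if (any(term_sds < 0)) stop("negative sd in term_sds")
  if (n < 2L) stop("need n >= 2 snapshots")
  rownames(term_means) <- rownames(term_sds) <- MMPBSA_ENTITIES
  colnames(term_means) <- colnames(term_sds) <- MMPBSA_TERMS
  with_seed(child_seed(seed, "energy_frames"), {
    lapply(seq_len(n), function(fi) {
      draw <- function(ent) {
        stats::setNames(stats::rnorm(4L, term_means[ent, ],
                                     term_sds[ent, ]), MMPBSA_TERMS)
      }
      comp <- draw("complex"); prot <- draw("protein")
      lig <- draw("ligand")
      pr <- NULL
      if (n_residues > 0L) {
        delta <- comp - (prot + lig)
        decomposable <- sum(delta[c("vdw", "elec", "polar")])
        w <- stats::runif(n_residues)
        pr <- stats::setNames(decomposable * w / sum(w),
                              as.character(seq_len(n_residues)))
      }
      energy_frame(fi, comp, prot, lig, per_residue = pr)
    })
  })
}

#' Synthetic aligned FASTA emitter
#'
#' Writes an alignment generated from a reference sequence by per-column
#' substitution, for reader round-trip tests and pipeline demos.
#'
#' @param n_seqs Number of sequences.
#' @param n_cols Alignment length.
#' @param sub_rate Per-column probability that a non-reference row
#'   carries a different residue.
#' @param gap_rate Per-column gap probability in non-reference rows.
#' @param seed Integer seed.
#' @param path Optional output path (aligned FASTA written when given).
#' @return An [aligned_set()] (reference id `"seq1"`).
#' @export
gen_alignment <- function(n_seqs = 4L, n_cols = 60L, sub_rate = 0.3,
                          gap_rate = 0.05, seed = 1L, path = NULL) {
  aa <- standard_aa()
  rows <- with_seed(child_seed(seed, "alignment"), {
    ref <- sample(aa, n_cols, replace = TRUE)
    rows <- list(paste(ref, collapse = ""))
    for (s in seq_len(n_seqs - 1L)) {
      mut <- ref
      flip <- stats::runif(n_cols) < sub_rate
      mut[flip] <- sample(aa, sum(flip), replace = TRUE)
      gap <- stats::runif(n_cols) < gap_rate
      mut[gap] <- "-"
      rows[[s + 1L]] <- paste(mut, collapse = "")
    }
    rows
  })
  aln <- aligned_set(paste0("seq", seq_len(n_seqs)),
                     unlist(rows), ref_id = "seq1")
  if (!is.null(path)) write_alignment(aln, path)
  aln
}
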