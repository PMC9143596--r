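# End-to-end reverse screen: sites -> alanine scan -> mean-minus-SD
# threshold -> combinatorial alanine scan -> site saturation ->
# sequence-space maps -> trajectory and MM/PBSA reports, driven by one
# declarative config. Every stage is a pure function of its declared
# inputs; reports embed a hash of the resolved config.

#' Default synthetic run configuration
#'
#' The study conditions of the reference workflow, with the physics
#' supplied by a planted landscape: 42 candidate sites (27 loop / 15
#' non-loop around the binding cleft, catalytic triad S160/D206/H237
#' excluded), eight strong sites whose alanine substitution gains
#' -1.4 kcal/mol, three weakly improving sites at -0.3 kcal/mol,
#' residue-specific gains at positions 112/119/238 with a
#' residue-specific synergy planted on the (112, 238) pair, a +1.0
#' kcal/mol crowding penalty on every other simultaneous pair, and
#' 0.15 kcal/mol of Gaussian scoring noise -- small enough (well under
#' half the planted effects) that a screen should recover the planted
#' structure. Screening parameters: 2.0 Angstrom cluster tolerance,
#' 4.0 Angstrom catalytic cutoff, conservation cutoff 6, 500 MM/PBSA
#' snapshots.
#'
#' @param seed Global integer seed; all stage randomness derives from it.
#' @return A nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  strong <- c(87, 112, 119, 205, 214, 238, 253, 280)
  weak <- c(186, 252, 278)
  named_wt <- c(`87` = "Y", `112` = "D", `119` = "Q", `186` = "D",
                `205` = "N", `214` = "S", `238` = "S", `252` = "K",
                `253` = "K", `278` = "S", `280` = "R")
  filler <- c(58, 61, 63, 88, 90, 93, 114, 117, 121, 150, 153, 157,
              164, 168, 181, 183, 188, 190, 208, 210, 212, 216, 218,
              232, 234, 241, 243, 246, 250, 255, 270)
  filler_wt <- stats::setNames(
    rep(c("T", "N", "G", "S", "Q", "L", "I", "V", "F", "W", "M"),
        length.out = length(filler)),
    as.character(filler))
  sites <- sort(c(strong, weak, filler))
  wt_residues <- c(named_wt, filler_wt)[as.character(sites)]
  additive <- rbind(
    data.frame(site = strong, aa = "A", effect = -1.4),
    data.frame(site = weak, aa = "A", effect = -0.3),
    data.frame(site = c(238, 238, 238, 119, 119, 112),
               aa = c("C", "F", "L", "F", "Y", "M"),
               effect = c(-2.1, -1.7, -1.6, -1.6, -1.4, -1.5))
  )
  prs <- utils::combn(strong, 2L)
  epistasis <- data.frame(site_a = prs[1, ], site_b = prs[2, ],
                          effect = 1.0,
                          aa_a = NA_character_, aa_b = NA_character_)
  epistasis$effect[epistasis$site_a == 112 &
                     epistasis$site_b == 238] <- -0.4
  epistasis <- rbind(epistasis,
                     data.frame(site_a = 112, site_b = 238,
                                effect = -1.2, aa_a = "M", aa_b = "F"))
  list(
    seed = as.integer(seed),
    sites = list(
      candidate_sites = sites,
      wt_residues = as.list(wt_residues),
      loop_sites = sites[seq_len(27)],
      catalytic_sites = c(160, 206, 237),
      score_cutoff = 6
    ),
    landscape = list(
      wt_energy = -7.0,
      additive = additive,
      epistasis = epistasis,
      noise_sd = 0.15,
      planted_strong_sites = strong
    ),
    screen = list(rmsd_tol = 2.0, catalytic_cutoff = 4.0,
                  contact_cutoff = 5.0, n_runs = 500),
    ssm = list(double_sites = c(112, 238)),
    md = list(n_residues = 50, n_frames = 200, dt = 10,
              sigma = list(base = 0.25, loop = 0.6)),
    mmpbsa = list(n_snapshots = 500,
                  dielectric_protein = 4, dielectric_water = 80),
    class_table = residue_class_table(),
    docking_provenance = docking_provenance()
  )
}

#' Hash of a resolved configuration
#'
#' MD5 over the canonical (sorted-name) JSON serialization; embedded in
#' every stage report so outputs can be traced to the exact settings
#' that produced them.
#'
#' @param config Configuration list (data only).
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  canonical <- function(x) {
    if (is.list(x) && !is.null(names(x))) {
      x <- x[order(names(x))]
      lapply(x, canonical)
    } else if (is.list(x)) {
      lapply(x, canonical)
    } else x
  }
  json <- jsonlite::toJSON(canonical(config), auto_unbox = TRUE,
                           digits = NA, force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

pipeline_landscape <- function(config) {
  wt_residues <- unlist(config$sites$wt_residues)
  gen_landscape(
    sites = config$sites$candidate_sites,
    wt_residues = wt_residues,
    wt_energy = config$landscape$wt_energy,
    additive = config$landscape$additive,
    epistasis = config$landscape$epistasis,
    noise_sd = config$landscape$noise_sd,
    seed = config$seed
  )
}

#' Run one pipeline stage
#'
#' Stages: `"sites"` (candidate-site nomination), `"asm"` (single
#' alanine scan + threshold -> nominated sites), `"asm_iter"`
#' (combinatorial alanine scan over nominated sites + mutation-count
#' and fixed-site maps), `"ssm"` (single saturation per nominated site
#' and the double grid + class maps), `"md"` (synthetic trajectory,
#' RMSD/RMSF), `"mmpbsa"` (synthetic energy frames, binding summary).
#' Later stages need the `state` returned by earlier ones.
#'
#' @param name Stage name.
#' @param config Configuration from [default_run_config()].
#' @param state Accumulated state list from previous stages.
#' @return List with `report` (serializable stage summary, including
#'   `config_hash`) and `state` (inputs for downstream stages).
#' @export
run_stage <- function(name, config = default_run_config(),
                      state = list()) {
  hash <- config_hash(config)
  need <- function(field, from) {
    if (is.null(state[[field]])) {
      stop("stage '", name, "' needs state from upstream stage '",
           from, "'; run it first")
    }
    state[[field]]
  }
  wt_residues <- unlist(config$sites$wt_residues)
  report <- switch(
    name,
    sites = {
      sc <- config$sites
      ann <- site_annotation(
        residue_number = c(sc$candidate_sites, sc$catalytic_sites),
        amino_acid = c(wt_residues[as.character(sc$candidate_sites)],
                       c("S", "D", "H")),
        region = c(ifelse(sc$candidate_sites %in% sc$loop_sites,
                          "loop", "non-loop"),
                   rep("non-loop", length(sc$catalytic_sites))),
        conservation = c(rep(4L, length(sc$candidate_sites)),
                         rep(11L, length(sc$catalytic_sites))),
        catalytic = c(rep(FALSE, length(sc$candidate_sites)),
                      rep(TRUE, length(sc$catalytic_sites))),
        near_active_site = c(sc$candidate_sites %in% sc$loop_sites,
                             rep(FALSE, length(sc$catalytic_sites)))
      )
      ann <- nominate_sites(ann, score_cutoff = sc$score_cutoff)
      state$candidate_sites <- ann$residue_number[ann$nominated]
      state$annotations <- ann
      list(n_annotated = nrow(ann),
           n_candidates = length(state$candidate_sites),
           n_loop = sum(ann$region == "loop" & ann$nominated),
           n_nonloop = sum(ann$region == "non-loop" & ann$nominated))
    },
    asm = {
      sites <- need("candidate_sites", "sites")
      landscape <- pipeline_landscape(config)
      state$landscape <- landscape
      lib <- alanine_combinatorial(
        sites, wt_residues, r_min = 1L, r_max = 1L,
        catalytic_sites = config$sites$catalytic_sites)
      records <- score_library(lib, landscape$score)
      thr <- selection_threshold(records$delta_delta_g)
      hits <- nominate_candidates(records, thr)
      nominated_sites <- sort(unlist(hits$sites))
      state$asm_records <- records
      state$threshold <- thr
      state$nominated_sites <- nominated_sites
      list(n_variants = nrow(records),
           n_negative = sum(records$delta_delta_g < 0),
           threshold = list(mean = thr$mean, sd = thr$sd,
                            cutoff = thr$cutoff, n = thr$n),
           n_nominated = length(nominated_sites),
           nominated_sites = nominated_sites)
    },
    asm_iter = {
      sites <- need("nominated_sites", "asm")
      landscape <- need("landscape", "asm")
      lib <- alanine_combinatorial(
        sites, wt_residues,
        catalytic_sites = config$sites$catalytic_sites)
      records <- score_library(lib, landscape$score)
      state$asm_iter_records <- records
      state$count_map <- map_by_mutation_count(records)
      state$site_map <- fixed_site_map(records, sites)
      best_r <- state$count_map$values$r[
        which.min(state$count_map$values$min)]
      list(n_variants = nrow(records),
           per_r = as.list(stats::setNames(
             state$count_map$values$n, state$count_map$values$r)),
           best = list(
             label = records$variant_label[
               which.min(records$delta_delta_g)],
             delta_delta_g = min(records$delta_delta_g),
             r = best_r))
    },
    ssm = {
      sites <- need("nominated_sites", "asm")
      landscape <- need("landscape", "asm")
      singles <- do.call(rbind, lapply(sites, function(s) {
        lib <- ssm_single(s, wt_residues[[as.character(s)]],
                          include_wt = FALSE,
                          catalytic_sites = config$sites$catalytic_sites)
        score_library(lib, landscape$score)
      }))
      best_single <- singles[which.min(singles$delta_delta_g), ]
      ds <- config$ssm$double_sites
      dlib <- ssm_double(ds[1], ds[2],
                         wt_residues[[as.character(ds[1])]],
                         wt_residues[[as.character(ds[2])]],
                         catalytic_sites = config$sites$catalytic_sites)
      doubles <- score_library(dlib, landscape$score)
      best_double <- doubles[which.min(doubles$delta_delta_g), ]
      state$ssm_single_records <- singles
      state$ssm_double_records <- doubles
      state$class_map_double <- class_map(
        doubles, ds, wt_residues, aggregator = "mean",
        class_table = config$class_table)
      list(n_single = nrow(singles), n_double = nrow(doubles),
           best_single = list(label = best_single$variant_label,
                              delta_delta_g = best_single$delta_delta_g),
           best_double = list(label = best_double$variant_label,
                              delta_delta_g = best_double$delta_delta_g))
    },
    md = {
      mc <- config$md
      sigma <- rep(mc$sigma$base, mc$n_residues)
      loop_idx <- seq(10, mc$n_residues, by = 10)
      sigma[loop_idx] <- mc$sigma$loop
      sim <- gen_trajectory(mc$n_residues, mc$n_frames, sigma,
                            dt = mc$dt,
                            seed = child_seed(config$seed, "md"))
      state$trajectory <- sim$traj
      state$sigma <- sim$sigma
      series <- rmsd_series(sim$traj)
      state$rmsd <- series
      state$rmsf <- rmsf_per_residue(sim$traj)
      list(n_frames = mc$n_frames, n_residues = mc$n_residues,
           rmsd_last = series$rmsd[nrow(series)],
           rmsf_range = range(state$rmsf$rmsf))
    },
    mmpbsa = {
      rep_row <- reported_mmpbsa()[1, ]
      delta <- c(vdw = rep_row$vdw, elec = rep_row$elec,
                 polar = rep_row$polar, apolar = rep_row$apolar)
      sds <- c(vdw = rep_row$vdw_sd, elec = rep_row$elec_sd,
               polar = rep_row$polar_sd, apolar = rep_row$apolar_sd)
      protein <- c(vdw = -3200, elec = -8800, polar = 2400,
                   apolar = 95)
      ligand <- c(vdw = -60, elec = -45, polar = 110, apolar = 20)
      term_means <- rbind(complex = protein + ligand + delta,
                          protein = protein, ligand = ligand)
      term_sds <- rbind(complex = sds, protein = 0.6 * sds,
                        ligand = 0.25 * sds)
      frames <- gen_energy_frames(term_means, term_sds,
                                  n = config$mmpbsa$n_snapshots,
                                  seed = child_seed(config$seed,
                                                    "mmpbsa"))
      state$energy_frames <- frames
      summary <- summarize_binding(frames)
      state$binding_summary <- summary
      list(n_snapshots = attr(summary, "n_snapshots"),
           total_mean = summary$mean[summary$term == "total"],
           total_sd = summary$sd[summary$term == "total"],
           dielectrics = list(
             protein = config$mmpbsa$dielectric_protein,
             water = config$mmpbsa$dielectric_water))
    },
    stop("unknown stage '", name, "'")
  )
  report$stage <- name
  report$config_hash <- hash
  list(report = report, state = state)
}

#' Run the full reverse-screening pipeline
#'
#' Executes sites -> asm -> asm_iter -> ssm -> md -> mmpbsa in order
#' and returns all stage reports plus a final summary naming the best
#' single- and double-substitution variants and, when the config
#' carries planted ground truth, whether the screen recovered it.
#'
#' @param config Configuration from [default_run_config()].
#' @param out_dir Optional directory; when given, stage reports are
#'   written as JSON and tabular outputs as TSV.
#' @return List with `reports` (per stage), `summary`, and `state`.
#' @export
run_pipeline <- function(config = default_run_config(),
                         out_dir = NULL) {
  stages <- c("sites", "asm", "asm_iter", "ssm", "md", "mmpbsa")
  state <- list()
  reports <- list()
  for (s in stages) {
    res <- run_stage(s, config, state)
    state <- res$state
    reports[[s]] <- res$report
  }
  landscape <- state$landscape
  summary <- list(
    config_hash = config_hash(config),
    n_candidate_sites = reports$sites$n_candidates,
    nominated_sites = reports$asm$nominated_sites,
    best_single = reports$ssm$best_single,
    best_double = reports$ssm$best_double
  )
  if (!is.null(landscape$ground_truth)) {
    gt <- landscape$ground_truth
    planted <- config$landscape$planted_strong_sites
    summary$ground_truth <- list(
      best_single = gt$single$label,
      best_double = gt$double$label,
      planted_strong_sites = planted)
    summary$recovered <- list(
      best_single = identical(reports$ssm$best_single$label,
                              gt$single$label),
      best_double = identical(reports$ssm$best_double$label,
                              gt$double$label),
      planted_sites_nominated =
        if (is.null(planted)) NA else
          sum(planted %in% reports$asm$nominated_sites))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in names(reports)) {
      jsonlite::write_json(
        reports[[s]], file.path(out_dir, paste0(s, ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(
      state$asm_records[, c("variant_label", "r", "delta_g",
                            "delta_delta_g")],
      file.path(out_dir, "asm_records.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    write_space_map(state$count_map,
                    file.path(out_dir, "mutation_count_map.tsv"))
    write_space_map(state$site_map,
                    file.path(out_dir, "fixed_site_map.tsv"))
    write_space_map(state$class_map_double,
                    file.path(out_dir, "class_map_double.tsv"))
  }
  list(reports = reports, summary = summary, state = state)
}

#' Read a pipeline run configuration from YAML or JSON
#'
#' Fields mirror [default_run_config()]; missing fields fall back to
#' the defaults. `additive` and `epistasis` may be given as lists of
#' records.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A configuration list.
#' @export
read_run_config <- function(path) {
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  config <- default_run_config(
    seed = if (is.null(user$seed)) 1L else as.integer(user$seed))
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(upd[[nm]]) && is.list(base[[nm]]) &&
          !is.data.frame(base[[nm]])) {
        base[[nm]] <- merge_into(base[[nm]], upd[[nm]])
      } else {
        base[[nm]] <- upd[[nm]]
      }
    }
    base
  }
  config <- merge_into(config, user)
  for (tab in c("additive", "epistasis")) {
    v <- config$landscape[[tab]]
    if (!is.data.frame(v) && is.list(v)) {
      config$landscape[[tab]] <-
        do.call(rbind, lapply(v, as.data.frame))
    }
  }
  config
}
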