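# Pipeline orchestration: generate or load inputs per stage, run the
# analyses, write per-stage CSV/TSV outputs and one machine-readable
# summary JSON. All randomness flows from config$seed; timestamps are
# deliberately excluded so reruns are byte-identical.

#' Default pipeline configuration
#'
#' A single nested list holding every stage input path, toggle and
#' threshold. Field-standard defaults: hydrophobic class M,A,V,I,L,C,Y,F,W;
#' consensus vote threshold 0.5; helicity conservation criterion 0.6;
#' contact cutoff 6.0 Angstroms; salt-bridge threshold 3.5 Angstroms;
#' cavity grid spacing 1.0 and probe 1.4 Angstroms. The `simulate` block
#' sizes the default synthetic bundle; its bilayer emulates a POPC patch
#' with a mean area per lipid of 65.58 Angstrom^2 (SD 0.82, 200 lipids).
#'
#' @param out_dir output directory.
#' @param seed master seed for the synthetic bundle.
#' @return a nested list usable with [run_pipeline()]; serialisable to
#'   YAML/JSON.
#' @export
default_pipeline_config <- function(out_dir = "memqc_run", seed = 1) {
  list(
    seed = seed,
    out_dir = out_dir,
    stages = list(conservation = TRUE, topology = TRUE, trajectory = TRUE,
                  pocket = TRUE, assay = TRUE),
    simulate = list(
      enabled = TRUE,
      msa = list(n_rows = 200, length = 60,
                 class_freq = 0.8, gap_prob = 0),
      tracks = list(n_residues = 60,
                    segments = data.frame(start = c(6, 31),
                                          end = c(25, 50)),
                    n_predictors = 4, flip_prob = 0.05),
      helix = list(n_residues = 30, n_frames = 60, n_replicas = 3,
                   unwind = 15, unwind_fraction = 0.4,
                   dihedral_noise_sd = 4, coord_noise_sd = 0.05),
      bilayer = list(n_lipids_total = 200, area_mean = 65.58,
                     area_sd = 0.82),
      contact = list(n_frames = 100, target_fraction = 0.21),
      salt_bridge = list(n_frames = 100, target_occupancy = 0.35),
      assay = list(pIC50 = 7.1, hill = 1.0, top = 100, bottom = 0,
                   concentrations = 10^seq(-10, -4, length.out = 10),
                   noise_sd = 0.01, n_experiments = 3)
    ),
    conservation = list(gap_policy = "all_rows",
                        report_positions = c(5, 15, 25)),
    topology = list(threshold = 0.5, min_len = 15, max_gap = 3,
                    expected_segments = NULL),
    trajectory = list(helical_codes = "H", criterion = 0.6,
                      selection = NULL, plateau_fraction = 0.25),
    pocket = list(contact_cutoff = 6.0, salt_bridge_threshold = 3.5,
                  cavity = list(spacing = 1.0, probe = 1.4))
  )
}

read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$simulate$tracks$segments)) {
    cfg$simulate$tracks$segments <-
      as.data.frame(cfg$simulate$tracks$segments)
  }
  cfg
}

# Stable config fingerprint: a small FNV-style hash of the deparsed config.
config_hash <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "out_dir")]),
               collapse = "")
  h <- 2166136261
  for (code in utf8ToInt(txt)) h <- ((h * 16777619) + code) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full model-assessment pipeline
#'
#' Executes the enabled stages — conservation profiling, topology
#' consensus, trajectory metrics (RMSD plateau, helicity conservation),
#' pocket statistics (contact occupancy, salt-bridge occupancy, area per
#' lipid) and dose-response fitting — writing per-stage tables under
#' `out_dir` and an aggregate `summary.json`. When `simulate$enabled` is
#' `TRUE`, the synthetic bundle is generated first (into
#' `out_dir/inputs/`) and consumed through the same file formats external
#' data would use.
#'
#' @param config a config list from [default_pipeline_config()], or a path
#'   to a YAML/JSON file with the same structure.
#' @return the summary list, invisibly. Per-stage failures are collected
#'   and re-raised as one error after all stages have been attempted;
#'   partial outputs are preserved.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  in_dir <- file.path(out_dir, "inputs")
  seed <- config$seed
  summary <- list(seed = seed, config_hash = config_hash(config),
                  package_version = as.character(
                    utils::packageVersion("memqc")))
  errors <- character()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors <<- c(errors, paste0(name, ": ", conditionMessage(e)))
      NULL
    })
  }

  sim <- config$simulate
  if (isTRUE(sim$enabled)) {
    dir.create(in_dir, showWarnings = FALSE)
    run_stage("simulate", {
      msa <- gen_msa(sim$msa$n_rows, sim$msa$length, sim$msa$class_freq,
                     sim$msa$gap_prob, seed = seed)
      write_alignment(msa, file.path(in_dir, "msa.fasta"))
      tr <- gen_tm_tracks(sim$tracks$n_residues,
                          as.data.frame(sim$tracks$segments),
                          sim$tracks$n_predictors, sim$tracks$flip_prob,
                          seed = seed)
      utils::write.table(tr, file.path(in_dir, "tm_tracks.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      h <- sim$helix
      area <- sim$bilayer$area_mean
      n_lip <- sim$bilayer$n_lipids_total
      side <- sqrt(area * n_lip / 2)
      side_sd <- sim$bilayer$area_sd * (n_lip / 2) / (2 * side)
      boxes <- with_seed(derive_seed(seed, "bilayer"), {
        lapply(seq_len(h$n_replicas), function(i) {
          s <- rnorm(h$n_frames, side, side_sd)
          cbind(s, s, 100)
        })
      })
      trajs <- gen_helix_trajectory(
        h$n_residues, h$n_frames, h$n_replicas, unwind = h$unwind,
        unwind_fraction = h$unwind_fraction,
        dihedral_noise_sd = h$dihedral_noise_sd,
        coord_noise_sd = h$coord_noise_sd, seed = seed)
      for (i in seq_along(trajs)) {
        trajs[[i]]$box <- boxes[[i]]
        write_trajectory(trajs[[i]],
                         file.path(in_dir, sprintf("traj_rep%d.pdb", i)))
      }
      ct <- gen_contact_trace(sim$contact$n_frames,
                              sim$contact$target_fraction, seed = seed)
      write_trajectory(ct, file.path(in_dir, "contact.pdb"))
      sb <- gen_salt_bridge_trace(sim$salt_bridge$n_frames,
                                  sim$salt_bridge$target_occupancy,
                                  seed = seed)
      write_trajectory(sb, file.path(in_dir, "salt_bridge.pdb"))
      a <- sim$assay
      rows <- lapply(seq_len(a$n_experiments), function(e) {
        dr <- gen_dose_response(a$pIC50, a$hill, a$top, a$bottom,
                                a$concentrations, noise_sd = a$noise_sd,
                                noise = "multiplicative",
                                seed = derive_seed(seed, paste0("exp", e)))
        data.frame(experiment_id = paste0("exp", e),
                   concentration_M = dr$concentration, signal = dr$signal,
                   b0 = a$top)
      })
      utils::write.csv(do.call(rbind, rows),
                       file.path(in_dir, "dose_response.csv"),
                       row.names = FALSE)
      truth <- list(
        msa_class_freq = sim$msa$class_freq,
        tm_segments = as.data.frame(sim$tracks$segments),
        helicity = attr(trajs, "ground_truth")[
          c("unwind", "unwind_fraction", "expected_helicity")],
        contact_fraction = sim$contact$target_fraction,
        salt_bridge_occupancy = sim$salt_bridge$target_occupancy,
        assay = a[c("pIC50", "hill", "top", "bottom")])
      jsonlite::write_json(truth, file.path(in_dir, "ground_truth.json"),
                           digits = NA, auto_unbox = TRUE)
      config$inputs <- list(
        msa = file.path(in_dir, "msa.fasta"), msa_reference = "ref",
        tracks = file.path(in_dir, "tm_tracks.tsv"),
        trajectories = file.path(in_dir, sprintf("traj_rep%d.pdb",
                                                 seq_len(h$n_replicas))),
        contact = file.path(in_dir, "contact.pdb"),
        salt_bridge = file.path(in_dir, "salt_bridge.pdb"),
        assay = file.path(in_dir, "dose_response.csv"))
    })
  }
  inp <- config$inputs

  if (isTRUE(config$stages$conservation) && !is.null(inp$msa)) {
    run_stage("conservation", {
      aln <- read_alignment(inp$msa, inp$msa_reference %||% "ref")
      prof <- conservation_profile(
        aln, gap_policy = config$conservation$gap_policy %||% "all_rows")
      write_conservation(prof, file.path(out_dir, "conservation.tsv"))
      pos <- config$conservation$report_positions
      rep_rows <- prof[prof$position %in% pos, , drop = FALSE]
      summary$conservation <- list(
        n_positions = nrow(prof),
        mean_class_pct = mean(prof$class_pct),
        reported = as.data.frame(rep_rows))
    })
  }
  if (isTRUE(config$stages$topology) && !is.null(inp$tracks)) {
    run_stage("topology", {
      tracks <- read_tm_tracks(inp$tracks)
      tc <- config$topology
      cons <- tm_consensus(tracks, threshold = tc$threshold %||% 0.5,
                           min_len = tc$min_len %||% 15,
                           max_gap = tc$max_gap %||% 3,
                           expected_segments = tc$expected_segments)
      write_tm_segments(cons, file.path(out_dir, "tm_segments.tsv"))
      summary$topology <- list(n_segments = nrow(cons$segments),
                                segments = cons$segments)
    })
  }

  trajs <- NULL
  if (!is.null(inp$trajectories)) {
    trajs <- lapply(seq_along(inp$trajectories), function(i) {
      read_trajectory(inp$trajectories[i], replica_id = paste0("rep", i))
    })
  }
  if (isTRUE(config$stages$trajectory) && !is.null(trajs)) {
    run_stage("trajectory", {
      tc <- config$trajectory
      sel <- tc$selection %||% unique(trajs[[1]]$atom$resno)
      plateaus <- lapply(trajs, function(tr) {
        rs <- rmsd_series(tr, selection = sel)
        utils::write.csv(
          data.frame(frame = seq_along(rs$values), rmsd_A = rs$values),
          file.path(out_dir, paste0("rmsd_", tr$replica_id, ".csv")),
          row.names = FALSE)
        rmsd_plateau(rs, tc$plateau_fraction %||% 0.25)
      })
      hp <- helicity_profile(trajs, helical_codes = tc$helical_codes %||% "H",
                             criterion = tc$criterion %||% 0.6)
      utils::write.csv(as.data.frame(hp),
                       file.path(out_dir, "helicity.csv"), row.names = FALSE)
      summary$trajectory <- list(
        rmsd_plateau = lapply(plateaus, function(p)
          list(mean = p$mean, sd = p$sd)),
        n_conserved = sum(hp$conserved),
        n_residues = nrow(hp),
        criterion = tc$criterion %||% 0.6)
    })
  }
  if (isTRUE(config$stages$pocket)) {
    run_stage("pocket", {
      pc <- config$pocket
      pocket_summary <- list()
      if (!is.null(inp$contact)) {
        ct <- read_trajectory(inp$contact, replica_id = "contact")
        truth_res <- 3
        occ <- contact_occupancy(ct, ligand = list(resid = "LIG"),
                                 residues = sort(unique(
                                   ct$atom$resno[ct$atom$resid != "LIG"])),
                                 cutoff = pc$contact_cutoff %||% 6.0)
        utils::write.csv(as.data.frame(occ),
                         file.path(out_dir, "contacts.csv"),
                         row.names = FALSE)
        pocket_summary$max_contact_fraction <- max(occ$fraction)
        pocket_summary$contact_fraction_target_residue <-
          occ$fraction[occ$residue == truth_res]
      }
      if (!is.null(inp$salt_bridge)) {
        sb <- read_trajectory(inp$salt_bridge)
        trace <- salt_bridge_trace(
          sb, donor = list(elety = "HZ1"),
          acceptor = list(elety = c("OD1", "OD2")),
          threshold = pc$salt_bridge_threshold %||% 3.5)
        utils::write.csv(
          data.frame(frame = seq_along(trace$distances),
                     min_distance_A = trace$distances),
          file.path(out_dir, "salt_bridge.csv"), row.names = FALSE)
        pocket_summary$salt_bridge <- list(occupancy = trace$occupancy,
                                           mean = trace$mean, sd = trace$sd)
      }
      if (!is.null(trajs) && !is.null(trajs[[1]]$box)) {
        apl <- lapply(trajs, function(tr)
          area_per_lipid(tr, config$simulate$bilayer$n_lipids_total %||% 200))
        utils::write.csv(
          data.frame(frame = seq_along(apl[[1]]$values),
                     area_A2 = apl[[1]]$values),
          file.path(out_dir, "lipid_area.csv"), row.names = FALSE)
        pocket_summary$area_per_lipid <- list(
          mean = mean(vapply(apl, `[[`, 1, "mean")),
          sd_within_first_replica = apl[[1]]$sd)
      }
      if (!is.null(trajs)) {
        co <- frame_coords(trajs[[1]], 1)
        centre <- colMeans(co)
        region <- list(x = centre[1] + c(-10, 10),
                       y = centre[2] + c(-10, 10),
                       z = centre[3] + c(-10, 10))
        vol <- tryCatch(
          cavity_volume(trajs[[1]], region,
                        seed_point = centre + c(8, 8, 8),
                        spacing = pc$cavity$spacing %||% 1.0,
                        probe = pc$cavity$probe %||% 1.4),
          error = function(e) NULL)
        if (!is.null(vol)) pocket_summary$cavity_volume_A3 <- vol$volume
      }
      summary$pocket <- pocket_summary
    })
  }
  if (isTRUE(config$stages$assay) && !is.null(inp$assay)) {
    run_stage("assay", {
      df <- read_dose_response_csv(inp$assay)
      res <- fit_binding_experiments(df)
      jsonlite::write_json(
        lapply(res$fits, function(f)
          f[c("pIC50", "hill_slope", "top", "bottom", "rss", "converged",
              "no_inhibition")]),
        file.path(out_dir, "fits.json"), digits = NA, auto_unbox = TRUE)
      summary$assay <- list(
        n_experiments = res$summary$n,
        mean_pIC50 = res$summary$mean_pIC50,
        sd_pIC50 = res$summary$sd_pIC50,
        n_no_inhibition = res$summary$n_no_inhibition)
    })
  }

  summary$errors <- errors
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  if (length(errors) > 0L) {
    stop("pipeline stage failures:\n  ", paste(errors, collapse = "\n  "))
  }
  invisible(summary)
}
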