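# End-to-end study orchestration from a config list or YAML file: gait,
# histology, qPCR and clinical-score runs, applying the study inclusion
# rules and emitting tidy tables plus a run log.

#' Read a study configuration file
#'
#' Thin wrapper over [yaml::read_yaml()]; paths in the config are resolved
#' relative to the config file's directory.
#'
#' @param path YAML config path.
#' @return Named list.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$.base_dir <- dirname(normalizePath(path))
  cfg
}

cfg_get <- function(config, name, default) {
  if (is.null(config[[name]])) default else config[[name]]
}

resolve_path <- function(path, base) {
  if (is.null(path)) return(NULL)
  if (file.exists(path) || grepl("^/", path)) path else file.path(base, path)
}

read_manifest <- function(path, required_cols) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required_cols, names(man))
  if (length(miss) > 0L)
    stop("manifest ", path, " is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(man) == 0L) stop("manifest is empty: ", path)
  base <- dirname(normalizePath(path))
  for (col in setdiff(required_cols, c("animal_id", "group", "dpi", "image_id",
                                       "field_id", "pixel_size_um")))
    man[[col]] <- vapply(man[[col]], resolve_path, character(1), base = base)
  man
}

write_table_if <- function(df, out_dir, name) {
  if (!is.null(out_dir) && !is.null(df)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  invisible(NULL)
}

#' Run the kinematic gait study over a cohort of recordings
#'
#' For every manifest row (animal x timepoint): apply the clinical-score
#' inclusion rule (gait is analysed only in animals still able to walk,
#' score <= `max_score`, default 2.5), then calibrate the track, compute
#' joint angles, segment phases, build the representative step cycle, and
#' derive average angles plus RMS differences against the animal's baseline
#' cycle (or within-recording variability when `rms_mode = "within"`).
#' Exclusions are recorded with machine-readable reasons; per-timepoint
#' two-group Mann-Whitney contrasts on each metric are emitted flagged as
#' exploratory.
#'
#' @param config list (or YAML path) with entries: `pose_manifest` (CSV with
#'   columns `animal_id`, `group`, `dpi`, `path`), `calibration_file`
#'   (see [write_calibration_file()]), `clinical_scores` (CSV with
#'   `animal_id`, `group`, `dpi`, `score`), and optionally `baseline_dpi`
#'   (-2), `max_score` (2.5), `likelihood_min` (0.9), `n_phase` (100),
#'   `phase` (a [phase_params()] list), `rms_mode` ("baseline" or "within"),
#'   `fps` (250), `out_dir`.
#' @return List with `metrics`, `exclusions`, `contrasts` data frames.
#' @export
run_gait_study <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  base <- cfg_get(config, ".base_dir", ".")
  manifest_path <- resolve_path(config$pose_manifest, base)
  if (is.null(manifest_path)) stop("config lacks pose_manifest")
  man <- read_manifest(manifest_path, c("animal_id", "group", "dpi", "path"))
  missing_files <- man$path[!file.exists(man$path)]
  if (length(missing_files) > 0L)
    stop("pose file(s) not found: ", paste(missing_files, collapse = ", "))

  cal_info <- read_calibration_file(resolve_path(config$calibration_file, base))
  scores <- utils::read.csv(resolve_path(config$clinical_scores, base),
                            stringsAsFactors = FALSE)

  baseline_dpi <- cfg_get(config, "baseline_dpi", -2)
  max_score <- cfg_get(config, "max_score", 2.5)
  likelihood_min <- cfg_get(config, "likelihood_min", 0.9)
  n_phase <- cfg_get(config, "n_phase", 100)
  fps <- cfg_get(config, "fps", 250)
  rms_mode <- match.arg(cfg_get(config, "rms_mode", "baseline"),
                        c("baseline", "within"))
  pp <- do.call(phase_params, cfg_get(config, "phase", list()))
  out_dir <- cfg_get(config, "out_dir", NULL)

  lookup_score <- function(animal, dpi) {
    hit <- scores$score[scores$animal_id == animal & scores$dpi == dpi]
    if (length(hit) == 0L) NA_real_ else hit[1L]
  }

  process <- function(path) {
    track <- read_pose_track(path, fps = fps)
    ct <- calibrate_track(track, cal_info$calibration,
                          likelihood_min = likelihood_min,
                          image_height_px = cal_info$image_height_px)
    ang <- joint_angle_series(ct)
    seg <- suppressWarnings(detect_phases(ct, pp))
    list(ct = ct, ang = ang, seg = seg)
  }

  metrics <- list()
  exclusions <- list()
  baselines <- list()
  man <- man[order(man$animal_id, man$dpi), , drop = FALSE]

  for (i in seq_len(nrow(man))) {
    animal <- man$animal_id[i]
    dpi <- man$dpi[i]
    score <- lookup_score(animal, dpi)
    if (dpi != baseline_dpi && !is.na(score) && score > max_score) {
      exclusions[[length(exclusions) + 1L]] <- data.frame(
        animal_id = animal, group = man$group[i], dpi = dpi, score = score,
        reason = sprintf("score>%g", max_score))
      next
    }
    res <- tryCatch(process(man$path[i]), error = function(e) e)
    if (inherits(res, "error")) {
      exclusions[[length(exclusions) + 1L]] <- data.frame(
        animal_id = animal, group = man$group[i], dpi = dpi, score = score,
        reason = paste0("error:", conditionMessage(res)))
      next
    }
    if (nrow(res$seg$cycles) == 0L) {
      exclusions[[length(exclusions) + 1L]] <- data.frame(
        animal_id = animal, group = man$group[i], dpi = dpi, score = score,
        reason = "no_cycles")
      next
    }
    rc <- representative_cycle(res$ang, res$seg, n_phase = n_phase)
    if (dpi == baseline_dpi) baselines[[animal]] <- rc
    if (rms_mode == "baseline") {
      ref <- baselines[[animal]]
      knee_rms <- if (is.null(ref)) NA_real_ else rms_difference(rc, ref, "knee")
      ankle_rms <- if (is.null(ref)) NA_real_ else rms_difference(rc, ref, "ankle")
    } else {
      knee_rms <- within_recording_rms(res$ang, res$seg, "knee", n_phase)
      ankle_rms <- within_recording_rms(res$ang, res$seg, "ankle", n_phase)
    }
    metrics[[length(metrics) + 1L]] <- data.frame(
      animal_id = animal, group = man$group[i], dpi = dpi, score = score,
      n_cycles = rc$n_cycles_averaged,
      avg_hip_deg = average_angle(rc, "hip"),
      avg_knee_deg = average_angle(rc, "knee"),
      avg_ankle_deg = average_angle(rc, "ankle"),
      knee_rms_deg = knee_rms, ankle_rms_deg = ankle_rms,
      duty_factor = duty_factor(res$seg))
  }

  metrics <- if (length(metrics)) do.call(rbind, metrics) else
    data.frame(animal_id = character(), group = character(), dpi = numeric())
  exclusions <- if (length(exclusions)) do.call(rbind, exclusions) else
    data.frame(animal_id = character(), group = character(), dpi = numeric(),
               score = numeric(), reason = character())

  # Exploratory per-timepoint two-group contrasts on each metric.
  contrasts <- list()
  groups <- sort(unique(metrics$group))
  if (length(groups) == 2L) {
    for (dpi in sort(unique(metrics$dpi[metrics$dpi != baseline_dpi]))) {
      for (metric in c("avg_knee_deg", "avg_ankle_deg", "knee_rms_deg",
                       "ankle_rms_deg")) {
        d <- metrics[metrics$dpi == dpi, , drop = FALSE]
        a <- d[[metric]][d$group == groups[1L]]
        b <- d[[metric]][d$group == groups[2L]]
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        if (length(a) == 0L || length(b) == 0L) next
        tst <- mann_whitney_u_one_tailed(a, b, "a_less")
        contrasts[[length(contrasts) + 1L]] <- data.frame(
          dpi = dpi, metric = metric, group_a = groups[1L], group_b = groups[2L],
          n_a = length(a), n_b = length(b), U = tst$U,
          p_one_tailed = tst$p_one_tailed, method = tst$method,
          alternative = "a_less", exploratory = TRUE)
      }
    }
  }
  contrasts <- if (length(contrasts)) do.call(rbind, contrasts) else NULL

  write_table_if(metrics, out_dir, "gait_metrics.csv")
  write_table_if(exclusions, out_dir, "gait_exclusions.csv")
  write_table_if(contrasts, out_dir, "gait_contrasts.csv")
  list(metrics = metrics, exclusions = exclusions, contrasts = contrasts)
}

#' Run the histology quantifications over image manifests
#'
#' Composes the eYFP transection, EC/NR white-matter-loss and g-ratio
#' remyelination analyses over whatever manifests the config provides. The
#' eYFP standardized ratio is computed once per run over all successfully
#' loaded images. Per-image failures are recorded and the run continues;
#' `status` is 2 when any item failed, 0 otherwise.
#'
#' @param config list (or YAML path) with optional entries `eyfp_manifest`
#'   (CSV: `image_id`, `intensity`, `wm_mask`, `gm_mask`, `healthy_mask`),
#'   `nr_manifest` (CSV: `image_id`, `rgb`, `wm_mask`), `tem_manifest`
#'   (CSV: `field_id`, `axon_mask`, `myelin_mask`, `pixel_size_um`), plus
#'   `eyfp_factor` (1.5), `nr_ratio_min` (1.2), `g_cutoff` (0.8),
#'   `min_axon_area_px` (10), `percent_denominator` ("all"), `out_dir`.
#' @return List with `eyfp`, `nr`, `tem` (per-field summaries), `axons`
#'   (per-axon records), `standardized_ratio`, `errors`, `status`.
#' @export
run_histology <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  base <- cfg_get(config, ".base_dir", ".")
  out_dir <- cfg_get(config, "out_dir", NULL)
  errors <- list()
  note_error <- function(id, stage, e) {
    errors[[length(errors) + 1L]] <<- data.frame(
      id = id, stage = stage, message = conditionMessage(e))
  }

  eyfp <- NULL
  ratio <- NA_real_
  path <- resolve_path(config$eyfp_manifest, base)
  if (!is.null(path)) {
    man <- read_manifest(path, c("image_id", "intensity", "wm_mask",
                                 "gm_mask", "healthy_mask"))
    loaded <- list()
    for (i in seq_len(nrow(man))) {
      im <- tryCatch(image_with_masks(
        read_intensity_image(man$intensity[i]),
        read_mask_image(man$wm_mask[i]),
        read_mask_image(man$gm_mask[i]),
        read_mask_image(man$healthy_mask[i])),
        error = function(e) e)
      if (inherits(im, "error")) note_error(man$image_id[i], "eyfp", im)
      else loaded[[man$image_id[i]]] <- im
    }
    if (length(loaded) > 0L) {
      ratio <- eyfp_standardized_ratio(unname(loaded))
      factor <- cfg_get(config, "eyfp_factor", 1.5)
      eyfp <- do.call(rbind, lapply(names(loaded), function(id) {
        cbind(image_id = id,
              eyfp_percent_transection(loaded[[id]], ratio, factor))
      }))
    }
  }

  nr <- NULL
  path <- resolve_path(config$nr_manifest, base)
  if (!is.null(path)) {
    man <- read_manifest(path, c("image_id", "rgb", "wm_mask"))
    rows <- list()
    for (i in seq_len(nrow(man))) {
      pct <- tryCatch(nr_percent_wm_loss(
        read_rgb_image(man$rgb[i]), read_mask_image(man$wm_mask[i]),
        cfg_get(config, "nr_ratio_min", 1.2)),
        error = function(e) e)
      if (inherits(pct, "error")) note_error(man$image_id[i], "nr", pct)
      else rows[[length(rows) + 1L]] <- data.frame(image_id = man$image_id[i],
                                                  percent_wm_loss = pct)
    }
    nr <- if (length(rows)) do.call(rbind, rows) else NULL
  }

  tem <- NULL
  axons <- NULL
  path <- resolve_path(config$tem_manifest, base)
  if (!is.null(path)) {
    man <- read_manifest(path, c("field_id", "axon_mask", "myelin_mask",
                                 "pixel_size_um"))
    srows <- list()
    arows <- list()
    for (i in seq_len(nrow(man))) {
      res <- tryCatch({
        am <- read_label_image(man$axon_mask[i])
        mm <- read_label_image(man$myelin_mask[i])
        px <- man$pixel_size_um[i]
        rec <- gratio_records(am, mm, pixel_size_um = px,
                              min_axon_area_px = cfg_get(config, "min_axon_area_px", 10),
                              g_cutoff = cfg_get(config, "g_cutoff", 0.8))
        area <- nrow(am) * ncol(am) * px^2
        list(rec = rec,
             summary = remyelination_summary(
               rec, area, g_cutoff = cfg_get(config, "g_cutoff", 0.8),
               percent_denominator = cfg_get(config, "percent_denominator", "all")))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        note_error(man$field_id[i], "tem", res)
      } else {
        srows[[length(srows) + 1L]] <- cbind(field_id = man$field_id[i],
                                             res$summary)
        if (nrow(res$rec) > 0L)
          arows[[length(arows) + 1L]] <- cbind(field_id = man$field_id[i],
                                               res$rec)
      }
    }
    tem <- if (length(srows)) do.call(rbind, srows) else NULL
    axons <- if (length(arows)) do.call(rbind, arows) else NULL
  }

  errors <- if (length(errors)) do.call(rbind, errors) else
    data.frame(id = character(), stage = character(), message = character())
  write_table_if(eyfp, out_dir, "eyfp_transection.csv")
  write_table_if(nr, out_dir, "nr_wm_loss.csv")
  write_table_if(tem, out_dir, "remyelination_summary.csv")
  write_table_if(axons, out_dir, "axon_records.csv")
  write_table_if(errors, out_dir, "histology_errors.csv")
  list(eyfp = eyfp, nr = nr, tem = tem, axons = axons,
       standardized_ratio = ratio, errors = errors,
       status = if (nrow(errors) > 0L) 2L else 0L)
}

#' Run the qPCR analysis: replicate collapse, geNorm check, ddCq
#'
#' Collapses technical replicates, evaluates geNorm M for the reference
#' genes against the context threshold (1.0 for tissue, 0.5 for cell
#' culture) with a warning naming any failing gene, and computes relative
#' expression by the delta-delta-Cq method.
#'
#' @param config list (or YAML path) with entries `cq_csv` (long-format Cq
#'   table), `targets`, `references`, `control_group`, and optionally
#'   `context` ("tissue" or "culture"), `out_dir`.
#' @return List with `collapsed`, `genorm`, `ddcq`, `group_summary`,
#'   `genorm_threshold`.
#' @export
run_qpcr <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  base <- cfg_get(config, ".base_dir", ".")
  tab <- cq_table(utils::read.csv(resolve_path(config$cq_csv, base),
                                  stringsAsFactors = FALSE))
  context <- match.arg(cfg_get(config, "context", "tissue"),
                       c("tissue", "culture"))
  threshold <- if (context == "tissue") 1.0 else 0.5
  collapsed <- collapse_triplicates(tab)
  gn <- genorm_m(collapsed, config$references)
  failing <- gn$gene[gn$m >= threshold]
  if (length(failing) > 0L)
    warning(sprintf("reference gene(s) %s fail the geNorm threshold (M >= %.1f, %s)",
                    paste(failing, collapse = ", "), threshold, context))
  dd <- relative_expression_ddcq(collapsed, config$targets, config$references,
                                 config$control_group)
  gs <- ddcq_group_summary(dd)
  out_dir <- cfg_get(config, "out_dir", NULL)
  write_table_if(collapsed, out_dir, "cq_collapsed.csv")
  write_table_if(gn, out_dir, "genorm.csv")
  write_table_if(as.data.frame(dd), out_dir, "ddcq.csv")
  write_table_if(gs, out_dir, "ddcq_group_summary.csv")
  list(collapsed = collapsed, genorm = gn, ddcq = dd, group_summary = gs,
       genorm_threshold = threshold)
}

#' Run the clinical-score analysis
#'
#' Cumulative clinical scores over the configured DPI window (16-44 by
#' default) per animal, compared between two groups with the exact
#' one-tailed Mann-Whitney U test.
#'
#' @param config list (or YAML path) with entries `scores_csv`, and
#'   optionally `start_dpi` (16), `end_dpi` (44), `group_a`, `group_b`
#'   (defaults: the two groups in sorted order), `alternative` ("a_less":
#'   group a has lower cumulative scores), `out_dir`.
#' @return List with `cumulative` (per-animal data frame) and `test`
#'   (an `mwu_test`).
#' @export
run_clinical <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  base <- cfg_get(config, ".base_dir", ".")
  scores <- utils::read.csv(resolve_path(config$scores_csv, base),
                            stringsAsFactors = FALSE)
  cum <- cumulative_clinical_score(scores,
                                   start_dpi = cfg_get(config, "start_dpi", 16),
                                   end_dpi = cfg_get(config, "end_dpi", 44))
  groups <- sort(unique(cum$group))
  group_a <- cfg_get(config, "group_a", groups[1L])
  group_b <- cfg_get(config, "group_b", groups[2L])
  tst <- mann_whitney_u_one_tailed(
    cum$cumulative_score[cum$group == group_a],
    cum$cumulative_score[cum$group == group_b],
    alternative = cfg_get(config, "alternative", "a_less"))
  out_dir <- cfg_get(config, "out_dir", NULL)
  write_table_if(cum, out_dir, "cumulative_scores.csv")
  write_table_if(data.frame(group_a = group_a, group_b = group_b, U = tst$U,
                            p_one_tailed = tst$p_one_tailed,
                            alternative = tst$alternative, method = tst$method),
                 out_dir, "clinical_test.csv")
  list(cumulative = cum, test = tst)
}

#' Write a complete synthetic gait study to disk
#'
#' Generates pose CSVs, a calibration YAML, a clinical-score table and a
#' manifest in the layout [run_gait_study()] consumes. Per-group,
#' per-timepoint knee offsets emulate an EAE deficit (default: -15 degrees
#' from DPI >= 16, partially recovering to -5 in the second group after
#' treatment onset).
#'
#' @param dir output directory (created if needed).
#' @param n_per_group animals per group (default 3).
#' @param groups two group labels.
#' @param dpis timepoints to record (default c(-2, 16, 23)).
#' @param knee_offset_fun `function(group, dpi)` returning the injected knee
#'   offset in degrees.
#' @param score_fun `function(animal_id, group, dpi)` returning the clinical
#'   score for disease-phase days.
#' @param duration_s recording length per timepoint (default 3).
#' @param cycle_noise_sd_deg,tracking_noise_sd_cm generator noise levels.
#' @param seed integer seed; per-recording seeds are derived from it.
#' @return List with `config` (ready for [run_gait_study()]), `manifest`,
#'   and `truth` (per-recording generator ground truth).
#' @export
simulate_gait_study <- function(dir, n_per_group = 3,
                                groups = c("EAE_Veh", "EAE_IRX"),
                                dpis = c(-2, 16, 23),
                                knee_offset_fun = function(group, dpi) {
                                  if (dpi < 0) 0
                                  else if (group == groups[2L] && dpi > 16) -5
                                  else -15
                                },
                                score_fun = function(animal_id, group, dpi) {
                                  if (dpi < 0) 0 else 2
                                },
                                duration_s = 3, cycle_noise_sd_deg = 1.5,
                                tracking_noise_sd_cm = 0.005, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list()
  scores <- list()
  truth <- list()
  idx <- 0L
  for (g in groups) {
    for (a in seq_len(n_per_group)) {
      animal <- sprintf("%s_%02d", g, a)
      for (dpi in dpis) {
        idx <- idx + 1L
        rec <- gen_gait_recording(gait_sim_params(
          duration_s = duration_s,
          knee_offset_deg = knee_offset_fun(g, dpi),
          cycle_noise_sd_deg = cycle_noise_sd_deg,
          tracking_noise_sd_cm = tracking_noise_sd_cm,
          seed = seed + 7919L * idx))
        fname <- sprintf("%s_dpi%+03d.csv", animal, dpi)
        write_gait_recording(rec$track, file.path(dir, fname))
        if (idx == 1L)
          write_calibration_file(file.path(dir, "calibration.yaml"),
                                 rec$marker_px,
                                 image_height_px = rec$image_height_px)
        manifest[[idx]] <- data.frame(animal_id = animal, group = g, dpi = dpi,
                                      path = fname)
        scores[[idx]] <- data.frame(animal_id = animal, group = g, dpi = dpi,
                                    score = score_fun(animal, g, dpi))
        truth[[paste(animal, dpi, sep = "@")]] <- rec$truth
      }
    }
  }
  man <- do.call(rbind, manifest)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, scores), file.path(dir, "scores.csv"),
                   row.names = FALSE)
  config <- list(pose_manifest = file.path(dir, "manifest.csv"),
                 calibration_file = file.path(dir, "calibration.yaml"),
                 clinical_scores = file.path(dir, "scores.csv"))
  list(config = config, manifest = man, truth = truth)
}

#' Write a synthetic eYFP image set to disk
#'
#' Generates `n_images` synthetic sections via [gen_eyfp_image()] and writes
#' intensity TIFFs, mask PNGs and the manifest [run_histology()] consumes.
#'
#' @param dir output directory.
#' @param n_images number of sections (default 4).
#' @param true_fractions painted WM fraction per image (recycled).
#' @param noise_sd generator noise SD.
#' @param seed integer seed.
#' @return List with `config` (for [run_histology()]) and `truth`
#'   (per-image true percents).
#' @export
simulate_eyfp_study <- function(dir, n_images = 4,
                                true_fractions = c(0.1, 0.05, 0.15, 0.08),
                                noise_sd = 0, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  true_fractions <- rep_len(true_fractions, n_images)
  rows <- list()
  truth <- numeric(n_images)
  for (i in seq_len(n_images)) {
    sim <- gen_eyfp_image(target_fraction = true_fractions[i],
                          noise_sd = noise_sd, seed = seed + 31L * i)
    id <- sprintf("img%02d", i)
    paths <- c(intensity = file.path(dir, paste0(id, "_int.tif")),
               wm_mask = file.path(dir, paste0(id, "_wm.png")),
               gm_mask = file.path(dir, paste0(id, "_gm.png")),
               healthy_mask = file.path(dir, paste0(id, "_hwm.png")))
    write_intensity_image(sim$image$intensity, paths["intensity"])
    write_mask_image(sim$image$wm_mask, paths["wm_mask"])
    write_mask_image(sim$image$gm_mask, paths["gm_mask"])
    write_mask_image(sim$image$healthy_wm_mask, paths["healthy_mask"])
    rows[[i]] <- data.frame(image_id = id, intensity = paths[["intensity"]],
                            wm_mask = paths[["wm_mask"]],
                            gm_mask = paths[["gm_mask"]],
                            healthy_mask = paths[["healthy_mask"]])
    truth[i] <- sim$true_percent
  }
  man_path <- file.path(dir, "eyfp_manifest.csv")
  utils::write.csv(do.call(rbind, rows), man_path, row.names = FALSE)
  list(config = list(eyfp_manifest = man_path), truth = truth)
}
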