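resolved_params <- function(config) {
  do.call(preset_genotype,
          c(list(name = config$preset), config$params_overrides))
}

resolved_optics <- function(config) do.call(optics_model, config$optics)

run_log <- function(path, ...) {
  msg <- sprintf(...)
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg)
  message(line)
  cat(line, "\n", file = path, append = TRUE)
}

#' Run the full simulation-to-measurement pipeline
#'
#' One reproducible end-to-end run: for each phagosome a scene is simulated
#' (per-phagosome sub-seed derived from the master seed), rendered, and
#' written (TIFF stack + sidecar + ground-truth JSON); the four measurement
#' time courses (luminal RInt, surface RInt, acidification index, nuclear
#' diameter and ratio) are computed from the rendered images and written as
#' one CSV per phagosome; fusion-onset and lifespan events are extracted
#' into `events.csv`; optionally a two-reporter colocalization summary is
#' computed (`coloc.json`); time-course figures are drawn to
#' `plots.pdf`; and the resolved configuration and a log with versions and
#' seeds are saved alongside.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the per-phagosome time courses, the
#'   events data frame, and the output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  if (file.exists(log_path)) unlink(log_path)
  run_log(log_path, "phagolapse %s | preset=%s seed=%d n=%d",
          as.character(utils::packageVersion("phagolapse")),
          config$preset, as.integer(config$seed), config$n_phagosomes)
  params <- resolved_params(config)
  optics <- resolved_optics(config)
  channels <- default_channels(config$brightness)
  if (isTRUE(config$coloc)) {
    fl <- fluorophore_presets(config$brightness)
    channels <- c(channels,
                  list(channel_spec("GFP::LGG", fl$GFP, "vesicle", "B")))
  }
  write_config(config, file.path(out_dir, "config.yaml"))

  all_tc <- list()
  events <- list()
  coloc_frames <- list()
  for (i in seq_len(config$n_phagosomes)) {
    id <- sprintf("phagosome_%02d", i)
    scene_seed <- derive_seed(config$seed, "scene", i)
    scene <- simulate_scene(params, scene_seed)
    stack <- render_stack(scene, channels, optics,
                          seed = derive_seed(config$seed, "render", i))
    stack_path <- file.path(out_dir, paste0(id, ".tif"))
    write_stack(stack, stack_path)
    write_scene(scene, file.path(out_dir, paste0(id, "_truth.json")))
    ann <- annotation_from_scene(scene)
    tc <- measure_timecourses(stack, ann,
                              box_side_lumen = config$box_side_lumen,
                              box_side_aidx = config$box_side_aidx)
    utils::write.csv(tc, file.path(out_dir, paste0(id, "_timecourses.csv")),
                     row.names = FALSE)
    all_tc[[id]] <- tc
    lum_tc <- time_course(tc$time_min, tc$rint_lumen, "luminal_rint")
    events[[paste0(id, "_fusion")]] <-
      fusion_onset(lum_tc, config$fusion_threshold,
                   config$fusion_persistence)
    events[[paste0(id, "_lifespan")]] <-
      phagosome_lifespan(scene_diameter_timecourse(scene))
    events[[paste0(id, "_engulfment")]] <-
      event_result("engulfment",
                   time = engulfment_duration(scene$pseudopod),
                   censor_horizon = scene$times[length(scene$times)])
    if (isTRUE(config$coloc))
      coloc_frames[[id]] <- coloc_summary(stack, scene, config)
    run_log(log_path, "%s: scene seed %d, %d frames", id, scene_seed,
            length(scene$frames))
  }
  ev <- events_to_data_frame(events)
  ev$phagosome_id <- sub("_(fusion|lifespan|engulfment)$", "",
                         ev$phagosome_id)
  utils::write.csv(ev, file.path(out_dir, "events.csv"), row.names = FALSE)
  if (length(coloc_frames))
    jsonlite::write_json(coloc_frames, file.path(out_dir, "coloc.json"),
                         auto_unbox = TRUE, digits = NA)
  plot_timecourses(all_tc, file.path(out_dir, "plots.pdf"))
  run_log(log_path, "done: %d phagosomes, %d events",
          config$n_phagosomes, nrow(ev))
  invisible(list(timecourses = all_tc, events = ev, out_dir = out_dir))
}

#' Measure all time courses of one annotated stack
#'
#' Computes luminal and surface relative intensity on the vesicle channel,
#' the acidification index from the nuclear GFP/mCherry pair, and the
#' nuclear FWHM diameter with its T0-normalized ratio, and returns them as
#' one tidy per-frame table (the per-phagosome CSV of a pipeline run).
#'
#' @param stack An [image_stack()] with the [default_channels()] layout
#'   (vesicle mCherry, nuclear GFP, nuclear mCherry).
#' @param annotation An [roi_annotation()].
#' @param box_side_lumen,box_side_aidx ROI box sides, px.
#' @return Data frame with columns `time_min`, `rint_lumen`,
#'   `rint_surface`, `a_idx`, `diameter_um`, `diameter_ratio`.
#' @export
measure_timecourses <- function(stack, annotation, box_side_lumen = 4,
                                box_side_aidx = 3) {
  lum <- luminal_relative_intensity(stack, "mCherry::LGG", annotation,
                                    box_side = box_side_lumen)
  surf <- surface_relative_intensity(stack, "mCherry::LGG", annotation)
  aidx <- acidification_index(stack, "HIS::GFP", "HIS::mCherry", annotation,
                              box_side = box_side_aidx)
  dia <- vapply(seq_len(dim(stack$data)[1]), function(f)
    measure_disc_diameter(stack, f, "HIS::mCherry",
                          annotation$center_track[f, ]), numeric(1))
  data.frame(time_min = lum$time_min,
             rint_lumen = lum$value,
             rint_surface = surf$value,
             a_idx = aidx$value,
             diameter_um = dia,
             diameter_ratio = dia / dia[1])
}

coloc_summary <- function(stack, scene, config) {
  n_frames <- dim(stack$data)[1]
  det_args <- config$detect
  per_frame <- lapply(seq_len(n_frames), function(f) {
    masks <- phagosome_region_masks(scene, f)
    mask <- masks$surface | masks$cytosol
    pa <- do.call(detect_puncta,
                  c(list(stack_frame(stack, f, "mCherry::LGG"),
                         mask = mask), det_args))
    pb <- do.call(detect_puncta,
                  c(list(stack_frame(stack, f, "GFP::LGG"),
                         mask = mask), det_args))
    m <- match_puncta(pa, pb, radius = config$match_radius)
    list(frame = f, n_A = nrow(pa), n_B = nrow(pb), n_both = m$n_both,
         n_A_only = m$n_A_only, n_B_only = m$n_B_only)
  })
  nA_only <- sum(vapply(per_frame, `[[`, numeric(1), "n_A_only"))
  nB_only <- sum(vapply(per_frame, `[[`, numeric(1), "n_B_only"))
  nboth <- sum(vapply(per_frame, `[[`, numeric(1), "n_both"))
  total <- nA_only + nB_only + nboth
  summary <- if (total > 0) {
    cd <- class_distribution(
      colocalization_result(nA_only, nB_only, nboth,
                            formula_tag = "pooled_frames"))
    list(pct_A_only = cd[["A_only"]], pct_B_only = cd[["B_only"]],
         pct_both = cd[["both"]],
         pct_A_also_B = percent_double_positive(nboth, nA_only + nboth),
         formula = c(class = "three-way class distribution",
                     double_positive = "100 * n_both / N_ref"))
  } else list()
  list(per_frame = per_frame, summary = summary)
}

#' Plot measurement time courses to a PDF
#'
#' One panel per measurement kind (luminal RInt, surface RInt,
#' acidification index, nuclear diameter ratio), one line per phagosome,
#' styled after the published time-course figures.  Plots are artifacts
#' only; no value is ever read back from them.
#'
#' @param timecourse_list Named list of [measure_timecourses()] tables.
#' @param path Output PDF path.
#' @export
plot_timecourses <- function(timecourse_list, path) {
  long <- do.call(rbind, lapply(names(timecourse_list), function(id) {
    tc <- timecourse_list[[id]]
    do.call(rbind, lapply(c("rint_lumen", "rint_surface", "a_idx",
                            "diameter_ratio"), function(k)
      data.frame(phagosome = id, time_min = tc$time_min, kind = k,
                 value = tc[[k]])))
  }))
  labs <- c(rint_lumen = "Luminal relative intensity",
            rint_surface = "Surface relative intensity",
            a_idx = "Acidification index",
            diameter_ratio = "Nuclear diameter ratio")
  long$kind <- factor(labs[long$kind], levels = labs)
  p <- ggplot2::ggplot(long,
         ggplot2::aes(x = .data$time_min, y = .data$value,
                      color = .data$phagosome)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(x = "Time after sealing (min)", y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "bottom")
  grDevices::pdf(path, width = 8, height = 6)
  print(p)
  grDevices::dev.off()
  invisible(path)
}

#' Simulate a cohort of genotypes and summarize per-genotype medians
#'
#' Runs the pipeline once per preset (in noise-free mode by default, so the
#' summary is deterministic for a fixed seed) and collects one row per
#' genotype with the median fusion onset, the censored-fusion fraction, and
#' the median lifespan.
#'
#' @param presets Character vector of [preset_genotype()] names.
#' @param n_phagosomes Phagosomes per genotype.
#' @param seed Master seed.
#' @param out_dir Parent output directory (one subdirectory per preset).
#' @param optics Named list of [optics_model()] arguments; default
#'   noise-free.
#' @return Data frame, one row per genotype.
#' @export
run_cohort <- function(presets, n_phagosomes = 3, seed = 1, out_dir,
                       optics = list(shot_noise = FALSE,
                                     read_noise_sd = 0)) {
  rows <- lapply(seq_along(presets), function(i) {
    cfg <- run_config(preset = presets[i], n_phagosomes = n_phagosomes,
                      seed = seed + i, optics = optics)
    res <- run_pipeline(cfg, file.path(out_dir, presets[i]))
    ev <- res$events
    fus <- ev[ev$kind == "fusion_onset", ]
    life <- ev[ev$kind == "lifespan", ]
    data.frame(genotype = presets[i],
               n = n_phagosomes,
               median_fusion_onset_min =
                 stats::median(fus$time_min[!fus$censored]),
               fusion_censored_fraction = mean(fus$censored),
               median_lifespan_min =
                 stats::median(life$time_min[!life$censored]),
               lifespan_censored_fraction = mean(life$censored))
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(out_dir, "cohort_summary.csv"),
                   row.names = FALSE)
  out
}
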