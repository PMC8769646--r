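sidecar_path <- function(path) paste0(path, ".json")

#' Write / read an image stack as multi-page TIFF with a JSON sidecar
#'
#' Stacks are stored as multi-page TIFF in TCYX page order (channel fastest)
#' next to a JSON sidecar (`<path>.json`) carrying the physical metadata:
#' channel names, pixel size (um/px), frame interval (min), array
#' dimensions, storage scale, and package version.  Integer-valued stacks up
#' to 65535 are stored as 16-bit integers and round-trip exactly; other data
#' are stored as 32-bit float (values preserved to single precision, noted
#' in the sidecar `dtype`).
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `write_stack()`: the path, invisibly.  `read_stack()`: an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  vals <- stack$data
  is_int <- all(vals == round(vals)) && max(vals) <= 65535
  if (is_int) {
    scale <- 65535
    bits <- 16L
    dtype <- "uint16"
  } else {
    scale <- max(vals, 1e-12)
    bits <- 32L
    dtype <- "float32"
  }
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (t in seq_len(d[1])) for (c in seq_len(d[2])) {
    pages[[k]] <- matrix(vals[t, c, , ], d[3], d[4]) / scale
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits,
                  compression = "deflate")
  meta <- list(axes = "TCYX", n_frames = d[1], n_channels = d[2],
               height = d[3], width = d[4],
               channel_names = stack$channel_names,
               pixel_size_um = stack$pixel_size,
               frame_interval_min = stack$frame_interval,
               scale = scale, dtype = dtype,
               package = "phagolapse",
               version = as.character(utils::packageVersion("phagolapse")))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("metadata sidecar ", sp, " not found; stacks written by ",
         "write_stack() carry pixel size and frame interval there")
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (field in c("pixel_size_um", "frame_interval_min")) {
    if (is.null(meta[[field]]) || !is.finite(meta[[field]]))
      stop("sidecar is missing '", field, "'; re-write the stack with ",
           "write_stack() or add the field to ", sp)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- c(meta$n_frames, meta$n_channels, meta$height, meta$width)
  if (length(pages) != d[1] * d[2])
    stop("page count does not match sidecar dimensions")
  data <- array(0, dim = d)
  k <- 1L
  for (t in seq_len(d[1])) for (c in seq_len(d[2])) {
    page <- pages[[k]] * meta$scale
    if (identical(meta$dtype, "uint16")) page <- round(page)
    data[t, c, , ] <- page
    k <- k + 1L
  }
  image_stack(data, meta$channel_names, meta$pixel_size_um,
              meta$frame_interval_min)
}

#' Write / read a scene's ground truth as a JSON sidecar
#'
#' One JSON object per frame: time, phagosome geometry, lumen pH, label
#' pools, nucleus state, and the puncta table, plus the scene-level metadata
#' and parameters, so every rendered stack travels with its latent truth.
#'
#' @param scene A [simulate_scene()] result.
#' @param path JSON path.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "phagosome_scene"))
  params <- unclass(scene$params)
  obj <- list(
    pixel_size = scene$pixel_size,
    frame_interval = scene$frame_interval,
    seal_frame_index = scene$seal_frame_index,
    pseudopod = as.list(scene$pseudopod),
    seed = scene$seed,
    genotype = attr(scene$params, "genotype"),
    params = params,
    frames = lapply(scene$frames, function(fr) {
      list(time = fr$time, phagosome_center = fr$phagosome_center,
           phagosome_radius = fr$phagosome_radius, lumen_pH = fr$lumen_pH,
           rim_label = as.list(fr$rim_label),
           lumen_label = as.list(fr$lumen_label),
           born_label = as.list(fr$born_label),
           nucleus_radius = fr$nucleus_radius,
           nucleus_label = fr$nucleus_label,
           puncta = fr$puncta)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  pargs <- obj$params
  pargs <- pargs[setdiff(names(pargs), "")]
  params <- do.call(kinetic_params, pargs)
  if (!is.null(obj$genotype)) attr(params, "genotype") <- obj$genotype
  empty_puncta <- data.frame(id = integer(), y = double(), x = double(),
                             angle = double(), state = character(),
                             label_A = double(), label_B = double(),
                             stringsAsFactors = FALSE)
  frames <- lapply(seq_len(nrow(obj$frames)), function(i) {
    fr <- obj$frames[i, ]
    p <- fr$puncta[[1]]
    if (is.null(p) || !length(p) || (is.data.frame(p) && !nrow(p)))
      p <- empty_puncta
    list(time = fr$time,
         phagosome_center = unlist(fr$phagosome_center),
         phagosome_radius = fr$phagosome_radius,
         lumen_pH = fr$lumen_pH,
         rim_label = unlist(fr$rim_label),
         lumen_label = unlist(fr$lumen_label),
         born_label = unlist(fr$born_label),
         nucleus_radius = fr$nucleus_radius,
         nucleus_label = fr$nucleus_label,
         puncta = as.data.frame(p))
  })
  times <- vapply(frames, `[[`, numeric(1), "time")
  structure(list(frames = frames, times = times,
                 pixel_size = obj$pixel_size,
                 frame_interval = obj$frame_interval,
                 seal_frame_index = obj$seal_frame_index,
                 pseudopod = unlist(obj$pseudopod),
                 params = params, seed = obj$seed),
            class = "phagosome_scene")
}

#' Assemble a reproducible run configuration
#'
#' A fully serializable description of one end-to-end run: genotype preset
#' (or explicit kinetic parameter overrides), optics, channel brightness,
#' seeds, measurement parameters, and the number of phagosomes.  A run
#' re-executed from its saved configuration and seed is bit-identical in
#' noise-free mode.
#'
#' @param preset Genotype preset name (see [preset_genotype()]).
#' @param params_overrides Named list of [kinetic_params()] overrides.
#' @param optics Named list of [optics_model()] arguments.
#' @param brightness Channel brightness, photons/label unit/frame.
#' @param n_phagosomes Number of phagosomes to simulate.
#' @param seed Master seed; per-phagosome and renderer sub-streams are
#'   derived from it.
#' @param fusion_threshold,fusion_persistence [fusion_onset()] parameters.
#' @param box_side_lumen,box_side_aidx ROI box sides, px.
#' @param detect Named list of [detect_puncta()] arguments.
#' @param match_radius Colocalization matching radius, px.
#' @param coloc Run the two-reporter colocalization stage?  (Requires
#'   `puncta_channel_probs` with mass on more than one class to be
#'   informative.)
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(preset = "wild_type", params_overrides = list(),
                       optics = list(), brightness = 500,
                       n_phagosomes = 3, seed = 1,
                       fusion_threshold = 1.5, fusion_persistence = 2,
                       box_side_lumen = 4, box_side_aidx = 3,
                       detect = list(), match_radius = 3,
                       coloc = FALSE) {
  structure(list(preset = preset, params_overrides = params_overrides,
                 optics = optics, brightness = brightness,
                 n_phagosomes = n_phagosomes, seed = seed,
                 fusion_threshold = fusion_threshold,
                 fusion_persistence = fusion_persistence,
                 box_side_lumen = box_side_lumen,
                 box_side_aidx = box_side_aidx,
                 detect = detect, match_radius = match_radius,
                 coloc = coloc),
            class = "run_config")
}

#' Save / load a run configuration (YAML or JSON by extension)
#'
#' @param config A [run_config()].
#' @param path File path ending in `.yaml`, `.yml`, or `.json`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- unclass(config)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(obj, path)
  else if (grepl("\\.json$", path))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  else stop("config path must end in .yaml, .yml, or .json")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else if (grepl("\\.json$", path))
           jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("config path must end in .yaml, .yml, or .json")
  obj$params_overrides <- as.list(obj$params_overrides)
  obj$optics <- as.list(obj$optics)
  obj$detect <- as.list(obj$detect)
  do.call(run_config, obj)
}
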