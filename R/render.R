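#' Optical model for the renderer
#'
#' @param psf_sigma Isotropic Gaussian point-spread-function sigma, pixels.
#' @param background Camera background offset, intensity units per pixel.
#' @param shot_noise Apply Poisson shot noise to expected photon counts?
#' @param read_noise_sd Gaussian read noise standard deviation (0 = off).
#' @param quantize Round final intensities to integer camera units?  Defaults
#'   to `TRUE` whenever any noise source is on (real detectors digitize), and
#'   `FALSE` in the fully noise-free mode so analytic expectations hold to
#'   machine precision.
#' @return Object of class `optics_model`.
#' @export
optics_model <- function(psf_sigma = 1.5, background = 20,
                         shot_noise = TRUE, read_noise_sd = 3,
                         quantize = shot_noise || read_noise_sd > 0) {
  stopifnot(psf_sigma > 0, background >= 0, read_noise_sd >= 0)
  structure(list(psf_sigma = psf_sigma, background = background,
                 shot_noise = isTRUE(shot_noise),
                 read_noise_sd = read_noise_sd,
                 quantize = isTRUE(quantize)),
            class = "optics_model")
}

#' Noise-free optics
#'
#' Convenience wrapper for [optics_model()] with all noise sources off; the
#' render is then a pure function of the scene (bit-reproducible) and pixel
#' sums match analytic expectations.
#' @param psf_sigma,background See [optics_model()].
#' @export
optics_noise_free <- function(psf_sigma = 1.5, background = 20) {
  optics_model(psf_sigma = psf_sigma, background = background,
               shot_noise = FALSE, read_noise_sd = 0, quantize = FALSE)
}

#' Define an imaging channel
#'
#' A channel couples a fluorophore to a labeled structure: `target =
#' "vesicle"` images the LGG-reporter pools (cytosolic/docked puncta, rim,
#' lumen) for reporter `"A"` or `"B"`; `target = "nucleus"` images the
#' engulfed-corpse nuclear reporter disc.
#'
#' @param name Channel name, e.g. `"mCherry::LGG-1"`.
#' @param fluorophore A [fluorophore()] object.
#' @param target `"vesicle"` or `"nucleus"`.
#' @param reporter Vesicle reporter pool, `"A"` or `"B"` (ignored for the
#'   nucleus target).
#' @export
channel_spec <- function(name, fluorophore, target = c("vesicle", "nucleus"),
                         reporter = c("A", "B")) {
  target <- match.arg(target)
  reporter <- match.arg(reporter)
  stopifnot(inherits(fluorophore, "fluorophore"))
  structure(list(name = name, fluorophore = fluorophore, target = target,
                 reporter = reporter),
            class = "channel_spec")
}

#' Default three-channel configuration
#'
#' Channel 1 images the vesicle reporter in mCherry (luminal-entry and
#' surface-recruitment assays), channels 2 and 3 image the nuclear
#' histone reporter in GFP and mCherry (acidification index and nuclear
#' diameter assays).
#' @param brightness Photons per label unit per frame for all channels.
#' @export
default_channels <- function(brightness = 500) {
  fl <- fluorophore_presets(brightness)
  list(channel_spec("mCherry::LGG", fl$mCherry, "vesicle", "A"),
       channel_spec("HIS::GFP", fl$GFP, "nucleus"),
       channel_spec("HIS::mCherry", fl$mCherry, "nucleus"))
}

cytosol_pH <- 7.2

# Normalized Gaussian PSF kernel (odd size, sums to exactly 1).
psf_kernel <- function(sigma) {
  half <- max(3L, as.integer(ceiling(4 * sigma)))
  g <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Binary disc / annulus masks on the pixel-center grid.
disc_mask <- function(n, center, radius) {
  dy <- (seq_len(n) - center[1])^2
  dx <- (seq_len(n) - center[2])^2
  outer(dy, dx, "+") <= radius^2
}

annulus_mask <- function(n, center, radius, half_width = 1) {
  d <- sqrt(outer((seq_len(n) - center[1])^2,
                  (seq_len(n) - center[2])^2, "+"))
  abs(d - radius) <= half_width
}

# Deposit point flux at a continuous position by bilinear spreading onto the
# 4 neighbouring pixel centers (flux-conserving, keeps sub-pixel location).
deposit_point <- function(img, y, x, flux) {
  n <- nrow(img)
  y <- min(max(y, 1), n); x <- min(max(x, 1), ncol(img))
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  y1 <- min(y0 + 1, n); x1 <- min(x0 + 1, ncol(img))
  img[y0, x0] <- img[y0, x0] + flux * (1 - fy) * (1 - fx)
  img[y1, x0] <- img[y1, x0] + flux * fy * (1 - fx)
  img[y0, x1] <- img[y0, x1] + flux * (1 - fy) * fx
  img[y1, x1] <- img[y1, x1] + flux * fy * fx
  img
}

# Spread `total` flux uniformly over a mask; degenerate masks collapse the
# flux onto the center point so label is never lost.
spread_over_mask <- function(img, mask, center, total) {
  if (total <= 0) return(img)
  npix <- sum(mask)
  if (npix == 0L) return(deposit_point(img, center[1], center[2], total))
  img[mask] <- img[mask] + total / npix
  img
}

# Expected photon image for one frame of one channel (before PSF and noise).
latent_photons <- function(frame, chan, n) {
  img <- matrix(0, n, n)
  fl <- chan$fluorophore
  em_cyt <- emission_fraction(fl$pKa, cytosol_pH, fl$floor)
  em_lum <- emission_fraction(fl$pKa, frame$lumen_pH, fl$floor)
  if (chan$target == "nucleus") {
    mask <- disc_mask(n, frame$phagosome_center, frame$nucleus_radius)
    img <- spread_over_mask(img, mask, frame$phagosome_center,
                            frame$nucleus_label * fl$brightness * em_lum)
    return(img)
  }
  rep <- chan$reporter
  # luminal pool: uniform over the phagosome disc, at luminal pH
  mask_l <- disc_mask(n, frame$phagosome_center, frame$phagosome_radius)
  img <- spread_over_mask(img, mask_l, frame$phagosome_center,
                          frame$lumen_label[[rep]] * fl$brightness * em_lum)
  # rim pool: annulus of fixed width, cytosol-facing leaflet at cytosolic pH
  mask_r <- annulus_mask(n, frame$phagosome_center, frame$phagosome_radius)
  img <- spread_over_mask(img, mask_r, frame$phagosome_center,
                          frame$rim_label[[rep]] * fl$brightness * em_cyt)
  # puncta (cytosolic or docked), at cytosolic pH
  pts <- frame$puncta
  if (nrow(pts)) {
    lab <- pts[[paste0("label_", rep)]]
    keep <- lab > 0
    for (i in which(keep))
      img <- deposit_point(img, pts$y[i], pts$x[i],
                           lab[i] * fl$brightness * em_cyt)
  }
  img
}

#' Render a multi-channel time-lapse stack from a scene
#'
#' Every label unit contributes `brightness * emission_fraction(pKa, local
#' pH)` expected photons: the luminal pool is spread uniformly over the
#' phagosome disc at luminal pH, the rim pool over a 2-px-wide annulus at
#' cytosolic pH (7.2), puncta are deposited at their sub-pixel positions, and
#' the nuclear reporter fills the nucleus disc at luminal pH.  The expected
#' image is convolved with an isotropic Gaussian PSF (flux-conserving
#' circular-boundary convolution), then corrupted by Poisson shot noise,
#' Gaussian read noise, and the camera background offset, and finally
#' clamped at zero (and digitized when any noise is on).  With
#' [optics_noise_free()] the output is the exact expectation and is
#' bit-reproducible.
#'
#' @param scene A [simulate_scene()] result.
#' @param channels List of [channel_spec()]s (default [default_channels()]).
#' @param optics An [optics_model()].
#' @param seed Integer seed for the noise stream (ignored in noise-free
#'   mode).
#' @return Object of class `image_stack`: `data` is a T x C x Y x X array of
#'   non-negative intensities, with `channel_names`, `pixel_size` (um/px) and
#'   `frame_interval` (min) metadata.
#' @examples
#' sc <- simulate_scene(preset_genotype("wild_type"), seed = 1)
#' st <- render_stack(sc, optics = optics_noise_free(), seed = 1)
#' dim(st$data)
#' @export
render_stack <- function(scene, channels = default_channels(),
                         optics = optics_model(), seed = 1) {
  stopifnot(inherits(scene, "phagosome_scene"),
            inherits(optics, "optics_model"))
  if (!length(channels) || !all(vapply(channels, inherits, logical(1),
                                       "channel_spec")))
    stop("channels must be a non-empty list of channel_spec objects")
  n <- scene$params$image_size
  n_frames <- length(scene$frames)
  n_chan <- length(channels)
  kern <- psf_kernel(optics$psf_sigma)
  data <- array(0, dim = c(n_frames, n_chan, n, n))
  noisy <- optics$shot_noise || optics$read_noise_sd > 0
  render_one <- function() {
    for (f in seq_len(n_frames)) {
      for (c in seq_len(n_chan)) {
        expected <- latent_photons(scene$frames[[f]], channels[[c]], n)
        expected <- EBImage::filter2(expected, kern, boundary = "circular")
        expected[expected < 0] <- 0  # FFT ringing guard
        img <- expected
        if (optics$shot_noise)
          img <- matrix(stats::rpois(length(img), img), n, n)
        if (optics$read_noise_sd > 0)
          img <- img + matrix(stats::rnorm(length(img),
                                           sd = optics$read_noise_sd), n, n)
        img <- img + optics$background
        img[img < 0] <- 0
        if (optics$quantize) img <- round(img)
        data[f, c, , ] <<- img
      }
    }
  }
  if (noisy) with_seed(derive_seed(seed, "render"), render_one())
  else render_one()
  structure(list(data = data,
                 channel_names = vapply(channels, `[[`, character(1), "name"),
                 pixel_size = scene$pixel_size,
                 frame_interval = scene$frame_interval),
            class = "image_stack")
}

#' Construct an image stack from an array
#'
#' @param data T x C x Y x X numeric array of non-negative intensities.
#' @param channel_names Character vector, one per channel.
#' @param pixel_size Micrometres per pixel.
#' @param frame_interval Minutes between frames.
#' @export
image_stack <- function(data, channel_names, pixel_size, frame_interval) {
  stopifnot(length(dim(data)) == 4L)
  if (any(data < 0)) stop("image intensities must be non-negative")
  if (length(channel_names) != dim(data)[2])
    stop("channel_names length must match the channel dimension")
  if (!is.finite(pixel_size) || pixel_size <= 0) stop("invalid pixel_size")
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stop("invalid frame_interval")
  structure(list(data = data, channel_names = channel_names,
                 pixel_size = pixel_size, frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %d frames x %d channels x %dx%d px (%g um/px, %g min)\n  channels: %s\n",
    d[1], d[2], d[3], d[4], x$pixel_size, x$frame_interval,
    paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

# Frame/channel slice as a plain Y x X matrix.
stack_frame <- function(stack, frame, channel) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  if (frame < 1 || frame > d[1]) stop("frame index out of range")
  ch <- resolve_channel(stack, channel)
  matrix(stack$data[frame, ch, , ], d[3], d[4])
}

resolve_channel <- function(stack, channel) {
  if (is.character(channel)) {
    ch <- match(channel, stack$channel_names)
    if (is.na(ch)) stop("unknown channel name: ", channel)
    return(ch)
  }
  if (channel < 1 || channel > dim(stack$data)[2])
    stop("channel index out of range")
  as.integer(channel)
}
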