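#' Kinetic and geometric parameters of a simulated phagosome
#'
#' Bundles every rate and switch governing one phagosome's maturation
#' scenario.  Times are minutes from phagosome sealing (t = 0), rates are
#' per minute, label amounts are arbitrary "label units" (only relative
#' quantities are meaningful), and geometry is in micrometres converted to
#' pixels through `pixel_size`.
#'
#' Vesicle kinetics: LGG-labeled puncta are born in the cytosol as a
#' homogeneous Poisson process (`puncta_birth_rate`), dock onto the phagosome
#' rim at per-punctum rate `k_recruit`, and fuse at per-docked-punctum rate
#' `k_fuse`.  On fusion with `membrane_topology = "double"` half of
#' `label_per_vesicle` joins the luminal pool and half the rim pool (both
#' leaflets of a double-membrane autophagosome carry the reporter); with
#' `"single"` all label stays on the rim, so the lumen never gains signal --
#' the discriminating prediction between autophagosome and LC3-associated
#' phagocytosis (LAP) vesicle fusion.
#'
#' Lumen pH relaxes exponentially from `pH_initial` to `pH_final` with time
#' constant `pH_tau`.  The phagosome radius is constant until `shrink_onset`,
#' then halves every `shrink_halftime` minutes; the engulfed-corpse nucleus
#' disc halves every `nucleus_decay_halftime` minutes from t = 0.  Use `Inf`
#' for either halftime/onset to switch degradation off.
#'
#' @param puncta_birth_rate Cytosolic punctum births, events/min.
#' @param k_recruit Docking rate per cytosolic punctum, /min.
#' @param k_fuse Fusion rate per docked punctum, /min.
#' @param membrane_topology `"double"` or `"single"`.
#' @param label_per_vesicle Label units carried by one vesicle (split 50/50
#'   between outer and inner membrane when double).
#' @param lumen_baseline_label,rim_baseline_label Diffuse label units present
#'   in the lumen / on the rim at sealing (soluble reporter plus out-of-focus
#'   light); these anchor the T0 normalization of the relative-intensity
#'   measures.
#' @param nucleus_label Label units of the engulfed-corpse nuclear reporter
#'   (histone::GFP::mCherry), per channel targeting the nucleus.
#' @param pH_initial,pH_final,pH_tau Lumen pH trajectory (`pH_final <=
#'   pH_initial`), tau in min.
#' @param shrink_onset,shrink_halftime Phagosome shrinkage, min.
#' @param engulf_duration Pseudopod budding-to-sealing span, min.
#' @param nucleus_decay_halftime Nuclear disc diameter halving time, min.
#' @param observation_span Recording length, min (>= 60 by default).
#' @param frame_interval Frame spacing, min (recordings every 2 min).
#' @param phagosome_radius_um,nucleus_radius_um Initial radii, micrometres.
#' @param pixel_size Micrometres per pixel.
#' @param image_size Square field side, pixels.
#' @param phagosome_center (y, x) pixel position of the phagosome; default
#'   slightly off-center so the farthest image corner stays label-free for
#'   the background ROI.
#' @param puncta_channel_probs Probabilities that a newborn punctum carries
#'   reporter A only, reporter B only, or both (sums to 1).  The default
#'   `c(0, 0, 1)` models a single dual-labeled population; set to the
#'   measured LGG-1/LGG-2 class frequencies to simulate two-reporter
#'   colocalization experiments.
#' @return Object of class `kinetic_params`.
#' @seealso [preset_genotype()], [simulate_scene()]
#' @export
kinetic_params <- function(puncta_birth_rate = 0.5,
                           k_recruit = 0.25,
                           k_fuse = 0.12,
                           membrane_topology = c("double", "single"),
                           label_per_vesicle = 20,
                           lumen_baseline_label = 40,
                           rim_baseline_label = 60,
                           nucleus_label = 150,
                           pH_initial = 7.2,
                           pH_final = 5.0,
                           pH_tau = 50,
                           shrink_onset = 30,
                           shrink_halftime = 18,
                           engulf_duration = 6,
                           nucleus_decay_halftime = 60,
                           observation_span = 60,
                           frame_interval = 2,
                           phagosome_radius_um = 1.5,
                           nucleus_radius_um = 0.8,
                           pixel_size = 0.1,
                           image_size = 128,
                           phagosome_center = NULL,
                           puncta_channel_probs = c(0, 0, 1)) {
  membrane_topology <- match.arg(membrane_topology)
  rates <- c(puncta_birth_rate = puncta_birth_rate, k_recruit = k_recruit,
             k_fuse = k_fuse)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rates must be finite and >= 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (pH_final > pH_initial) stop("pH_final must be <= pH_initial")
  if (observation_span < frame_interval)
    stop("observation_span must cover at least one frame interval")
  if (label_per_vesicle < 0 || lumen_baseline_label < 0 ||
      rim_baseline_label < 0 || nucleus_label < 0)
    stop("label amounts must be >= 0")
  if (length(puncta_channel_probs) != 3L || any(puncta_channel_probs < 0) ||
      abs(sum(puncta_channel_probs) - 1) > 1e-8)
    stop("puncta_channel_probs must be 3 non-negative values summing to 1")
  if (is.null(phagosome_center))
    phagosome_center <- c(round(image_size * 0.41), round(image_size * 0.41))
  p <- list(puncta_birth_rate = puncta_birth_rate, k_recruit = k_recruit,
            k_fuse = k_fuse, membrane_topology = membrane_topology,
            label_per_vesicle = label_per_vesicle,
            lumen_baseline_label = lumen_baseline_label,
            rim_baseline_label = rim_baseline_label,
            nucleus_label = nucleus_label,
            pH_initial = pH_initial, pH_final = pH_final, pH_tau = pH_tau,
            shrink_onset = shrink_onset, shrink_halftime = shrink_halftime,
            engulf_duration = engulf_duration,
            nucleus_decay_halftime = nucleus_decay_halftime,
            observation_span = observation_span,
            frame_interval = frame_interval,
            phagosome_radius_um = phagosome_radius_um,
            nucleus_radius_um = nucleus_radius_um,
            pixel_size = pixel_size, image_size = image_size,
            phagosome_center = phagosome_center,
            puncta_channel_probs = puncta_channel_probs)
  structure(p, class = "kinetic_params")
}

#' Genotype presets for the simulator
#'
#' Maps the classical mutant phenotypes of the apoptotic-cell clearance
#' pathway onto kinetic parameters:
#' \describe{
#'   \item{wild_type}{Defaults, calibrated so the median fusion onset falls
#'     in the 12--20 min band and the phagosome half-diameter time in the
#'     40--60 min band observed in vivo.}
#'   \item{ced1_like}{Recruitment-defective engulfment-receptor pathway
#'     (`k_recruit = 0`); degradation and acidification off.}
#'   \item{rab7_like}{Fusion-defective (`k_fuse = 0`): puncta still dock on
#'     the rim but the lumen never receives label; observation extended to
#'     90 min to exercise "no fusion" censoring; degradation/acidification
#'     off (lysosome delivery is also RAB-7 dependent).}
#'   \item{atg7_like}{Autophagosome biogenesis blocked
#'     (`puncta_birth_rate` ~ 0); moderate acidification and nuclear
#'     degradation defects.}
#'   \item{cup5_like}{Lysosome biogenesis defective: pH stays at its initial
#'     value and nuclear degradation is nearly absent (diameter ~ 89% of the
#'     initial value at 60 min).}
#'   \item{single_membrane_control}{Wild-type kinetics with
#'     single-membrane (LAP-vesicle-like) topology: rim labeling without any
#'     luminal entry.  Shrinkage is off so the luminal readout isolates
#'     membrane topology from geometric concentration of the diffuse
#'     luminal baseline.}
#' }
#'
#' @param name Preset name (see above).
#' @param ... Overrides passed on to [kinetic_params()].
#' @return A `kinetic_params` object.
#' @examples
#' preset_genotype("rab7_like")$k_fuse   # 0
#' @export
preset_genotype <- function(name = c("wild_type", "ced1_like", "rab7_like",
                                     "atg7_like", "cup5_like",
                                     "single_membrane_control"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    wild_type = list(),
    ced1_like = list(k_recruit = 0, shrink_onset = Inf,
                     nucleus_decay_halftime = Inf, pH_final = 7.2),
    rab7_like = list(k_fuse = 0, observation_span = 90, shrink_onset = Inf,
                     nucleus_decay_halftime = Inf, pH_final = 7.2),
    atg7_like = list(puncta_birth_rate = 0.002, pH_final = 5.7,
                     nucleus_decay_halftime = 100, shrink_onset = 40,
                     shrink_halftime = 30),
    cup5_like = list(pH_final = 7.2, nucleus_decay_halftime = 360,
                     shrink_onset = Inf),
    single_membrane_control = list(membrane_topology = "single",
                                   shrink_onset = Inf))
  over <- list(...)
  args[names(over)] <- over
  params <- do.call(kinetic_params, args)
  attr(params, "genotype") <- name
  params
}

# Evaluate and restore the RNG state around a seeded computation so that
# simulation calls do not perturb the caller's random stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation: one master seed spawns independent
# streams per phagosome / per renderer, all below 2^31.
derive_seed <- function(seed, stream, index = 0L) {
  offset <- switch(stream, scene = 1L, render = 2L,
                   stop("unknown seed stream: ", stream))
  as.integer((as.double(seed) * 48271 + offset * 1e6 + index) %%
               .Machine$integer.max)
}

phagosome_radius_at <- function(params, t) {
  r0 <- params$phagosome_radius_um / params$pixel_size
  if (!is.finite(params$shrink_onset) || t < params$shrink_onset) return(r0)
  r0 * 0.5^((t - params$shrink_onset) / params$shrink_halftime)
}

nucleus_radius_at <- function(params, t) {
  r0 <- params$nucleus_radius_um / params$pixel_size
  if (!is.finite(params$nucleus_decay_halftime)) return(r0)
  r0 * 0.5^(t / params$nucleus_decay_halftime)
}

lumen_pH_at <- function(params, t) {
  params$pH_final +
    (params$pH_initial - params$pH_final) * exp(-t / params$pH_tau)
}

#' Simulate the latent maturation process of one phagosome
#'
#' Runs the per-frame stochastic vesicle kinetics (birth, docking, fusion;
#' per-interval Bernoulli probabilities `1 - exp(-k * dt)`, events resolved
#' in birth, dock, fuse order within a frame) together with the
#' deterministic pH, shrinkage, and nuclear-decay trajectories, and returns
#' the full ground truth for every frame.  Identical `(params, seed)` pairs
#' yield identical scenes, and the caller's RNG state is left untouched.
#'
#' Label bookkeeping is exact: at every frame the label ever born (baselines
#' plus one `label_per_vesicle` per punctum, per carried reporter) equals the
#' label held by cytosolic + docked puncta plus the rim and lumen pools.
#' A fused punctum hands its label to the pools on its fusion frame, remains
#' listed (state `"fused"`, zero label) for that frame, and is dropped from
#' the next frame on.
#'
#' Newborn puncta are placed uniformly in an annular cytosol region outside
#' an exclusion zone around the phagosome (rim + measurement donut + PSF
#' support), so that un-recruited vesicles never overlap the surface or
#' background ROIs; docked puncta sit on the rim at a random angle and follow
#' the rim as the phagosome shrinks.
#'
#' @param params A [kinetic_params()] object.
#' @param seed Integer seed for this scene's random stream.
#' @return Object of class `phagosome_scene`: list with `frames` (one
#'   ground-truth record per frame: time, phagosome center/radius, lumen pH,
#'   per-reporter rim/lumen/born label, nucleus radius and label, and a
#'   puncta data frame with positions, states, and per-reporter label), plus
#'   `times`, `pixel_size`, `frame_interval`, `seal_frame_index` (frame of
#'   t = 0), `pseudopod` bud/seal times, `params`, and `seed`.
#' @examples
#' sc <- simulate_scene(preset_genotype("wild_type"), seed = 1)
#' sc$frames[[31]]$lumen_label   # luminal label at 60 min, per reporter
#' @export
simulate_scene <- function(params, seed) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$frame_interval <= 0) stop("frame_interval must be > 0")
  with_seed(seed, {
    dt <- params$frame_interval
    times <- seq(0, params$observation_span, by = dt)
    n_frames <- length(times)
    p_dock <- 1 - exp(-params$k_recruit * dt)
    p_fuse <- 1 - exp(-params$k_fuse * dt)
    ctr <- params$phagosome_center
    r0 <- params$phagosome_radius_um / params$pixel_size
    # births excluded from rim/donut/PSF support; capped inside the field
    r_excl <- r0 + 1 + 5 + 6
    edge_margin <- min(ctr[1] - 1, ctr[2] - 1,
                       params$image_size - ctr[1],
                       params$image_size - ctr[2]) - 8
    r_max <- min(edge_margin, r_excl + 30)
    if (r_max <= r_excl)
      stop("image too small for the cytosol annulus; increase image_size")

    # punctum ledger: columns y, x, angle, state, label_A, label_B
    pool <- data.frame(id = integer(), y = double(), x = double(),
                       angle = double(), state = character(),
                       label_A = double(), label_B = double(),
                       stringsAsFactors = FALSE)
    next_id <- 1L
    rim <- c(A = params$rim_baseline_label, B = params$rim_baseline_label)
    lumen <- c(A = params$lumen_baseline_label,
               B = params$lumen_baseline_label)
    born <- rim + lumen
    frames <- vector("list", n_frames)

    for (f in seq_len(n_frames)) {
      t <- times[f]
      r_t <- phagosome_radius_at(params, t)
      # drop puncta that fused on the previous frame
      if (nrow(pool)) pool <- pool[pool$state != "fused", , drop = FALSE]
      if (f > 1L) {
        # births
        n_new <- stats::rpois(1L, params$puncta_birth_rate * dt)
        if (n_new > 0L) {
          u <- stats::runif(n_new)
          rad <- sqrt(u * (r_max^2 - r_excl^2) + r_excl^2)
          ang <- stats::runif(n_new, 0, 2 * pi)
          cls <- sample.int(3L, n_new, replace = TRUE,
                            prob = params$puncta_channel_probs)
          newp <- data.frame(
            id = seq.int(next_id, length.out = n_new),
            y = ctr[1] + rad * sin(ang), x = ctr[2] + rad * cos(ang),
            angle = ang, state = "cytosolic",
            label_A = params$label_per_vesicle * as.numeric(cls != 2L),
            label_B = params$label_per_vesicle * as.numeric(cls != 1L),
            stringsAsFactors = FALSE)
          next_id <- next_id + n_new
          born <- born + c(A = sum(newp$label_A), B = sum(newp$label_B))
          pool <- rbind(pool, newp)
        }
        # docking: cytosolic -> docked, punctum jumps to the rim
        cyt <- which(pool$state == "cytosolic")
        if (length(cyt)) {
          dock <- cyt[stats::runif(length(cyt)) < p_dock]
          if (length(dock)) pool$state[dock] <- "docked"
        }
        # fusion: docked -> fused, label transfers to rim/lumen pools
        dk <- which(pool$state == "docked")
        if (length(dk)) {
          fuse <- dk[stats::runif(length(dk)) < p_fuse]
          if (length(fuse)) {
            lab <- c(A = sum(pool$label_A[fuse]),
                     B = sum(pool$label_B[fuse]))
            if (params$membrane_topology == "double") {
              lumen <- lumen + lab / 2
              rim <- rim + lab / 2
            } else {
              rim <- rim + lab
            }
            pool$state[fuse] <- "fused"
            pool$label_A[fuse] <- 0
            pool$label_B[fuse] <- 0
          }
        }
      }
      # docked (and just-fused) puncta ride on the shrinking rim
      on_rim <- pool$state %in% c("docked", "fused")
      if (any(on_rim)) {
        pool$y[on_rim] <- ctr[1] + r_t * sin(pool$angle[on_rim])
        pool$x[on_rim] <- ctr[2] + r_t * cos(pool$angle[on_rim])
      }
      frames[[f]] <- list(
        time = t,
        phagosome_center = ctr,
        phagosome_radius = r_t,
        lumen_pH = lumen_pH_at(params, t),
        rim_label = rim,
        lumen_label = lumen,
        born_label = born,
        nucleus_radius = nucleus_radius_at(params, t),
        nucleus_label = params$nucleus_label,
        puncta = pool)
    }
    structure(list(frames = frames, times = times,
                   pixel_size = params$pixel_size,
                   frame_interval = params$frame_interval,
                   seal_frame_index = 1L,
                   pseudopod = c(bud_time = -params$engulf_duration,
                                 seal_time = 0),
                   params = params, seed = as.integer(seed)),
              class = "phagosome_scene")
  })
}

#' @export
print.phagosome_scene <- function(x, ...) {
  g <- attr(x$params, "genotype")
  cat(sprintf(
    "<phagosome_scene> %d frames @ %g min%s, pixel %g um, seed %d\n",
    length(x$frames), x$frame_interval,
    if (is.null(g)) "" else paste0(", preset ", g), x$pixel_size, x$seed))
  invisible(x)
}

#' Ground-truth scalar time courses of a scene
#'
#' Convenience extractors used both by the tests (as oracles for the
#' image-based measurements) and by the event statistics that operate on the
#' latent state directly.
#'
#' @param scene A [simulate_scene()] result.
#' @param reporter `"A"` or `"B"`.
#' @return `scene_lumen_label()` / `scene_rim_label()`: numeric vector per
#'   frame; `scene_diameter_timecourse()` / `scene_nucleus_diameter_timecourse()`:
#'   a [time_course()] of diameters in micrometres.
#' @export
scene_lumen_label <- function(scene, reporter = "A") {
  vapply(scene$frames, function(fr) fr$lumen_label[[reporter]], numeric(1))
}

#' @rdname scene_lumen_label
#' @export
scene_rim_label <- function(scene, reporter = "A") {
  vapply(scene$frames, function(fr) fr$rim_label[[reporter]], numeric(1))
}

#' @rdname scene_lumen_label
#' @export
scene_diameter_timecourse <- function(scene) {
  d <- vapply(scene$frames, function(fr) 2 * fr$phagosome_radius, numeric(1))
  time_course(scene$times, d * scene$pixel_size, kind = "diameter_um")
}

#' @rdname scene_lumen_label
#' @export
scene_nucleus_diameter_timecourse <- function(scene) {
  d <- vapply(scene$frames, function(fr) 2 * fr$nucleus_radius, numeric(1))
  time_course(scene$times, d * scene$pixel_size, kind = "diameter_um")
}
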