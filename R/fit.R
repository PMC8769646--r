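#' Expected luminal label accumulation under the fusion kinetics
#'
#' Exact expectation of the luminal label pool (above its baseline) for the
#' birth -> dock -> fuse chain under the simulator's per-frame discretization:
#' each frame interval `dt` adds `birth_rate * dt` expected cytosolic puncta,
#' cytosolic puncta dock with probability `1 - exp(-k_recruit * dt)`, docked
#' puncta fuse with probability `1 - exp(-k_fuse * dt)` (events resolved
#' birth, dock, fuse within a frame), and each fusion of a double-membrane
#' vesicle delivers `label_per_vesicle / 2` to the lumen.  By linearity of
#' expectation the mean pool sizes follow the recursion implemented here,
#' which is the model curve used when recovering `k_fuse` from measured
#' accumulation curves.
#'
#' @param t Frame times from sealing, min (uniformly spaced, starting at 0).
#' @param k_fuse,k_recruit Rates, /min.
#' @param birth_rate Punctum births, /min.
#' @param label_per_vesicle Label units per vesicle.
#' @param topology `"double"` (half the label reaches the lumen) or
#'   `"single"` (none does).
#' @return Expected luminal label above baseline at each `t`.
#' @export
expected_lumen_label <- function(t, k_fuse, k_recruit, birth_rate,
                                 label_per_vesicle = 1,
                                 topology = "double") {
  n <- length(t)
  if (topology == "single" || k_fuse <= 0 || k_recruit <= 0 ||
      birth_rate <= 0)
    return(rep(0, n))
  dt <- if (n > 1) t[2] - t[1] else 0
  p_dock <- 1 - exp(-k_recruit * dt)
  p_fuse <- 1 - exp(-k_fuse * dt)
  births <- birth_rate * dt
  cyt <- 0; docked <- 0; lumen <- numeric(n)
  for (f in seq_len(n)[-1]) {
    pool <- cyt + births
    newly_docked <- pool * p_dock
    cyt <- pool - newly_docked
    at_rim <- docked + newly_docked
    fused <- at_rim * p_fuse
    docked <- at_rim - fused
    lumen[f] <- lumen[f - 1] + fused * label_per_vesicle / 2
  }
  lumen
}

#' Recover the fusion rate from luminal accumulation curves
#'
#' Inverse fit of `k_fuse` from measured luminal relative-intensity time
#' courses: each RInt curve is converted back to luminal label units via the
#' known luminal baseline (`lumen = (RInt - 1) * baseline`, valid while the
#' phagosome geometry is constant), curves are averaged across replicates,
#' and `k_fuse` is estimated by least squares against
#' [expected_lumen_label()] with the remaining kinetic parameters held at
#' their known values.
#'
#' @param timecourses List of luminal-RInt [time_course()]s from replicate
#'   phagosomes simulated (or imaged) under the same conditions.
#' @param params The [kinetic_params()] the replicates were generated with
#'   (supplies `k_recruit`, `puncta_birth_rate`, `label_per_vesicle`, and
#'   the luminal baseline).
#' @param interval Search interval for `k_fuse`, /min.
#' @return List with `k_fuse` (the estimate) and `sse`.
#' @export
fit_fusion_rate <- function(timecourses, params,
                            interval = c(1e-4, 2)) {
  stopifnot(length(timecourses) >= 1L)
  times <- timecourses[[1]]$time_min
  vals <- vapply(timecourses, function(tc) {
    stopifnot(identical(tc$time_min, times))
    tc$value
  }, numeric(length(times)))
  mean_lumen <- (rowMeans(as.matrix(vals)) - 1) * params$lumen_baseline_label
  sse <- function(kf) {
    pred <- expected_lumen_label(times, kf, params$k_recruit,
                                 params$puncta_birth_rate,
                                 params$label_per_vesicle,
                                 params$membrane_topology)
    sum((pred - mean_lumen)^2)
  }
  opt <- stats::optimize(sse, interval = interval)
  list(k_fuse = opt$minimum, sse = opt$objective)
}
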