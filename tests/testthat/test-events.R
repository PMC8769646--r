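test_that("engulfment duration is the bud-to-seal interval", {
  expect_equal(engulfment_duration(c(bud_time = 0, seal_time = 6)), 6)
  expect_equal(engulfment_duration(c(bud_time = 10, seal_time = 10)), 0)
  expect_error(engulfment_duration(c(bud_time = 5, seal_time = 2)),
               "precedes")
  # recovered exactly from simulated scenes
  sc <- simulate_scene(preset_genotype("wild_type", engulf_duration = 4),
                       seed = 1)
  expect_equal(engulfment_duration(sc$pseudopod), 4)
})

test_that("lifespan is the first half-diameter crossing, else censored", {
  tc <- time_course(seq(0, 8, 2), c(4.0, 3.8, 3.0, 2.2, 1.9),
                    kind = "diameter_um")
  ev <- phagosome_lifespan(tc)
  expect_equal(ev$time, 8)
  expect_false(ev$censored)
  flat <- time_course(seq(0, 90, 2), rep(3, 46), kind = "diameter_um")
  ev2 <- phagosome_lifespan(flat)
  expect_true(ev2$censored)
  expect_equal(ev2$censor_horizon, 90)
  expect_true(is.na(ev2$time))
  expect_error(phagosome_lifespan(flat[0, ]), "empty|positive")
})

test_that("fusion onset needs persistent threshold crossing", {
  tc <- time_course(seq(0, 8, 2), c(1.0, 1.1, 1.2, 1.6, 2.0),
                    kind = "luminal_rint")
  expect_equal(fusion_onset(tc)$time, 6)
  # a single-frame blip does not trigger with persistence 2
  blip <- time_course(seq(0, 8, 2), c(1.0, 1.8, 1.2, 1.3, 1.4),
                      kind = "luminal_rint")
  expect_true(fusion_onset(blip)$censored)
  expect_equal(fusion_onset(blip, persistence = 1)$time, 2)
})

test_that("raising the fusion threshold never yields an earlier onset", {
  set.seed(33)
  for (i in 1:20) {
    vals <- cumprod(c(1, exp(rnorm(25, 0.04, 0.08))))
    tc <- time_course(seq(0, 50, 2), vals, kind = "luminal_rint")
    onsets <- vapply(c(1.2, 1.5, 2, 3), function(th) {
      ev <- fusion_onset(tc, threshold = th)
      if (ev$censored) Inf else ev$time
    }, numeric(1))
    expect_false(is.unsorted(onsets))
    # censoring consistency
    ev <- fusion_onset(tc, threshold = 1.5)
    if (!ev$censored) expect_lte(ev$time, ev$censor_horizon)
  }
})

test_that("event histograms count fractions like the brute-force oracle", {
  ev_at <- function(t) event_result("lifespan", time = t,
                                    censor_horizon = 90)
  h <- summarize_event_distribution(replicate(10, ev_at(50), simplify = FALSE),
                                    c(40, 60))
  expect_equal(h$fractions, 1)
  mixed <- list(ev_at(30), ev_at(50), ev_at(70),
                event_result("lifespan", censored = TRUE,
                             censor_horizon = 90))
  h2 <- summarize_event_distribution(mixed, c(0, 60, Inf))
  expect_equal(h2$fractions, c(0.5, 0.25))
  expect_equal(h2$censored_fraction, 0.25)
  expect_equal(sum(h2$fractions) + h2$censored_fraction, 1)
  # random cohorts match direct counting
  set.seed(44)
  for (i in 1:10) {
    times <- sample(5:95, 30, replace = TRUE)
    cens <- runif(30) < 0.2
    evs <- lapply(seq_along(times), function(j)
      if (cens[j]) event_result("fusion_onset", censored = TRUE,
                                censor_horizon = 100)
      else event_result("fusion_onset", time = times[j],
                        censor_horizon = 100))
    edges <- c(0, 30, 60, 100)
    h3 <- summarize_event_distribution(evs, edges)
    direct <- c(sum(!cens & times < 30), sum(!cens & times >= 30 & times < 60),
                sum(!cens & times >= 60 & times < 100)) / 30
    expect_equal(h3$fractions, direct)
    expect_equal(h3$censored_fraction, mean(cens))
  }
  expect_error(summarize_event_distribution(list(), c(0, 1)), "no events")
})

test_that("event results enforce censoring consistency", {
  expect_error(event_result("lifespan", time = 10, censored = TRUE),
               "censored")
  expect_error(event_result("lifespan", time = -2), "finite")
  df <- events_to_data_frame(list(a = event_result("lifespan", time = 48,
                                                   censor_horizon = 60)))
  expect_equal(df$time_min, 48)
  expect_equal(df$phagosome_id, "a")
})

test_that("median measured onset decreases with the fusion rate", {
  median_onset <- function(k_fuse, n = 12) {
    onsets <- vapply(seq_len(n), function(s) {
      sc <- simulate_scene(
        preset_genotype("wild_type", k_fuse = k_fuse, shrink_onset = Inf),
        seed = 1000 + s)
      st <- render_stack(sc, default_channels()[1], optics_noise_free(),
                         seed = s)
      ev <- fusion_onset(luminal_relative_intensity(
        st, 1, annotation_from_scene(sc)))
      if (ev$censored) sc$times[length(sc$times)] + 2 else ev$time
    }, numeric(1))
    stats::median(onsets)
  }
  m <- vapply(c(0.02, 0.05, 0.1), median_onset, numeric(1))
  expect_true(all(diff(m) < 0))
})

test_that("fusion rate is recovered from luminal accumulation curves", {
  # degradation and acidification off so box density tracks the label pool
  params <- preset_genotype("wild_type", k_fuse = 0.08, shrink_onset = Inf,
                            pH_final = 7.2)
  tcs <- lapply(1:15, function(s) {
    sc <- simulate_scene(params, seed = 2000 + s)
    st <- render_stack(sc, default_channels()[1], optics_noise_free(),
                       seed = s)
    luminal_relative_intensity(st, 1, annotation_from_scene(sc))
  })
  fit <- fit_fusion_rate(tcs, params)
  expect_lt(abs(fit$k_fuse - 0.08) / 0.08, 0.3)
})

test_that("expected luminal accumulation matches a Monte Carlo average", {
  params <- preset_genotype("wild_type", shrink_onset = Inf)
  sims <- vapply(1:200, function(s)
    scene_lumen_label(simulate_scene(params, seed = s)) -
      params$lumen_baseline_label,
    numeric(31))
  mc <- rowMeans(sims)
  model <- expected_lumen_label(seq(0, 60, 2), params$k_fuse,
                                params$k_recruit,
                                params$puncta_birth_rate,
                                params$label_per_vesicle)
  # agreement within Monte Carlo error at the late frames
  expect_lt(abs(mc[31] - model[31]) / model[31], 0.1)
  expect_lt(mean(abs(mc[10:31] - model[10:31]) / model[31]), 0.05)
})
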