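test_that("box intensity matches arithmetic and the loop oracle", {
  st <- constant_stack(5, n = 16)
  expect_equal(box_intensity(st, 1, 1, c(8, 8), 4), 80)  # 16 pixels x 5
  expect_equal(box_intensity(constant_stack(0, n = 16), 1, 1, c(8, 8), 4), 0)
  set.seed(101)
  for (i in 1:25) {
    img <- matrix(as.double(sample(0:50, 24 * 24, replace = TRUE)), 24, 24)
    st <- image_stack(array(img, c(1, 1, 24, 24)), "a", 0.1, 2)
    ctr <- c(sample(6:18, 1), sample(6:18, 1))
    side <- sample(c(3, 4, 5), 1)
    expect_identical(box_intensity(st, 1, 1, ctr, side),
                     oracle_box_sum(img, ctr, side))
  }
  expect_error(box_intensity(constant_stack(1, n = 8), 1, 1, c(1, 1), 4),
               "outside")
})

test_that("polygon rasterization equals the per-pixel crossing oracle", {
  set.seed(202)
  for (i in 1:20) {
    img <- matrix(as.double(sample(0:30, 20 * 20, replace = TRUE)), 20, 20)
    # random star-shaped polygon around a random center
    ctr <- runif(2, 7, 13)
    nv <- sample(5:9, 1)
    ang <- sort(runif(nv, 0, 2 * pi))
    rad <- runif(nv, 2, 6)
    poly <- cbind(ctr[1] + rad * sin(ang), ctr[2] + rad * cos(ang))
    mask <- pixels_in_polygon(poly, 20, 20)
    oracle <- oracle_polygon_sum(img, poly)
    expect_identical(sum(img[mask]), oracle$sum)
    expect_identical(sum(mask), oracle$area)
  }
})

test_that("luminal relative intensity reproduces the printed formula", {
  # Int_center 200 -> 500, Int_bg 50 constant: RInt = 450 / 150 = 3
  n <- 32
  arr <- array(0, c(2, 1, n, n))
  arr[1, 1, , ] <- 50 / 16
  arr[2, 1, , ] <- 50 / 16
  arr[1, 1, 15:18, 15:18] <- 200 / 16
  arr[2, 1, 15:18, 15:18] <- 500 / 16
  st <- image_stack(arr, "a", 0.1, 2)
  ann <- simple_annotation(2, center = c(16, 16))
  tc <- luminal_relative_intensity(st, 1, ann)
  expect_equal(tc$value, c(1, 3), tolerance = 1e-12)
  expect_equal(attr(tc, "anchor_value"), 150, tolerance = 1e-12)
})

test_that("relative measures are constant on constant stacks", {
  st <- constant_stack(12, n = 32, n_frames = 4)
  ann <- simple_annotation(4)
  # constant-plus-disc so the T0 anchors are positive
  st$data[, 1, 10:22, 10:22] <- 30
  lum <- luminal_relative_intensity(st, 1, ann)
  surf <- surface_relative_intensity(st, 1, ann)
  expect_equal(lum$value, rep(1, 4), tolerance = 1e-12)
  expect_equal(surf$value, rep(1, 4), tolerance = 1e-12)
})

test_that("donut unit intensity follows the two-polygon formula", {
  # Int_outer 1000 over area 100, Int_inner 400 over area 60 -> UI 15
  ui <- (1000 - 400) / (100 - 60)
  expect_equal(ui, 15)
  # same computed through the rasterized path on a synthetic image
  n <- 40
  img <- matrix(10, n, n)
  st <- image_stack(array(img, c(1, 1, n, n)), "a", 0.1, 2)
  ann <- simple_annotation(1, center = c(20, 20))
  m_out <- pixels_in_polygon(ann$outer_polygon[[1]], n, n)
  m_in <- pixels_in_polygon(ann$inner_polygon[[1]], n, n)
  ui_phag <- (sum(img[m_out]) - sum(img[m_in])) / (sum(m_out) - sum(m_in))
  expect_equal(ui_phag, 10)
})

test_that("luminal RInt is anchored to ground truth in a rendered scene", {
  # constant geometry and flat pH isolate label accumulation
  sc <- tiny_scene("wild_type", seed = 2, shrink_onset = Inf,
                   pH_final = 7.2)
  st <- render_noise_free(sc)
  ann <- annotation_from_scene(sc)
  lum <- luminal_relative_intensity(st, "mCherry::LGG", ann)
  truth <- scene_lumen_label(sc)
  base <- sc$params$lumen_baseline_label
  # matches the ground-truth pool ratio and accumulates monotonically
  expect_true(all(abs(lum$value - truth / base) < 0.05 * truth / base + 0.02))
  first_gain <- which(diff(truth) > 0)[1]
  expect_true(all(diff(lum$value)[-seq_len(first_gain - 1)] > -1e-9))
  expect_gt(lum$value[length(lum$value)], 3)
  # with wild-type acidification the curve additionally carries the slight
  # mCherry quenching, bounded by the emission-fraction change
  sc_ph <- tiny_scene("wild_type", seed = 2, shrink_onset = Inf)
  lum_ph <- luminal_relative_intensity(render_noise_free(sc_ph),
                                       "mCherry::LGG",
                                       annotation_from_scene(sc_ph))
  em_lo <- emission_fraction(4.5, min(vapply(sc_ph$frames, `[[`,
                                             numeric(1), "lumen_pH"))) /
    emission_fraction(4.5, 7.2)
  expect_true(all(lum_ph$value >= em_lo * truth / base - 0.05))
  expect_true(all(lum_ph$value <= truth / base + 0.05))
})

test_that("surface RInt tracks rim recruitment and stays flat without it", {
  sc_wt <- tiny_scene("wild_type", seed = 3, shrink_onset = Inf)
  st <- render_noise_free(sc_wt)
  ann <- annotation_from_scene(sc_wt)
  surf <- surface_relative_intensity(st, "mCherry::LGG", ann)
  # rises with rim accumulation (rim pool + docked puncta all sit in donut)
  expect_gt(surf$value[length(surf$value)], 2)
  sc_ced <- tiny_scene("ced1_like", seed = 3)
  st_c <- render_noise_free(sc_ced)
  surf_c <- surface_relative_intensity(st_c, "mCherry::LGG",
                                       annotation_from_scene(sc_ced))
  expect_true(all(surf_c$value >= 0.9 & surf_c$value <= 1.1))
})

test_that("acidification index follows the ratio formula and edge cases", {
  # GFP halves while mCherry is constant -> index 0.5
  n <- 16
  arr <- array(0, c(2, 2, n, n))
  arr[1, 1, , ] <- 8; arr[2, 1, , ] <- 4   # GFP
  arr[1, 2, , ] <- 6; arr[2, 2, , ] <- 6   # mCherry
  st <- image_stack(arr, c("g", "m"), 0.1, 2)
  ann <- simple_annotation(2, center = c(8, 8), bg = c(1, 1, 3, 3))
  tc <- acidification_index(st, "g", "m", ann)
  expect_equal(tc$value, c(1, 0.5), tolerance = 1e-12)
  # zero mCherry -> error
  arr[2, 2, , ] <- 0
  st0 <- image_stack(arr, c("g", "m"), 0.1, 2)
  expect_error(acidification_index(st0, "g", "m", ann), "mCherry")
})

test_that("flat-pH scenes keep the acidification index at one", {
  sc <- tiny_scene("cup5_like", seed = 4)
  st <- render_noise_free(sc)
  ann <- annotation_from_scene(sc)
  a <- acidification_index(st, "HIS::GFP", "HIS::mCherry", ann)
  # residual deviation (~5e-4) comes from slow nuclear shrinkage changing
  # the signal-to-offset mix in the unsubtracted ratio
  expect_equal(a$value, rep(1, nrow(a)), tolerance = 5e-3)
})

test_that("offset and gain invariances hold where the formulas promise them", {
  sc <- tiny_scene("wild_type", seed = 5, observation_span = 20)
  st <- render_noise_free(sc)
  ann <- annotation_from_scene(sc)
  shifted <- st; shifted$data <- st$data + 37
  scaled <- st; scaled$data <- st$data * 2.5
  lum <- luminal_relative_intensity(st, 1, ann)
  expect_equal(luminal_relative_intensity(shifted, 1, ann)$value,
               lum$value, tolerance = 1e-9)
  expect_equal(luminal_relative_intensity(scaled, 1, ann)$value,
               lum$value, tolerance = 1e-9)
  surf <- surface_relative_intensity(st, 1, ann)
  expect_equal(surface_relative_intensity(shifted, 1, ann)$value,
               surf$value, tolerance = 1e-9)
  expect_equal(surface_relative_intensity(scaled, 1, ann)$value,
               surf$value, tolerance = 1e-9)
  # A_idx is scale-invariant but NOT offset-invariant (formula has no
  # background subtraction)
  aidx <- acidification_index(st, 2, 3, ann)
  expect_equal(acidification_index(scaled, 2, 3, ann)$value, aidx$value,
               tolerance = 1e-9)
  expect_gt(max(abs(acidification_index(shifted, 2, 3, ann)$value -
                      aidx$value)), 1e-3)
})

test_that("FWHM diameter recovers disc geometry", {
  # rendered noise-free disc of true radius 10 px at 0.1 um/px -> ~2 um
  n <- 64
  img <- matrix(0, n, n)
  img[disc_mask_test(n, c(32, 32), 10)] <- 50
  img <- as.matrix(EBImage::filter2(img, phagolapse:::psf_kernel(1.5),
                                    boundary = "circular")) + 5
  st <- image_stack(array(img, c(1, 1, n, n)), "a", 0.1, 2)
  d <- measure_disc_diameter(st, 1, 1, c(32, 32))
  expect_equal(d, 2.0, tolerance = 0.05)
  # all-background frame -> not found
  flat <- constant_stack(5, n = 32)
  expect_true(is.na(measure_disc_diameter(flat, 1, 1, c(16, 16))))
})

test_that("nuclear diameters track the simulated decay", {
  sc <- tiny_scene("wild_type", seed = 6)
  st <- render_noise_free(sc)
  ann <- annotation_from_scene(sc)
  truth <- scene_nucleus_diameter_timecourse(sc)
  d <- vapply(seq_len(nrow(truth)), function(f)
    measure_disc_diameter(st, f, "HIS::mCherry", ann$center_track[f, ]),
    numeric(1))
  # FWHM carries a small curvature bias on blurred few-pixel discs
  expect_lte(mean(abs(d - truth$value)), 0.1)     # 1 px on average
  expect_true(all(abs(d - truth$value) <= 0.15))  # 1.5 px worst case
  ratio <- nuclear_diameter_ratio(st, "HIS::mCherry", ann)
  half_idx <- which(sc$times == sc$params$nucleus_decay_halftime)
  expect_equal(ratio$value[half_idx], 0.5, tolerance = 0.05)
  # degradation-off scene keeps the disc near its initial size
  sc5 <- tiny_scene("cup5_like", seed = 6)
  r5 <- nuclear_diameter_ratio(render_noise_free(sc5), "HIS::mCherry",
                               annotation_from_scene(sc5))
  expect_gte(r5$value[nrow(r5)], 0.85)
})

test_that("luminal RInt at 60 min is noise-robust under default optics", {
  devs <- vapply(1:50, function(s) {
    sc <- simulate_scene(preset_genotype("wild_type"), seed = s)
    ann <- annotation_from_scene(sc)
    ch <- default_channels()[1]
    nf <- luminal_relative_intensity(
      render_stack(sc, ch, optics_noise_free(), seed = s), 1, ann)
    ny <- luminal_relative_intensity(
      render_stack(sc, ch, optics_model(), seed = s), 1, ann)
    (ny$value[nrow(ny)] - nf$value[nrow(nf)]) / nf$value[nrow(nf)]
  }, numeric(1))
  expect_lte(stats::median(abs(devs)), 0.15)
  expect_lte(mean(abs(devs)), 0.15)
  expect_lte(abs(mean(devs)), 0.1)   # no systematic bias
})
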