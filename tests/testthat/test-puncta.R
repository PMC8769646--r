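render_spot_frame <- function(spots, flux = 10000, n = 96, background = 5,
                              sigma = 1.5) {
  img <- matrix(0, n, n)
  for (i in seq_len(nrow(spots)))
    img[spots[i, 1], spots[i, 2]] <- img[spots[i, 1], spots[i, 2]] + flux
  as.matrix(EBImage::filter2(img, phagolapse:::psf_kernel(sigma),
                             boundary = "circular")) + background
}

random_spots <- function(n_spots, n = 96, min_sep = 6, margin = 8) {
  pts <- matrix(numeric(0), 0, 2)
  while (nrow(pts) < n_spots) {
    cand <- c(sample(margin:(n - margin), 1), sample(margin:(n - margin), 1))
    if (!nrow(pts) ||
        min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= min_sep)
      pts <- rbind(pts, cand)
  }
  pts
}

test_that("blob detection finds isolated puncta exactly", {
  expect_equal(nrow(detect_puncta(matrix(5, 64, 64))), 0)  # blank
  expect_error(detect_puncta(matrix(numeric(0), 0, 0)), "non-empty")
  set.seed(7)
  spots <- random_spots(7)
  det <- detect_puncta(render_spot_frame(spots))
  expect_equal(nrow(det), 7)
  d <- sqrt(outer(det$y, spots[, 1], "-")^2 + outer(det$x, spots[, 2], "-")^2)
  expect_true(all(apply(d, 1, min) <= 1))
})

test_that("detection count is non-increasing in the threshold", {
  set.seed(8)
  img <- render_spot_frame(random_spots(10), flux = 6000)
  counts <- vapply(c(20, 50, 120, 250, 600, 2000),
                   function(th) nrow(detect_puncta(img, threshold = th)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection recall and precision reach 95% on separated spots", {
  set.seed(9)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (rep in 1:40) {
    spots <- random_spots(sample(3:9, 1))
    det <- detect_puncta(render_spot_frame(spots))
    if (nrow(det)) {
      d <- sqrt(outer(det$y, spots[, 1], "-")^2 +
                  outer(det$x, spots[, 2], "-")^2)
      hit <- apply(d, 2, min) <= 2
      tp <- tp + sum(hit)
      fn <- fn + sum(!hit)
      fp <- fp + max(0L, nrow(det) - sum(hit))
    } else fn <- fn + nrow(spots)
  }
  expect_gte(tp / (tp + fn), 0.95)
  expect_gte(tp / (tp + fp), 0.95)
})

test_that("greedy matching handles the degenerate cases", {
  a <- cbind(c(10, 20, 30), c(10, 20, 30))
  m_same <- match_puncta(a, a, radius = 2)
  expect_equal(m_same$n_both, 3L)
  expect_equal(m_same$n_A_only, 0L)
  b_far <- a + 50
  m_far <- match_puncta(a, b_far, radius = 2)
  expect_equal(m_far$n_both, 0L)
  expect_equal(m_far$n_A_only, 3L)
  expect_equal(m_far$n_B_only, 3L)
  expect_error(match_puncta(a, a, frame = c(1, 2)), "different frames")
})

test_that("greedy matching partitions and is channel-symmetric", {
  set.seed(10)
  for (i in 1:30) {
    A <- matrix(runif(2 * sample(0:8, 1), 1, 40), ncol = 2)
    B <- matrix(runif(2 * sample(0:8, 1), 1, 40), ncol = 2)
    m <- match_puncta(A, B, radius = 4)
    expect_equal(m$n_A_only + m$n_both, nrow(A))
    expect_equal(m$n_B_only + m$n_both, nrow(B))
    swapped <- match_puncta(B, A, radius = 4)
    expect_equal(swapped$n_both, m$n_both)
    expect_equal(swapped$n_A_only, m$n_B_only)
    expect_equal(swapped$n_B_only, m$n_A_only)
  }
})

test_that("greedy matching equals optimal bipartite matching up to 8 spots", {
  set.seed(11)
  for (i in 1:40) {
    nA <- sample(1:8, 1); nB <- sample(1:8, 1)
    # cluster scale comparable to the radius so matchings are contested
    A <- matrix(runif(2 * nA, 1, 15), ncol = 2)
    B <- matrix(runif(2 * nB, 1, 15), ncol = 2)
    m <- match_puncta(A, B, radius = 3)
    opt <- oracle_optimal_matching(A, B, radius = 3)
    expect_equal(m$n_both, opt$n_both)
  }
})

test_that("class distribution reproduces the percentage formulas", {
  # 29 A-only, 33 B-only, 19 both of 81: the published 35.8/40.7/23.5 split
  cd <- class_distribution(colocalization_result(29, 33, 19))
  expect_equal(unname(round(cd, 1)), c(35.8, 40.7, 23.5))
  expect_equal(sum(cd), 100, tolerance = 1e-9)
  expect_equal(unname(class_distribution(colocalization_result(1, 0, 0))),
               c(100, 0, 0))
  expect_equal(unname(class_distribution(colocalization_result(2, 2, 2))),
               rep(100 / 3, 3), tolerance = 1e-9)
  expect_error(class_distribution(colocalization_result(0, 0, 0)),
               "no puncta")
})

test_that("double-positive percentage follows the counting formula", {
  expect_equal(percent_double_positive(4, 10), 40)
  expect_equal(percent_double_positive(10, 10), 100)  # saturated case
  expect_equal(percent_double_positive(0, 7), 0)
  expect_error(percent_double_positive(1, 0), "empty")
  expect_error(percent_double_positive(5, 3), "n_both")
})

test_that("two-reporter rendering recovers the configured class mixture", {
  params <- preset_genotype("wild_type", k_recruit = 0,
                            puncta_birth_rate = 0.8,
                            observation_span = 30,
                            puncta_channel_probs = c(0.358, 0.407, 0.235),
                            shrink_onset = Inf)
  fl <- fluorophore_presets()
  chans <- list(channel_spec("chA", fl$mCherry, "vesicle", "A"),
                channel_spec("chB", fl$GFP, "vesicle", "B"))
  tot <- c(0L, 0L, 0L)
  truth_tot <- c(0L, 0L, 0L)
  for (s in 1:8) {
    sc <- simulate_scene(params, seed = 300 + s)
    st <- render_stack(sc, chans, optics_noise_free(), seed = s)
    f <- length(sc$frames)
    pa <- detect_puncta(phagolapse:::stack_frame(st, f, 1))
    pb <- detect_puncta(phagolapse:::stack_frame(st, f, 2))
    m <- match_puncta(pa, pb)
    tot <- tot + c(m$n_A_only, m$n_B_only, m$n_both)
    pts <- sc$frames[[f]]$puncta
    truth_tot <- truth_tot +
      c(sum(pts$label_A > 0 & pts$label_B == 0),
        sum(pts$label_B > 0 & pts$label_A == 0),
        sum(pts$label_A > 0 & pts$label_B > 0))
  }
  # pooled class counts track the ground truth (a few overlapping puncta
  # merge in detection, so exact equality is not expected)
  expect_true(all(abs(tot - truth_tot) <= pmax(2, 0.25 * truth_tot)))
  cd <- class_distribution(colocalization_result(tot[1], tot[2], tot[3]))
  truth_cd <- 100 * truth_tot / sum(truth_tot)
  expect_true(all(abs(cd - truth_cd) < 10))
})
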