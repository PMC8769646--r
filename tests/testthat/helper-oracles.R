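# Independent brute-force oracles used to validate the fast implementations.

# Double-loop pixel sum over a half-open box window (even sides anchored so
# the center is the upper-left pixel of the central 2x2 block).
oracle_box_sum <- function(img, center, box_side) {
  start_y <- round(center[1]) - floor((box_side - 1) / 2)
  start_x <- round(center[2]) - floor((box_side - 1) / 2)
  total <- 0
  for (dy in 0:(box_side - 1)) for (dx in 0:(box_side - 1))
    total <- total + img[start_y + dy, start_x + dx]
  total
}

# Per-pixel even-odd crossing test, written independently of the package
# (scalar loop over pixels and edges).
oracle_polygon_sum <- function(img, polygon) {
  v <- nrow(polygon)
  total <- 0
  count <- 0L
  for (py in seq_len(nrow(img))) for (px in seq_len(ncol(img))) {
    inside <- FALSE
    j <- v
    for (i in seq_len(v)) {
      y1 <- polygon[i, 1]; x1 <- polygon[i, 2]
      y2 <- polygon[j, 1]; x2 <- polygon[j, 2]
      if ((y1 > py) != (y2 > py)) {
        xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
        if (px < xint) inside <- !inside
      }
      j <- i
    }
    if (inside) {
      total <- total + img[py, px]
      count <- count + 1L
    }
  }
  list(sum = total, area = count)
}

# Exhaustive optimal bipartite matching under a distance cap: maximize the
# number of matched pairs, break ties by minimum total distance.  Feasible
# for <= 8 spots per side (recursion over the smaller side).
oracle_optimal_matching <- function(A, B, radius) {
  nA <- nrow(A); nB <- nrow(B)
  if (nA == 0 || nB == 0) return(list(n_both = 0L))
  d <- sqrt(outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2)
  best <- list(n = -1L, dist = Inf)
  recurse <- function(a, used_b, n, dist) {
    if (a > nA) {
      if (n > best$n || (n == best$n && dist < best$dist))
        best <<- list(n = n, dist = dist)
      return(invisible())
    }
    # leave spot a unmatched
    recurse(a + 1L, used_b, n, dist)
    for (b in seq_len(nB)) {
      if (!used_b[b] && d[a, b] <= radius) {
        used_b[b] <- TRUE
        recurse(a + 1L, used_b, n + 1L, dist + d[a, b])
        used_b[b] <- FALSE
      }
    }
  }
  recurse(1L, logical(nB), 0L, 0)
  list(n_both = best$n, total_dist = best$dist)
}

# Shared fixture: a small scene + noise-free render, cached per test run.
tiny_scene <- local({
  cache <- new.env()
  function(preset = "wild_type", seed = 1, ...) {
    key <- paste(preset, seed, paste(deparse(list(...)), collapse = ""),
                 sep = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- simulate_scene(preset_genotype(preset, ...), seed)
    cache[[key]]
  }
})

render_noise_free <- function(scene, channels = default_channels(),
                              background = 20) {
  render_stack(scene, channels,
               optics_noise_free(background = background), seed = 1)
}

# Flat-field stack helper for analytic ROI tests.
constant_stack <- function(value, n = 32, n_frames = 3, n_channels = 1,
                           frame_interval = 2) {
  image_stack(array(value, c(n_frames, n_channels, n, n)),
              paste0("ch", seq_len(n_channels)), pixel_size = 0.1,
              frame_interval = frame_interval)
}

simple_annotation <- function(n_frames, center = c(16, 16), r_in = 4,
                              r_out = 8, bg = c(2, 2, 4, 4)) {
  ctr <- matrix(rep(center, each = n_frames), ncol = 2)
  roi_annotation(ctr,
                 replicate(n_frames, circle_polygon_test(center, r_in),
                           simplify = FALSE),
                 replicate(n_frames, circle_polygon_test(center, r_out),
                           simplify = FALSE),
                 bg)
}

disc_mask_test <- function(n, center, radius) {
  sqrt(outer((seq_len(n) - center[1])^2,
             (seq_len(n) - center[2])^2, "+")) <= radius
}

circle_polygon_test <- function(center, radius, n_vertices = 20L) {
  a <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(center[1] + radius * sin(a), center[2] + radius * cos(a))
}
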