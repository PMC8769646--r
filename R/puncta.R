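# Scale-normalized Laplacian-of-Gaussian kernel for bright-blob detection.
# Zero-mean so a constant background yields zero response.
log_kernel <- function(sigma) {
  half <- max(3L, as.integer(ceiling(3.5 * sigma)))
  ax <- -half:half
  r2 <- outer(ax^2, ax^2, "+")
  g <- exp(-r2 / (2 * sigma^2))
  k <- -sigma^2 * ((r2 - 2 * sigma^2) / sigma^4) * g / (2 * pi * sigma^2)
  k - mean(k)
}

#' Detect fluorescent puncta in one frame
#'
#' Multi-scale Laplacian-of-Gaussian blob detection: the frame is filtered
#' with scale-normalized LoG kernels at `n_scales` sigmas geometrically
#' spaced in \[`min_sigma`, `max_sigma`\]; local maxima of the response over
#' space and scale that exceed `threshold` are kept, then thinned by
#' greedy non-maximum suppression so no two detections lie closer than
#' `min_separation`.  Deterministic for a fixed input.
#'
#' @param image 2D numeric matrix (one frame, one channel).
#' @param min_sigma,max_sigma Blob scale range, px.
#' @param n_scales Number of scales.
#' @param threshold Minimum scale-normalized LoG response (> 0).  The
#'   default is calibrated for the renderer's default brightness and label
#'   scale (a one-vesicle punctum peaks near 350 response units) and
#'   rejects the edge response of the luminal disc (~15 units).
#' @param min_separation Minimum distance between detections, px.
#' @param mask Optional logical matrix; detections outside it are dropped
#'   (e.g. a cytosol mask excluding the phagosome and its rim).
#' @return Object of class `puncta_set`: data frame with `y`, `x`, `sigma`,
#'   `response`, `peak` plus the detection parameters as attributes.
#' @export
detect_puncta <- function(image, min_sigma = 1, max_sigma = 3,
                          n_scales = 4, threshold = 50,
                          min_separation = 2, mask = NULL) {
  if (!is.matrix(image) || !length(image)) stop("image must be a non-empty 2D matrix")
  if (threshold <= 0) stop("threshold must be > 0")
  sigmas <- exp(seq(log(min_sigma), log(max_sigma), length.out = n_scales))
  n_r <- nrow(image); n_c <- ncol(image)
  resp <- array(0, c(n_r, n_c, n_scales))
  for (s in seq_along(sigmas))
    resp[, , s] <- EBImage::filter2(image, log_kernel(sigmas[s]),
                                    boundary = "replicate")
  # spatial 3x3 local maxima per scale, then maxima across adjacent scales
  cand <- NULL
  for (s in seq_along(sigmas)) {
    r <- resp[, , s]
    is_max <- r >= threshold
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      shifted <- shift_matrix(r, dy, dx)
      is_max <- is_max & (r >= shifted)
    }
    lo <- if (s > 1) resp[, , s - 1] else -Inf
    hi <- if (s < n_scales) resp[, , s + 1] else -Inf
    is_max <- is_max & (r >= lo) & (r >= hi)
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx))
      cand <- rbind(cand, data.frame(y = idx[, 1], x = idx[, 2],
                                     sigma = sigmas[s],
                                     response = r[idx]))
  }
  if (is.null(cand)) cand <- data.frame(y = integer(), x = integer(),
                                        sigma = double(),
                                        response = double())
  if (!is.null(mask) && nrow(cand))
    cand <- cand[mask[cbind(cand$y, cand$x)], , drop = FALSE]
  # non-maximum suppression: strongest response wins
  if (nrow(cand) > 1L) {
    cand <- cand[order(-cand$response, cand$y, cand$x), , drop = FALSE]
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!any(keep)) { keep[i] <- TRUE; next }
      d2 <- (cand$y[keep] - cand$y[i])^2 + (cand$x[keep] - cand$x[i])^2
      if (all(d2 >= min_separation^2)) keep[i] <- TRUE
    }
    cand <- cand[keep, , drop = FALSE]
    cand <- cand[order(cand$y, cand$x), , drop = FALSE]
  }
  cand$peak <- if (nrow(cand)) image[cbind(cand$y, cand$x)] else double()
  rownames(cand) <- NULL
  structure(cand,
            detection_params = list(min_sigma = min_sigma,
                                    max_sigma = max_sigma,
                                    n_scales = n_scales,
                                    threshold = threshold,
                                    min_separation = min_separation),
            class = c("puncta_set", "data.frame"))
}

shift_matrix <- function(m, dy, dx) {
  n_r <- nrow(m); n_c <- ncol(m)
  out <- matrix(-Inf, n_r, n_c)
  ys <- seq_len(n_r); xs <- seq_len(n_c)
  ys_src <- ys - dy; xs_src <- xs - dx
  ok_y <- ys_src >= 1 & ys_src <= n_r
  ok_x <- xs_src >= 1 & xs_src <= n_c
  out[ys[ok_y], xs[ok_x]] <- m[ys_src[ok_y], xs_src[ok_x]]
  out
}

as_spot_matrix <- function(s) {
  if (inherits(s, "puncta_set") || is.data.frame(s))
    cbind(y = s$y, x = s$x)
  else {
    s <- as.matrix(s)
    if (!ncol(s) == 2L) stop("spots must have (y, x) columns")
    colnames(s) <- c("y", "x")
    s
  }
}

#' Match puncta between two channels
#'
#' Nearest-neighbor matching under a distance cap: candidate pairs within
#' `radius` are taken greedily in order of increasing distance (ties broken
#' by lower (y, x) of the first-channel spot, then of the second), each spot
#' used at most once; the greedy solution is then refined by augmenting
#' paths so the final matching always reaches maximum cardinality (pure
#' greedy can strand a matchable pair when one spot sits between two
#' partners).  The result therefore agrees with exhaustive optimal bipartite
#' matching on the pair counts.
#'
#' @param setA,setB [detect_puncta()] results (or two-column (y, x)
#'   matrices) from the same frame.
#' @param radius Maximum matching distance, px (default 3, about twice the
#'   PSF sigma).
#' @param frame Optional frame indices used for a same-frame sanity check.
#' @return Object of class `colocalization_result`: counts `n_A_only`,
#'   `n_B_only`, `n_both`, per-class percentages, the matched index pairs,
#'   and a `formula_tag`.
#' @export
match_puncta <- function(setA, setB, radius = 3, frame = NULL) {
  if (!is.null(frame) && length(frame) == 2L && frame[1] != frame[2])
    stop("puncta sets come from different frames")
  A <- as_spot_matrix(setA); B <- as_spot_matrix(setB)
  nA <- nrow(A); nB <- nrow(B)
  pairs <- NULL
  if (nA && nB) {
    d <- sqrt(outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2)
    idx <- which(d <= radius, arr.ind = TRUE)
    if (nrow(idx)) {
      o <- order(d[idx], A[idx[, 1], 1], A[idx[, 1], 2],
                 B[idx[, 2], 1], B[idx[, 2], 2])
      idx <- idx[o, , drop = FALSE]
      match_of_a <- integer(nA)  # 0 = unmatched
      match_of_b <- integer(nB)
      for (i in seq_len(nrow(idx))) {
        a <- idx[i, 1]; b <- idx[i, 2]
        if (!match_of_a[a] && !match_of_b[b]) {
          match_of_a[a] <- b; match_of_b[b] <- a
        }
      }
      # augmenting-path refinement (Kuhn): guarantees maximum cardinality
      adj <- split(idx[, 2], idx[, 1])
      try_augment <- function(a, state) {
        for (b in adj[[as.character(a)]]) {
          if (state$seen[b]) next
          state$seen[b] <- TRUE
          if (!match_of_b[b] || try_augment(match_of_b[b], state)) {
            match_of_a[a] <<- b
            match_of_b[b] <<- a
            return(TRUE)
          }
        }
        FALSE
      }
      for (a in unique(idx[, 1])) {
        if (!match_of_a[a]) {
          state <- new.env()
          state$seen <- logical(nB)
          try_augment(a, state)
        }
      }
      matched_a <- which(match_of_a > 0L)
      if (length(matched_a))
        pairs <- cbind(row = matched_a, col = match_of_a[matched_a])
    }
  }
  n_both <- if (is.null(pairs)) 0L else nrow(pairs)
  colocalization_result(n_A_only = nA - n_both, n_B_only = nB - n_both,
                        n_both = n_both, pairs = pairs,
                        formula_tag = "greedy_nn")
}

#' Construct a colocalization result
#'
#' @param n_A_only,n_B_only,n_both Non-negative counts.
#' @param pairs Optional matched index pairs.
#' @param formula_tag Label recording which counting rule produced the
#'   result.
#' @export
colocalization_result <- function(n_A_only, n_B_only, n_both, pairs = NULL,
                                  formula_tag = "manual") {
  stopifnot(n_A_only >= 0, n_B_only >= 0, n_both >= 0)
  structure(list(n_A_only = as.integer(n_A_only),
                 n_B_only = as.integer(n_B_only),
                 n_both = as.integer(n_both),
                 pairs = pairs, formula_tag = formula_tag),
            class = "colocalization_result")
}

#' @export
print.colocalization_result <- function(x, ...) {
  cat(sprintf("<colocalization_result> A-only %d, B-only %d, both %d (%s)\n",
              x$n_A_only, x$n_B_only, x$n_both, x$formula_tag))
  invisible(x)
}

#' Three-way class distribution of a puncta population
#'
#' Percentages of single- and double-labeled puncta among all distinct
#' puncta (the LGG-1-only / LGG-2-only / double-positive classes); the
#' three percentages sum to 100.
#'
#' @param result A [colocalization_result()].
#' @return Named numeric vector `c(A_only, B_only, both)` in percent.
#' @export
class_distribution <- function(result) {
  stopifnot(inherits(result, "colocalization_result"))
  total <- result$n_A_only + result$n_B_only + result$n_both
  if (total <= 0) stop("no puncta to classify")
  100 * c(A_only = result$n_A_only, B_only = result$n_B_only,
          both = result$n_both) / total
}

#' Percentage of double-positive puncta in a reference population
#'
#' The counting formulas of the colocalization assays: the fraction of a
#' reference channel's puncta that also carry the second label, e.g.
#' `% mCh+GFP+ = 100 * n(mCh+ GFP+) / N(mCh+)` for RAB-7 co-labeling, or the
#' autolysosome percentage `%AL = 100 * n(mNG+ mCh+) / (n(mNG+ mCh+) +
#' n(mNG+ mCh-))`.
#'
#' @param n_both Double-positive count.
#' @param n_ref_total Total puncta in the reference channel
#'   (`>= n_both`, `> 0`).
#' @return Percentage.
#' @examples
#' percent_double_positive(4, 10)   # 40
#' @export
percent_double_positive <- function(n_both, n_ref_total) {
  if (n_ref_total <= 0) stop("reference population is empty")
  if (n_both < 0 || n_both > n_ref_total)
    stop("need 0 <= n_both <= n_ref_total")
  100 * n_both / n_ref_total
}

#' Region masks around an annotated phagosome
#'
#' Builds the counting-scope masks used when classifying puncta "on the
#' phagosomal surface" (an annulus of `annulus_width` px outside the rim)
#' versus "in the cytoplasm" (everything outside phagosome + annulus).
#'
#' @param scene A [simulate_scene()] result.
#' @param frame Frame index.
#' @param annulus_width Width of the surface annulus, px.
#' @return List of logical matrices `surface` and `cytosol`.
#' @export
phagosome_region_masks <- function(scene, frame, annulus_width = 4) {
  fr <- scene$frames[[frame]]
  n <- scene$params$image_size
  d <- sqrt(outer((seq_len(n) - fr$phagosome_center[1])^2,
                  (seq_len(n) - fr$phagosome_center[2])^2, "+"))
  r <- fr$phagosome_radius
  list(surface = d > r - 2 & d <= r + annulus_width,
       cytosol = d > r + annulus_width)
}
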