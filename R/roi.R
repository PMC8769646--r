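#' A scalar per-frame measurement series
#'
#' Container for the measurement time courses (relative intensities,
#' acidification index, diameters): a data frame with `time_min` and `value`
#' columns, carrying the measurement kind and the T0 anchor used for
#' normalization as attributes.
#'
#' @param times Minutes from phagosome sealing, strictly increasing.
#' @param values Measurement values (dimensionless ratios or micrometres).
#' @param kind One of `"luminal_rint"`, `"surface_rint"`,
#'   `"acidification_index"`, `"diameter_ratio"`, `"diameter_um"`.
#' @param anchor_value Raw T0 value the series was normalized by (if any).
#' @return A `time_course` data frame.
#' @export
time_course <- function(times, values,
                        kind = c("luminal_rint", "surface_rint",
                                 "acidification_index", "diameter_ratio",
                                 "diameter_um"),
                        anchor_value = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(length(times) == length(values), length(times) >= 1L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(data.frame(time_min = times, value = values),
            kind = kind, anchor_value = anchor_value,
            class = c("time_course", "data.frame"))
}

tc_kind <- function(tc) attr(tc, "kind")

#' Per-phagosome ROI annotation
#'
#' The manual annotations the intensity measurements operate on: a per-frame
#' center track, per-frame inner/outer polygons outlining the phagosome
#' surface "donut", and a fixed background box outside the cell region.
#' Polygons are closed vertex lists in pixel coordinates (row = y, col = x,
#' 1-based, pixel centers at integers).
#'
#' @param center_track T x 2 matrix of (y, x) centers, one row per frame.
#' @param inner_polygon,outer_polygon Lists (one per frame) of V x 2 vertex
#'   matrices; the outer polygon must strictly contain the inner one.
#' @param background_box `c(y0, x0, height, width)`: top-left corner and size
#'   of the background region, which must not intersect the phagosome.
#' @return Object of class `roi_annotation`.
#' @seealso [annotation_from_scene()]
#' @export
roi_annotation <- function(center_track, inner_polygon, outer_polygon,
                           background_box) {
  center_track <- as.matrix(center_track)
  stopifnot(ncol(center_track) == 2L,
            length(inner_polygon) == nrow(center_track),
            length(outer_polygon) == nrow(center_track),
            length(background_box) == 4L)
  structure(list(center_track = center_track,
                 inner_polygon = inner_polygon,
                 outer_polygon = outer_polygon,
                 background_box = background_box),
            class = "roi_annotation")
}

circle_polygon <- function(center, radius, n_vertices = 24L) {
  a <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(y = center[1] + radius * sin(a), x = center[2] + radius * cos(a))
}

#' Build an annotation from simulation ground truth
#'
#' Mirrors how the in vivo measurements are annotated by hand: the center
#' track follows the phagosome center, the donut polygons are circles drawn
#' `donut_margin` px inside/outside the rim (following the shrinking
#' radius), and the background box sits in the image corner farthest from
#' the phagosome.
#'
#' @param scene A [simulate_scene()] result.
#' @param donut_margin Half-width of the surface donut, px.
#' @param bg_box_side Background box side, px.
#' @return An [roi_annotation()].
#' @export
annotation_from_scene <- function(scene, donut_margin = 5, bg_box_side = 8) {
  n <- scene$params$image_size
  ctr <- t(vapply(scene$frames, `[[`, numeric(2), "phagosome_center"))
  radii <- vapply(scene$frames, `[[`, numeric(1), "phagosome_radius")
  inner <- lapply(seq_along(radii), function(i)
    circle_polygon(ctr[i, ], max(radii[i] - donut_margin, 1.5)))
  outer <- lapply(seq_along(radii), function(i)
    circle_polygon(ctr[i, ], radii[i] + donut_margin))
  # farthest corner from the (initial) center
  corner_y <- if (ctr[1, 1] > n / 2) 3 else n - bg_box_side - 2
  corner_x <- if (ctr[1, 2] > n / 2) 3 else n - bg_box_side - 2
  roi_annotation(ctr, inner, outer,
                 c(corner_y, corner_x, bg_box_side, bg_box_side))
}

# Row/column index ranges of a box_side x box_side window centered at
# (cy, cx); for even sides the center pixel is the upper-left of the
# central 2x2 block.
box_indices <- function(center, box_side, nrow, ncol) {
  start_y <- round(center[1]) - floor((box_side - 1) / 2)
  start_x <- round(center[2]) - floor((box_side - 1) / 2)
  ys <- start_y:(start_y + box_side - 1)
  xs <- start_x:(start_x + box_side - 1)
  if (ys[1] < 1 || xs[1] < 1 || ys[box_side] > nrow || xs[box_side] > ncol)
    stop(sprintf("measurement box [%d:%d, %d:%d] falls outside the %dx%d image",
                 ys[1], ys[box_side], xs[1], xs[box_side], nrow, ncol))
  list(ys = ys, xs = xs)
}

#' Total intensity in a fixed square box
#'
#' Sum of pixel intensities over a `box_side` x `box_side` window centered
#' on `center` (the 4 x 4 px fixed area of the luminal measurement).  For
#' even sides the center pixel is the upper-left pixel of the central 2 x 2
#' block.
#'
#' @param stack An [image_stack()].
#' @param frame,channel Frame index / channel index or name.
#' @param center (y, x) center in pixels.
#' @param box_side Box side in pixels (default 4).
#' @return Summed intensity.  Errors if the box leaves the image.
#' @export
box_intensity <- function(stack, frame, channel, center, box_side = 4) {
  img <- stack_frame(stack, frame, channel)
  idx <- box_indices(center, box_side, nrow(img), ncol(img))
  sum(img[idx$ys, idx$xs])
}

bg_box_center <- function(background_box) {
  c(background_box[1] + floor((background_box[3] - 1) / 2),
    background_box[2] + floor((background_box[4] - 1) / 2))
}

#' Relative luminal intensity time course
#'
#' The luminal-entry measurement: at every frame the total intensity of a
#' fixed `box_side` x `box_side` box at the phagosome center and of an
#' equal-sized box in the background region are recorded, and
#' \deqn{RInt(T_n) = \frac{(Int_{center} - Int_{background})_{T_n}}
#'                        {(Int_{center} - Int_{background})_{T_0}}}
#' so RInt(T0) = 1 by construction and RInt stays at 1 when no label enters
#' the lumen.
#'
#' @param stack An [image_stack()].
#' @param channel Channel index or name.
#' @param annotation An [roi_annotation()].
#' @param box_side Box side, px (default 4).
#' @return A [time_course()] of kind `"luminal_rint"`.
#' @export
luminal_relative_intensity <- function(stack, channel, annotation,
                                       box_side = 4) {
  stopifnot(inherits(annotation, "roi_annotation"))
  n_frames <- dim(stack$data)[1]
  bg_ctr <- bg_box_center(annotation$background_box)
  raw <- vapply(seq_len(n_frames), function(f) {
    box_intensity(stack, f, channel, annotation$center_track[f, ], box_side) -
      box_intensity(stack, f, channel, bg_ctr, box_side)
  }, numeric(1))
  anchor <- raw[1]
  if (!is.finite(anchor) || anchor <= 0)
    stop("background-subtracted T0 intensity is not positive; ",
         "check that the background ROI lies outside the labeled region")
  times <- (seq_len(n_frames) - 1) * stack$frame_interval
  time_course(times, raw / anchor, kind = "luminal_rint",
              anchor_value = anchor)
}

#' Pixels whose centers fall inside a polygon
#'
#' Even-odd (crossing-number) point-in-polygon test evaluated at every pixel
#' center of an `nrow` x `ncol` grid.  This is the rasterization used for
#' the donut intensity and area sums: area is the rasterized pixel count,
#' matching how intensity is summed, not the continuous shoelace area.
#'
#' @param polygon V x 2 matrix of (y, x) vertices (closed implicitly).
#' @param nrow,ncol Grid dimensions.
#' @return Logical nrow x ncol matrix.
#' @export
pixels_in_polygon <- function(polygon, nrow, ncol) {
  polygon <- as.matrix(polygon)
  v <- base::nrow(polygon)
  if (v < 3L) stop("polygon needs at least 3 vertices")
  py <- rep(seq_len(nrow), times = ncol)
  px <- rep(seq_len(ncol), each = nrow)
  inside <- logical(nrow * ncol)
  j <- v
  for (i in seq_len(v)) {
    y1 <- polygon[i, 1]; x1 <- polygon[i, 2]
    y2 <- polygon[j, 1]; x2 <- polygon[j, 2]
    crosses <- which((y1 > py) != (y2 > py))
    if (length(crosses)) {
      xint <- x1 + (py[crosses] - y1) * (x2 - x1) / (y2 - y1)
      flip <- crosses[px[crosses] < xint]
      inside[flip] <- !inside[flip]
    }
    j <- i
  }
  matrix(inside, nrow, ncol)
}

#' Relative surface intensity time course (donut measurement)
#'
#' The recruitment measurement: the phagosome surface is outlined by two
#' closed polygons and the unit intensity of the donut between them is
#' \deqn{UI_{phag} = \frac{Int_{outer} - Int_{inner}}{Area_{outer} - Area_{inner}}}
#' with the unit background intensity \eqn{UI_{bg} = Int_{bg}/Area_{bg}}
#' taken from the background box, and
#' \deqn{RInt(T_n) = (UI_{phag} - UI_{bg})_{T_n} / (UI_{phag} - UI_{bg})_{T_0}.}
#' Intensities and areas are computed on the pixel-center rasterization of
#' the polygons ([pixels_in_polygon()]).
#'
#' @inheritParams luminal_relative_intensity
#' @return A [time_course()] of kind `"surface_rint"`.
#' @export
surface_relative_intensity <- function(stack, channel, annotation) {
  stopifnot(inherits(annotation, "roi_annotation"))
  n_frames <- dim(stack$data)[1]
  bb <- annotation$background_box
  raw <- vapply(seq_len(n_frames), function(f) {
    img <- stack_frame(stack, f, channel)
    m_out <- pixels_in_polygon(annotation$outer_polygon[[f]],
                               nrow(img), ncol(img))
    m_in <- pixels_in_polygon(annotation$inner_polygon[[f]],
                              nrow(img), ncol(img))
    a_out <- sum(m_out); a_in <- sum(m_in)
    if (a_out - a_in < 1)
      stop("degenerate donut at frame ", f,
           ": outer and inner polygon areas differ by < 1 px^2")
    ui_phag <- (sum(img[m_out]) - sum(img[m_in])) / (a_out - a_in)
    ys <- bb[1]:(bb[1] + bb[3] - 1); xs <- bb[2]:(bb[2] + bb[4] - 1)
    ui_bg <- sum(img[ys, xs]) / (bb[3] * bb[4])
    ui_phag - ui_bg
  }, numeric(1))
  anchor <- raw[1]
  if (!is.finite(anchor) || anchor <= 0)
    stop("background-subtracted T0 unit intensity is not positive; ",
         "check the background ROI and donut polygons")
  times <- (seq_len(n_frames) - 1) * stack$frame_interval
  time_course(times, raw / anchor, kind = "surface_rint",
              anchor_value = anchor)
}

#' Acidification index time course
#'
#' Ratiometric pH readout from the dual-tagged nuclear reporter: at every
#' frame the total GFP and mCherry intensities of a fixed 3 x 3 px box at
#' the phagosome center are recorded and
#' \deqn{A_{idx}(T_n) = \frac{(Int_{GFP}/Int_{mCherry})_{T_n}}
#'                           {(Int_{GFP}/Int_{mCherry})_{T_0}}}
#' so A_idx(T0) = 1 and the index falls as the lumen acidifies (GFP, pKa
#' 6.0, is quenched before mCherry, pKa 4.5).  Following the printed
#' definition there is no background subtraction, so the index is not
#' invariant to a constant camera offset; `background_correct = TRUE`
#' enables an offset-subtracted variant (off by default).
#'
#' @param stack An [image_stack()].
#' @param gfp_channel,mcherry_channel Channel indices or names.
#' @param annotation An [roi_annotation()].
#' @param box_side Box side, px (default 3).
#' @param background_correct Subtract the background-box intensity from both
#'   channels before forming the ratio?
#' @return A [time_course()] of kind `"acidification_index"`.
#' @export
acidification_index <- function(stack, gfp_channel, mcherry_channel,
                                annotation, box_side = 3,
                                background_correct = FALSE) {
  stopifnot(inherits(annotation, "roi_annotation"))
  n_frames <- dim(stack$data)[1]
  bg_ctr <- bg_box_center(annotation$background_box)
  ratio <- vapply(seq_len(n_frames), function(f) {
    ctr <- annotation$center_track[f, ]
    g <- box_intensity(stack, f, gfp_channel, ctr, box_side)
    m <- box_intensity(stack, f, mcherry_channel, ctr, box_side)
    if (background_correct) {
      g <- g - box_intensity(stack, f, gfp_channel, bg_ctr, box_side)
      m <- m - box_intensity(stack, f, mcherry_channel, bg_ctr, box_side)
    }
    if (!is.finite(m) || m <= 0)
      stop("mCherry intensity is not positive at frame ", f,
           "; the GFP/mCherry ratio is undefined")
    g / m
  }, numeric(1))
  times <- (seq_len(n_frames) - 1) * stack$frame_interval
  time_course(times, ratio / ratio[1], kind = "acidification_index",
              anchor_value = ratio[1])
}

# Half-maximum crossing positions of a 1D profile around a peak index.
# Returns the interpolated chord length, or NA if no crossing brackets the
# peak on either side.
fwhm_chord <- function(profile, peak_idx, threshold) {
  n <- length(profile)
  left <- NA_real_
  for (j in seq(peak_idx, 2)) {
    if (profile[j - 1] < threshold && profile[j] >= threshold) {
      left <- (j - 1) + (threshold - profile[j - 1]) /
        (profile[j] - profile[j - 1])
      break
    }
  }
  right <- NA_real_
  for (j in seq(peak_idx, n - 1)) {
    if (profile[j + 1] < threshold && profile[j] >= threshold) {
      right <- j + (profile[j] - threshold) / (profile[j] - profile[j + 1])
      break
    }
  }
  if (is.na(left)) left <- 1
  if (is.na(right)) right <- n
  right - left
}

#' Full-width-at-half-maximum diameter of a bright disc
#'
#' Measures the diameter of a labeled disc (the mCherry-positive nuclear
#' disc of an engulfed corpse, or any filled structure) at a seed point:
#' the peak intensity near the seed and a local background (median of the
#' image border) define a half-maximum threshold; the chord lengths of the
#' above-threshold runs along the horizontal and vertical profiles through
#' the peak are found with linear interpolation at the crossings, and the
#' diameter is their mean converted to micrometres.
#'
#' @param stack An [image_stack()].
#' @param frame,channel Frame index / channel index or name.
#' @param seed_point (y, x) pixel position inside the disc.
#' @param search_radius Half-size of the window searched for the peak, px.
#' @param min_prominence Minimum peak-above-background contrast required to
#'   call a disc present; below it the result is "not found" (`NA`).
#' @return Diameter in micrometres, or `NA_real_` when no disc is found.
#' @export
measure_disc_diameter <- function(stack, frame, channel, seed_point,
                                  search_radius = 4, min_prominence = 0) {
  img <- stack_frame(stack, frame, channel)
  n_r <- nrow(img); n_c <- ncol(img)
  ys <- max(1, round(seed_point[1]) - search_radius):
    min(n_r, round(seed_point[1]) + search_radius)
  xs <- max(1, round(seed_point[2]) - search_radius):
    min(n_c, round(seed_point[2]) + search_radius)
  win <- img[ys, xs, drop = FALSE]
  pk <- which(win == max(win), arr.ind = TRUE)[1, ]
  cy <- ys[pk[1]]; cx <- xs[pk[2]]
  peak <- img[cy, cx]
  bg <- stats::median(c(img[1, ], img[n_r, ], img[, 1], img[, n_c]))
  if (!(peak - bg > max(min_prominence, 1e-9))) return(NA_real_)
  threshold <- bg + (peak - bg) / 2
  chord_h <- fwhm_chord(img[cy, ], cx, threshold)
  chord_v <- fwhm_chord(img[, cx], cy, threshold)
  if (chord_h <= 0 || chord_v <= 0) return(NA_real_)
  mean(c(chord_h, chord_v)) * stack$pixel_size
}

#' Nuclear diameter ratio time course
#'
#' The chromatin-degradation assay: the FWHM diameter of the nuclear disc is
#' measured at every frame (seeded on the annotation center track) and
#' normalized to the 0-min diameter, so the ratio starts at 1 and falls as
#' the engulfed nucleus is degraded.  Frames where no disc is found
#' propagate `NA`.
#'
#' @inheritParams luminal_relative_intensity
#' @param ... Passed to [measure_disc_diameter()].
#' @return A [time_course()] of kind `"diameter_ratio"`.
#' @export
nuclear_diameter_ratio <- function(stack, channel, annotation, ...) {
  stopifnot(inherits(annotation, "roi_annotation"))
  n_frames <- dim(stack$data)[1]
  d <- vapply(seq_len(n_frames), function(f)
    measure_disc_diameter(stack, f, channel,
                          annotation$center_track[f, ], ...), numeric(1))
  if (!is.finite(d[1]) || d[1] <= 0)
    stop("nuclear disc diameter is not measurable at T0")
  times <- (seq_len(n_frames) - 1) * stack$frame_interval
  time_course(times, d / d[1], kind = "diameter_ratio", anchor_value = d[1])
}
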