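#' An event-time result with censoring
#'
#' @param kind `"engulfment"`, `"lifespan"`, or `"fusion_onset"`.
#' @param time Event time in minutes, or `NA` when censored.
#' @param censored Logical; `TRUE` when the event had not occurred by the
#'   observation horizon.
#' @param censor_horizon Last observed time, min.
#' @return Object of class `event_result`.
#' @export
event_result <- function(kind = c("engulfment", "lifespan", "fusion_onset"),
                         time = NA_real_, censored = FALSE,
                         censor_horizon = NA_real_) {
  kind <- match.arg(kind)
  censored <- isTRUE(censored)
  if (censored && !is.na(time))
    stop("a censored result must not carry an event time")
  if (!censored && (!is.finite(time) || time < 0))
    stop("an uncensored event time must be finite and >= 0")
  structure(list(kind = kind, time = if (censored) NA_real_ else time,
                 censored = censored, censor_horizon = censor_horizon),
            class = "event_result")
}

#' @export
print.event_result <- function(x, ...) {
  cat(sprintf("<event_result> %s: %s\n", x$kind,
              if (x$censored)
                sprintf("censored at %g min", x$censor_horizon)
              else sprintf("%g min", x$time)))
  invisible(x)
}

#' Engulfment duration
#'
#' The period between the budding of the pseudopods and their sealing into a
#' closed phagosome.
#'
#' @param pseudopod_events Named vector or list with `bud_time` and
#'   `seal_time` in minutes (`seal_time >= bud_time`).
#' @return Duration in minutes.
#' @examples
#' engulfment_duration(c(bud_time = 0, seal_time = 6))   # 6
#' @export
engulfment_duration <- function(pseudopod_events) {
  bud <- pseudopod_events[["bud_time"]]
  seal <- pseudopod_events[["seal_time"]]
  if (!is.finite(bud) || !is.finite(seal))
    stop("bud_time and seal_time must be finite")
  if (seal < bud)
    stop("seal_time precedes bud_time; check the event annotations")
  seal - bud
}

#' Phagosome lifespan from a diameter time course
#'
#' Lifespan is the interval from sealing (T0) to the first frame at which
#' the phagosome diameter has shrunk to one-half of its initial value; when
#' the half-diameter point is never reached the result is censored at the
#' last observed frame.  The first crossing is reported at frame resolution
#' (no interpolation), matching the 2-min sampling of the recordings.
#' Frames with missing diameters are ignored.
#'
#' @param diameters A [time_course()] of diameters in micrometres.
#' @return An [event_result()] of kind `"lifespan"`.
#' @export
phagosome_lifespan <- function(diameters) {
  if (!nrow(diameters)) stop("empty diameter series")
  d0 <- diameters$value[1]
  if (!is.finite(d0) || d0 <= 0) stop("diameter at T0 must be positive")
  ok <- is.finite(diameters$value)
  hit <- which(ok & diameters$value <= 0.5 * d0)
  horizon <- diameters$time_min[nrow(diameters)]
  if (length(hit))
    event_result("lifespan", time = diameters$time_min[hit[1]],
                 censor_horizon = horizon)
  else
    event_result("lifespan", censored = TRUE, censor_horizon = horizon)
}

#' Fusion onset from a luminal intensity time course
#'
#' Operationalizes the visual "first obvious signal in the lumen" call as
#' the first time the normalized luminal relative intensity reaches
#' `threshold` and stays there for `persistence` consecutive frames; if that
#' never happens the result is censored ("no fusion") at the series horizon.
#'
#' @param lumen A [time_course()] of luminal relative intensity (starts
#'   at 1).
#' @param threshold Fold-increase over T0 that counts as signal entry.
#' @param persistence Number of consecutive frames the threshold must hold.
#' @return An [event_result()] of kind `"fusion_onset"`.
#' @examples
#' tc <- time_course(seq(0, 8, 2), c(1, 1.1, 1.2, 1.6, 2.0), "luminal_rint")
#' fusion_onset(tc)$time   # 6
#' @export
fusion_onset <- function(lumen, threshold = 1.5, persistence = 2) {
  if (!nrow(lumen)) stop("empty luminal series")
  stopifnot(threshold > 0, persistence >= 1)
  above <- lumen$value >= threshold
  n <- length(above)
  horizon <- lumen$time_min[n]
  if (n >= persistence) {
    run <- stats::filter(as.numeric(above), rep(1, persistence),
                         sides = 1)
    start <- which(run == persistence) - persistence + 1L
    if (length(start))
      return(event_result("fusion_onset",
                          time = lumen$time_min[start[1]],
                          censor_horizon = horizon))
  }
  event_result("fusion_onset", censored = TRUE, censor_horizon = horizon)
}

#' Histogram summary of censored event times
#'
#' Bins the uncensored event times into right-open intervals
#' `[edge_i, edge_{i+1})` and reports the fraction of all events (censored
#' included) per bin plus the censored fraction; the fractions sum to 1.
#'
#' @param events List of [event_result()]s.
#' @param bin_edges Increasing numeric vector of bin edges, min; the last
#'   edge may be `Inf`.
#' @return List with `bin_edges`, `fractions`, `counts`,
#'   `censored_fraction`, `censored_count`, and `n`.
#' @export
summarize_event_distribution <- function(events, bin_edges) {
  if (!length(events)) stop("no events to summarize")
  stopifnot(length(bin_edges) >= 2L, !is.unsorted(bin_edges, strictly = TRUE))
  censored <- vapply(events, `[[`, logical(1), "censored")
  times <- vapply(events, `[[`, numeric(1), "time")[!censored]
  counts <- if (length(times))
    vapply(seq_len(length(bin_edges) - 1L), function(i)
      sum(times >= bin_edges[i] & times < bin_edges[i + 1L]), integer(1))
  else integer(length(bin_edges) - 1L)
  n <- length(events)
  list(bin_edges = bin_edges, counts = counts, fractions = counts / n,
       censored_count = sum(censored), censored_fraction = sum(censored) / n,
       n = n)
}

#' Events list to data frame
#'
#' @param events Named or unnamed list of [event_result()]s.
#' @param ids Optional identifiers (defaults to names or indices).
#' @return Data frame with columns `phagosome_id`, `kind`, `time_min`,
#'   `censored`, `censor_horizon_min`.
#' @export
events_to_data_frame <- function(events, ids = NULL) {
  if (is.null(ids))
    ids <- if (!is.null(names(events))) names(events)
           else as.character(seq_along(events))
  data.frame(
    phagosome_id = ids,
    kind = vapply(events, `[[`, character(1), "kind"),
    time_min = vapply(events, `[[`, numeric(1), "time"),
    censored = vapply(events, `[[`, logical(1), "censored"),
    censor_horizon_min = vapply(events, `[[`, numeric(1), "censor_horizon"),
    stringsAsFactors = FALSE)
}
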