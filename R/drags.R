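#' Stage-2 drag thresholds
#'
#' Duration bounds defining a single cigarette drag: a hand raise to the
#' mouth lasting between 0.3 and 0.7 seconds, followed by the hand
#' stationary at the mouth for between 0.4 and 8.0 seconds, followed by
#' movement of the hand away from the mouth (the lower phase is not
#' duration-bounded). Raise/dwell bounds are closed intervals.
#' `max_feature_gap_s` bounds the tolerated gap between consecutive
#' pattern elements.
#'
#' @param raise_min_s,raise_max_s raise duration bounds (seconds).
#' @param dwell_min_s,dwell_max_s dwell duration bounds (seconds).
#' @param max_feature_gap_s maximum gap between consecutive pattern
#'   elements (seconds).
#' @return a `drag_thresholds` list.
#' @export
drag_thresholds <- function(raise_min_s = 0.3, raise_max_s = 0.7,
                            dwell_min_s = 0.4, dwell_max_s = 8.0,
                            max_feature_gap_s = 0.5) {
  if (!(0 < raise_min_s && raise_min_s < raise_max_s)) {
    stop("parameter error: need 0 < raise_min_s < raise_max_s", call. = FALSE)
  }
  if (!(0 < dwell_min_s && dwell_min_s < dwell_max_s)) {
    stop("parameter error: need 0 < dwell_min_s < dwell_max_s", call. = FALSE)
  }
  if (max_feature_gap_s < 0) {
    stop("parameter error: max_feature_gap_s must be non-negative",
         call. = FALSE)
  }
  structure(list(raise_min_s = raise_min_s, raise_max_s = raise_max_s,
                 dwell_min_s = dwell_min_s, dwell_max_s = dwell_max_s,
                 max_feature_gap_s = max_feature_gap_s),
            class = "drag_thresholds")
}

# closed-interval membership with a small tolerance against floating
# point round-off in durations derived as t_end - t_start
in_bounds <- function(x, lo, hi, eps = 1e-9) x >= lo - eps & x <= hi + eps

#' Detect individual drags (stage 2)
#'
#' Greedy left-to-right scan over time-ordered motion-feature events for
#' the drag pattern: an in-bounds RAISE, followed (within
#' `max_feature_gap_s`) by an in-bounds DWELL, followed (within
#' `max_feature_gap_s`) by a LOWER of any duration. Consumed events are
#' not reused; emitted drags are disjoint and ordered, and every emitted
#' drag satisfies the duration bounds by construction.
#'
#' @param features motion-feature events (tibble with `kind`, `t_start`,
#'   `t_end`), ordered by `t_start`.
#' @param th a [drag_thresholds()].
#' @return tibble of drags: `t_start` (raise start), `t_end` (lower
#'   end), `raise_duration_s`, `dwell_duration_s`.
#' @export
detect_drags <- function(features, th = drag_thresholds()) {
  empty <- tibble::tibble(t_start = numeric(), t_end = numeric(),
                          raise_duration_s = numeric(),
                          dwell_duration_s = numeric())
  if (nrow(features) == 0L) return(empty)
  if (is.unsorted(features$t_start)) {
    stop("ordering error: features must be ordered by t_start", call. = FALSE)
  }
  f <- features[features$kind %in% c("RAISE", "DWELL", "LOWER"), ]
  if (nrow(f) == 0L) return(empty)
  dur <- f$t_end - f$t_start
  consumed <- rep(FALSE, nrow(f))
  raises <- which(f$kind == "RAISE" & in_bounds(dur, th$raise_min_s, th$raise_max_s))
  out <- list()
  last_end <- -Inf
  for (r in raises) {
    if (consumed[r] || f$t_start[r] < last_end) next
    dwells <- which(!consumed & f$kind == "DWELL" &
                      in_bounds(dur, th$dwell_min_s, th$dwell_max_s) &
                      f$t_start >= f$t_start[r] &
                      f$t_start - f$t_end[r] <= th$max_feature_gap_s + 1e-9)
    matched <- FALSE
    for (d in dwells) {
      lowers <- which(!consumed & f$kind == "LOWER" &
                        f$t_start >= f$t_start[d] &
                        f$t_start - f$t_end[d] <= th$max_feature_gap_s + 1e-9)
      if (length(lowers) > 0L) {
        l <- lowers[1L]
        consumed[c(r, d, l)] <- TRUE
        out[[length(out) + 1L]] <- tibble::tibble(
          t_start = f$t_start[r], t_end = f$t_end[l],
          raise_duration_s = dur[r], dwell_duration_s = dur[d])
        last_end <- f$t_end[l]
        matched <- TRUE
        break
      }
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}
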