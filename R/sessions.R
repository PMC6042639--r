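#' Stage-3 session rule configuration
#'
#' A run of detected drags is designated an instance of smoking a
#' cigarette when at least `min_drags` drags occur with every
#' consecutive inter-drag interval strictly under `max_gap_s`. Intervals
#' are measured start-to-start by default (robust to variable dwell
#' lengths); `gap_mode = "end_to_start"` switches to the gap between one
#' drag's end and the next drag's start.
#'
#' @param min_drags minimum number of drags in a run (default 6).
#' @param max_gap_s strict upper bound on the inter-drag interval in
#'   seconds (default 80).
#' @param gap_mode how the inter-drag interval is measured.
#' @return a `session_config` list.
#' @export
session_config <- function(min_drags = 6L, max_gap_s = 80,
                           gap_mode = c("start_to_start", "end_to_start")) {
  gap_mode <- match.arg(gap_mode)
  if (min_drags < 1L) stop("parameter error: min_drags must be >= 1",
                           call. = FALSE)
  if (max_gap_s <= 0) stop("parameter error: max_gap_s must be positive",
                           call. = FALSE)
  structure(list(min_drags = as.integer(min_drags), max_gap_s = max_gap_s,
                 gap_mode = gap_mode),
            class = "session_config")
}

#' Detect smoking instances (stage 3)
#'
#' Partitions time-ordered drags into maximal runs in which every
#' consecutive inter-drag interval is strictly below `max_gap_s`; a gap
#' at or above the bound resets the run. Each run containing at least
#' `min_drags` drags yields exactly one smoking instance spanning the
#' whole run (a long run is one episode, not several).
#'
#' @param drags tibble of drags (`t_start`, `t_end`), ordered and
#'   disjoint.
#' @param cfg a [session_config()].
#' @return tibble of instances: `t_start` (first drag start), `t_end`
#'   (last drag end), `n_drags`, `first_drag`, `last_drag` (row indices
#'   into `drags`).
#' @export
detect_smoking_instances <- function(drags, cfg = session_config()) {
  empty <- tibble::tibble(t_start = numeric(), t_end = numeric(),
                          n_drags = integer(), first_drag = integer(),
                          last_drag = integer())
  n <- nrow(drags)
  if (n == 0L) return(empty)
  if (is.unsorted(drags$t_start)) {
    stop("ordering error: drags must be ordered by t_start", call. = FALSE)
  }
  gaps <- if (n >= 2L) {
    if (cfg$gap_mode == "start_to_start") {
      drags$t_start[-1L] - drags$t_start[-n]
    } else {
      drags$t_start[-1L] - drags$t_end[-n]
    }
  } else numeric(0)
  run_id <- cumsum(c(1L, as.integer(gaps >= cfg$max_gap_s)))
  out <- list()
  for (id in unique(run_id)) {
    idx <- which(run_id == id)
    if (length(idx) >= cfg$min_drags) {
      out[[length(out) + 1L]] <- tibble::tibble(
        t_start = drags$t_start[idx[1L]],
        t_end = drags$t_end[idx[length(idx)]],
        n_drags = length(idx),
        first_drag = idx[1L], last_drag = idx[length(idx)])
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}
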