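EVENT_COLS <- c("label", "t_start", "t_end", "source")

#' Construct an event-interval table
#'
#' Annotation carrier used throughout the pipeline: one row per labelled
#' time interval with columns `label` (free text, e.g. `raise`, `drag`,
#' `smoking_instance`), `t_start`, `t_end` (seconds) and `source`
#' (`"truth"` or `"predicted"`). Every interval must satisfy
#' `t_start < t_end`.
#'
#' @param df data frame with the four schema columns, or `NULL` for an
#'   empty table.
#' @return a tibble of event intervals.
#' @export
event_intervals <- function(df = NULL) {
  if (is.null(df) || nrow(as.data.frame(df)) == 0L) {
    return(tibble::tibble(label = character(), t_start = numeric(),
                          t_end = numeric(), source = character()))
  }
  df <- tibble::as_tibble(df)
  missing <- setdiff(EVENT_COLS, names(df))
  if (length(missing) > 0L) {
    stop("event schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[EVENT_COLS]
  bad <- which(!(df$t_start < df$t_end))
  if (length(bad) > 0L) {
    stop("interval error: t_start >= t_end at row ", bad[1L], call. = FALSE)
  }
  df[order(df$t_start, df$t_end, df$label), ]
}

#' Check that same-label intervals within each source track do not overlap
#' @param events an event-interval table.
#' @return `TRUE` invisibly; errors on overlap.
#' @export
validate_event_tracks <- function(events) {
  events <- event_intervals(events)
  for (key in unique(paste(events$source, events$label))) {
    sub <- events[paste(events$source, events$label) == key, ]
    if (nrow(sub) >= 2L) {
      sub <- sub[order(sub$t_start), ]
      if (any(sub$t_start[-1L] < sub$t_end[-nrow(sub)] - 1e-9)) {
        stop("track error: overlapping '", sub$label[1L],
             "' intervals in source '", sub$source[1L], "'", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Read event intervals from CSV
#'
#' Schema: header `label,t_start,t_end,source`; leading `#` lines are
#' skipped as provenance comments.
#'
#' @param path path to a CSV file.
#' @return a tibble of event intervals.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  event_intervals(read_table_skip_comments(path))
}

#' Write event intervals to CSV
#' @param events an event-interval table.
#' @param path output path.
#' @param header optional provenance lines written as leading `#` comments.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, header = NULL) {
  events <- event_intervals(events)
  write_csv_with_header(as.data.frame(events), path, header)
}

filter_events <- function(events, label = NULL, source = NULL) {
  keep <- rep(TRUE, nrow(events))
  if (!is.null(label)) keep <- keep & events$label %in% label
  if (!is.null(source)) keep <- keep & events$source %in% source
  events[keep, ]
}
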