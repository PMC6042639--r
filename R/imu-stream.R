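#' @importFrom stats approx median rnorm runif rpois predict sd quantile
#' @importFrom utils head tail
NULL

IMU_COLS <- c("t", "ax", "ay", "az", "gx", "gy", "gz")

#' Construct an IMU stream
#'
#' An `imu_stream` is a tibble with one row per sample and columns
#' `t` (seconds since stream start), `ax, ay, az` (linear acceleration,
#' m/s^2, gravity-inclusive, device frame) and `gx, gy, gz` (angular
#' velocity, rad/s, device frame), carrying a nominal sampling rate as
#' the `rate_hz` attribute. Timestamps must be finite, non-negative and
#' strictly increasing; all channel values must be finite.
#'
#' @param samples data frame with columns `t,ax,ay,az,gx,gy,gz`.
#' @param rate_hz nominal sampling rate in Hz; if `NULL`, inferred as the
#'   reciprocal of the median inter-sample interval.
#' @return an `imu_stream` object.
#' @export
imu_stream <- function(samples, rate_hz = NULL) {
  samples <- tibble::as_tibble(samples)
  missing <- setdiff(IMU_COLS, names(samples))
  if (length(missing) > 0L) {
    stop("IMU schema error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  samples <- samples[IMU_COLS]
  for (col in IMU_COLS) {
    if (!all(is.finite(samples[[col]]))) {
      stop("IMU value error: non-finite values in column '", col, "'",
           call. = FALSE)
    }
  }
  if (nrow(samples) > 0L && samples$t[1L] < 0) {
    stop("IMU value error: negative timestamp at row 1", call. = FALSE)
  }
  check_monotone_t(samples$t)
  if (is.null(rate_hz)) {
    rate_hz <- if (nrow(samples) >= 2L) 1 / median(diff(samples$t)) else 100
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop("parameter error: rate_hz must be a positive number", call. = FALSE)
  }
  structure(samples, rate_hz = as.numeric(rate_hz),
            class = c("imu_stream", class(samples)))
}

check_monotone_t <- function(t) {
  if (length(t) >= 2L) {
    bad <- which(diff(t) <= 0)
    if (length(bad) > 0L) {
      stop("IMU ordering error: timestamps not strictly increasing at row ",
           bad[1L] + 1L, call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("<imu_stream> %d samples, %.6g Hz nominal, %.3f s span\n",
              nrow(x), attr(x, "rate_hz"),
              if (nrow(x) > 0L) x$t[nrow(x)] - x$t[1L] else 0))
  NextMethod()
}

#' Nominal sampling rate of a stream
#' @param stream an `imu_stream`.
#' @return sampling rate in Hz.
#' @export
stream_rate <- function(stream) attr(stream, "rate_hz")

# Drop leading '#' provenance/comment lines so round trips survive the
# header stamped by the CLI.
read_table_skip_comments <- function(path) {
  first <- readLines(path, n = 50L)
  skip <- 0L
  while (skip < length(first) && startsWith(first[skip + 1L], "#")) {
    skip <- skip + 1L
  }
  data.table::fread(path, skip = skip, header = TRUE, data.table = FALSE)
}

#' Read an IMU stream from CSV
#'
#' Expects the documented schema: a header row naming columns
#' `t,ax,ay,az,gx,gy,gz`, decimal point, UTF-8, one sample per row.
#' Leading lines starting with `#` are treated as provenance comments
#' and skipped. The nominal rate is inferred as the reciprocal of the
#' median inter-sample interval.
#'
#' @param path path to a CSV file.
#' @return an `imu_stream`.
#' @export
read_imu_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read_table_skip_comments(path)
  imu_stream(df)
}

#' Write an IMU stream to CSV
#'
#' @param stream an `imu_stream`.
#' @param path output path.
#' @param header optional character vector of provenance lines, written as
#'   leading `#` comments.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(stream, path, header = NULL) {
  write_csv_with_header(as.data.frame(stream)[IMU_COLS], path, header)
}

write_csv_with_header <- function(df, path, header = NULL) {
  if (!is.null(header)) {
    writeLines(paste0("# ", header), path)
    data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
  } else {
    data.table::fwrite(df, path)
  }
  invisible(path)
}

#' Resample a stream onto a uniform grid
#'
#' Linearly interpolates every channel onto a uniform grid running from
#' the first to the last timestamp at the requested rate. The pipeline
#' assumes a uniform 100 Hz input; irregularly sampled recordings should
#' pass through this first.
#'
#' @param stream an `imu_stream` with at least 2 samples.
#' @param rate_hz target rate in Hz (positive).
#' @return a uniform `imu_stream` at `rate_hz`.
#' @export
resample_stream <- function(stream, rate_hz = 100) {
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop("parameter error: rate_hz must be a positive number", call. = FALSE)
  }
  if (nrow(stream) < 2L) {
    stop("resample error: stream must have at least 2 samples", call. = FALSE)
  }
  t0 <- stream$t[1L]
  t1 <- stream$t[nrow(stream)]
  n_out <- floor((t1 - t0) * rate_hz + 1e-9) + 1L
  grid <- t0 + (seq_len(n_out) - 1L) / rate_hz
  out <- data.frame(t = grid)
  for (col in setdiff(IMU_COLS, "t")) {
    out[[col]] <- approx(stream$t, stream[[col]], xout = grid, rule = 2)$y
  }
  imu_stream(out, rate_hz = rate_hz)
}
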