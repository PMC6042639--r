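# Independent oracles and fixture builders shared across test files.

.test_cache <- new.env(parent = emptyenv())

# One trained stage-1 tree per test run (training is seeded, so this is
# purely a time saver, not a source of coupling between tests).
get_test_classifier <- function() {
  if (is.null(.test_cache$clf)) {
    .test_cache$clf <- train_default_classifier(seed = 99)
  }
  .test_cache$clf
}

# Build a motion-feature event table from kind/duration/gap vectors:
# event k starts gap[k] after event k-1 ends.
make_features <- function(kinds, durations, gaps = rep(0.1, length(kinds))) {
  t_start <- numeric(length(kinds))
  t_cur <- 0
  for (k in seq_along(kinds)) {
    t_cur <- t_cur + gaps[k]
    t_start[k] <- t_cur
    t_cur <- t_cur + durations[k]
  }
  tibble::tibble(kind = kinds, t_start = t_start,
                 t_end = t_start + durations, score = 1)
}

# Drag table with given start times (3 s nominal duration).
make_drags <- function(starts, duration = 3) {
  tibble::tibble(t_start = starts, t_end = starts + duration)
}

# --- stage-2 oracle: exhaustive search for the largest set of valid ---
# --- RAISE/DWELL/LOWER triplets that are event-disjoint and          ---
# --- time-disjoint, under the same bounds as detect_drags            ---
valid_triplets <- function(f, th) {
  dur <- f$t_end - f$t_start
  ok <- function(x, lo, hi) x >= lo - 1e-9 & x <= hi + 1e-9
  trip <- list()
  for (r in which(f$kind == "RAISE" & ok(dur, th$raise_min_s, th$raise_max_s))) {
    for (d in which(f$kind == "DWELL" & ok(dur, th$dwell_min_s, th$dwell_max_s))) {
      if (f$t_start[d] < f$t_start[r] ||
          f$t_start[d] - f$t_end[r] > th$max_feature_gap_s + 1e-9) next
      for (l in which(f$kind == "LOWER")) {
        if (f$t_start[l] < f$t_start[d] ||
            f$t_start[l] - f$t_end[d] > th$max_feature_gap_s + 1e-9) next
        trip[[length(trip) + 1L]] <- c(r, d, l)
      }
    }
  }
  trip
}

brute_force_drag_count <- function(features, th = drag_thresholds()) {
  f <- features[features$kind %in% c("RAISE", "DWELL", "LOWER"), ]
  trip <- valid_triplets(f, th)
  if (length(trip) == 0L) return(0L)
  span <- function(tr) c(f$t_start[tr[1L]], f$t_end[tr[3L]])
  best <- 0L
  recurse <- function(i, used, spans, count) {
    if (count + (length(trip) - i + 1L) <= best) return()
    if (i > length(trip)) {
      best <<- max(best, count)
      return()
    }
    tr <- trip[[i]]
    sp <- span(tr)
    disjoint <- !any(tr %in% used) &&
      (length(spans) == 0L ||
         !any(vapply(spans, function(s) sp[1L] < s[2L] && sp[2L] > s[1L], TRUE)))
    if (disjoint) {
      recurse(i + 1L, c(used, tr), c(spans, list(sp)), count + 1L)
    }
    recurse(i + 1L, used, spans, count)
    invisible()
  }
  recurse(1L, integer(0), list(), 0L)
  best
}

# Random feature sequences for the stage-2 equivalence check.
random_feature_sequence <- function(n_events) {
  kinds <- sample(c("RAISE", "DWELL", "LOWER", "OTHER"), n_events,
                  replace = TRUE, prob = c(0.3, 0.3, 0.3, 0.1))
  durations <- ifelse(kinds == "DWELL", runif(n_events, 0.1, 9),
                      runif(n_events, 0.1, 1.0))
  gaps <- runif(n_events, 0, 0.8)
  make_features(kinds, durations, gaps)
}

# --- stage-3 oracle: enumerate every maximal admissible run (all ---
# --- consecutive start-to-start gaps under the bound) directly    ---
brute_force_instances <- function(drags, cfg = session_config()) {
  n <- nrow(drags)
  if (n == 0L) return(tibble::tibble(t_start = numeric(), t_end = numeric(),
                                     n_drags = integer()))
  gaps <- if (n >= 2L) drags$t_start[-1L] - drags$t_start[-n] else numeric(0)
  admissible <- function(i, j) i == j || all(gaps[i:(j - 1L)] < cfg$max_gap_s)
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      maximal <- admissible(i, j) &&
        (i == 1L || gaps[i - 1L] >= cfg$max_gap_s) &&
        (j == n || gaps[j] >= cfg$max_gap_s)
      if (maximal && j - i + 1L >= cfg$min_drags) {
        out[[length(out) + 1L]] <- tibble::tibble(
          t_start = drags$t_start[i], t_end = drags$t_end[j],
          n_drags = j - i + 1L)
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(t_start = numeric(), t_end = numeric(),
                          n_drags = integer()))
  }
  do.call(rbind, out)
}

# --- evaluation oracle: maximum one-to-one matching cardinality by ---
# --- exhaustive recursion over admissible pred/truth pairs         ---
brute_force_match_count <- function(predicted, truth, tolerance_s = 0) {
  np <- nrow(predicted); nt <- nrow(truth)
  admissible <- matrix(FALSE, np, nt)
  for (p in seq_len(np)) {
    for (tr in seq_len(nt)) {
      ov <- min(predicted$t_end[p], truth$t_end[tr]) -
        max(predicted$t_start[p], truth$t_start[tr])
      admissible[p, tr] <- ov > 0 || -ov <= tolerance_s
    }
  }
  recurse <- function(p, used) {
    if (p > np) return(0L)
    best <- recurse(p + 1L, used)
    for (tr in which(admissible[p, ])) {
      if (!(tr %in% used)) {
        best <- max(best, 1L + recurse(p + 1L, c(used, tr)))
      }
    }
    best
  }
  recurse(1L, integer(0))
}

# Non-overlapping random interval track on [0, span].
random_track <- function(n, span = 100) {
  starts <- sort(runif(n, 0, span))
  ends <- starts + runif(n, 0.5, 4)
  ends <- pmin(ends, c(starts[-1L] - 0.01, span + 5))
  keep <- ends > starts
  tibble::tibble(t_start = starts[keep], t_end = ends[keep])
}
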