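#' Match predicted events to truth events
#'
#' One-to-one matching by maximal temporal overlap: candidate pairs
#' either overlap in time or have a boundary gap of at most
#' `tolerance_s`; pairs are accepted in order of decreasing overlap
#' (then increasing gap, then earlier truth start, then earlier
#' predicted start), and remaining unmatched predictions are then
#' completed along augmenting paths so the matching attains the maximum
#' possible number of pairs. The procedure is deterministic. Matched
#' pairs are the true positives; unmatched predictions are false
#' positives and unmatched truths false negatives.
#'
#' @param predicted,truth interval tables with `t_start`, `t_end`;
#'   each must be internally non-overlapping.
#' @param tolerance_s boundary tolerance in seconds for non-overlapping
#'   pairs.
#' @return a `match_result`: list with `pairs` (tibble `pred`, `truth`,
#'   `overlap`), `fp`, `fn` (row indices), `tp` count, `n_pred`,
#'   `n_truth`, `tolerance_s`.
#' @export
match_events <- function(predicted, truth, tolerance_s = 0) {
  check_no_overlap <- function(x, what) {
    if (nrow(x) >= 2L) {
      x <- x[order(x$t_start), ]
      if (any(x$t_start[-1L] < x$t_end[-nrow(x)] - 1e-9)) {
        stop("input error: overlapping intervals within ", what,
             call. = FALSE)
      }
    }
  }
  check_no_overlap(predicted, "predicted")
  check_no_overlap(truth, "truth")
  np <- nrow(predicted); nt <- nrow(truth)
  cand <- NULL
  if (np > 0L && nt > 0L) {
    grid <- expand.grid(pred = seq_len(np), truth = seq_len(nt))
    ov <- pmin(predicted$t_end[grid$pred], truth$t_end[grid$truth]) -
      pmax(predicted$t_start[grid$pred], truth$t_start[grid$truth])
    keep <- ov > 0 | -ov <= tolerance_s
    cand <- grid[keep, , drop = FALSE]
    cand$overlap <- pmax(ov[keep], 0)
    cand$gap <- pmax(-ov[keep], 0)
    cand <- cand[order(-cand$overlap, cand$gap, truth$t_start[cand$truth],
                       predicted$t_start[cand$pred]), , drop = FALSE]
  }
  match_of_pred <- rep(NA_integer_, np)
  match_of_truth <- rep(NA_integer_, nt)
  for (i in seq_len(NROW(cand))) {
    p <- cand$pred[i]; tr <- cand$truth[i]
    if (is.na(match_of_pred[p]) && is.na(match_of_truth[tr])) {
      match_of_pred[p] <- tr
      match_of_truth[tr] <- p
    }
  }
  # augmenting-path completion: the greedy overlap pass can strand a
  # prediction whose only admissible truth was claimed by a prediction
  # that had alternatives; alternating-path search fixes that without
  # disturbing which overlap-preferred pairs exist where no conflict does
  if (NROW(cand) > 0L) {
    adj <- split(seq_len(nrow(cand)), cand$pred)
    visited <- logical(nt)
    augment <- function(p) {
      for (i in adj[[as.character(p)]]) {
        tr <- cand$truth[i]
        if (visited[tr]) next
        visited[tr] <<- TRUE
        occupant <- match_of_truth[tr]
        if (is.na(occupant) || augment(occupant)) {
          match_of_pred[p] <<- tr
          match_of_truth[tr] <<- p
          return(TRUE)
        }
      }
      FALSE
    }
    for (p in seq_len(np)) {
      if (is.na(match_of_pred[p]) && !is.null(adj[[as.character(p)]])) {
        visited <- logical(nt)
        augment(p)
      }
    }
  }
  matched <- which(!is.na(match_of_pred))
  ov_final <- vapply(matched, function(p) {
    max(0, min(predicted$t_end[p], truth$t_end[match_of_pred[p]]) -
          max(predicted$t_start[p], truth$t_start[match_of_pred[p]]))
  }, 0)
  pairs <- tibble::tibble(pred = matched, truth = match_of_pred[matched],
                          overlap = ov_final)
  structure(list(pairs = pairs, fp = which(is.na(match_of_pred)),
                 fn = which(is.na(match_of_truth)), tp = nrow(pairs),
                 n_pred = np, n_truth = nt, tolerance_s = tolerance_s),
            class = "match_result")
}

#' Wilson score interval for a binomial proportion
#' @param k number of successes.
#' @param n number of trials.
#' @param level confidence level.
#' @return named vector `c(lower, upper)`; `NA` when `n == 0`.
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (n == 0) return(c(lower = NA_real_, upper = NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Score a match result
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN); either is flagged
#' undefined (NA) when its denominator is zero, never reported as 0.
#' Accuracy = (TP+TN)/(TP+TN+FP+FN) is available only in laboratory
#' mode, where true negatives were recorded; in free-living mode true
#' negatives are structurally absent (counting them would artificially
#' inflate performance) and accuracy cannot be computed. 95% Wilson
#' intervals accompany precision and recall.
#'
#' @param match a [match_events()] result, or a list with `tp`, `fp`,
#'   `fn` counts.
#' @param tn true-negative count (laboratory mode only).
#' @param mode `"free_living"` (no TN, no accuracy) or `"laboratory"`.
#' @return an `evaluation_report` list.
#' @export
score_match <- function(match, tn = NULL,
                        mode = if (is.null(tn)) "free_living" else "laboratory") {
  mode <- match.arg(mode, c("free_living", "laboratory"))
  if (mode == "laboratory" && is.null(tn)) {
    stop("mode error: laboratory scoring requires a true-negative count",
         call. = FALSE)
  }
  if (mode == "free_living" && !is.null(tn)) {
    stop("mode error: true negatives are not recorded in free-living mode",
         call. = FALSE)
  }
  tp <- if (inherits(match, "match_result")) match$tp else match$tp
  fp <- if (inherits(match, "match_result")) length(match$fp) else match$fp
  fn <- if (inherits(match, "match_result")) length(match$fn) else match$fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  accuracy <- if (mode == "laboratory") {
    (tp + tn) / (tp + tn + fp + fn)
  } else NA_real_
  structure(list(mode = mode, tp = tp, fp = fp, fn = fn,
                 tn = if (is.null(tn)) NA_integer_ else tn,
                 precision = precision, recall = recall, accuracy = accuracy,
                 precision_ci = wilson_ci(tp, tp + fp),
                 recall_ci = wilson_ci(tp, tp + fn)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat(sprintf("<evaluation_report> mode=%s TP=%d FP=%d FN=%d%s\n", x$mode,
              x$tp, x$fp, x$fn,
              if (!is.na(x$tn)) sprintf(" TN=%d", x$tn) else ""))
  cat(sprintf("  precision %s (95%% CI %s-%s)\n", fmt(x$precision),
              fmt(x$precision_ci[1L]), fmt(x$precision_ci[2L])))
  cat(sprintf("  recall    %s (95%% CI %s-%s)\n", fmt(x$recall),
              fmt(x$recall_ci[1L]), fmt(x$recall_ci[2L])))
  if (x$mode == "laboratory") cat(sprintf("  accuracy  %s\n", fmt(x$accuracy)))
  invisible(x)
}

#' Cohen's kappa for two aligned label sequences
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with
#' expected agreement `p_e` the sum over categories of the product of
#' the two marginal proportions. When both sequences are constant and
#' identical (`p_e = 1`), kappa is 1 by convention.
#'
#' @param labels_a,labels_b equal-length vectors (length >= 1) of
#'   categorical labels.
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("input error: label sequences differ in length", call. = FALSE)
  }
  if (length(labels_a) < 1L) {
    stop("input error: label sequences must be non-empty", call. = FALSE)
  }
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(as.character(labels_a), levels = lev)
  b <- factor(as.character(labels_b), levels = lev)
  p_o <- mean(a == b)
  p_e <- sum((table(a) / length(a)) * (table(b) / length(b)))
  if (1 - p_e < 1e-12) return(if (p_o >= 1 - 1e-12) 1 else 0)
  as.numeric((p_o - p_e) / (1 - p_e))
}

#' Presence-per-bin indicator for events
#'
#' Splits `[0, duration_s)` into consecutive bins of `bin_s` and marks a
#' bin positive when any event interval overlaps it. This is the unit
#' of agreement used when comparing detections against a diary of
#' smoking instances.
#'
#' @param events interval table with `t_start`, `t_end`.
#' @param duration_s recording length in seconds.
#' @param bin_s bin width in seconds (default 10 minutes).
#' @return logical vector, one element per bin.
#' @export
presence_bins <- function(events, duration_s, bin_s = 600) {
  n_bin <- max(1L, ceiling(duration_s / bin_s))
  starts <- (seq_len(n_bin) - 1L) * bin_s
  ends <- pmin(starts + bin_s, duration_s)
  vapply(seq_len(n_bin), function(i) {
    nrow(events) > 0L &&
      any(events$t_start < ends[i] & events$t_end > starts[i])
  }, TRUE)
}
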