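#' Detection parameters for the classical endpoints
#'
#' Defaults reflect a 120-fps recording calibrated at ~2 px/mm: a hindpaw
#' excursion of 18 px (~9 mm) below the beam surface counts as a slip, slip
#' events closer than 32 frames (~250 ms) are amalgamated into one, and a
#' detected event matches a human annotation within +/- 30 frames.
#'
#' @param spatial_threshold Pixels below the beam surface that define a slip.
#' @param merge_gap Frames; events with a smaller inter-event gap are merged.
#' @param match_tolerance Frames; matching window against annotations.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(spatial_threshold = 18, merge_gap = 32,
                             match_tolerance = 30) {
  stopifnot(spatial_threshold > 0, merge_gap > 0, match_tolerance > 0)
  structure(list(spatial_threshold = spatial_threshold, merge_gap = merge_gap,
                 match_tolerance = match_tolerance),
            class = "detection_params")
}

#' Time for the nose to cross the central beam region
#'
#' Entry is the first frame with the nose inside `[x_left, x_right)`; exit is
#' the first later frame with the nose at or beyond the boundary opposite the
#' entry side. Intermediate re-entries are ignored. Frames are 0-based.
#'
#' @param track A [tracking_table].
#' @param geom A [locate_region] result.
#' @return List with `seconds`, `direction` (`"left_to_right"` or
#'   `"right_to_left"`), `entry_frame`, `exit_frame` (0-based).
#' @export
time_to_cross <- function(track, geom) {
  x <- track$x[, "nose"]
  inside <- x >= geom$x_left & x < geom$x_right
  if (!any(inside)) stop("nose never entered the central region")
  entry <- which(inside)[1]
  from_left <- if (entry == 1) {
    x[entry] < (geom$x_left + geom$x_right) / 2
  } else {
    x[entry - 1] < geom$x_left
  }
  after <- seq(entry, length(x))
  exit <- if (from_left) after[x[after] >= geom$x_right][1]
          else after[x[after] < geom$x_left][1]
  if (is.na(exit)) stop("nose never exited past the far boundary")
  list(seconds = (exit - entry) / track$fps,
       direction = if (from_left) "left_to_right" else "right_to_left",
       entry_frame = entry - 1L, exit_frame = exit - 1L)
}

#' Detect hindpaw foot slips in a height series
#'
#' A slip is a maximal run of frames where the (surface-relative, up-positive)
#' height drops below `-spatial_threshold`. Runs whose inter-event gap
#' (`next onset - previous offset - 1`) is smaller than `merge_gap` frames are
#' amalgamated into a single event keeping the first onset, the last offset
#' and the deepest nadir.
#'
#' @param height Numeric vector of heights above the beam (pixels); element i
#'   is frame `frame0 + i - 1`.
#' @param params A [detection_params] list.
#' @param frame0 0-based frame index of the first element of `height`.
#' @return data.frame with columns `onset`, `offset` (inclusive), `nadir`
#'   (all 0-based frames) and `depth` (pixels below the surface, positive).
#' @export
detect_foot_slips <- function(height, params = detection_params(),
                              frame0 = 0L) {
  empty <- data.frame(onset = integer(), offset = integer(),
                      nadir = integer(), depth = numeric())
  if (!length(height)) return(empty)
  below <- height < -params$spatial_threshold
  if (!any(below)) return(empty)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  events <- data.frame(onset = starts[keep], offset = ends[keep])
  events$nadir <- vapply(seq_len(nrow(events)), function(i) {
    span <- events$onset[i]:events$offset[i]
    span[which.min(height[span])]
  }, integer(1))
  events$depth <- -height[events$nadir]
  events <- merge_slip_events(events, params$merge_gap, height)
  events$onset <- events$onset - 1L + as.integer(frame0)
  events$offset <- events$offset - 1L + as.integer(frame0)
  events$nadir <- events$nadir - 1L + as.integer(frame0)
  events
}

# Amalgamate events whose gap is below merge_gap; indices are 1-based into
# `height`. Idempotent: the output's pairwise gaps are all >= merge_gap.
merge_slip_events <- function(events, merge_gap, height) {
  if (nrow(events) < 2) return(events)
  events <- events[order(events$onset), ]
  out <- events[1, ]
  for (i in 2:nrow(events)) {
    gap <- events$onset[i] - out$offset[nrow(out)] - 1L
    if (gap < merge_gap) {
      j <- nrow(out)
      out$offset[j] <- events$offset[i]
      if (events$depth[i] > out$depth[j]) {
        out$depth[j] <- events$depth[i]
        out$nadir[j] <- events$nadir[i]
      }
    } else {
      out <- rbind(out, events[i, ])
    }
  }
  rownames(out) <- NULL
  out
}

#' Classical endpoints for one trial
#'
#' Combines [time_to_cross] with [detect_foot_slips] run on the hindpaw
#' height restricted to frames where the hindpaw x lies inside the central
#' region (the analysis window of the assay).
#'
#' @param track A [tracking_table].
#' @param geom A [locate_region] result.
#' @param params A [detection_params] list.
#' @return List of class `endpoint_result` with `time_to_cross`, `direction`,
#'   `n_slips`, `slips` (data.frame of events), `entry_frame`, `exit_frame`.
#' @export
trial_endpoints <- function(track, geom, params = detection_params()) {
  cross <- time_to_cross(track, geom)
  h <- height_above_beam(track, geom, "hindpaw")
  inside <- in_region(track, geom, "hindpaw")
  slips <- if (any(inside)) {
    first <- which(inside)[1]
    last <- which(inside)[length(which(inside))]
    detect_foot_slips(h[first:last], params, frame0 = first - 1L)
  } else {
    detect_foot_slips(numeric(0), params)
  }
  structure(list(time_to_cross = cross$seconds, direction = cross$direction,
                 n_slips = nrow(slips), slips = slips,
                 entry_frame = cross$entry_frame,
                 exit_frame = cross$exit_frame),
            class = "endpoint_result")
}

#' @export
print.endpoint_result <- function(x, ...) {
  cat(sprintf("<endpoint_result> %.3f s (%s), %d foot slip(s)\n",
              x$time_to_cross, x$direction, x$n_slips))
  invisible(x)
}

#' Match detected slip events against human annotations
#'
#' Greedy one-to-one matching in increasing frame order: each detection is
#' paired with the earliest still-unmatched annotation within
#' `+/- tolerance` frames (ties to the earlier annotation). Matched pairs are
#' true positives, unmatched annotations false negatives, unmatched
#' detections false positives. Precision or recall with a 0/0 denominator is
#' reported as 0 and flagged in `degenerate`.
#'
#' @param detected,annotated Sorted integer vectors of event frames.
#' @param tolerance Matching window in frames (>= 0).
#' @return List with `TP`, `FP`, `FN`, `recall`, `precision`, `f1`,
#'   `degenerate`.
#' @export
match_events <- function(detected, annotated, tolerance = 30) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  detected <- sort(as.numeric(detected))
  annotated <- sort(as.numeric(annotated))
  used <- rep(FALSE, length(annotated))
  tp <- 0L
  for (d in detected) {
    cand <- which(!used & abs(annotated - d) <= tolerance)
    if (length(cand)) {
      used[cand[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- length(detected) - tp
  fn <- length(annotated) - tp
  safe <- function(num, den) if (den == 0) 0 else num / den
  recall <- safe(tp, tp + fn)
  precision <- safe(tp, tp + fp)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(TP = tp, FP = fp, FN = fn, recall = recall, precision = precision,
       f1 = f1, degenerate = (tp + fn == 0) || (tp + fp == 0))
}

#' Pooled precision/recall across trials over a threshold sweep
#'
#' Re-runs slip detection at each candidate spatial threshold on every
#' trial's height series, pools TP/FP/FN against the fixed annotations, and
#' reports the pooled metrics per threshold. Since annotations are fixed,
#' `TP + FN` is constant across thresholds.
#'
#' @param trials List of lists, each with elements `height` (numeric series)
#'   and `annotated` (annotation frames on the same frame axis; the first
#'   height element is frame 0 unless a `frame0` element is supplied).
#' @param thresholds Numeric vector of spatial thresholds (pixels).
#' @param params A [detection_params] list (supplies `merge_gap` and
#'   `match_tolerance`).
#' @return data.frame, one row per threshold: `threshold`, `TP`, `FP`, `FN`,
#'   `recall`, `precision`, `f1`.
#' @export
threshold_sweep <- function(trials, thresholds, params = detection_params()) {
  if (!length(trials)) stop("need at least one trial")
  if (!length(thresholds)) stop("empty threshold list")
  out <- lapply(thresholds, function(th) {
    p <- detection_params(th, params$merge_gap, params$match_tolerance)
    tp <- fp <- fn <- 0L
    for (tr in trials) {
      ev <- detect_foot_slips(tr$height, p, frame0 = tr$frame0 %||% 0L)
      m <- match_events(ev$nadir, tr$annotated, params$match_tolerance)
      tp <- tp + m$TP; fp <- fp + m$FP; fn <- fn + m$FN
    }
    safe <- function(num, den) if (den == 0) 0 else num / den
    rec <- safe(tp, tp + fn); prec <- safe(tp, tp + fp)
    data.frame(threshold = th, TP = tp, FP = fp, FN = fn, recall = rec,
               precision = prec,
               f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
  })
  do.call(rbind, out)
}

#' Cohen's kappa on per-video slip counts
#'
#' Agreement between two raters scored per video: each video's total slip
#' count is treated as a categorical label, and Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)` is computed from the observed agreement and the
#' chance agreement implied by the raters' marginal count frequencies. When
#' both raters are constant and identical (`p_e = 1`), agreement is perfect
#' by construction and kappa is reported as 1 with `degenerate = TRUE`.
#'
#' @param counts_a,counts_b Integer vectors of per-video slip counts, equal
#'   length.
#' @return List with `kappa`, `p_o`, `p_e`, `degenerate`.
#' @export
kappa_per_video <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b))
    stop("count vectors must have equal length")
  if (!length(counts_a)) stop("need at least one video")
  n <- length(counts_a)
  cats <- sort(unique(c(counts_a, counts_b)))
  p_o <- mean(counts_a == counts_b)
  pa <- vapply(cats, function(k) mean(counts_a == k), numeric(1))
  pb <- vapply(cats, function(k) mean(counts_b == k), numeric(1))
  p_e <- sum(pa * pb)
  if (p_e >= 1)
    return(list(kappa = 1, p_o = p_o, p_e = p_e, degenerate = TRUE))
  list(kappa = (p_o - p_e) / (1 - p_e), p_o = p_o, p_e = p_e,
       degenerate = FALSE)
}
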