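#' The feature manifest
#'
#' Enumerates, in a fixed deterministic order, every engineered feature:
#' all C(13,2) = 78 pairwise body-part distances, the 4 joint angles (elbow,
#' ankle, knee, hip) and the 13 body-part heights above the beam surface,
#' each summarized by mean, min, max and variance, plus the animal sex and
#' weight and the two classical endpoints (number of foot slips, time to
#' cross) -- 78*4 + 4*4 + 13*4 + 2 + 2 = 384 entries. Distances and heights
#' are normalized by the mean elbow-shoulder distance (the reference
#' dimension) and are therefore unitless; angles are in degrees.
#'
#' @return data.frame of class `feature_registry` with columns `name`,
#'   `category` (distance/angle/height/meta/endpoint), `statistic`
#'   (mean/min/max/variance/none) and `constituents`.
#' @export
feature_registry <- function() {
  stats4 <- c("mean", "min", "max", "variance")
  rows <- list()
  pairs <- utils::combn(body_parts, 2)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    for (s in stats4)
      rows[[length(rows) + 1]] <- data.frame(
        name = paste("dist", a, b, s, sep = "_"), category = "distance",
        statistic = s, constituents = paste(a, b, sep = ","))
  }
  for (joint in names(joint_triplets()))
    for (s in stats4)
      rows[[length(rows) + 1]] <- data.frame(
        name = paste("angle", joint, s, sep = "_"), category = "angle",
        statistic = s,
        constituents = paste(joint_triplets()[[joint]], collapse = ","))
  for (p in body_parts)
    for (s in stats4)
      rows[[length(rows) + 1]] <- data.frame(
        name = paste("height", p, s, sep = "_"), category = "height",
        statistic = s, constituents = p)
  rows[[length(rows) + 1]] <- data.frame(
    name = "sex", category = "meta", statistic = "none", constituents = "")
  rows[[length(rows) + 1]] <- data.frame(
    name = "weight", category = "meta", statistic = "none", constituents = "")
  rows[[length(rows) + 1]] <- data.frame(
    name = "n_slips", category = "endpoint", statistic = "none",
    constituents = "")
  rows[[length(rows) + 1]] <- data.frame(
    name = "time_to_cross", category = "endpoint", statistic = "none",
    constituents = "")
  reg <- do.call(rbind, rows)
  rownames(reg) <- NULL
  class(reg) <- c("feature_registry", "data.frame")
  reg
}

#' Joint angle definitions
#'
#' The three anatomically adjacent keypoints defining each measured joint
#' angle; the angle is the interior angle at the middle point.
#' @return Named list of character triplets.
#' @export
joint_triplets <- function() {
  list(elbow = c("shoulder", "elbow", "forepaw"),
       ankle = c("knee", "ankle", "hindpaw"),
       knee = c("hip", "knee", "ankle"),
       hip = c("iliac_crest", "hip", "knee"))
}

#' Reference dimension: mean elbow-shoulder distance
#'
#' All distances and heights are normalized by this per-trial scalar to
#' remove body-size effects (the elbow-shoulder distance correlates strongly
#' with body weight).
#'
#' @param track A [tracking_table].
#' @param geom A [locate_region] result; only frames with the nose inside
#'   the central region contribute.
#' @return Positive scalar, pixels.
#' @export
reference_length <- function(track, geom) {
  fr <- analysis_frames(track, geom)
  d <- sqrt((track$x[fr, "elbow"] - track$x[fr, "shoulder"])^2 +
            (track$y[fr, "elbow"] - track$y[fr, "shoulder"])^2)
  ref <- mean(d)
  if (!is.finite(ref) || ref <= 0)
    stop("degenerate reference: elbow and shoulder coincide")
  ref
}

# Frames contributing to feature series: the nose-based crossing window
# clipped to frames with the nose inside the region. Falls back to all
# frames inside the region if the crossing is incomplete.
analysis_frames <- function(track, geom) {
  inside <- in_region(track, geom, "nose")
  if (!any(inside)) stop("nose never inside the central region")
  cross <- tryCatch(time_to_cross(track, geom), error = function(e) NULL)
  if (is.null(cross)) return(which(inside))
  span <- (cross$entry_frame + 1L):(cross$exit_frame + 1L)
  span[inside[span]]
}

#' Normalized pairwise distance series
#' @param track A [tracking_table].
#' @param partA,partB Body-part names.
#' @param ref Reference length in pixels (> 0).
#' @param frames Frame indices (1-based) to evaluate; default all.
#' @return Unitless numeric series.
#' @export
series_distance <- function(track, partA, partB, ref,
                            frames = seq_len(n_frames(track))) {
  check_part(track, partA); check_part(track, partB)
  stopifnot(ref > 0)
  sqrt((track$x[frames, partA] - track$x[frames, partB])^2 +
       (track$y[frames, partA] - track$y[frames, partB])^2) / ref
}

#' Joint angle series in degrees
#'
#' Interior angle at the middle point of the joint triplet, computed as the
#' arccosine of the normalized dot product of the two limb vectors, in
#' `[0, 180]`. Frames with a zero-length limb vector are interpolated from
#' neighboring frames and flagged via the `"interpolated"` attribute.
#'
#' @param track A [tracking_table].
#' @param joint One of `"elbow"`, `"ankle"`, `"knee"`, `"hip"`.
#' @param frames Frame indices (1-based) to evaluate; default all.
#' @return Numeric series of degrees, attribute `interpolated` = indices.
#' @export
series_angle <- function(track, joint, frames = seq_len(n_frames(track))) {
  tri <- joint_triplets()[[joint]]
  if (is.null(tri)) stop("unknown joint: ", joint)
  ax <- track$x[frames, tri[1]] - track$x[frames, tri[2]]
  ay <- track$y[frames, tri[1]] - track$y[frames, tri[2]]
  bx <- track$x[frames, tri[3]] - track$x[frames, tri[2]]
  by <- track$y[frames, tri[3]] - track$y[frames, tri[2]]
  na <- sqrt(ax^2 + ay^2); nb <- sqrt(bx^2 + by^2)
  cosang <- (ax * bx + ay * by) / (na * nb)
  deg <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  bad <- which(!is.finite(deg))
  if (length(bad)) {
    ok <- which(is.finite(deg))
    if (!length(ok)) stop("all frames degenerate for joint ", joint)
    deg <- stats::approx(ok, deg[ok], xout = seq_along(deg), rule = 2)$y
  }
  attr(deg, "interpolated") <- bad
  deg
}

#' Summary statistics of a feature series
#'
#' Mean, minimum, maximum and sample variance (denominator n - 1).
#'
#' @param series Numeric vector, length >= 2.
#' @return Named numeric vector `mean`, `min`, `max`, `variance`.
#' @export
summarize_series <- function(series) {
  if (length(series) < 2) stop("series must have length >= 2")
  c(mean = mean(series), min = min(series), max = max(series),
    variance = stats::var(series))
}

#' Engineer the full feature vector for one trial
#'
#' Computes every entry of the [feature_registry] in manifest order:
#' normalized distance summaries, joint-angle summaries, normalized height
#' summaries, sex encoded F = 0 / M = 1, weight in grams, and the classical
#' endpoints.
#'
#' @param track A [tracking_table].
#' @param geom A [locate_region] result.
#' @param meta List or one-row data.frame with at least `sex` ("F"/"M") and
#'   `weight` (grams).
#' @param endpoints A [trial_endpoints] result (computed if `NULL`).
#' @param registry A [feature_registry]; the default manifest if `NULL`.
#' @param params [detection_params] used when `endpoints` is `NULL`.
#' @return Named numeric vector aligned to the registry, with attribute
#'   `reference_length` (pixels).
#' @export
build_feature_vector <- function(track, geom, meta, endpoints = NULL,
                                 registry = NULL,
                                 params = detection_params()) {
  registry <- registry %||% feature_registry()
  if (is.null(endpoints)) endpoints <- trial_endpoints(track, geom, params)
  fr <- analysis_frames(track, geom)
  if (length(fr) < 2) stop("fewer than 2 analysis frames in the region")
  ref <- reference_length(track, geom)
  stats4 <- c("mean", "min", "max", "variance")
  values <- numeric(nrow(registry))
  names(values) <- registry$name
  pairs <- utils::combn(body_parts, 2)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    s <- summarize_series(series_distance(track, a, b, ref, fr))
    values[paste("dist", a, b, stats4, sep = "_")] <- s
  }
  for (joint in names(joint_triplets())) {
    s <- summarize_series(series_angle(track, joint, fr))
    values[paste("angle", joint, stats4, sep = "_")] <- s
  }
  for (p in body_parts) {
    h <- height_above_beam(track, geom, p)[fr] / ref
    values[paste("height", p, stats4, sep = "_")] <- summarize_series(h)
  }
  sex <- toupper(as.character(meta$sex))
  if (!sex %in% c("F", "M")) stop("sex must be F or M")
  values["sex"] <- if (sex == "M") 1 else 0
  values["weight"] <- as.numeric(meta$weight)
  values["n_slips"] <- endpoints$n_slips
  values["time_to_cross"] <- endpoints$time_to_cross
  bad <- names(values)[!is.finite(values)]
  if (length(bad))
    stop("non-finite feature value(s): ", paste(bad, collapse = ", "))
  attr(values, "reference_length") <- ref
  values
}

#' Feature table for a set of trials
#'
#' Applies [build_feature_vector] to each trial and binds the results with
#' the trial identifiers into one row per trial.
#'
#' @param tracks Named list of [tracking_table]s (names = video ids).
#' @param metadata data.frame with one row per video: `video_id`,
#'   `mouse_id`, `sex`, `weight`, `group`, `beam`, `trial` (and optionally
#'   `cohort`).
#' @param registry A [feature_registry]; default manifest if `NULL`.
#' @param params [detection_params] for the endpoint computation.
#' @return data.frame: identifier columns followed by one column per
#'   registry feature.
#' @export
build_feature_table <- function(tracks, metadata, registry = NULL,
                                params = detection_params()) {
  registry <- registry %||% feature_registry()
  rows <- lapply(seq_len(nrow(metadata)), function(i) {
    m <- metadata[i, ]
    track <- tracks[[as.character(m$video_id)]]
    if (is.null(track)) stop("no tracking table for video ", m$video_id)
    geom <- locate_region(track, beam_type = as.character(m$beam))
    v <- build_feature_vector(track, geom, m, registry = registry,
                              params = params)
    cbind(data.frame(video_id = m$video_id, mouse_id = m$mouse_id,
                     group = m$group, beam = m$beam, trial = m$trial,
                     stringsAsFactors = FALSE),
          as.data.frame(t(v)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Identifier columns of a feature table
#' @keywords internal
id_columns <- function() c("video_id", "mouse_id", "group", "beam", "trial")
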