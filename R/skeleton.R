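#' Average skeleton of one animal
#'
#' Pools all of an animal's trials and summarizes each body part by a
#' nose-anchored display position: the nose sits at x = 0 and every other
#' part at minus its mean euclidean distance from the nose, normalized by
#' the reference dimension (parts trail the nose of a mouse walking in the
#' +x direction); the display y is the mean normalized height above the
#' beam, and `y_var` is the per-trial variance of that normalized height,
#' averaged over trials. Only in-region frames contribute.
#'
#' @param tracks List of [tracking_table]s belonging to one animal.
#' @param geoms List of matching [locate_region] results (recycled if
#'   length 1).
#' @return data.frame of class `skeleton_summary`: `part`, `x_display`,
#'   `y_display`, `y_var`, plus attribute `n_trials`.
#' @export
skeleton_per_animal <- function(tracks, geoms) {
  stopifnot(length(tracks) >= 1)
  if (inherits(geoms, "beam_geometry")) geoms <- list(geoms)
  if (length(geoms) == 1) geoms <- rep(geoms, length(tracks))
  per_trial <- lapply(seq_along(tracks), function(i) {
    track <- tracks[[i]]; geom <- geoms[[i]]
    fr <- analysis_frames(track, geom)
    ref <- reference_length(track, geom)
    t(vapply(body_parts, function(p) {
      d <- sqrt((track$x[fr, p] - track$x[fr, "nose"])^2 +
                (track$y[fr, p] - track$y[fr, "nose"])^2) / ref
      h <- height_above_beam(track, geom, p)[fr] / ref
      c(x = -mean(d), y = mean(h), y_var = stats::var(h))
    }, numeric(3)))
  })
  agg <- Reduce(`+`, per_trial) / length(per_trial)
  out <- data.frame(part = body_parts, x_display = agg[, "x"],
                    y_display = agg[, "y"], y_var = agg[, "y_var"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_trials") <- length(tracks)
  class(out) <- c("skeleton_summary", "data.frame")
  out
}

#' Group-average skeleton
#'
#' Unweighted mean across animals of the display coordinates; `y_var` is the
#' mean of the per-animal variances.
#'
#' @param summaries List of [skeleton_per_animal] results.
#' @return A `skeleton_summary` with attribute `n_animals`.
#' @export
skeleton_group_mean <- function(summaries) {
  if (!length(summaries)) stop("no skeleton summaries supplied")
  stopifnot(all(vapply(summaries, inherits, logical(1), "skeleton_summary")))
  out <- summaries[[1]]
  num <- c("x_display", "y_display", "y_var")
  vals <- Reduce(`+`, lapply(summaries, function(s) as.matrix(s[, num])))
  out[, num] <- vals / length(summaries)
  attr(out, "n_animals") <- length(summaries)
  out
}

skeleton_polylines <- function() {
  list(c("nose", "eye", "shoulder", "elbow", "forepaw"),
       c("shoulder", "iliac_crest", "hip", "knee", "ankle", "hindpaw"),
       c("hip", "tail_base", "tail_center", "tail_tip"))
}

#' Render group skeletons to a figure file
#'
#' Draws each group's average skeleton as connected polylines
#' (head-forelimb, trunk-hindlimb and tail chains) with vertical bars of
#' +/- sqrt(y_var) around each body part, overlaid with a legend. The
#' layout is deterministic: identical input produces an identical file.
#'
#' @param group_summaries Named list of `skeleton_summary` objects.
#' @param path Output file; extension picks the device (`.svg` or `.pdf`).
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
render_skeletons <- function(group_summaries, path, width = 7, height = 4) {
  if (!length(group_summaries)) stop("no groups to render")
  if (is.null(names(group_summaries)))
    names(group_summaries) <- paste0("group", seq_along(group_summaries))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "svg") grDevices::svg(path, width = width, height = height)
  else grDevices::pdf(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  xs <- unlist(lapply(group_summaries, `[[`, "x_display"))
  ys <- unlist(lapply(group_summaries, function(s)
    c(s$y_display - sqrt(s$y_var), s$y_display + sqrt(s$y_var))))
  graphics::plot(NA, xlim = range(xs) + c(-0.5, 0.5), ylim = range(ys),
                 xlab = "normalized x (nose = 0)",
                 ylab = "normalized height above beam", bty = "l")
  graphics::abline(h = 0, col = "grey70", lty = 2)
  cols <- grDevices::hcl.colors(max(3, length(group_summaries)), "Dark 3")
  for (gi in seq_along(group_summaries)) {
    s <- group_summaries[[gi]]
    idx <- stats::setNames(seq_len(nrow(s)), s$part)
    for (chain in skeleton_polylines())
      graphics::lines(s$x_display[idx[chain]], s$y_display[idx[chain]],
                      col = cols[gi])
    graphics::points(s$x_display, s$y_display, pch = 16, col = cols[gi])
    graphics::segments(s$x_display, s$y_display - sqrt(s$y_var),
                       s$x_display, s$y_display + sqrt(s$y_var),
                       col = cols[gi])
  }
  graphics::legend("topleft", legend = names(group_summaries),
                   col = cols[seq_along(group_summaries)], lty = 1, pch = 16,
                   bty = "n")
  invisible(path)
}
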