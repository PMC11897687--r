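#' beamwalkr: automated beam-walk phenotyping from pose-estimation keypoints
#'
#' The package takes DeepLabCut-style keypoint tables of mice traversing a
#' 1-m elevated beam, automates the classical endpoints (time to cross the
#' central 80-cm region, hindpaw foot slips), engineers a normalized
#' posture/balance feature set, and discriminates experimental groups with a
#' nested leave-one-mouse-out random-forest workflow. See
#' \code{vignette("beamwalk-methods")} for the underlying model and the
#' design choices.
#'
#' @keywords internal
"_PACKAGE"

#' Canonical keypoint names
#'
#' The 13 tracked mouse body parts and the 5 beam reference markers. Two
#' vertical lines mark the extremities of the central 80-cm analysis region;
#' two optional dots encode the beam type; one auxiliary marker is carried
#' but unused by the analysis.
#'
#' @format Character vectors.
#' @export
body_parts <- c(
  "nose", "eye", "forepaw", "elbow", "shoulder",
  "hindpaw", "ankle", "knee", "hip", "iliac_crest",
  "tail_base", "tail_center", "tail_tip"
)

#' @rdname body_parts
#' @export
beam_markers <- c("line_left", "line_right", "dot_left", "dot_right", "aux")

all_keypoints <- function() c(body_parts, beam_markers)

#' Construct a tracking table
#'
#' A tracking table holds, for one video, the per-frame image coordinates and
#' tracking likelihood of every keypoint, plus the recording rate and trial
#' identifiers. Coordinates use the image convention: y increases downward.
#' Frames are indexed from 0.
#'
#' @param x,y,likelihood Numeric matrices, frames x keypoints, with column
#'   names covering all canonical keypoints (see [body_parts]).
#' @param fps Frames per second (> 0), nominally 120.
#' @param video_id,mouse_id Identifier strings.
#' @return An object of class `tracking_table`.
#' @export
tracking_table <- function(x, y, likelihood, fps = 120,
                           video_id = "video", mouse_id = "mouse") {
  stopifnot(is.matrix(x), is.matrix(y), is.matrix(likelihood))
  if (!identical(dim(x), dim(y)) || !identical(dim(x), dim(likelihood)))
    stop("x, y and likelihood must have identical dimensions")
  missing <- setdiff(all_keypoints(), colnames(x))
  if (length(missing))
    stop("missing required keypoint(s): ", paste(missing, collapse = ", "))
  if (nrow(x) < 2) stop("a tracking table needs at least 2 frames")
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0) stop("fps must be > 0")
  lk <- likelihood[, colnames(x), drop = FALSE]
  if (any(!is.finite(lk)) || any(lk < 0 | lk > 1))
    stop("likelihood values must lie in [0, 1]")
  structure(
    list(
      video_id = as.character(video_id), mouse_id = as.character(mouse_id),
      fps = as.numeric(fps),
      x = x[, all_keypoints(), drop = FALSE],
      y = y[, all_keypoints(), drop = FALSE],
      likelihood = lk[, all_keypoints(), drop = FALSE]
    ),
    class = "tracking_table"
  )
}

#' @export
print.tracking_table <- function(x, ...) {
  cat("<tracking_table> video", x$video_id, "mouse", x$mouse_id, "\n")
  cat(" ", n_frames(x), "frames at", x$fps, "fps,", ncol(x$x), "keypoints\n")
  invisible(x)
}

#' Number of frames in a tracking table
#' @param track A [tracking_table].
#' @export
n_frames <- function(track) nrow(track$x)

check_part <- function(track, part) {
  if (!part %in% colnames(track$x)) stop("unknown keypoint: ", part)
  part
}

#' Read a DeepLabCut-dialect keypoint CSV
#'
#' The file must carry the 3-row DLC header (scorer / bodyparts / coords)
#' with an (x, y, likelihood) column triplet per keypoint; the frame index is
#' implicit in row order, starting at 0. Keypoint names are mapped to the
#' canonical names through `alias`.
#'
#' @param path Path to the CSV file.
#' @param fps Frames per second of the recording.
#' @param video_id,mouse_id Identifiers; default to the file name stem.
#' @param alias Named character vector mapping file body-part names to
#'   canonical names, e.g. `c(Hind_paw = "hindpaw")`.
#' @return A [tracking_table].
#' @export
read_tracking <- function(path, fps = 120, video_id = NULL, mouse_id = NULL,
                          alias = NULL) {
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE)
  if (nrow(raw) < 5) stop("not a DLC keypoint file (too few rows): ", path)
  hdr <- tolower(raw[[1]][1:3])
  if (!identical(hdr, c("scorer", "bodyparts", "coords")))
    stop("expected DLC header rows scorer/bodyparts/coords in ", path)
  parts <- as.character(raw[2, -1])
  coords <- tolower(as.character(raw[3, -1]))
  if (!all(coords %in% c("x", "y", "likelihood")))
    stop("coords row must contain only x/y/likelihood in ", path)
  if (!is.null(alias)) {
    hit <- parts %in% names(alias)
    parts[hit] <- unname(alias[parts[hit]])
  }
  missing <- setdiff(all_keypoints(), unique(parts))
  if (length(missing))
    stop("missing required body part(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  body <- raw[-(1:3), -1, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (is.null(dim(num))) num <- matrix(num, nrow = 1)
  bad <- which(is.na(num) & !(toupper(as.matrix(body)) %in% c("NA", "NAN", "")),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at data row %d, column %d in %s",
                 bad[1, 1], bad[1, 2] + 1L, path))
  grab <- function(coord) {
    m <- num[, coords == coord, drop = FALSE]
    colnames(m) <- parts[coords == coord]
    m[, all_keypoints(), drop = FALSE]
  }
  stem <- sub("\\.[Cc][Ss][Vv]$", "", basename(path))
  tracking_table(grab("x"), grab("y"), grab("likelihood"), fps = fps,
                 video_id = video_id %||% stem, mouse_id = mouse_id %||% stem)
}

#' Write a tracking table as a DeepLabCut-dialect CSV
#'
#' Numeric cells are written with 17 significant digits so that
#' `read_tracking(write_tracking(t))` reproduces every value bit-exactly.
#'
#' @param track A [tracking_table].
#' @param path Output file path.
#' @param scorer Scorer string for the first header row.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(track, path, scorer = "beamwalkr") {
  kp <- colnames(track$x)
  header <- rbind(
    c("scorer", rep(scorer, 3 * length(kp))),
    c("bodyparts", rep(kp, each = 3)),
    c("coords", rep(c("x", "y", "likelihood"), length(kp)))
  )
  n <- n_frames(track)
  cells <- matrix("", n, 3 * length(kp))
  for (j in seq_along(kp)) {
    cells[, 3 * j - 2] <- sprintf("%.17g", track$x[, j])
    cells[, 3 * j - 1] <- sprintf("%.17g", track$y[, j])
    cells[, 3 * j] <- sprintf("%.17g", track$likelihood[, j])
  }
  body <- cbind(as.character(seq_len(n) - 1L), cells)
  utils::write.table(rbind(header, body), path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect the beam type from the dot markers
#'
#' The rigs mark the 16-mm square beam with a small dot on the right side,
#' the 9-mm square beam with a dot on the left side, and the 16-mm round
#' beam with no dot. A dot counts as confidently tracked when its median
#' likelihood over frames reaches `likelihood_floor`.
#'
#' @param track A [tracking_table].
#' @param likelihood_floor Confidence cutoff in `[0, 1]`.
#' @return One of `"BEAM1_16SQ"`, `"BEAM2_16RD"`, `"BEAM3_9SQ"`.
#' @export
detect_beam_type <- function(track, likelihood_floor = 0.6) {
  right <- stats::median(track$likelihood[, "dot_right"]) >= likelihood_floor
  left <- stats::median(track$likelihood[, "dot_left"]) >= likelihood_floor
  if (right && left)
    stop("ambiguous beam markers: both dots confidently tracked")
  if (right) "BEAM1_16SQ" else if (left) "BEAM3_9SQ" else "BEAM2_16RD"
}

#' Derive the beam geometry from the line markers
#'
#' The two vertical line markers delimit the central 80-cm analysis region.
#' Their median x positions give the half-open region interval
#' `[x_left, x_right)` and the pixel calibration `px_per_mm = width / 800`;
#' the beam surface is the least-squares line through the two per-marker
#' median `(x, y)` points (slope 0 when the x-span is under 1 px).
#'
#' @param track A [tracking_table].
#' @param beam_type Optional beam type label carried along (see
#'   [detect_beam_type]).
#' @return An object of class `beam_geometry` with fields `x_left`,
#'   `x_right`, `px_per_mm`, `surface_intercept`, `surface_slope`,
#'   `beam_type`.
#' @export
locate_region <- function(track, beam_type = NULL) {
  lx <- stats::median(track$x[, "line_left"])
  rx <- stats::median(track$x[, "line_right"])
  ly <- stats::median(track$y[, "line_left"])
  ry <- stats::median(track$y[, "line_right"])
  x_left <- min(lx, rx); x_right <- max(lx, rx)
  width <- x_right - x_left
  if (width <= 0) stop("beam region has non-positive width")
  slope <- if (abs(rx - lx) < 1) 0 else (ry - ly) / (rx - lx)
  intercept <- ly - slope * lx
  structure(
    list(x_left = x_left, x_right = x_right, px_per_mm = width / 800,
         surface_intercept = intercept, surface_slope = slope,
         beam_type = beam_type),
    class = "beam_geometry"
  )
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat("<beam_geometry>", if (!is.null(x$beam_type)) x$beam_type else "", "\n")
  cat(sprintf("  region [%.1f, %.1f) px, %.3f px/mm, surface y = %.2f %+.4f x\n",
              x$x_left, x$x_right, x$px_per_mm,
              x$surface_intercept, x$surface_slope))
  invisible(x)
}

#' Beam surface height at given x positions
#' @param geom A [locate_region] result.
#' @param x Pixel x positions.
#' @return Surface y (image convention) at each `x`.
#' @export
surface_y <- function(geom, x) geom$surface_intercept + geom$surface_slope * x

#' Interpolate low-confidence keypoint coordinates
#'
#' Frames where a body part's likelihood falls below `likelihood_floor` get
#' that part's x and y replaced by linear interpolation between the nearest
#' confident frames; runs of dropout at either end copy the nearest
#' confident frame. Likelihood values are left untouched. Only the 13 body
#' parts are gap-filled: beam markers are static (their medians are used
#' downstream) and the type-encoding dots are legitimately untracked on
#' beams without a dot.
#'
#' @param track A [tracking_table].
#' @param likelihood_floor Confidence cutoff in `[0, 1]`.
#' @return A [tracking_table] with gap-filled coordinates.
#' @export
clean_track <- function(track, likelihood_floor = 0.6) {
  n <- n_frames(track)
  for (part in body_parts) {
    ok <- track$likelihood[, part] >= likelihood_floor
    if (all(ok)) next
    if (!any(ok)) stop("no confident frames for keypoint: ", part)
    idx <- seq_len(n)
    track$x[, part] <- stats::approx(idx[ok], track$x[ok, part], xout = idx,
                                     rule = 2)$y
    track$y[, part] <- stats::approx(idx[ok], track$y[ok, part], xout = idx,
                                     rule = 2)$y
  }
  track
}

#' Height of a body part above the beam surface
#'
#' Converts image-convention y (down-positive) into an up-positive height:
#' `surface_y(x_part) - y_part`. Positive values are above the beam,
#' negative values below it.
#'
#' @param track A [tracking_table].
#' @param geom A [locate_region] result.
#' @param part Keypoint name.
#' @return Numeric vector of heights (pixels), one per frame.
#' @export
height_above_beam <- function(track, geom, part) {
  check_part(track, part)
  surface_y(geom, track$x[, part]) - track$y[, part]
}

#' Frames of a keypoint inside the central region
#' @param track A [tracking_table].
#' @param geom A [locate_region] result.
#' @param part Keypoint whose x position is tested.
#' @return Logical vector: x in `[x_left, x_right)` per frame.
#' @export
in_region <- function(track, geom, part = "nose") {
  x <- track$x[, check_part(track, part)]
  x >= geom$x_left & x < geom$x_right
}
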