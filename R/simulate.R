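#' Simulation parameters for a synthetic beam-walk trial
#'
#' The generator emulates the statistical structure of a side-view recording
#' of a mouse traversing a 1-m beam: a monotonically advancing nose, body
#' parts at template offsets behind/above it, sinusoidal limb oscillation,
#' optional hindpaw dips below the beam surface (foot slips) with controlled
#' depth and duration, Gaussian tracking jitter and likelihood dropouts.
#' Defaults are sized to the reference rig: 120 fps and 2 px/mm, so that the
#' 18 px slip threshold corresponds to ~9 mm.
#'
#' @param fps Frames per second.
#' @param x_left,x_right Pixel bounds of the central 80-cm region (half-open
#'   interval); their span fixes the calibration at `(x_right - x_left)/800`
#'   px per mm.
#' @param surface_intercept,surface_slope Beam surface line (image y, px).
#' @param speed Nose speed in px/frame; ignored when `region_frames` is set,
#'   in which case the speed is chosen so the nose spends exactly
#'   `region_frames` frames inside the region.
#' @param region_frames Optional exact number of frames between region entry
#'   and exit.
#' @param lead_frames Frames recorded before the nose reaches the region.
#' @param tail_frames Frames recorded after the nose passes the far bound.
#' @param template Named list with numeric vectors `dx_mm` (distance behind
#'   the nose along the beam) and `height_mm` (height above the surface),
#'   one entry per body part.
#' @param gait_parts Body parts that oscillate.
#' @param gait_amp_px,gait_period Sinusoid amplitude (px) and period (frames).
#' @param slips data.frame with columns `onset` (0-based absolute frame),
#'   `duration` (frames >= 1), `depth` (px below the surface, > 0), or NULL.
#' @param noise_sd Gaussian jitter SD in px applied to body-part coordinates.
#' @param var_mult Named multipliers of per-part oscillation amplitude
#'   (group-level variance effects).
#' @param dropout_rate Per-frame, per-part probability of a likelihood
#'   dropout; `dropout_likelihood` is the value emitted for dropped frames.
#' @param beam_type Beam type to encode through the dot markers.
#' @param seed Integer seed; same seed, same trial, bit for bit.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(fps = 120, x_left = 100, x_right = 1700,
                       surface_intercept = 300, surface_slope = 0,
                       speed = 4, region_frames = NULL,
                       lead_frames = 30, tail_frames = 30,
                       template = mouse_template(),
                       gait_parts = c("forepaw", "hindpaw", "ankle", "knee",
                                      "elbow"),
                       gait_amp_px = 2, gait_period = 15,
                       slips = NULL, noise_sd = 1, var_mult = NULL,
                       dropout_rate = 0, dropout_likelihood = 0.1,
                       beam_type = "BEAM1_16SQ", seed = 1) {
  stopifnot(x_right > x_left, fps > 0, dropout_rate >= 0, dropout_rate < 1)
  if (!is.null(slips)) {
    stopifnot(all(slips$depth > 0), all(slips$duration >= 1))
  }
  structure(as.list(environment()), class = "sim_params")
}

#' Default posture template of a simulated mouse
#'
#' Offsets approximate an adult mouse in side view: body length ~60 mm from
#' nose to hip, tail extending another ~70 mm, paws near the surface and
#' trunk points 15-35 mm above it.
#'
#' @return List with named vectors `dx_mm` and `height_mm` (one per body
#'   part).
#' @export
mouse_template <- function() {
  list(
    dx_mm = c(nose = 0, eye = 8, shoulder = 25, elbow = 30, forepaw = 32,
              iliac_crest = 55, hip = 62, knee = 68, ankle = 74,
              hindpaw = 78, tail_base = 85, tail_center = 110,
              tail_tip = 135),
    height_mm = c(nose = 25, eye = 30, shoulder = 28, elbow = 15,
                  forepaw = 2, iliac_crest = 32, hip = 28, knee = 15,
                  ankle = 8, hindpaw = 2, tail_base = 22, tail_center = 18,
                  tail_tip = 15)
  )
}

#' Apply a group effect to simulation parameters
#'
#' Group effects are additive shifts (in mm) on named template entries and
#' multiplicative factors on named parts' oscillation amplitude. The names of
#' the perturbed template parameters are recorded so that downstream tests
#' know which engineered features carry signal.
#'
#' @param params A [sim_params] list.
#' @param height_shift_mm,dx_shift_mm Named numeric vectors of additive
#'   shifts on `template$height_mm` / `template$dx_mm`.
#' @param var_mult Named numeric vector of per-part amplitude multipliers.
#' @return The modified [sim_params], with an `informative` attribute naming
#'   the shifted parameters.
#' @export
apply_group_effect <- function(params, height_shift_mm = NULL,
                               dx_shift_mm = NULL, var_mult = NULL) {
  info <- character()
  if (!is.null(height_shift_mm)) {
    params$template$height_mm[names(height_shift_mm)] <-
      params$template$height_mm[names(height_shift_mm)] + height_shift_mm
    info <- c(info, paste0("height.", names(height_shift_mm)))
  }
  if (!is.null(dx_shift_mm)) {
    params$template$dx_mm[names(dx_shift_mm)] <-
      params$template$dx_mm[names(dx_shift_mm)] + dx_shift_mm
    info <- c(info, paste0("dx.", names(dx_shift_mm)))
  }
  if (!is.null(var_mult)) {
    params$var_mult <- c(params$var_mult, var_mult)
    info <- c(info, paste0("var.", names(var_mult)))
  }
  attr(params, "informative") <- union(attr(params, "informative"), info)
  params
}

#' Generate one synthetic beam-walk trial
#'
#' Emits a [tracking_table] plus the exact ground truth it was built from:
#' the planted slip intervals, the noiseless region entry/exit frames and
#' the implied crossing time. With `noise_sd = 0` and no dropouts the output
#' is fully deterministic in the geometry; with any setting, the same seed
#' reproduces the trial bit for bit.
#'
#' @param params A [sim_params] list.
#' @param video_id,mouse_id Identifiers stamped on the tracking table.
#' @return List with `track` ([tracking_table]) and `truth` (list: `slips`
#'   data.frame, `entry_frame`, `exit_frame`, `seconds`, `px_per_mm`).
#' @export
generate_trial <- function(params, video_id = "sim", mouse_id = "m1") {
  p <- params
  set.seed(p$seed)
  width <- p$x_right - p$x_left
  if (!is.null(p$region_frames)) {
    k <- p$region_frames
    n <- p$lead_frames + k + p$tail_frames
    t <- seq_len(n) - 1L
    # hit the far bound exactly at frame lead + k: x = left + width * s/k
    nose_x <- p$x_left + width * (t - p$lead_frames) / k
  } else {
    k <- ceiling(width / p$speed)
    n <- p$lead_frames + k + p$tail_frames
    t <- seq_len(n) - 1L
    nose_x <- p$x_left + p$speed * (t - p$lead_frames)
  }
  px_mm <- width / 800
  entry <- p$lead_frames            # 0-based: first frame with x >= x_left
  exit <- p$lead_frames + k

  kp <- all_keypoints()
  X <- Y <- L <- matrix(0, n, length(kp), dimnames = list(NULL, kp))
  surf <- function(x) p$surface_intercept + p$surface_slope * x

  amp <- stats::setNames(rep(0, length(body_parts)), body_parts)
  amp[p$gait_parts] <- p$gait_amp_px
  if (!is.null(p$var_mult))
    amp[names(p$var_mult)] <- pmax(amp[names(p$var_mult)], 1) * p$var_mult
  phase <- stats::setNames(2 * pi * (seq_along(body_parts) - 1) /
                             length(body_parts), body_parts)

  for (part in body_parts) {
    x <- nose_x - p$template$dx_mm[[part]] * px_mm
    h <- rep(p$template$height_mm[[part]] * px_mm, n)
    if (amp[[part]] > 0)
      h <- h + amp[[part]] * sin(2 * pi * t / p$gait_period + phase[[part]])
    if (part == "hindpaw" && !is.null(p$slips) && nrow(p$slips)) {
      for (i in seq_len(nrow(p$slips))) {
        on <- p$slips$onset[i]; dur <- p$slips$duration[i]
        dep <- p$slips$depth[i]
        fr <- on:(on + dur - 1L)
        fr <- fr[fr >= 0 & fr < n]
        if (!length(fr)) stop("slip ", i, " lies outside the recording")
        s <- (fr - on + 0.5) / dur
        w <- sin(pi * s)
        h[fr + 1L] <- h[fr + 1L] - (h[fr + 1L] + dep) * w
      }
    }
    X[, part] <- x + stats::rnorm(n, 0, p$noise_sd)
    Y[, part] <- surf(x) - h + stats::rnorm(n, 0, p$noise_sd)
    L[, part] <- 0.99
  }

  # beam markers: static, tracked with the same jitter
  marker <- function(x0, y0, lik) {
    c(x0, y0, lik)
  }
  dots <- switch(p$beam_type,
    BEAM1_16SQ = list(dot_left = 0.02, dot_right = 0.99),
    BEAM2_16RD = list(dot_left = 0.02, dot_right = 0.02),
    BEAM3_9SQ = list(dot_left = 0.99, dot_right = 0.02),
    stop("unknown beam_type: ", p$beam_type))
  marker_pos <- list(
    line_left = c(p$x_left, surf(p$x_left)),
    line_right = c(p$x_right, surf(p$x_right)),
    dot_left = c(p$x_left - 40, surf(p$x_left - 40) + 6),
    dot_right = c(p$x_right + 40, surf(p$x_right + 40) + 6),
    aux = c((p$x_left + p$x_right) / 2, surf((p$x_left + p$x_right) / 2))
  )
  for (mk in beam_markers) {
    X[, mk] <- marker_pos[[mk]][1] + stats::rnorm(n, 0, p$noise_sd)
    Y[, mk] <- marker_pos[[mk]][2] + stats::rnorm(n, 0, p$noise_sd)
    L[, mk] <- if (mk %in% names(dots)) dots[[mk]] else 0.99
  }

  if (p$dropout_rate > 0) {
    drop <- matrix(stats::runif(n * length(body_parts)) < p$dropout_rate,
                   n, length(body_parts))
    L[, body_parts][drop] <- p$dropout_likelihood
  }

  truth_slips <- if (!is.null(p$slips) && nrow(p$slips)) {
    data.frame(onset = p$slips$onset,
               offset = p$slips$onset + p$slips$duration - 1L,
               depth = p$slips$depth)
  } else {
    data.frame(onset = integer(), offset = integer(), depth = numeric())
  }
  list(
    track = tracking_table(X, Y, L, fps = p$fps, video_id = video_id,
                           mouse_id = mouse_id),
    truth = list(slips = truth_slips, entry_frame = entry, exit_frame = exit,
                 seconds = (exit - entry) / p$fps, px_per_mm = px_mm,
                 informative = attr(params, "informative"))
  )
}

#' Place n slips evenly inside the crossing window
#'
#' Helper producing a slip table whose onsets start after region entry and
#' are separated by `spacing` frames.
#'
#' @param params A [sim_params] list.
#' @param n Number of slips.
#' @param depth Depth in px below the surface.
#' @param duration Duration in frames.
#' @param spacing Frames between consecutive onsets.
#' @return data.frame suitable for `sim_params(slips = ...)`.
#' @export
plant_slips <- function(params, n, depth = 30, duration = 10, spacing = 100) {
  if (n == 0)
    return(data.frame(onset = integer(), duration = integer(),
                      depth = numeric()))
  win <- slip_window(params, duration)
  last <- win$start + spacing * (n - 1L) + duration
  if (last > win$end)
    stop("cannot fit ", n, " slips at spacing ", spacing,
         " inside the hindpaw's in-region window")
  data.frame(onset = win$start + spacing * (seq_len(n) - 1L),
             duration = duration, depth = depth)
}

# Frame window in which a planted slip is guaranteed to fall inside the
# hindpaw's in-region span: the hindpaw trails the nose, so it enters the
# region dx_hindpaw/speed frames after the nose does.
slip_window <- function(params, duration = 10) {
  width <- params$x_right - params$x_left
  k <- if (!is.null(params$region_frames)) params$region_frames else
    ceiling(width / params$speed)
  speed <- width / k
  lag <- ceiling(params$template$dx_mm[["hindpaw"]] * (width / 800) / speed)
  list(start = params$lead_frames + lag + 10L,
       end = params$lead_frames + k)
}

# Largest slip count that plant_slips() can fit for these parameters.
max_plantable_slips <- function(params, duration = 10, spacing = 100) {
  win <- slip_window(params, duration)
  max(0L, (win$end - win$start - duration) %/% spacing + 1L)
}

#' Generate a full synthetic experiment
#'
#' Simulates `n_per_group` mice per group, each crossing each beam
#' `trials_per_mouse` times. Mice get log-normal random effects on body size
#' and speed and a small posture offset; body weight is generated from the
#' animal's elbow-shoulder template length (its strong anatomical correlate)
#' plus noise. Group effects are applied through [apply_group_effect].
#'
#' @param n_per_group Mice per group (>= 2).
#' @param group_effects Named list: one entry per group, each a list with
#'   optional `height_shift_mm`, `dx_shift_mm`, `var_mult` (see
#'   [apply_group_effect]); use `list()` for the control group.
#' @param trials_per_mouse Trials per mouse and beam (default 2).
#' @param beams Character vector of beam types.
#' @param base_params [sim_params] shared by all trials.
#' @param n_slips_lambda Poisson mean of planted slips per trial.
#' @param seed Master seed; all per-mouse and per-trial randomness derives
#'   from it.
#' @param cohort Cohort label stamped in the metadata.
#' @return List with `tracks` (named list of tracking tables), `metadata`
#'   (data.frame), `truth` (named list per video) and `informative`
#'   (template parameters perturbed by any group effect).
#' @export
generate_experiment <- function(n_per_group = 8,
                                group_effects = list(WT = list(),
                                                     KO = list()),
                                trials_per_mouse = 2,
                                beams = "BEAM1_16SQ",
                                base_params = sim_params(),
                                n_slips_lambda = 1,
                                seed = 1, cohort = "cohort1") {
  stopifnot(n_per_group >= 2, length(group_effects) >= 1)
  groups <- names(group_effects)
  set.seed(seed)
  mice <- data.frame(
    mouse_id = sprintf("m%02d", seq_len(n_per_group * length(groups))),
    group = rep(groups, each = n_per_group),
    sex = rep_len(c("F", "M"), n_per_group * length(groups)),
    stringsAsFactors = FALSE
  )
  mice$size_mult <- stats::rlnorm(nrow(mice), 0, 0.05)
  mice$speed_mult <- stats::rlnorm(nrow(mice), 0, 0.08)
  mice$height_off_mm <- stats::rnorm(nrow(mice), 0, 0.8)

  tmpl <- base_params$template
  ref_mm <- sqrt((tmpl$dx_mm[["elbow"]] - tmpl$dx_mm[["shoulder"]])^2 +
                 (tmpl$height_mm[["elbow"]] - tmpl$height_mm[["shoulder"]])^2)
  mice$weight <- round(1.8 * ref_mm * mice$size_mult +
                         stats::rnorm(nrow(mice), 0, 0.8), 1)

  tracks <- list(); truth <- list(); meta <- list()
  informative <- character()
  counter <- 0L
  for (i in seq_len(nrow(mice))) {
    for (b in seq_along(beams)) {
      for (tr in seq_len(trials_per_mouse)) {
        counter <- counter + 1L
        vid <- sprintf("%s_%s_b%d_t%d", cohort, mice$mouse_id[i], b, tr)
        p <- base_params
        p$beam_type <- beams[b]
        p$template$dx_mm <- p$template$dx_mm * mice$size_mult[i]
        p$template$height_mm <- p$template$height_mm * mice$size_mult[i] +
          mice$height_off_mm[i]
        p$speed <- p$speed * mice$speed_mult[i]
        eff <- group_effects[[mice$group[i]]]
        if (length(eff)) {
          p <- do.call(apply_group_effect, c(list(params = p), eff))
          informative <- union(informative, attr(p, "informative"))
        }
        p$seed <- (seed + 7919L * counter) %% 2147483647L
        set.seed(p$seed)
        n_slips <- min(stats::rpois(1, n_slips_lambda),
                       max_plantable_slips(p, duration = 10, spacing = 120))
        p$slips <- plant_slips(p, n_slips, depth = 25 + stats::runif(1, 0, 10),
                               duration = 10,
                               spacing = 120)
        g <- generate_trial(p, video_id = vid, mouse_id = mice$mouse_id[i])
        tracks[[vid]] <- g$track
        truth[[vid]] <- g$truth
        meta[[vid]] <- data.frame(
          video_id = vid, mouse_id = mice$mouse_id[i], sex = mice$sex[i],
          weight = mice$weight[i], group = mice$group[i],
          beam = beams[b], trial = tr, cohort = cohort,
          fps = base_params$fps, stringsAsFactors = FALSE)
      }
    }
  }
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  list(tracks = tracks, metadata = metadata, truth = truth,
       informative = informative)
}

#' Simulate a feature-level experiment
#'
#' Draws a trials x features matrix directly at the feature level: every
#' feature is the sum of a per-mouse random effect (SD `mouse_sd`) and
#' per-trial noise (SD `trial_sd`); in the second group, `n_informative`
#' features are additionally shifted by `effect_size * mouse_sd`. This is
#' the study-condition generator for calibrating the nested
#' cross-validation: effect size 0 gives an exact permutation null.
#'
#' @param n_mice Total mice, split evenly over two groups ("A" control,
#'   "B" shifted).
#' @param n_features Number of features.
#' @param n_informative Number of shifted features (the first
#'   `n_informative` columns).
#' @param effect_size Group shift in units of the mouse-level SD.
#' @param trials Trials per mouse.
#' @param mouse_sd,trial_sd Random-effect and residual SDs.
#' @param seed Integer seed.
#' @return List of class `experiment_dataset`: `features` (matrix with
#'   rownames = trial ids), `labels`, `mouse_ids`, `informative` (feature
#'   names carrying signal).
#' @export
simulate_feature_experiment <- function(n_mice = 16, n_features = 120,
                                        n_informative = 10, effect_size = 0,
                                        trials = 2, mouse_sd = 1,
                                        trial_sd = 0.5, seed = 1) {
  stopifnot(n_mice %% 2 == 0, n_informative <= n_features)
  set.seed(seed)
  fnames <- sprintf("f%03d", seq_len(n_features))
  labels <- rep(c("A", "B"), each = n_mice / 2)
  mouse_eff <- matrix(stats::rnorm(n_mice * n_features, 0, mouse_sd),
                      n_mice, n_features)
  shift <- matrix(0, n_mice, n_features)
  if (n_informative > 0)
    shift[labels == "B", seq_len(n_informative)] <- effect_size * mouse_sd
  rows <- list(); row_labels <- character(); row_mice <- character()
  for (i in seq_len(n_mice)) {
    for (tr in seq_len(trials)) {
      rows[[length(rows) + 1]] <- mouse_eff[i, ] + shift[i, ] +
        stats::rnorm(n_features, 0, trial_sd)
      row_labels <- c(row_labels, labels[i])
      row_mice <- c(row_mice, sprintf("m%02d", i))
    }
  }
  feat <- do.call(rbind, rows)
  colnames(feat) <- fnames
  rownames(feat) <- sprintf("%s_t%d", row_mice,
                            rep(seq_len(trials), n_mice))
  experiment_dataset(feat, row_labels, row_mice,
                     informative = fnames[seq_len(n_informative)][n_informative > 0])
}
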