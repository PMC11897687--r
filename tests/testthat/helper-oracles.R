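# Independent oracles and small fixture builders used across the suite.

# Brute-force run-length slip scanner: frame-by-frame loop, then an explicit
# merge pass. Kept deliberately naive and separate from the package's
# vectorized implementation.
oracle_slips <- function(height, spatial_threshold = 18, merge_gap = 32) {
  runs <- list()
  cur <- NULL
  for (i in seq_along(height)) {
    if (height[i] < -spatial_threshold) {
      if (is.null(cur)) cur <- c(i, i) else cur[2] <- i
    } else if (!is.null(cur)) {
      runs[[length(runs) + 1]] <- cur; cur <- NULL
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
  if (!length(runs)) return(data.frame(onset = integer(), offset = integer()))
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] - last[2] - 1 < merge_gap) {
      merged[[length(merged)]] <- c(last[1], r[2])
    } else {
      merged[[length(merged) + 1]] <- r
    }
  }
  data.frame(onset = vapply(merged, `[`, numeric(1), 1) - 1,
             offset = vapply(merged, `[`, numeric(1), 2) - 1)
}

# Exact two-sided sign-flip distribution of the Wilcoxon signed-rank W for
# small n (all 2^n sign assignments, tied ranks allowed).
oracle_signed_rank_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(1, p)
}

# A perfectly rigid mouse translating at constant speed: no gait, no noise,
# no slips. Useful wherever exact zero-variance output is expected.
rigid_trial <- function(seed = 1, region_frames = NULL, speed = 4) {
  p <- sim_params(noise_sd = 0, gait_amp_px = 0, speed = speed,
                  region_frames = region_frames, seed = seed)
  generate_trial(p)
}

# Apply scale-and-translate (a rotation-free similarity transform) to every
# keypoint of a tracking table, beam markers included.
transform_track <- function(track, scale = 1, dx = 0, dy = 0) {
  track$x <- track$x * scale + dx
  track$y <- track$y * scale + dy
  track
}

fast_cv_config <- function(seed = 1, n_select = 50) {
  cv_config(n_select = n_select,
            hyper_grid = list(num_trees = c(100), max_depth = c(3, 0),
                              min_node_size = c(1)),
            rfe_num_trees = 50, seed = seed)
}
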