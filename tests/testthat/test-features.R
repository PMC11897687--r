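test_that("the manifest enumerates 384 features with the documented split", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 384)
  expect_false(anyDuplicated(reg$name) > 0)
  tab <- table(reg$category)
  expect_equal(as.integer(tab[c("distance", "angle", "height")]),
               c(78L, 4L, 13L) * 4L)
  expect_equal(as.integer(tab["meta"]), 2L)
  expect_equal(as.integer(tab["endpoint"]), 2L)
  # exactly C(13,2) distinct pairs, no beam markers anywhere
  dist_names <- reg$constituents[reg$category == "distance"]
  expect_equal(length(unique(dist_names)), choose(13, 2))
  expect_false(any(vapply(beam_markers, function(m)
    any(grepl(m, reg$constituents)), logical(1))))
})

test_that("reference length is the mean elbow-shoulder distance", {
  g <- rigid_trial(seed = 1)
  geom <- locate_region(g$track)
  t2 <- g$track
  fr <- seq_len(n_frames(t2))
  t2$x[, "elbow"] <- 0; t2$y[, "elbow"] <- 0
  t2$x[, "shoulder"] <- 3; t2$y[, "shoulder"] <- 4
  expect_equal(reference_length(t2, geom), 5)
  # alternating distances 4 and 6 average to 5
  t2$x[, "shoulder"] <- rep_len(c(4, 6), n_frames(t2)); t2$y[, "shoulder"] <- 0
  expect_equal(reference_length(t2, geom), 5)
  # homogeneity: scaling all coordinates doubles the reference
  t3 <- transform_track(g$track, scale = 2)
  expect_equal(reference_length(t3, locate_region(t3)),
               2 * reference_length(g$track, geom))
  # coincident points throughout -> error
  t4 <- g$track
  t4$x[, "elbow"] <- t4$x[, "shoulder"]; t4$y[, "elbow"] <- t4$y[, "shoulder"]
  expect_error(reference_length(t4, geom), "reference")
})

test_that("normalized distances cancel a global scale", {
  g <- rigid_trial(seed = 1)
  expect_equal(unique(series_distance(g$track, "hip", "hip", 5)), 0)
  ref <- reference_length(g$track, locate_region(g$track))
  d0 <- series_distance(g$track, "nose", "tail_tip", ref)
  t2 <- transform_track(g$track, scale = 3, dx = 11, dy = -7)
  d1 <- series_distance(t2, "nose", "tail_tip",
                        reference_length(t2, locate_region(t2)))
  expect_equal(d1, d0)
  expect_error(series_distance(g$track, "nose", "whisker", 1), "unknown")
})

test_that("joint angles follow the interior-angle definition", {
  g <- rigid_trial(seed = 1)
  set_pts <- function(track, shoulder, elbow, forepaw) {
    track$x[, "shoulder"] <- shoulder[1]; track$y[, "shoulder"] <- shoulder[2]
    track$x[, "elbow"] <- elbow[1]; track$y[, "elbow"] <- elbow[2]
    track$x[, "forepaw"] <- forepaw[1]; track$y[, "forepaw"] <- forepaw[2]
    track
  }
  t90 <- set_pts(g$track, c(0, 1), c(0, 0), c(1, 0))
  expect_equal(unique(series_angle(t90, "elbow")), 90)
  t45 <- set_pts(g$track, c(1, 1), c(0, 0), c(1, 0))
  expect_equal(unique(series_angle(t45, "elbow")), 45)
  tcol <- set_pts(g$track, c(-1, 0), c(0, 0), c(1, 0))
  expect_equal(unique(series_angle(tcol, "elbow")), 180)
  # a degenerate frame is interpolated from its neighbours and flagged
  tdeg <- set_pts(g$track, c(0, 1), c(0, 0), c(1, 0))
  tdeg$x[5, "shoulder"] <- 0; tdeg$y[5, "shoulder"] <- 0
  a <- series_angle(tdeg, "elbow")
  expect_equal(a[5], 90)
  expect_equal(attr(a, "interpolated"), 5L)
  expect_error(series_angle(g$track, "wrist"), "unknown joint")
})

test_that("series summaries use the sample (n-1) variance", {
  expect_equal(summarize_series(rep(3, 10)),
               c(mean = 3, min = 3, max = 3, variance = 0))
  s <- summarize_series(c(0, 1, 2, 3))
  expect_equal(unname(s), c(1.5, 0, 3, 5 / 3))
  # translation shifts the mean, preserves the variance
  s2 <- summarize_series(c(0, 1, 2, 3) + 10)
  expect_equal(unname(s2["mean"]), 11.5)
  expect_equal(s2["variance"], s["variance"])
  expect_error(summarize_series(1), "length")
})

test_that("a rigid mouse yields zero variance for distances and angles", {
  g <- rigid_trial(seed = 1)
  geom <- locate_region(g$track)
  v <- build_feature_vector(g$track, geom, list(sex = "M", weight = 25))
  reg <- feature_registry()
  var_feats <- reg$name[reg$statistic == "variance" &
                          reg$category %in% c("distance", "angle")]
  expect_true(all(abs(v[var_feats]) < 1e-20))
  expect_equal(unname(v["sex"]), 1)
  expect_equal(unname(v["weight"]), 25)
})

test_that("feature vectors have manifest length and invariance to zoom", {
  p <- sim_params(seed = 6, noise_sd = 1)
  p$slips <- plant_slips(p, 1)
  g <- generate_trial(p)
  geom <- locate_region(g$track)
  meta <- list(sex = "F", weight = 21.5)
  v0 <- build_feature_vector(g$track, geom, meta)
  expect_length(v0, 384)
  expect_identical(names(v0), feature_registry()$name)
  expect_true(all(is.finite(v0)))

  # pure power-of-two camera zoom: every feature is bit-identical
  t2 <- transform_track(g$track, scale = 2)
  v1 <- build_feature_vector(t2, locate_region(t2), meta)
  strip <- function(v) { attr(v, "reference_length") <- NULL; v }
  expect_identical(strip(v1), strip(v0))
  expect_equal(attr(v1, "reference_length"),
               2 * attr(v0, "reference_length"))
  # adding a translation keeps features equal to machine precision
  t3 <- transform_track(g$track, scale = 2, dx = 64, dy = -32)
  v2 <- build_feature_vector(t3, locate_region(t3), meta)
  expect_equal(strip(v2), strip(v0), tolerance = 1e-12)
})

test_that("two runs over the same input give bit-identical vectors", {
  g <- generate_trial(sim_params(seed = 10, noise_sd = 2))
  geom <- locate_region(g$track)
  v1 <- build_feature_vector(g$track, geom, list(sex = "F", weight = 20))
  v2 <- build_feature_vector(g$track, geom, list(sex = "F", weight = 20))
  expect_identical(v1, v2)
})

test_that("feature tables carry one row per trial with id columns first", {
  exp <- generate_experiment(n_per_group = 2, seed = 3,
                             group_effects = list(WT = list(), KO = list()))
  tab <- build_feature_table(exp$tracks, exp$metadata)
  expect_equal(nrow(tab), nrow(exp$metadata))
  expect_identical(names(tab)[1:5],
                   c("video_id", "mouse_id", "group", "beam", "trial"))
  expect_equal(ncol(tab), 5 + 384)
})
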