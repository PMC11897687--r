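test_that("time to cross matches linear nose motion analytically", {
  g <- rigid_trial(seed = 1, speed = 4)  # region width 1600 px
  geom <- locate_region(g$track)
  tt <- time_to_cross(g$track, geom)
  expect_equal(tt$seconds, 400 / 120)
  expect_identical(tt$direction, "left_to_right")

  # reversing the direction of travel mirrors direction, keeps duration
  rev <- g$track
  rev$x <- 1800 - rev$x
  rev$x[, c("line_left", "line_right")] <-
    rev$x[, c("line_right", "line_left")]
  ttr <- time_to_cross(rev, locate_region(rev))
  expect_identical(ttr$direction, "right_to_left")
  expect_equal(ttr$seconds, tt$seconds)
})

test_that("incomplete crossings raise contract errors", {
  g <- rigid_trial(seed = 1)
  geom <- locate_region(g$track)
  osc <- g$track
  osc$x[, "nose"] <- 900 + 50 * sin(seq_len(n_frames(osc)) / 9)
  expect_error(time_to_cross(osc, geom), "never exited")
  out <- g$track
  out$x[, "nose"] <- 50
  expect_error(time_to_cross(out, geom), "never entered")
})

test_that("time to cross ignores frames outside the crossing window", {
  g <- rigid_trial(seed = 1)
  geom <- locate_region(g$track)
  tt <- time_to_cross(g$track, geom)
  t2 <- g$track
  pre <- seq_len(tt$entry_frame)              # frames before entry (0-based)
  t2$x[pre, "nose"] <- 60 + 5 * sin(pre)      # arbitrary pre-entry wiggle
  tt2 <- time_to_cross(t2, geom)
  expect_equal(tt2$seconds, tt$seconds)
})

test_that("slip detection matches the brute-force run-length oracle", {
  base <- rep(40, 500)
  h <- base
  h[101:111] <- -30
  h[301:313] <- -25
  ev <- detect_foot_slips(h, detection_params())
  expect_equal(nrow(ev), 2)
  oracle <- oracle_slips(h)
  expect_equal(ev$onset, oracle$onset)
  expect_equal(ev$offset, oracle$offset)

  expect_equal(nrow(detect_foot_slips(rep(40, 500), detection_params())), 0)
  expect_equal(nrow(detect_foot_slips(numeric(0), detection_params())), 0)

  # randomized dip patterns agree with the oracle event for event
  set.seed(42)
  for (i in 1:20) {
    h <- rnorm(400, 30, 5)
    dips <- sort(sample(20:380, 3))
    for (d in dips) h[d:min(400, d + sample(3:12, 1))] <- -runif(1, 19, 40)
    ev <- detect_foot_slips(h, detection_params())
    oracle <- oracle_slips(h)
    expect_equal(ev$onset, oracle$onset)
    expect_equal(ev$offset, oracle$offset)
  }
})

test_that("events within the merge gap amalgamate into one", {
  h <- rep(40, 400)
  h[101:106] <- -30
  h[126:131] <- -35    # gap 19 < 32 -> merged
  ev <- detect_foot_slips(h, detection_params())
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset, 100)
  expect_equal(ev$offset, 130)
  expect_equal(ev$depth, 35)

  h2 <- rep(40, 400)
  h2[101:106] <- -30
  h2[147:152] <- -35   # gap 40 >= 32 -> two events
  ev2 <- detect_foot_slips(h2, detection_params())
  expect_equal(nrow(ev2), 2)
})

test_that("the merge step is idempotent and separates events by the gap", {
  set.seed(7)
  for (i in 1:20) {
    h <- rep(40, 600)
    for (d in sort(sample(10:560, 6))) h[d:(d + sample(2:20, 1))] <- -25
    h <- h[1:600]
    ev <- detect_foot_slips(h, detection_params())
    if (nrow(ev) > 1) {
      gaps <- ev$onset[-1] - ev$offset[-nrow(ev)] - 1
      expect_true(all(gaps >= 32))
    }
    again <- beamwalkr:::merge_slip_events(
      transform(ev, onset = onset + 1L, offset = offset + 1L,
                nadir = nadir + 1L), 32, h)
    expect_equal(nrow(again), nrow(ev))
    expect_equal(again$onset - 1L, ev$onset)
    expect_equal(again$offset - 1L, ev$offset)
  }
})

test_that("event matching is greedy, one-to-one and within tolerance", {
  m <- match_events(c(50, 200, 400), c(50, 200, 400), 30)
  expect_equal(m[c("TP", "FP", "FN")], list(TP = 3L, FP = 0L, FN = 0L))
  expect_equal(m$recall, 1); expect_equal(m$precision, 1)

  m2 <- match_events(numeric(0), c(50, 200, 400), 30)
  expect_equal(m2$recall, 0)
  expect_equal(m2$precision, 0)   # 0/0 convention
  expect_true(m2$degenerate)

  m3 <- match_events(60, 75, 30)
  expect_equal(m3$TP, 1L)
  m4 <- match_events(60, 95, 30)
  expect_equal(m4$TP, 0L)
  expect_equal(m4$FP, 1L); expect_equal(m4$FN, 1L)
  # one detection cannot consume two annotations
  m5 <- match_events(c(100), c(90, 110), 30)
  expect_equal(m5$TP, 1L); expect_equal(m5$FN, 1L)
  expect_error(match_events(1, 1, -2), ">= 0")
})

test_that("threshold sweep pools counts and recall is non-increasing", {
  mk <- function(depth) {
    h <- rep(40, 500)
    h[101:110] <- -depth; h[301:310] <- -depth
    list(height = h, annotated = c(105, 305))
  }
  trials <- list(mk(30), mk(30))
  sw <- threshold_sweep(trials, c(10, 18, 40))
  expect_equal(sw$recall[sw$threshold == 10], 1)
  expect_equal(sw$recall[sw$threshold == 18], 1)
  expect_equal(sw$recall[sw$threshold == 40], 0)
  expect_true(all(diff(sw$recall) <= 0))
  expect_true(all(sw$TP + sw$FN == 4))   # annotations fixed

  # duplicating a trial doubles every pooled count
  sw1 <- threshold_sweep(list(mk(30)), c(10, 18))
  sw2 <- threshold_sweep(list(mk(30), mk(30)), c(10, 18))
  expect_equal(sw2$TP, 2 * sw1$TP)
  expect_equal(sw2$FP, 2 * sw1$FP)
  expect_equal(sw2$FN, 2 * sw1$FN)

  # no slips anywhere: FP = 0 and 0/0 precision reported as 0
  quiet <- list(list(height = rep(40, 200), annotated = numeric(0)))
  sq <- threshold_sweep(quiet, c(10, 18))
  expect_true(all(sq$FP == 0) && all(sq$precision == 0))
  expect_error(threshold_sweep(trials, numeric(0)), "empty")
})

test_that("Cohen's kappa reproduces hand-computed values", {
  expect_equal(kappa_per_video(c(0, 1, 2, 3), c(0, 1, 2, 3))$kappa, 1)
  expect_equal(kappa_per_video(c(0, 0, 1, 1), c(1, 1, 0, 0))$kappa, -1)
  # hand evaluation: a=[0,1,0,1], b=[0,1,1,1]:
  # p_o = 3/4; p_a = (.5,.5), p_b = (.25,.75); p_e = .125+.375 = .5
  # kappa = (0.75-0.5)/0.5 = 0.5
  k <- kappa_per_video(c(0, 1, 0, 1), c(0, 1, 1, 1))
  expect_equal(k$kappa, 0.5)
  expect_equal(k$p_o, 0.75)
  expect_equal(k$p_e, 0.5)
  # degenerate: both raters constant and equal
  kd <- kappa_per_video(c(2, 2, 2), c(2, 2, 2))
  expect_equal(kd$kappa, 1)
  expect_true(kd$degenerate)
  expect_error(kappa_per_video(1:3, 1:4), "equal length")
})

test_that("trial endpoints restrict slip detection to the central region", {
  p <- sim_params(seed = 9, noise_sd = 0)
  p$slips <- plant_slips(p, 2, depth = 30, duration = 10, spacing = 150)
  g <- generate_trial(p)
  geom <- locate_region(g$track)
  ep <- trial_endpoints(g$track, geom)
  expect_equal(ep$n_slips, 2)
  expect_s3_class(ep$slips, "data.frame")
  # planted intervals overlap the detected ones
  for (i in seq_len(nrow(g$truth$slips)))
    expect_true(any(ep$slips$onset <= g$truth$slips$offset[i] &
                    ep$slips$offset >= g$truth$slips$onset[i]))
})
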