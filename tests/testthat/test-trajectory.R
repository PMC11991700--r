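# compact constructor for cleaning / QC tests
toy_track <- function(n = 1200, frame_rate = 20, bad_frac = 0,
                      climb_frac = 0, all_lik = NULL) {
  cfg <- behavior_sim_config(n_animals_per_genotype = 1L,
                             session_length = n / frame_rate,
                             genotypes = list(
                               g = list(v = c(neutral = 0.2, test = 0.3),
                                        sv = c(neutral = 0.02, test = 0.02))),
                             frame_rate = frame_rate, dropout_prob = 0,
                             climbing_frac = climb_frac, seed = 77)
  tr <- gen_behavior_sessions(cfg)$tracks[[1]]
  if (bad_frac > 0) {
    set.seed(1)
    for (k in thermodrift:::ANIMAL_KEYPOINTS) {
      bad <- sample(n, round(bad_frac * n))
      tr$likelihood[bad, k] <- 0.5
    }
  }
  if (!is.null(all_lik)) tr$likelihood[, thermodrift:::ANIMAL_KEYPOINTS] <- all_lik
  tr
}

test_that("cleaning rejects above the missingness threshold (strict >)", {
  expect_true(is_rejected(clean_track(toy_track(bad_frac = 0.26))))
  expect_false(is_rejected(clean_track(toy_track(bad_frac = 0.24))))
  # perfect track returns unchanged coordinates
  tr <- toy_track(all_lik = 1)
  cl <- clean_track(tr)
  expect_identical(cl$x, tr$x)
})

test_that("sub-threshold frames are linearly interpolated", {
  tr <- toy_track(n = 100)
  tr$x[50, "body_centre"] <- 999 # corrupted value
  tr$likelihood[50, "body_centre"] <- 0.1
  x49 <- tr$x[49, "body_centre"]; x51 <- tr$x[51, "body_centre"]
  cl <- clean_track(tr)
  expect_equal(cl$x[50, "body_centre"], (x49 + x51) / 2, tolerance = 1e-12)
})

test_that("an entirely missing keypoint rejects the session", {
  tr <- toy_track(n = 100)
  tr$likelihood[, "snout"] <- 0.1
  # keep overall missingness below the session threshold
  tr$likelihood[, setdiff(thermodrift:::ANIMAL_KEYPOINTS, "snout")] <- 1
  out <- clean_track(tr)
  expect_true(is_rejected(out))
  expect_match(out$reason, "snout")
})

test_that("climbing QC uses a strict threshold", {
  expect_true(qc_climbing(toy_track(climb_frac = 0.965)))
  expect_false(qc_climbing(toy_track(climb_frac = 0.950)))
  expect_false(qc_climbing(toy_track(climb_frac = 0)))
  tr <- toy_track(n = 100)
  tr$x <- tr$x[, setdiff(colnames(tr$x), "top_bl")]
  tr$y <- tr$y[, colnames(tr$x)]
  tr$likelihood <- tr$likelihood[, colnames(tr$x)]
  tr$keypoints <- colnames(tr$x)
  expect_error(qc_climbing(tr), "reference")
})

test_that("positions are centroid-based, normalized, and camera-shift invariant", {
  tr <- toy_track(n = 36000, frame_rate = 20) # 30 min at 20 Hz
  pos <- to_position(tr)
  expect_equal(nrow(pos), 1800)
  expect_true(all(pos$x > -0.1 & pos$x < 1.1))
  shifted <- tr
  shifted$x <- tr$x + 57.3
  shifted$y <- tr$y - 12.1
  pos2 <- to_position(shifted)
  expect_equal(pos2$x, pos$x, tolerance = 1e-9)
  expect_equal(pos2$y, pos$y, tolerance = 1e-9)
  # short sessions are rejected
  expect_true(is_rejected(to_position(toy_track(n = 1200))))
})

test_that("visit segmentation handles runs, tunnels and censoring", {
  pos <- make_position_trace(c(rep("left", 60), rep("right", 120), rep("left", 60)))
  vis <- segment_visits(pos)
  expect_equal(nrow(vis), 3)
  expect_equal(vis$chamber, c("neutral", "test", "neutral"))
  expect_equal(vis$duration, c(60, 120, 60))
  expect_equal(attr(vis, "crossings"), 2L)
  expect_equal(vis$censored, c(FALSE, FALSE, TRUE))

  whole <- segment_visits(make_position_trace(rep("left", 1800)))
  expect_equal(nrow(whole), 1)
  expect_equal(whole$duration, 1800)
  expect_equal(attr(whole, "crossings"), 0L)

  # tunnel samples attach to the preceding visit
  pos3 <- make_position_trace(c(rep("left", 10), rep("tunnel", 5), rep("right", 10)))
  vis3 <- segment_visits(pos3)
  expect_equal(vis3$duration, c(15, 10))

  expect_warning(out <- segment_visits(make_position_trace(rep("tunnel", 20))),
                 "tunnel")
  expect_equal(nrow(out), 0)
})

test_that("session summary matches hand-computed rolling statistics", {
  vis <- tibble::tibble(
    chamber = c("neutral", "test", "neutral", "test", "neutral", "test"),
    start = c(0, 100, 220, 300, 500, 1400),
    end = c(100, 220, 300, 500, 1400, 1800),
    duration = c(100, 120, 80, 200, 900, 400),
    censored = c(rep(FALSE, 5), TRUE))
  sm <- summarize_session(vis)
  # bin 1 (0-180): test time = 80 of 180
  expect_equal(sm$preference$test_fraction[1], 80 / 180)
  # bin 2 (180-360): test occupies 180-220 and 300-360
  expect_equal(sm$preference$test_fraction[2], (40 + 60) / 180)
  expect_true(all(sm$preference$test_fraction >= 0 &
                    sm$preference$test_fraction <= 1))
  # window starting at 60 s covers starts at 100 and 220
  w60 <- sm$visit_lengths[sm$visit_lengths$window_start == 60, ]
  expect_equal(w60$mean_visit_length, mean(c(120, 80)))
  expect_equal(w60$n_visits, 2)
  # crossings in window 0-180: visit starts at 100 (session start excluded)
  expect_equal(sm$crossings$crossings[sm$crossings$window_start == 0], 1)
})

test_that("per-bin occupancy fractions over chambers sum to one", {
  s <- gen_behavior_sessions(small_cfg(seed = 9))
  vis <- s$visits[s$visits$animal == s$visits$animal[1], ]
  sm <- summarize_session(vis, session_length = 600)
  test_fr <- sm$preference$test_fraction
  flip <- vis
  flip$chamber <- ifelse(vis$chamber == "test", "neutral", "test")
  neut_fr <- summarize_session(flip, session_length = 600)$preference$test_fraction
  expect_equal(test_fr + neut_fr, rep(1, length(test_fr)), tolerance = 1e-9)
})

test_that("generator round-trip recovers visits exactly at either frame rate", {
  for (fr in c(20, 30)) {
    cfg <- behavior_sim_config(n_animals_per_genotype = 1L,
                               frame_rate = fr, seed = 41)
    s <- gen_behavior_sessions(cfg)
    id <- names(s$tracks)[1]
    cl <- clean_track(s$tracks[[id]])
    vis <- segment_visits(to_position(cl), cfg$geometry)
    gt <- s$visits[s$visits$animal == id, ]
    expect_equal(nrow(vis), nrow(gt))
    expect_equal(vis$chamber, gt$chamber)
    expect_lt(max(abs(vis$duration - gt$duration)), 1.001)
  }
})
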