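# classifier trained once for the whole file (deterministic given seed)
clf <- NULL
get_clf <- function() {
  if (is.null(clf)) clf <<- suppressWarnings(train_responder_classifier())
  clf
}

test_that("neuropil correction is exact arithmetic with shape checks", {
  F <- matrix(100, 2, 5); Fneu <- matrix(50, 2, 5)
  expect_equal(neuropil_correct(F, Fneu, 0.7), matrix(65, 2, 5))
  expect_equal(neuropil_correct(F, Fneu, 0), F)
  expect_error(neuropil_correct(F, matrix(0, 3, 5)), "shape")
  expect_error(neuropil_correct(F, Fneu, 1), "r")
})

test_that("dF/F0 follows its definition, flags bad baselines, clips percentiles", {
  F <- rbind(rep(100, 100), c(rep(100, 50), rep(130, 50)))
  d <- dff(F, sample_rate = 1, baseline_s = 10)
  expect_true(all(d[1, ] == 0))
  expect_equal(max(d[2, ]), 0.30, tolerance = 1e-12)

  bad <- rbind(rep(0, 100), rep(100, 100))
  db <- dff(bad, 1)
  expect_equal(attr(db, "invalid_cells"), 1L)
  expect_true(all(is.na(db[1, ])))

  set.seed(1)
  M <- matrix(100 + rnorm(20000), 4)
  dc <- dff(M, 1, clip = TRUE)
  b <- attr(dc, "clip_bounds")
  expect_equal(b, quantile(dff(M, 1), c(0.001, 0.999), names = FALSE),
               tolerance = 1e-12)
  expect_true(all(dc >= b[1] & dc <= b[2]))
})

test_that("dF/F0 and onsets are invariant to a common positive gain", {
  cfg <- calcium_sim_config(n_cells = 10L, frac_responders = 0.5, isi_s = 30,
                            include_agonists = FALSE, seed = 6)
  b <- gen_calcium_dataset(cfg)
  fc <- neuropil_correct(b$F, b$Fneu, 0.7)
  d1 <- dff(fc, cfg$sample_rate)
  d2 <- dff(3.7 * fc, cfg$sample_rate)
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("phase segmentation finds the ramp end and ignores offsets", {
  st <- make_ramp_stimulus()
  ph <- segment_phases(st$stimulus, st$epochs)
  expect_lt(abs(ph$boundary - st$ramp_end), 0.1 + 1e-9)
  shifted <- st$stimulus; shifted$temperature <- shifted$temperature + 5
  ph2 <- segment_phases(shifted, st$epochs)
  expect_equal(ph2$boundary, ph$boundary)
  flat <- st$stimulus; flat$temperature <- 32
  expect_error(segment_phases(flat, st$epochs), "peak")
})

test_that("phase boundary is robust to thermocouple noise", {
  errs <- vapply(1:100, function(i) {
    set.seed(i)
    st <- make_ramp_stimulus(noise_sd = 0.05)
    segment_phases(st$stimulus, st$epochs)$boundary - st$ramp_end
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.5)
})

test_that("onset timing follows the 10%-of-max rule", {
  tt <- seq(0, 40, by = 0.25)
  step <- ifelse(tt >= 15, 1, 0)
  o <- onset_time(step, tt, epoch_start = 10, epoch_end = 35)
  expect_equal(o$onset, 15)
  ramp <- pmax(0, (tt - 10) / 25) # linear 0 -> max over the epoch
  o2 <- onset_time(ramp, tt, 10, 35)
  expect_equal(o2$onset - 10, 0.1 * 25, tolerance = 0.26)
  o3 <- onset_time(step, tt, 10, 35, boundary = 20)
  expect_equal(o3$phase, "dynamic")
  o4 <- onset_time(step, tt, 10, 35, boundary = 12)
  expect_equal(o4$phase, "static")
  expect_error(onset_time(rep(0, length(tt)), tt, 10, 35), "maximum")
})

test_that("heatmap ordering equals the brute-force cumulative scan", {
  set.seed(8)
  M <- matrix(abs(rnorm(600)), 20)
  M[3, ] <- c(10, rep(0, 29)) # all signal in first frame -> first
  M[7, ] <- M[5, ] # tie with cell 5 -> original order
  M[9, ] <- -1 # non-positive total -> last
  ord <- heatmap_order(M)
  expect_equal(ord, cumsum_order_oracle(M))
  expect_equal(ord[1], 3)
  expect_lt(which(ord == 5), which(ord == 7))
  expect_equal(ord[20], 9)
})

test_that("classifier calls are deterministic and frac_responders = 0 yields none", {
  m <- get_clf()
  cfg <- calcium_sim_config(n_cells = 60L, frac_responders = 0, isi_s = 60,
                            include_agonists = FALSE, seed = 13)
  b <- gen_calcium_dataset(cfg)
  fc <- neuropil_correct(b$F, b$Fneu, 0.7)
  c1 <- classify_responders(fc, cfg$sample_rate, b$epochs, m)
  c2 <- classify_responders(fc, cfg$sample_rate, b$epochs, m)
  expect_identical(c1, c2)
  expect_equal(sum(c1$responder), 0)
  expect_error(classify_responders(fc, cfg$sample_rate, b$epochs, list()),
               "trained")
})

test_that("classifier reaches high balanced accuracy on held-out labelled traces", {
  m <- get_clf()
  cfg <- calcium_sim_config(n_cells = 250L, frac_responders = 0.5,
                            response_prob = c(1, 1, 1),
                            include_agonists = FALSE, seed = 77)
  b <- gen_calcium_dataset(cfg)
  fc <- neuropil_correct(b$F, b$Fneu, 0.7)
  calls <- classify_responders(fc, cfg$sample_rate, b$epochs, m)
  lab <- unlist(lapply(1:3, function(k) b$truth[[paste0("responds_s", k)]]))
  key <- paste(rep(seq_len(250), 3), rep(paste0("warm", 1:3), each = 250))
  pred <- calls$responder[match(key, paste(calls$cell, calls$stimulus))]
  bal <- 0.5 * (sum(pred & lab) / sum(lab) + sum(!pred & !lab) / sum(!lab))
  expect_gte(bal, 0.95)
})

test_that("responder table handles agonist epochs and the exclusion rule", {
  m <- get_clf()
  cfg <- calcium_sim_config(n_cells = 80L, frac_responders = 0.15, isi_s = 60,
                            frac_capsaicin = 0.3, seed = 21)
  b <- gen_calcium_dataset(cfg)
  fc <- neuropil_correct(b$F, b$Fneu, 0.7)
  ph <- segment_phases(b$stimulus, b$epochs)
  rt <- responder_table(fc, cfg$sample_rate, b$epochs, m, ph)
  excluded <- attr(rt, "excluded_cells")
  expect_false(any(rt$cell %in% excluded))
  truth <- b$truth
  # capsaicin-only cells: capsaicin flag without warm sensitivity
  caps_only <- truth$cell[truth$capsaicin & !truth$responder]
  if (length(caps_only)) {
    sub <- rt[rt$cell %in% caps_only, ]
    expect_true(all(sub$capsaicin))
    expect_true(mean(sub$warm_sensitive) < 0.2)
  }
  # onsets exist only for responders
  expect_true(all(is.na(rt$onset[!rt$responder])))
  # stats: proportions in [0,1], AUC of the geometry checks below
  st <- fov_stats(rt, fc, cfg$sample_rate, b$epochs)
  expect_true(all(st$proportions$proportion >= 0 &
                    st$proportions$proportion <= 1))
})

test_that("AUC follows the trapezoid rule", {
  # constant zero trace and a triangular pulse on a synthetic epoch
  tt <- seq(0, 50, by = 0.1)
  tri <- pmax(0, 1 - abs(tt - 25) / 5) # base 10 s, height 1
  expect_equal(pracma::trapz(tt, tri), 0.5 * 10 * 1, tolerance = 1e-6)
  expect_equal(pracma::trapz(tt, rep(0, length(tt))), 0)
})

test_that("dynamic-onset cells are labelled dynamic at default noise", {
  m <- get_clf()
  cfg <- calcium_sim_config(n_cells = 150L, frac_responders = 0.5,
                            frac_dynamic_onset = 1, response_prob = c(1, 1, 1),
                            isi_s = 60, include_agonists = FALSE, seed = 31)
  b <- gen_calcium_dataset(cfg)
  fc <- neuropil_correct(b$F, b$Fneu, 0.7)
  ph <- segment_phases(b$stimulus, b$epochs)
  rt <- responder_table(fc, cfg$sample_rate, b$epochs, m, ph)
  lab <- rt$onset_phase[rt$responder & !is.na(rt$onset_phase)]
  expect_gte(mean(lab == "dynamic"), 0.9)
})
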