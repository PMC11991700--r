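test_that("visit durations tile the session exactly and outputs are reproducible", {
  s1 <- gen_behavior_sessions(small_cfg(seed = 3))
  s2 <- gen_behavior_sessions(small_cfg(seed = 3))
  expect_identical(s1$visits, s2$visits)
  expect_identical(s1$tracks[[1]]$x, s2$tracks[[1]]$x)
  sums <- tapply(s1$visits$duration, s1$visits$animal, sum)
  expect_true(all(abs(sums - 600) < 1e-9))
  expect_true(all(tapply(s1$visits$censored, s1$visits$animal,
                         function(x) sum(x) == 1 && x[length(x)])))
  # consecutive visits alternate chambers
  ch <- s1$visits$chamber
  expect_true(all(ch[-1] != ch[-length(ch)]))
})

test_that("a strongly asymmetric drift keeps the animal in the neutral chamber", {
  cfg <- behavior_sim_config(
    n_animals_per_genotype = 1L, session_length = 600,
    genotypes = list(g = list(v = c(neutral = 0.02, test = 3),
                              sv = c(neutral = 0, test = 0))),
    a = 13, z = 0.5, re_sd = 0, seed = 8)
  s <- gen_behavior_sessions(cfg)
  tn <- tapply(s$visits$duration, s$visits$chamber, sum)
  expect_gt(tn["neutral"] / sum(tn), 0.9)
})

test_that("raising the test drift shortens test-chamber visits", {
  mk <- function(v_test) behavior_sim_config(
    n_animals_per_genotype = 2L, session_length = 1200,
    genotypes = list(g = list(v = c(neutral = 0.18, test = v_test),
                              sv = c(neutral = 0.04, test = 0.04))),
    re_sd = 0, seed = 31)
  lo <- gen_behavior_sessions(mk(0.2))
  hi <- gen_behavior_sessions(mk(0.6))
  med_lo <- median(lo$visits$duration[lo$visits$chamber == "test" & !lo$visits$censored])
  med_hi <- median(hi$visits$duration[hi$visits$chamber == "test" & !hi$visits$censored])
  expect_lt(med_hi, med_lo)
})

test_that("keypoint CSV round-trips", {
  s <- gen_behavior_sessions(small_cfg(seed = 12, session_length = 60))
  tr <- s$tracks[[1]]
  path <- tempfile(fileext = ".csv")
  write_keypoint_csv(tr, path)
  back <- read_keypoint_csv(path)
  expect_equal(back$x, tr$x, tolerance = 1e-9)
  expect_equal(back$likelihood, tr$likelihood, tolerance = 1e-9)
  expect_identical(back$frame_rate, tr$frame_rate)
})

test_that("design-table generator matches configured cells and records truth", {
  g <- gen_visit_table(hier_sim_config(n_animals_per_genotype = 4L,
                                       n_visits_per_animal = 30L, seed = 2))
  expect_equal(nrow(g$table), 2 * 4 * 30)
  expect_true(all(g$table$duration > 0))
  expect_true(all(g$table$duration[g$table$censored] == 120))
  # true coefficients reproduce the configured cell means
  X <- model.matrix(~ chamber * genotype,
                    expand.grid(chamber = factor(c("neutral", "test")),
                                genotype = factor(c("wildtype", "mutant"),
                                                  levels = c("wildtype", "mutant"))))
  v_cells <- as.numeric(X %*% g$truth$beta_v)
  expect_equal(v_cells, c(0.12, 0.20, 0.12, 0.70), tolerance = 1e-12)
  sv_cells <- thermodrift:::softplus(as.numeric(X %*% g$truth$beta_sv))
  expect_equal(sv_cells, c(0.2, 0.2, 0.2, 0.5), tolerance = 1e-12)
})

test_that("ground-truth label fractions converge to configured fractions", {
  cfg <- calcium_sim_config(n_cells = 2000L, frac_responders = 0.3,
                            isi_s = 30, include_agonists = FALSE, seed = 5)
  b <- gen_calcium_dataset(cfg)
  phat <- mean(b$truth$responder)
  se <- sqrt(0.3 * 0.7 / 2000)
  expect_lt(abs(phat - 0.3), 3 * se)
})
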