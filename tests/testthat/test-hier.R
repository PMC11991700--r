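# a small design table shared across this file
small_design <- function(seed = 2) {
  gen_visit_table(hier_sim_config(n_animals_per_genotype = 6L,
                                  n_visits_per_animal = 40L, seed = seed))
}

test_that("build_model produces a saturated factorial design with stable row mapping", {
  g <- small_design()
  m <- build_model(g$table, model_spec(a = fixed(13)))
  expect_equal(ncol(m$X), 4) # 2 chambers x 2 genotypes, saturated
  expect_equal(qr(m$X)$rank, 4)
  expect_equal(m$coef_names,
               c("(Intercept)", "chambertest", "genotypemutant",
                 "chambertest:genotypemutant"))
  # permuting rows permutes the pointwise mapping with them
  perm <- sample(nrow(g$table))
  m2 <- build_model(g$table[perm, ], model_spec(a = fixed(13)))
  expect_equal(m2$X, m$X[perm, ], ignore_attr = TRUE)
  # validation errors
  bad <- g$table; bad$chamber[1] <- "left"
  expect_error(build_model(bad, model_spec(a = fixed(13))), "chamber")
  bad2 <- g$table; bad2$genotype[bad2$animal == bad2$animal[1]][1] <- "other"
  expect_error(build_model(bad2, model_spec(a = fixed(13))), "genotype")
})

test_that("model specification modes are validated", {
  expect_error(model_spec(v = fixed(1)), "cannot be fixed")
  expect_error(model_spec(v = "floating", sv = fixed(0.2), a = fixed(1)),
               "predictor")
  expect_error(model_spec(z = fixed(1.2)), "0, 1")
  sp <- model_spec(sv = "floating")
  expect_identical(sp$sv, "floating")
})

test_that("prior-predictive sampling reproduces the prior moments", {
  g <- small_design()
  m <- build_model(g$table, model_spec(a = fixed(13)))
  post <- sample_posterior(m, chains = 2, tune = 300, draws = 400, seed = 4,
                           prior_only = TRUE)
  dm <- as_draws_matrix(post)
  # coefficients are normal(0, 2) a priori
  for (p in c("v_(Intercept)", "sv_chambertest")) {
    expect_lt(abs(mean(dm[, p])), 0.5)
    expect_lt(abs(sd(dm[, p]) - 2), 0.7)
  }
})

test_that("posterior recovers generating parameters on a scaled design", {
  g <- gen_visit_table(hier_sim_config(n_animals_per_genotype = 10L,
                                       n_visits_per_animal = 60L, seed = 31))
  post <- fit_ddm(g$table, model_spec(a = fixed(13), z = fixed(0.9)),
                  chains = 2, tune = 500, draws = 400, seed = 6)
  s <- posterior_summary(post)
  truth <- c(g$truth$beta_v, g$truth$beta_sv)
  covered <- s$lower[1:8] <= truth & truth <= s$upper[1:8]
  expect_gte(sum(covered), 6)
  # the large test-chamber drift offset is recovered decisively
  i <- which(s$param == "v_chambertest:genotypemutant")
  expect_gt(s$median[i], 0.2)
  expect_lt(abs(s$median[i] - 0.5), 0.3)
})

test_that("a flat-data edge case completes and flags a near-degenerate fit", {
  tab <- tibble::tibble(
    animal = rep(sprintf("a%02d", 1:6), each = 20),
    genotype = "wildtype", temp_combo = "31v34",
    chamber = rep(c("neutral", "test"), 60),
    duration = 5, censored = FALSE)
  post <- fit_ddm(tab, model_spec(a = fixed(13), z = fixed(0.9)),
                  chains = 2, tune = 200, draws = 150, seed = 3)
  expect_s3_class(post, "ddm_posterior")
  expect_true(all(is.finite(as_draws_matrix(post))))
})

test_that("wildtype-subtracted contrasts obey their identities", {
  g <- small_design(seed = 5)
  post <- fit_ddm(g$table, model_spec(a = fixed(13), z = fixed(0.9)),
                  chains = 2, tune = 300, draws = 300, seed = 9)
  ctr <- contrasts_vs_wildtype(post)
  wt <- ctr[ctr$genotype == "wildtype", ]
  expect_true(all(abs(wt$median) < 1e-12))
  expect_true(all(abs(wt$lower) < 1e-12 & abs(wt$upper) < 1e-12))
  draws <- attr(ctr, "draws")
  expect_true(all(draws[["wildtype.31v34.v"]] == 0))
  # adding a constant to both chambers' drifts of a genotype leaves the
  # drift contrast unchanged: shift the mutant draws directly
  m <- as_draws_matrix(post)
  shift <- m
  shift[, "v_genotypemutant"] <- shift[, "v_genotypemutant"] + 0.7
  post2 <- post
  for (ch in seq_len(post$chains)) {
    post2$draws[ch, , ] <- shift[seq((ch - 1) * post$n_draws + 1,
                                     ch * post$n_draws), ]
  }
  ctr2 <- contrasts_vs_wildtype(post2)
  expect_equal(ctr2$median[ctr2$parameter == "v"],
               ctr$median[ctr$parameter == "v"], tolerance = 1e-9)
  expect_error(contrasts_vs_wildtype(post, ref_genotype = "missing"), "absent")
})
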