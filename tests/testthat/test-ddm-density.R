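test_that("upper and lower passage densities conserve probability", {
  for (pars in list(ddm_params(v = 0.5, sv = 0, a = 1, z = 0.5),
                    ddm_params(v = -0.8, sv = 0, a = 2, z = 0.7),
                    ddm_params(v = 0, sv = 0, a = 1, z = 0.3))) {
    iu <- integrate(function(t) fpt_density_upper(t, pars), 0, Inf,
                    rel.tol = 1e-10)$value
    il <- integrate(function(t) fpt_density_lower(t, pars), 0, Inf,
                    rel.tol = 1e-10)$value
    expect_equal(iu + il, 1, tolerance = 1e-6)
    expect_equal(iu, absorption_prob_upper(pars), tolerance = 1e-6)
  }
  # with across-visit drift variability
  p <- ddm_params(v = 1, sv = 0.4, a = 1, z = 0.9)
  iu <- integrate(function(t) fpt_density_upper(t, p), 0, Inf, rel.tol = 1e-9)$value
  il <- integrate(function(t) fpt_density_lower(t, p), 0, Inf, rel.tol = 1e-9)$value
  expect_equal(iu + il, 1, tolerance = 1e-4)
})

test_that("sv -> 0 limit of the drift-mixture density matches the plain density", {
  tg <- seq(0.05, 3, by = 0.15)
  for (z in c(0.5, 0.9)) {
    d0 <- fpt_density_upper(tg, ddm_params(v = 1, sv = 0, a = 1, z = z))
    d1 <- fpt_density_upper(tg, ddm_params(v = 1, sv = 1e-9, a = 1, z = z))
    expect_lt(max(abs(d0 - d1)), 1e-8)
  }
})

test_that("absorption probability matches the classical closed form", {
  for (v in c(-1, 0.3, 2)) for (z in c(0.3, 0.9)) {
    p <- ddm_params(v = v, sv = 0, a = 1.5, z = z)
    closed <- if (abs(v) < 1e-12) z else
      (1 - exp(-2 * v * z * 1.5)) / (1 - exp(-2 * v * 1.5))
    expect_equal(absorption_prob_upper(p), closed, tolerance = 1e-10)
  }
})

test_that("survival series agrees with numerical integration of the density", {
  p <- ddm_params(v = 1, sv = 0.3, a = 1, z = 0.9)
  pu <- absorption_prob_upper(p)
  for (tt in c(0.05, 0.3, 1, 3)) {
    s_num <- pu - integrate(function(s) fpt_density_upper(s, p), 0, tt,
                            rel.tol = 1e-10)$value
    expect_equal(fpt_survival_upper(tt, p), s_num, tolerance = 1e-6)
  }
})

test_that("density matches an independent Euler-Maruyama oracle histogram", {
  set.seed(42)
  p <- ddm_params(v = 1, sv = 0.3, a = 1, z = 0.9)
  o <- em_fpt_oracle(20000, p$v, p$sv, p$a, p$z, dt = 1e-4)
  up <- o$time[o$boundary == 1L & !is.na(o$boundary)]
  pu <- absorption_prob_upper(p)
  br <- c(0, quantile(up, c(0.25, 0.5, 0.75), names = FALSE), Inf)
  emp <- as.numeric(table(cut(up, br))) / length(up)
  th <- vapply(1:4, function(i) integrate(function(t) fpt_density_upper(t, p),
                                          br[i], min(br[i + 1], 100),
                                          rel.tol = 1e-8)$value / pu, 0)
  # allows for the plain-Euler oracle's own boundary-miss bias
  expect_lt(0.5 * sum(abs(emp - th)), 0.03)
})

test_that("visit log-likelihood definitions hold", {
  p <- ddm_params(v = 0.5, sv = 0.2, a = 2, z = 0.9)
  # empty visit set
  expect_identical(visit_loglik(data.frame(duration = numeric(),
                                           censored = logical()), p), 0)
  # single uncensored visit equals the upper-bound log-density
  expect_equal(visit_loglik(data.frame(duration = 0.8, censored = FALSE), p),
               fpt_density_upper(0.8, p, log = TRUE))
  # censored visit (total convention): log(1 - F_upper)
  cens <- visit_loglik(data.frame(duration = 2, censored = TRUE), p)
  expected <- log(1 - absorption_prob_upper(p) + fpt_survival_upper(2, p))
  expect_equal(cens, expected, tolerance = 1e-8)
  # upper-only censoring convention
  cens_up <- visit_loglik(data.frame(duration = 2, censored = TRUE), p,
                          censor = "upper")
  expect_equal(cens_up, fpt_survival_upper(2, p, log = TRUE), tolerance = 1e-8)
  # durations at or below t0 are rejected with the visit identified
  p2 <- ddm_params(v = 0.5, sv = 0, a = 1, z = 0.5, t0 = 0.1)
  expect_error(visit_loglik(data.frame(duration = c(1, 0.05),
                                       censored = c(FALSE, FALSE)), p2), "2")
})

test_that("conditional passage density is symmetric in the drift sign", {
  # f_upper(t|v)/P_up(v) == f_upper(t|-v)/P_up(-v): exit times identify
  # only the drift magnitude
  tg <- c(0.1, 0.5, 2)
  for (v in c(0.3, 1)) {
    pp <- ddm_params(v = v, sv = 0, a = 1.4, z = 0.8)
    pm <- ddm_params(v = -v, sv = 0, a = 1.4, z = 0.8)
    cp <- fpt_density_upper(tg, pp) / absorption_prob_upper(pp)
    cm <- fpt_density_upper(tg, pm) / absorption_prob_upper(pm)
    expect_equal(cp, cm, tolerance = 1e-10)
  }
})

test_that("log-likelihood is finite over a randomized parameter sweep", {
  set.seed(7)
  vis <- data.frame(duration = c(runif(30, 0.2, 40), 120, 120),
                    censored = c(rep(FALSE, 30), TRUE, TRUE))
  for (i in 1:40) {
    p <- list(v = runif(1, -1, 2), sv = runif(1, 0, 0.8),
              a = runif(1, 1, 15), z = runif(1, 0.1, 0.95), t0 = 0)
    ll <- visit_loglik(vis, p)
    expect_true(is.finite(ll))
  }
})
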