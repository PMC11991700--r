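fake_pointwise <- function(S = 400, n = 60, seed = 1) {
  set.seed(seed)
  mu <- rnorm(n, -2, 0.5)
  sweep(matrix(rnorm(S * n, 0, 0.3), S, n), 2, mu, "+")
}

test_that("a model compared with itself ties exactly", {
  ll <- fake_pointwise()
  l1 <- compute_loo(ll); l2 <- compute_loo(ll)
  expect_equal(l1$elpd - l2$elpd, 0)
  expect_equal(l1$pointwise$elpd_i, l2$pointwise$elpd_i)
})

test_that("elpd is invariant to observation order", {
  ll <- fake_pointwise(seed = 3)
  l1 <- compute_loo(ll)
  perm <- sample(ncol(ll))
  l2 <- compute_loo(ll[, perm])
  expect_equal(l1$elpd, l2$elpd, tolerance = 1e-10)
  expect_equal(l1$pointwise$elpd_i[perm], l2$pointwise$elpd_i,
               tolerance = 1e-12)
})

test_that("an injected outlier observation has an elevated Pareto k", {
  ll <- fake_pointwise(S = 600, n = 50, seed = 4)
  # one observation whose likelihood varies wildly across draws
  ll[, 1] <- -2 + rnorm(600, 0, 3)^2 * -1
  lo <- compute_loo(ll)
  expect_gt(lo$pointwise$pareto_k[1], max(lo$pointwise$pareto_k[-1]))
})

test_that("gpdfit recovers known generalised Pareto parameters", {
  set.seed(2)
  for (k_true in c(0.2, 0.5)) {
    x <- sort((runif(5000)^(-k_true) - 1) / k_true * 1.5)
    f <- thermodrift:::gpdfit(x)
    expect_lt(abs(f$k - k_true), 0.06)
    expect_lt(abs(f$sigma - 1.5), 0.15)
  }
})

test_that("PSIS-LOO agrees with an independent implementation", {
  # cross-check against the Python arviz implementation on the same matrix
  ll <- fake_pointwise(S = 500, n = 40, seed = 9)
  mine <- compute_loo(ll, r_eff = 1)
  csv <- tempfile(fileext = ".csv")
  out <- tempfile(fileext = ".txt")
  write.csv(ll, csv, row.names = FALSE)
  script <- sprintf("
import warnings; warnings.filterwarnings('ignore')
import numpy as np, arviz as az
from scipy.special import logsumexp
ll = np.loadtxt('%s', delimiter=',', skiprows=1)
lw, k = az.psislw(-ll.T)
elpd = logsumexp(np.asarray(lw) + ll.T, axis=1).sum()
print(elpd)
print(np.asarray(k).max())
", csv, out)
  res <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  ref_elpd <- as.numeric(res[1])
  ref_maxk <- as.numeric(res[2])
  expect_equal(mine$elpd, ref_elpd, tolerance = 0.01)
  expect_lt(abs(max(mine$pointwise$pareto_k) - ref_maxk), 0.15)
})

test_that("rank_models orders by elpd and excludes unreliable candidates", {
  set.seed(11)
  good <- fake_pointwise(S = 500, n = 80, seed = 12)
  worse <- good - matrix(rexp(500 * 80, 2), 500, 80) # uniformly lower ll
  mk_post <- function(pw) {
    structure(list(pointwise = pw,
                   diagnostics = tibble::tibble(param = "x", rhat = 1,
                                                ess = nrow(pw))),
              class = "ddm_posterior")
  }
  out <- rank_models(fits = list(a = mk_post(good), b = mk_post(worse)))
  expect_equal(out$model[1], "a")
  expect_equal(out$elpd_diff[1], 0)
  expect_lt(out$elpd_diff[2], 0)
  expect_error(rank_models(fits = list(a = mk_post(good))), "two models")
})
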