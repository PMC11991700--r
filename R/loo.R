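logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Generalised Pareto fit to exceedances (Zhang & Stephens 2009 profile
# posterior-mean estimator). `x` must be sorted ascending and positive.
gpdfit <- function(x, prior = 3) {
  n <- length(x)
  if (n < 5L) return(list(k = NaN, sigma = NaN))
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior * xstar)
  k_j <- vapply(theta, function(th) mean(log1p(-th * x)), 0)
  l_j <- n * (log(-theta / k_j) - k_j - 1)
  w <- exp(l_j - logsumexp(l_j))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  # weakly-informative shrink of k towards 0.5 for small tails
  k <- (n * k + 10 * 0.5) / (n + 10)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smoothed importance weights for one observation.
# `lr` are unnormalised log importance ratios; returns normalised log
# weights and the tail-shape diagnostic k.
psis_smooth <- function(lr, r_eff = 1) {
  S <- length(lr)
  lr <- lr - max(lr)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S / r_eff)))
  k <- NaN
  if (M >= 5L && S > 2 * M) {
    ord <- order(lr)
    tail_ids <- ord[(S - M + 1):S]
    cut <- lr[ord[S - M]]
    exc <- exp(lr[tail_ids]) - exp(cut)
    exc_ord <- order(exc)
    fit <- gpdfit(sort(exc))
    k <- fit$k
    if (is.finite(k) && is.finite(fit$sigma) && fit$sigma > 0) {
      p <- (seq_len(M) - 0.5) / M
      smoothed <- log(qgpd(p, k, fit$sigma) + exp(cut))
      smoothed <- pmin(smoothed, 0) # cap at the largest raw weight
      lr[tail_ids[exc_ord]] <- smoothed
    }
  }
  list(log_weights = lr - logsumexp(lr), k = k)
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Estimates the expected log pointwise predictive density (ELPD) of a
#' fitted model by PSIS-LOO: for every observation the importance ratios
#' `1 / p(y_i | theta_s)` are stabilised by replacing their largest tail
#' with the quantiles of a generalised Pareto fit; the per-observation
#' Pareto shape `k` diagnoses reliability, and the result is flagged
#' unreliable when any `k > 0.7`.
#'
#' @param samples a `ddm_posterior` (its stored pointwise log-likelihood
#'   matrix is used) or a draws x observations log-likelihood matrix.
#' @param k_threshold reliability cutoff on the Pareto shape (default 0.7).
#' @param r_eff relative MCMC efficiency of the draws (effective sample
#'   size over number of draws), used to size the Pareto tail; estimated
#'   from the stored chain diagnostics when a posterior is supplied.
#' @return an object of class `loo_result`: `elpd`, `se`, `pointwise`
#'   (tibble with `elpd_i`, `pareto_k`), `reliable`, `n`.
#' @export
compute_loo <- function(samples, k_threshold = 0.7, r_eff = NULL) {
  ll <- if (inherits(samples, "ddm_posterior")) samples$pointwise else samples
  stopifnot(is.matrix(ll))
  S <- nrow(ll); n <- ncol(ll)
  if (S < 50L) stop("too few posterior draws (", S, ") for a Pareto tail fit")
  if (is.null(r_eff)) {
    r_eff <- if (inherits(samples, "ddm_posterior")) {
      min(1, max(0.05, median(samples$diagnostics$ess) / S))
    } else {
      1
    }
  }
  elpd_i <- numeric(n); k_i <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-ll[, i], r_eff)
    elpd_i[i] <- logsumexp(sm$log_weights + ll[, i])
    k_i[i] <- sm$k
  }
  structure(list(
    elpd = sum(elpd_i),
    se = sqrt(n * var(elpd_i)),
    pointwise = tibble::tibble(elpd_i = elpd_i, pareto_k = k_i),
    reliable = !any(k_i > k_threshold, na.rm = TRUE),
    n = n
  ), class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd = %.1f (SE %.1f), n = %d, max Pareto k = %.2f%s\n",
              x$elpd, x$se, x$n, max(x$pointwise$pareto_k, na.rm = TRUE),
              if (x$reliable) "" else " [UNRELIABLE]"))
  invisible(x)
}

#' Rank candidate models by ELPD
#'
#' Fits each specification (or reuses supplied fits), computes PSIS-LOO for
#' each, discards unreliable models (any Pareto `k > 0.7`) from the
#' ranking, and reports ELPD differences to the best reliable model with
#' the SE of each pairwise difference computed from the pointwise ELPD
#' contributions.
#'
#' @param specs named list of [model_spec()]s (ignored when `fits` given).
#' @param table the shared design table.
#' @param fits optional named list of `ddm_posterior` objects.
#' @param ... passed to [sample_posterior()].
#' @return tibble: model, elpd, se, elpd_diff, se_diff, reliable, rank
#'   (NA for unreliable models).
#' @export
rank_models <- function(specs = NULL, table = NULL, fits = NULL, ...) {
  if (is.null(fits)) {
    stopifnot(length(specs) >= 2L, !is.null(table))
    fits <- lapply(specs, function(sp) fit_ddm(table, sp, ...))
  }
  if (length(fits) < 2L) stop("at least two models are required")
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  loos <- lapply(fits, compute_loo)
  elpd <- vapply(loos, `[[`, 0, "elpd")
  se <- vapply(loos, `[[`, 0, "se")
  reliable <- vapply(loos, `[[`, TRUE, "reliable")
  if (!any(reliable)) stop("all candidate models are unreliable (Pareto k > 0.7)")
  best <- names(which.max(elpd[reliable]))
  best_pw <- loos[[best]]$pointwise$elpd_i
  diff_se <- vapply(loos, function(l) {
    d <- l$pointwise$elpd_i - best_pw
    sqrt(length(d) * var(d))
  }, 0)
  elpd_diff <- unname(elpd - elpd[best])
  out <- tibble::tibble(model = names(fits), elpd = unname(elpd),
                        se = unname(se),
                        elpd_diff = elpd_diff,
                        se_diff = unname(diff_se),
                        reliable = unname(reliable))
  out <- out[order(-out$elpd), ]
  out$rank <- NA_integer_
  out$rank[out$reliable] <- seq_len(sum(out$reliable))
  out
}
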