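#' Drift-diffusion parameter set
#'
#' Bundles the parameters of the chamber-leaving decision process: a Wiener
#' diffusion between absorbing bounds `0` and `a`, started at `z * a`, with
#' within-visit diffusion coefficient fixed at 1 evidence/sqrt(s) and the
#' per-visit drift drawn from `Normal(v, sv^2)`. Reaching the upper bound
#' models the decision to leave the chamber; the starting point `z` is
#' conventionally fixed near the upper bound (0.9) when fitting, so that the
#' lower bound is rarely reached.
#'
#' Two boundary conventions circulate for this model (bounds at `{0, a}` with
#' relative start `z`, or bounds at `{-a, a}`); they are affine relabellings
#' of one another and `z = 0.9` means the same thing in both. This package
#' uses bounds `{0, a}` throughout.
#'
#' @param v drift rate (evidence/s); mean rate of evidence accumulation.
#' @param sv standard deviation of the drift across visits (evidence/s);
#'   inter-trial drift variability, called "noise" in this assay's modelling.
#' @param a boundary separation (evidence), `> 0`.
#' @param z relative starting point in `(0, 1)`.
#' @param t0 non-decision offset (s), `>= 0`; defaults to 0.
#' @return An object of class `ddm_params`.
#' @export
ddm_params <- function(v, sv = 0, a = 1, z = 0.5, t0 = 0) {
  stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
  if (!(a > 0)) stop("boundary separation `a` must be > 0")
  if (!(z > 0 && z < 1)) stop("relative start `z` must lie strictly in (0, 1)")
  if (sv < 0) stop("`sv` must be >= 0")
  if (t0 < 0) stop("`t0` must be >= 0")
  structure(list(v = v, sv = sv, a = a, z = z, t0 = t0, sigma = 1),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf("DDM parameters: v = %.4g, sv = %.4g, a = %.4g, z = %.4g, t0 = %.4g (sigma = 1)\n",
              x$v, x$sv, x$a, x$z, x$t0))
  invisible(x)
}

# Gauss-Hermite nodes/weights by Golub-Welsch (symmetric tridiagonal
# eigen-decomposition); used to mix fixed-drift absorption/survival
# quantities over the across-visit drift distribution.
gauss_hermite <- function(n = 21L) {
  i <- seq_len(n - 1L)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- sqrt(pi) * e$vectors[1L, ]^2
  ord <- order(x)
  list(x = x[ord], w = w[ord])
}

.gh_default <- NULL
gh_nodes <- function() {
  if (is.null(.gh_default)) {
    utils::assignInMyNamespace(".gh_default", gauss_hermite(21L))
  }
  .gh_default
}

#' First-passage-time density at the upper boundary
#'
#' Density (1/s) of absorption at the upper bound at time `t`, for the
#' diffusion described in [ddm_params()]. The drift-free part of the density
#' is evaluated with both small-time and large-time series expansions,
#' switching by a truncation-error criterion; across-visit drift variability
#' (`sv > 0`) enters through the analytic Gaussian-drift-mixture factor, so
#' no quadrature is needed for the density itself.
#'
#' The density is *defective*: it integrates to the upper-bound absorption
#' probability, not to 1 (see [absorption_prob_upper()]).
#'
#' @param t vector of times (s), each `> t0`.
#' @param params a [ddm_params()] object.
#' @param log return the log-density?
#' @param eps series truncation tolerance.
#' @return numeric vector of (log-)densities.
#' @export
fpt_density_upper <- function(t, params, log = FALSE, eps = 1e-10) {
  stopifnot(inherits(params, "ddm_params"))
  tt <- t - params$t0
  bad <- is.finite(tt) & tt <= 0
  ld <- rep(-Inf, length(tt))
  ok <- which(tt > 0)
  if (length(ok)) {
    ld[ok] <- wfpt_log_density_upper_cpp(tt[ok], params$v, params$sv,
                                         params$a, params$z, eps)
  }
  if (any(is.nan(ld[ok]))) {
    stop("first-passage density series failed at t = ",
         paste(signif(t[ok][is.nan(ld[ok])], 4), collapse = ", "),
         " for v = ", params$v, ", sv = ", params$sv,
         ", a = ", params$a, ", z = ", params$z)
  }
  ld[bad] <- -Inf
  if (log) ld else exp(ld)
}

#' @rdname fpt_density_upper
#' @export
fpt_density_lower <- function(t, params, log = FALSE, eps = 1e-10) {
  stopifnot(inherits(params, "ddm_params"))
  tt <- t - params$t0
  ld <- rep(-Inf, length(tt))
  ok <- which(tt > 0)
  if (length(ok)) {
    ld[ok] <- wfpt_log_density_lower_cpp(tt[ok], params$v, params$sv,
                                         params$a, params$z, eps)
  }
  if (log) ld else exp(ld)
}

#' Upper-boundary absorption probability
#'
#' Probability that the accumulator is absorbed at the upper bound (the
#' chamber is eventually left by decision rather than the lower-bound
#' defect). For `sv = 0` this is the classical closed form
#' `(1 - exp(-2 v z a)) / (1 - exp(-2 v a))`; for `sv > 0` the fixed-drift
#' form is mixed over the drift distribution by Gauss-Hermite quadrature.
#'
#' @inheritParams fpt_density_upper
#' @return scalar probability.
#' @export
absorption_prob_upper <- function(params) {
  gh <- gh_nodes()
  upper_prob_cpp(params$v, params$sv, params$a, params$z, gh$x, gh$w)[1]
}

#' Upper-boundary survival mass
#'
#' `P(T > t, absorbed at upper bound)`: the probability mass of visits still
#' ongoing at time `t` that will end in an exit. This is the censoring term
#' of the visit likelihood.
#'
#' @inheritParams fpt_density_upper
#' @export
fpt_survival_upper <- function(t, params, log = FALSE, eps = 1e-12) {
  gh <- gh_nodes()
  tt <- pmax(t - params$t0, 0)
  ls <- upper_log_survival_cpp(tt, params$v, params$sv, params$a, params$z,
                               gh$x, gh$w, eps)
  if (log) ls else exp(ls)
}

#' Visit-length log-likelihood
#'
#' Sums, over the visits of a session (or any table of visits), the
#' upper-boundary passage log-density for completed visits and a
#' log-survival mass beyond the censoring time for visits cut short by the
#' session end.
#'
#' The default convention is fully generative for one-observed-choice data:
#' a completed visit is an upper-bound passage and contributes the
#' (defective) upper-bound density; a censored visit contributes the total
#' remaining mass `1 - F_upper(t)`, which includes both exits slower than
#' the censoring time and the lower-bound mass (visits that would never end
#' in an exit). These terms integrate to one over the observation space, so
#' the likelihood is an exact match for data in which non-exits are
#' censored. `censor = "upper"` restricts the censoring term to the
#' upper-bound survival mass `P(T > t, upper)` only, and
#' `normalize = "conditional"` instead conditions every visit on ending in
#' an exit (dividing by the absorption probability); note that conditional
#' passage densities for drifts `v` and `-v` are exactly proportional, so
#' the conditional form identifies only the drift magnitude.
#'
#' @param visits a data frame with columns `duration` (s) and `censored`
#'   (logical), e.g. a [segment_visits()] result, or a numeric vector of
#'   uncensored durations.
#' @param params a [ddm_params()] object. `v`/`sv` may also be vectors with
#'   one entry per visit (used by the hierarchical model).
#' @param normalize `"defective"` (default) or `"conditional"`.
#' @param censor censoring mass: `"total"` (default; `1 - F_upper`) or
#'   `"upper"` (`P(T > t, upper)` only). Ignored under
#'   `normalize = "conditional"`, which always uses the conditional
#'   upper-bound survival.
#' @return scalar log-likelihood (0 for an empty visit set).
#' @export
visit_loglik <- function(visits, params, normalize = c("defective", "conditional"),
                         censor = c("total", "upper")) {
  sum(visit_loglik_pointwise(visits, params, normalize, censor))
}

#' @rdname visit_loglik
#' @export
visit_loglik_pointwise <- function(visits, params,
                                   normalize = c("defective", "conditional"),
                                   censor = c("total", "upper")) {
  normalize <- match.arg(normalize)
  censor <- match.arg(censor)
  if (is.numeric(visits)) {
    visits <- data.frame(duration = visits, censored = FALSE)
  }
  if (nrow(visits) == 0L) return(numeric(0))
  stopifnot(all(c("duration", "censored") %in% names(visits)))
  t0 <- if (inherits(params, "ddm_params")) params$t0 else 0
  if (any(visits$duration <= t0)) {
    stop("visit durations must exceed t0; offending visit(s): ",
         paste(which(visits$duration <= t0), collapse = ", "))
  }
  gh <- gh_nodes()
  conditional <- normalize == "conditional"
  visit_pointwise_loglik_cpp(
    visits$duration - t0, as.logical(visits$censored),
    params$v, params$sv, params$a, params$z,
    conditional, !conditional && censor == "total", gh$x, gh$w, 1e-10
  )
}
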