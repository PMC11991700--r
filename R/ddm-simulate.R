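#' Simulate first-passage times of the decision process
#'
#' Euler-Maruyama paths of the Wiener accumulator between absorbing bounds
#' `0` and `a`, started at `z * a`, with a fresh drift draw
#' `Normal(v, sv^2)` for every path. Crossings inside a step are detected
#' with the Brownian-bridge probability, which removes the boundary-miss
#' bias of the naive scheme at order `sqrt(dt)`.
#'
#' @param params a [ddm_params()] object.
#' @param n number of paths.
#' @param dt Euler step (s); must be small relative to the expected passage
#'   time (default 1e-3).
#' @param seed optional integer seed (`set.seed()` is called when supplied;
#'   otherwise the current RNG stream is used).
#' @param max_time paths not absorbed by `max_time` are returned with
#'   `boundary = "none"` and flagged by a warning.
#' @return A [tibble::tibble] with columns `time` (s, including `t0`),
#'   `boundary` (`"upper"`, `"lower"` or `"none"`) and `drift_draw`.
#' @export
simulate_fpt <- function(params, n, dt = 1e-3, seed = NULL, max_time = 1e4) {
  stopifnot(inherits(params, "ddm_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  sim <- sim_fpt_cpp(as.integer(n), params$v, params$sv, params$a, params$z,
                     dt, max_time)
  bound <- factor(sim$boundary, levels = c(1, -1, 0),
                  labels = c("upper", "lower", "none"))
  if (any(sim$boundary == 0L)) {
    warning(sum(sim$boundary == 0L), " path(s) not absorbed by max_time = ",
            max_time, " s")
  }
  tibble::tibble(time = sim$time + params$t0, boundary = bound,
                 drift_draw = sim$drift)
}

# Upper-boundary passage times for a vector of visit-level (v, sv).
# Lower-bound absorptions are latent non-exits and are resampled (counted).
sim_visit_durations <- function(v, sv, a, z, dt = 1e-3, max_time = 1e4,
                                max_tries = 200L) {
  sim <- sim_visits_cpp(v, sv, a, z, dt, max_time, as.integer(max_tries))
  if (sim$n_failed > 0) {
    warning(sim$n_failed, " visit(s) failed to reach the upper bound within ",
            max_tries, " resampling attempts")
  }
  attr(sim, "class") <- NULL
  sim
}
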