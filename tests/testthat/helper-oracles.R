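# Independent oracles used across the suite. These deliberately avoid the
# package's C++ path.

# Plain (no bridge correction) Euler-Maruyama first-passage simulation,
# vectorised over paths in base R.
em_fpt_oracle <- function(n, v, sv, a, z, dt = 1e-4, max_time = 50) {
  drift <- rnorm(n, v, sv)
  x <- rep(z * a, n)
  t_abs <- rep(NA_real_, n)
  bound <- rep(NA_integer_, n)
  alive <- seq_len(n)
  steps <- ceiling(max_time / dt)
  sdt <- sqrt(dt)
  for (s in seq_len(steps)) {
    x[alive] <- x[alive] + drift[alive] * dt + sdt * rnorm(length(alive))
    hit_up <- alive[x[alive] >= a]
    hit_lo <- alive[x[alive] <= 0]
    t_abs[hit_up] <- s * dt; bound[hit_up] <- 1L
    t_abs[hit_lo] <- s * dt; bound[hit_lo] <- -1L
    alive <- setdiff(alive, c(hit_up, hit_lo))
    if (!length(alive)) break
  }
  list(time = t_abs, boundary = bound)
}

# brute-force cumulative-sum crossing scan (heatmap ordering oracle)
cumsum_order_oracle <- function(mat, frac = 0.1) {
  keys <- apply(mat, 1, function(x) {
    tot <- sum(x)
    if (!(tot > 0)) return(Inf)
    cs <- cumsum(x)
    for (i in seq_along(cs)) if (cs[i] > frac * tot) return(i)
    Inf
  })
  order(keys)
}

# ideal ramp+plateau stimulus trace
make_ramp_stimulus <- function(ramp_s = 10, plateau_s = 15, sr = 10,
                               base = 32, top = 40, pre_s = 30, post_s = 30,
                               noise_sd = 0) {
  tt <- seq(0, pre_s + ramp_s + plateau_s + post_s, by = 1 / sr)
  temp <- rep(base, length(tt))
  ramp <- tt >= pre_s & tt < pre_s + ramp_s
  temp[ramp] <- base + (top - base) * (tt[ramp] - pre_s) / ramp_s
  temp[tt >= pre_s + ramp_s & tt < pre_s + ramp_s + plateau_s] <- top
  fall <- tt >= pre_s + ramp_s + plateau_s
  temp[fall] <- pmax(base, top - (top - base) * (tt[fall] - (pre_s + ramp_s + plateau_s)) / 10)
  list(stimulus = tibble::tibble(time = tt, temperature = temp + rnorm(length(tt), 0, noise_sd)),
       epochs = tibble::tibble(stimulus = "warm1", kind = "warm",
                               start = pre_s, end = pre_s + ramp_s + plateau_s,
                               plateau = top),
       ramp_end = pre_s + ramp_s)
}

# synthetic keypoint track with prescribed chamber occupancy at 1-s
# resolution (used for segmentation unit tests without the full generator)
make_position_trace <- function(chambers, x_left = 0.2, x_right = 0.8) {
  x <- ifelse(chambers == "left", x_left,
              ifelse(chambers == "right", x_right, 0.5))
  tibble::tibble(time = seq_along(chambers) - 1, x = x, y = 0.3)
}

# one-genotype short-session behaviour config used by several files
small_cfg <- function(session_length = 600, ...) {
  behavior_sim_config(n_animals_per_genotype = 1L,
                      session_length = session_length,
                      genotypes = list(
                        wildtype = list(v = c(neutral = 0.18, test = 0.30),
                                        sv = c(neutral = 0.04, test = 0.08))),
                      ...)
}

# Resolve the sub-resolution ambiguity of the final censored visit before a
# round-trip comparison: a ground-truth tail shorter than one 1-Hz sample
# cannot be observed, and one of 0.5-1 s may or may not surface as a single
# 1-sample recovered tail depending on where the crossing falls within the
# second. Drops the ground-truth tail when it is sub-sample, and the
# 1-sample recovered tail only in that case.
align_subresolution_tail <- function(gt, vis) {
  if (nrow(gt) && gt$censored[nrow(gt)] && gt$duration[nrow(gt)] < 1) {
    gt <- gt[-nrow(gt), ]
    gt$censored[nrow(gt)] <- TRUE
    if (nrow(vis) == nrow(gt) + 1L && vis$censored[nrow(vis)] &&
        vis$duration[nrow(vis)] <= 1) {
      vis <- vis[-nrow(vis), ]
      vis$censored[nrow(vis)] <- TRUE
    }
  }
  list(gt = gt, vis = vis)
}
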