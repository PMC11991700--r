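#' Default cage geometry for the chamber preference test
#'
#' Coordinates are normalized to the floor-corner frame: `x` runs 0..1 from
#' the neutral-side wall to the test-side wall, `y` 0..1 across the floor
#' depth. The tunnel connecting the chambers occupies an x-interval; samples
#' inside it are attached to the visit they interrupt.
#'
#' @param tunnel_x length-2 numeric, tunnel x-interval in normalized units.
#' @param test_side which side (`"right"` = larger x) is the test chamber.
#' @export
cage_geometry <- function(tunnel_x = c(0.45, 0.55), test_side = c("right", "left")) {
  test_side <- match.arg(test_side)
  stopifnot(length(tunnel_x) == 2L, tunnel_x[1] < tunnel_x[2],
            tunnel_x[1] > 0, tunnel_x[2] < 1)
  structure(list(tunnel_x = tunnel_x, test_side = test_side,
                 # pixel frame used by the generator: floor corners and tops
                 px = list(x0 = 50, x1 = 450, y0 = 50, y1 = 250, y_top = 400)),
            class = "cage_geometry")
}

#' Configuration for synthetic behaviour sessions
#'
#' Defines the study conditions emulated by [gen_behavior_sessions()]:
#' 30-minute two-chamber sessions in which the length of every chamber visit
#' is a first-passage time of the drift-diffusion decision process for the
#' currently occupied chamber, with genotype- and chamber-dependent drift
#' `v` and across-visit drift variability `sv`, and a Gaussian per-animal
#' random effect on the drift.
#'
#' The default decision-scale parameters (`a = 13`, `z = 0.5`, drifts of
#' 0.18-0.30 evidence/s, `sv` 0.04-0.08) produce visit lengths of tens of
#' seconds and roughly 60-100 visits per 30-minute session, matching the
#' visit structure typical of this assay; the second default genotype has a
#' reduced test-chamber drift, i.e. longer warm-chamber visits.
#'
#' @param genotypes named list; one entry per genotype, each a list with
#'   numeric vectors `v` and `sv` named by chamber (`neutral`, `test`).
#' @param n_animals_per_genotype animals simulated per genotype.
#' @param a,z boundary separation and relative starting point shared by all
#'   conditions (the within-visit diffusion coefficient is fixed at 1).
#' @param re_sd SD of the per-animal drift random effect.
#' @param session_length session duration (s).
#' @param temp_combo label of the temperature combination (e.g. `"31v34"`).
#' @param geometry a [cage_geometry()].
#' @param frame_rate keypoint sampling rate (Hz).
#' @param keypoint_noise_sd keypoint jitter SD in normalized cage units.
#' @param dropout_prob per-frame probability that an animal keypoint is a
#'   low-likelihood (corrupted) prediction, in `[0, 1)`.
#' @param climbing_frac fraction of frames placed in the wall band between
#'   floor and top corners (flag-level climbing injection for QC tests).
#' @param seed integer seed.
#' @export
behavior_sim_config <- function(
    genotypes = list(
      wildtype = list(v = c(neutral = 0.18, test = 0.30),
                      sv = c(neutral = 0.04, test = 0.08)),
      trpm2_ko = list(v = c(neutral = 0.18, test = 0.20),
                      sv = c(neutral = 0.04, test = 0.08))),
    n_animals_per_genotype = 5L,
    a = 13, z = 0.5, re_sd = 0.02,
    session_length = 1800, temp_combo = "31v34",
    geometry = cage_geometry(), frame_rate = 20,
    keypoint_noise_sd = 0.01, dropout_prob = 0.05,
    climbing_frac = 0, seed = 1L) {
  stopifnot(session_length > 0, a > 0, frame_rate > 0)
  if (!(z > 0 && z < 1)) stop("`z` must lie strictly in (0, 1)")
  if (!(dropout_prob >= 0 && dropout_prob < 1)) stop("`dropout_prob` must be in [0, 1)")
  for (g in genotypes) {
    stopifnot(all(c("neutral", "test") %in% names(g$v)),
              all(c("neutral", "test") %in% names(g$sv)))
    if (any(g$sv < 0)) stop("`sv` must be >= 0")
  }
  structure(as.list(environment()), class = "behavior_sim_config")
}

ANIMAL_KEYPOINTS <- c("snout", "ear_right", "ear_left", "body_centre",
                      "tail_base", "tail_tip")
CAGE_KEYPOINTS <- c("corner_bl", "corner_br", "corner_tl", "corner_tr",
                    "top_bl", "top_br", "top_tl", "top_tr")

new_keypoint_track <- function(x, y, likelihood, frame_rate) {
  stopifnot(identical(dim(x), dim(y)), identical(dim(x), dim(likelihood)))
  structure(list(x = x, y = y, likelihood = likelihood,
                 keypoints = colnames(x), frame_rate = frame_rate),
            class = "keypoint_track")
}

#' @export
print.keypoint_track <- function(x, ...) {
  cat(sprintf("Keypoint track: %d frames at %g Hz, %d keypoints\n",
              nrow(x$x), x$frame_rate, ncol(x$x)))
  invisible(x)
}

# alternating-chamber visit sequence filling one session
sim_session_visits <- function(v, sv, a, z, session_length, start_chamber,
                               dt = 1e-3) {
  chambers <- character(0); durations <- numeric(0); drifts <- numeric(0)
  cur <- start_chamber; total <- 0
  while (total < session_length) {
    one <- sim_visit_durations(v[cur], sv[cur], a, z, dt = dt)
    chambers <- c(chambers, cur)
    durations <- c(durations, one$time)
    drifts <- c(drifts, one$drift)
    total <- total + one$time
    cur <- if (cur == "neutral") "test" else "neutral"
  }
  start <- cumsum(c(0, durations[-length(durations)]))
  end <- pmin(start + durations, session_length)
  censored <- c(rep(FALSE, length(durations) - 1L), TRUE)
  tibble::tibble(chamber = chambers, start = start, end = end,
                 duration = end - start, censored = censored,
                 drift_draw = drifts)
}

#' Generate synthetic behaviour sessions with known ground truth
#'
#' For every animal, simulates an alternating neutral/test visit sequence
#' whose visit lengths are upper-boundary first-passage times of the
#' configured decision process (drift drawn per visit; lower-bound
#' absorptions are latent non-exits and are resampled), truncates the final
#' visit at the session end (censored flag), and renders a keypoint track
#' placing the animal centroid inside the occupied chamber with Gaussian
#' jitter and likelihood dropouts, together with the eight cage reference
#' points.
#'
#' @param config a [behavior_sim_config()].
#' @return list with `tracks` (named list of `keypoint_track`), `visits`
#'   (ground-truth visit table over all sessions), `animals` (animal,
#'   genotype, random effect), and `config`.
#' @export
gen_behavior_sessions <- function(config = behavior_sim_config()) {
  stopifnot(inherits(config, "behavior_sim_config"))
  set.seed(config$seed)
  geom <- config$geometry
  tracks <- list(); visit_tabs <- list(); animal_rows <- list()
  for (g in names(config$genotypes)) {
    pars <- config$genotypes[[g]]
    for (i in seq_len(config$n_animals_per_genotype)) {
      id <- sprintf("%s_%02d", g, i)
      b <- rnorm(1, 0, config$re_sd)
      start_chamber <- if (runif(1) < 0.5) "neutral" else "test"
      vis <- sim_session_visits(pars$v + b, pars$sv, config$a, config$z,
                                config$session_length, start_chamber)
      tracks[[id]] <- render_keypoint_track(vis, config)
      visit_tabs[[id]] <- dplyr::mutate(vis, animal = id, genotype = g,
                                        temp_combo = config$temp_combo,
                                        .before = 1)
      animal_rows[[id]] <- tibble::tibble(animal = id, genotype = g,
                                          random_effect = b)
    }
  }
  list(tracks = tracks,
       visits = dplyr::bind_rows(visit_tabs),
       animals = dplyr::bind_rows(animal_rows),
       config = config)
}

# place keypoints frame by frame from the ground-truth visit sequence
render_keypoint_track <- function(visits, config) {
  geom <- config$geometry
  px <- geom$px
  fr <- config$frame_rate
  n <- round(config$session_length * fr)
  tt <- (seq_len(n) - 1) / fr
  # chamber occupied at each frame time
  idx <- findInterval(tt, visits$start)
  chamber <- visits$chamber[idx]
  x_centre <- ifelse(chamber == "test",
                     if (geom$test_side == "right") 0.78 else 0.22,
                     if (geom$test_side == "right") 0.22 else 0.78)
  sd_px <- config$keypoint_noise_sd * (px$x1 - px$x0)
  cx <- px$x0 + x_centre * (px$x1 - px$x0) + rnorm(n, 0, 3 * sd_px)
  cy <- px$y0 + 0.3 * (px$y1 - px$y0) + rnorm(n, 0, 3 * sd_px)
  if (config$climbing_frac > 0) {
    n_cl <- round(config$climbing_frac * n)
    cl <- seq_len(n_cl) # leading block; which frames does not matter for QC
    cy[cl] <- px$y1 + 0.5 * (px$y_top - px$y1) + rnorm(n_cl, 0, sd_px)
  }
  offs <- list(snout = c(10, 0), ear_right = c(5, 4), ear_left = c(5, -4),
               body_centre = c(0, 0), tail_base = c(-8, 0), tail_tip = c(-18, 0))
  K <- length(ANIMAL_KEYPOINTS) + length(CAGE_KEYPOINTS)
  X <- Y <- L <- matrix(NA_real_, n, K,
                        dimnames = list(NULL, c(ANIMAL_KEYPOINTS, CAGE_KEYPOINTS)))
  for (k in ANIMAL_KEYPOINTS) {
    X[, k] <- cx + offs[[k]][1] + rnorm(n, 0, sd_px)
    Y[, k] <- cy + offs[[k]][2] + rnorm(n, 0, sd_px)
    drop <- runif(n) < config$dropout_prob
    L[, k] <- ifelse(drop, runif(n, 0, 0.949), runif(n, 0.97, 1))
    X[drop, k] <- X[drop, k] + runif(sum(drop), -80, 80)
    Y[drop, k] <- Y[drop, k] + runif(sum(drop), -80, 80)
  }
  ref <- list(corner_bl = c(px$x0, px$y0), corner_br = c(px$x1, px$y0),
              corner_tl = c(px$x0, px$y1), corner_tr = c(px$x1, px$y1),
              top_bl = c(px$x0, px$y_top), top_br = c(px$x1, px$y_top),
              top_tl = c(px$x0, px$y_top), top_tr = c(px$x1, px$y_top))
  for (k in CAGE_KEYPOINTS) {
    X[, k] <- ref[[k]][1] + rnorm(n, 0, 0.5)
    Y[, k] <- ref[[k]][2] + rnorm(n, 0, 0.5)
    L[, k] <- runif(n, 0.99, 1)
  }
  new_keypoint_track(X, Y, L, fr)
}

#' Write / read a keypoint track as delimited text
#'
#' One row per frame and keypoint with columns
#' `frame, keypoint, x, y, likelihood`, mirroring common pose-estimation
#' export dialects.
#'
#' @param track a `keypoint_track`.
#' @param path file path.
#' @export
write_keypoint_csv <- function(track, path) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(cbind(frame = seq_len(nrow(track$x)) - 1L,
                            as.data.frame(track$x))),
    -"frame", names_to = "keypoint", values_to = "x")
  df$y <- as.vector(t(track$y))
  df$likelihood <- as.vector(t(track$likelihood))
  df$frame_rate <- track$frame_rate
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_keypoint_csv
#' @param path file path.
#' @export
read_keypoint_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  kp <- unique(df$keypoint)
  n <- max(df$frame) + 1L
  shape <- function(col) {
    m <- matrix(df[[col]], nrow = n, ncol = length(kp), byrow = TRUE)
    colnames(m) <- kp
    m
  }
  new_keypoint_track(shape("x"), shape("y"), shape("likelihood"),
                     frame_rate = df$frame_rate[1])
}
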