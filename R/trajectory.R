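#' Clean a keypoint track
#'
#' Replaces low-likelihood predictions (below `likelihood_thresh`) with
#' missing values, rejects sessions whose animal-keypoint missing fraction
#' exceeds `max_missing_frac` (strict `>`), and linearly interpolates the
#' remaining gaps.
#'
#' @param track a `keypoint_track`.
#' @param likelihood_thresh predictions with likelihood `<` this value are
#'   treated as missing (default 0.95).
#' @param max_missing_frac sessions with a missing fraction `>` this value
#'   (over all animal keypoints and frames) are rejected (default 0.25).
#' @return the cleaned `keypoint_track`, or an object of class
#'   `session_rejection` carrying the reason.
#' @export
clean_track <- function(track, likelihood_thresh = 0.95, max_missing_frac = 0.25) {
  stopifnot(inherits(track, "keypoint_track"),
            likelihood_thresh > 0, likelihood_thresh < 1,
            max_missing_frac > 0, max_missing_frac < 1)
  animal <- intersect(ANIMAL_KEYPOINTS, track$keypoints)
  bad <- track$likelihood[, animal, drop = FALSE] < likelihood_thresh
  missing_frac <- mean(bad | is.na(track$x[, animal, drop = FALSE]))
  if (missing_frac > max_missing_frac) {
    return(session_rejection(sprintf(
      "missing fraction %.1f%% exceeds %.0f%%", 100 * missing_frac,
      100 * max_missing_frac)))
  }
  x <- track$x; y <- track$y
  x[, animal][bad] <- NA_real_
  y[, animal][bad] <- NA_real_
  for (k in animal) {
    if (all(is.na(x[, k]))) {
      return(session_rejection(sprintf("keypoint '%s' entirely missing", k)))
    }
    x[, k] <- zoo::na.approx(x[, k], na.rm = FALSE, rule = 2)
    y[, k] <- zoo::na.approx(y[, k], na.rm = FALSE, rule = 2)
  }
  new_keypoint_track(x, y, track$likelihood, track$frame_rate)
}

session_rejection <- function(reason) {
  structure(list(reason = reason), class = "session_rejection")
}

#' @export
print.session_rejection <- function(x, ...) {
  cat("Session rejected:", x$reason, "\n")
  invisible(x)
}

#' Is an object a session rejection?
#' @param x object.
#' @export
is_rejected <- function(x) inherits(x, "session_rejection")

centroid_xy <- function(track) {
  kp <- intersect(c("ear_right", "ear_left", "body_centre", "tail_base"),
                  track$keypoints)
  list(x = rowMeans(track$x[, kp, drop = FALSE]),
       y = rowMeans(track$y[, kp, drop = FALSE]))
}

#' Flag excessive climbing
#'
#' TRUE iff the fraction of frames in which the animal centroid sits in the
#' wall band between the (lower) cage corners and the cage tops exceeds
#' `frac_thresh` (strict `>`). The band starts `band_margin` of the wall
#' height above the floor-corner line.
#'
#' @param track a `keypoint_track` including corner and top keypoints.
#' @param frac_thresh climbing-time fraction threshold (default 0.95).
#' @param band_margin fraction of the corner-to-top distance above which a
#'   centroid counts as on the wall (default 0.2).
#' @export
qc_climbing <- function(track, frac_thresh = 0.95, band_margin = 0.2) {
  corners <- intersect(c("corner_bl", "corner_br", "corner_tl", "corner_tr"),
                       track$keypoints)
  tops <- intersect(c("top_bl", "top_br", "top_tl", "top_tr"), track$keypoints)
  if (length(corners) < 4L || length(tops) < 4L) {
    stop("corner/top reference keypoints are required for the climbing QC")
  }
  y_floor <- max(apply(track$y[, corners, drop = FALSE], 2, median))
  y_top <- median(apply(track$y[, tops, drop = FALSE], 2, median))
  band_lo <- y_floor + band_margin * (y_top - y_floor)
  cy <- centroid_xy(track)$y
  frac <- mean(cy > band_lo & cy <= y_top)
  frac > frac_thresh
}

#' Convert a cleaned track to a 1 Hz normalized position trace
#'
#' Uses the centroid of the ears, body centre and tail base as the animal
#' position, scales it affinely to the tracked cage-corner frame (so camera
#' or setup shifts cancel), downsamples to 1 Hz by within-second averaging,
#' and keeps exactly the first 30 minutes.
#'
#' @param track a cleaned `keypoint_track`.
#' @param session_length required session length (s); shorter sessions are
#'   rejected.
#' @return tibble with columns `time` (s, start of each second), `x`, `y`
#'   (normalized units), or a `session_rejection`.
#' @export
to_position <- function(track, session_length = 1800) {
  stopifnot(inherits(track, "keypoint_track"))
  cen <- centroid_xy(track)
  corners <- c("corner_bl", "corner_br", "corner_tl", "corner_tr")
  cx <- apply(track$x[, corners, drop = FALSE], 2, median)
  cy <- apply(track$y[, corners, drop = FALSE], 2, median)
  xn <- (cen$x - min(cx)) / (max(cx) - min(cx))
  yn <- (cen$y - min(cy)) / (max(cy) - min(cy))
  sec <- floor((seq_along(xn) - 1) / track$frame_rate)
  n_full <- floor(length(xn) / track$frame_rate)
  if (n_full < session_length) {
    return(session_rejection(sprintf(
      "session shorter than %d s (%d s recorded)", session_length, n_full)))
  }
  keep <- sec < session_length
  counts <- tabulate(sec[keep] + 1L, nbins = session_length)
  tibble::tibble(
    time = 0:(session_length - 1),
    x = as.numeric(rowsum(xn[keep], sec[keep])) / counts,
    y = as.numeric(rowsum(yn[keep], sec[keep])) / counts)
}

#' Segment a position trace into chamber visits
#'
#' Assigns each 1 Hz sample to a chamber from its x-position (tunnel samples
#' inherit the chamber of the preceding visit; a leading tunnel run joins
#' the first visit), merges maximal runs into visits, and censors the last
#' visit at the session end. A crossing is a completed chamber change.
#'
#' @param pos a position trace from [to_position()].
#' @param geometry a [cage_geometry()].
#' @return tibble of visits (`chamber`, `start`, `end`, `duration`,
#'   `censored`); attribute `crossings` carries the crossing count. An
#'   entirely-in-tunnel trace yields zero rows with a warning.
#' @export
segment_visits <- function(pos, geometry = cage_geometry()) {
  stopifnot(inherits(geometry, "cage_geometry"))
  tun <- geometry$tunnel_x
  side <- function(x) ifelse(x < tun[1], "left", ifelse(x > tun[2], "right", "tunnel"))
  lab <- side(pos$x)
  right_is_test <- geometry$test_side == "right"
  lab[lab == "left"] <- if (right_is_test) "neutral" else "test"
  lab[lab == "right"] <- if (right_is_test) "test" else "neutral"
  if (all(lab == "tunnel")) {
    warning("position trace lies entirely in the tunnel; no visits")
    out <- tibble::tibble(chamber = character(), start = numeric(),
                          end = numeric(), duration = numeric(),
                          censored = logical())
    attr(out, "crossings") <- 0L
    return(out)
  }
  # tunnel samples inherit the previous chamber; leading tunnel samples the next
  lab <- zoo::na.locf(replace(lab, lab == "tunnel", NA), na.rm = FALSE)
  lab <- zoo::na.locf(lab, fromLast = TRUE, na.rm = FALSE)
  r <- rle(lab)
  end_idx <- cumsum(r$lengths)
  start_idx <- end_idx - r$lengths + 1L
  dt <- if (length(pos$time) > 1) pos$time[2] - pos$time[1] else 1
  out <- tibble::tibble(
    chamber = r$values,
    start = pos$time[start_idx],
    end = pos$time[end_idx] + dt,
    censored = c(rep(FALSE, length(r$values) - 1L), TRUE))
  out$duration <- out$end - out$start
  out <- out[, c("chamber", "start", "end", "duration", "censored")]
  attr(out, "crossings") <- length(r$values) - 1L
  out
}

#' Descriptive session summary
#'
#' The assay's standard descriptive statistics: proportion of time in the
#' test chamber per 3-minute bin; mean visit length in a 3-minute rolling
#' window advanced with a 1-minute lag (windows keyed on visit start times;
#' a visit belongs to every window containing its start); and the crossing
#' count per rolling window.
#'
#' @param visits a visit table from [segment_visits()] (or the generator's
#'   ground truth).
#' @param session_length session duration (s).
#' @param bin_s preference bin width (s).
#' @param window_s,lag_s rolling-window width and lag (s).
#' @return list of tibbles `preference` (bin, start, test_fraction),
#'   `visit_lengths` (window_start, mean_visit_length, n_visits) and
#'   `crossings` (window_start, crossings).
#' @export
summarize_session <- function(visits, session_length = 1800, bin_s = 180,
                              window_s = 180, lag_s = 60) {
  stopifnot(nrow(visits) > 0)
  bins <- seq(0, session_length - bin_s, by = bin_s)
  test_time <- vapply(bins, function(b0) {
    ov <- pmin(visits$end, b0 + bin_s) - pmax(visits$start, b0)
    sum(pmax(ov, 0)[visits$chamber == "test"])
  }, numeric(1))
  preference <- tibble::tibble(bin = seq_along(bins), start = bins,
                               test_fraction = test_time / bin_s)
  wins <- seq(0, session_length - window_s, by = lag_s)
  starts <- visits$start
  in_win <- function(w0) starts >= w0 & starts < w0 + window_s
  visit_lengths <- tibble::tibble(
    window_start = wins,
    mean_visit_length = vapply(wins, function(w0) {
      sel <- in_win(w0)
      if (any(sel)) mean(visits$duration[sel]) else NA_real_
    }, numeric(1)),
    n_visits = vapply(wins, function(w0) sum(in_win(w0)), numeric(1)))
  # a crossing is a visit start that is not the session start
  cross_starts <- starts[-1L]
  crossings <- tibble::tibble(
    window_start = wins,
    crossings = vapply(wins, function(w0)
      sum(cross_starts >= w0 & cross_starts < w0 + window_s), numeric(1)))
  list(preference = preference, visit_lengths = visit_lengths,
       crossings = crossings)
}
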