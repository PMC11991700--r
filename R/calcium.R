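#' Neuropil correction
#'
#' Subtracts a fraction `r` of the surrounding-neuropil trace from each
#' cell's raw fluorescence (the conventional 70% rule by default).
#'
#' @param F,Fneu cell x time matrices of identical shape (a.u.).
#' @param r contamination fraction in `[0, 1)`.
#' @export
neuropil_correct <- function(F, Fneu, r = 0.7) {
  if (!identical(dim(F), dim(Fneu))) {
    stop("F and Fneu must have identical shapes")
  }
  if (!(r >= 0 && r < 1)) stop("`r` must lie in [0, 1)")
  F - r * Fneu
}

#' Normalise fluorescence to dF/F0
#'
#' `(F - F0) / F0` per cell, with the session convention: F0 is the mean
#' over the first `baseline_s` seconds (10 s by default). Cells with
#' `F0 <= 0` are flagged invalid (rows set to `NA`, indices in attribute
#' `"invalid_cells"`) and must be excluded downstream. Optional percentile
#' clipping bounds the result at the empirical 0.1 and 99.9 percentiles.
#'
#' @param F cell x time matrix (neuropil-corrected a.u.).
#' @param sample_rate acquisition rate (Hz).
#' @param baseline_s length of the baseline window (s).
#' @param clip apply percentile clipping?
#' @param clip_probs lower/upper clipping percentiles.
#' @return cell x time dF/F0 matrix (attributes: `invalid_cells`,
#'   `clip_bounds` when clipped).
#' @export
dff <- function(F, sample_rate, baseline_s = 10, clip = FALSE,
                clip_probs = c(0.001, 0.999)) {
  nb <- round(baseline_s * sample_rate)
  if (nb < 1 || nb > ncol(F)) stop("baseline window must lie inside the recording")
  f0 <- rowMeans(F[, seq_len(nb), drop = FALSE])
  invalid <- which(!(f0 > 0))
  d <- sweep(sweep(F, 1, f0, "-"), 1, f0, "/")
  if (length(invalid)) d[invalid, ] <- NA_real_
  if (clip) {
    bounds <- quantile(d, probs = clip_probs, na.rm = TRUE, names = FALSE)
    d[d < bounds[1]] <- bounds[1]
    d[d > bounds[2]] <- bounds[2]
    attr(d, "clip_bounds") <- bounds
  }
  attr(d, "invalid_cells") <- invalid
  d
}

#' Per-stimulus dF/F0 windows
#'
#' Cuts a window `[start - pre_s, end + post_s]` around every epoch and
#' renormalises each cell with the per-stimulus convention: F0 is the mean
#' of the first `n_frames` frames of the window.
#'
#' @param F cell x time matrix (neuropil-corrected a.u.).
#' @param sample_rate Hz.
#' @param epochs tibble with `stimulus`, `start`, `end` (s).
#' @param pre_s,post_s window margins (s).
#' @param n_frames frames used as F0.
#' @return named list (per stimulus) of cell x window dF/F0 matrices, each
#'   with attribute `"time"` (s).
#' @export
dff_per_stimulus <- function(F, sample_rate, epochs, pre_s = 10, post_s = 10,
                             n_frames = 10) {
  out <- list()
  n_t <- ncol(F)
  for (j in seq_len(nrow(epochs))) {
    i0 <- max(1L, round((epochs$start[j] - pre_s) * sample_rate) + 1L)
    i1 <- min(n_t, round((epochs$end[j] + post_s) * sample_rate))
    w <- F[, i0:i1, drop = FALSE]
    f0 <- rowMeans(w[, seq_len(min(n_frames, ncol(w))), drop = FALSE])
    d <- sweep(sweep(w, 1, f0, "-"), 1, f0, "/")
    d[!(f0 > 0), ] <- NA_real_
    attr(d, "time") <- (seq(i0, i1) - 1) / sample_rate
    out[[epochs$stimulus[j]]] <- d
  }
  out
}

#' Split stimuli into dynamic and static phases
#'
#' Computes the temperature change rate (centred 1-s finite difference),
#' smooths it with a centred moving average of width `smooth_s`, locates
#' the rate peak inside each epoch and places the phase boundary at the end
#' of that peak: the first time after the peak at which the smoothed rate
#' falls below `thresh_frac` of the peak rate. The default half-maximum
#' threshold puts the boundary at the ramp end for an ideal ramp+plateau
#' stimulus. Dynamic phase = epoch start to boundary; static = boundary to
#' epoch end.
#'
#' @param stimulus tibble with `time` (s) and `temperature` (degC).
#' @param epochs tibble of stimulus epochs (`stimulus`, `start`, `end`);
#'   only rows with `kind == "warm"` are used when a `kind` column exists.
#' @param smooth_s smoothing window (s).
#' @param thresh_frac fraction of the peak rate defining the end of the
#'   peak (default 0.5).
#' @return tibble: stimulus, dynamic_start, boundary, static_end.
#' @export
segment_phases <- function(stimulus, epochs, smooth_s = 2, thresh_frac = 0.5) {
  if ("kind" %in% names(epochs)) epochs <- epochs[epochs$kind == "warm", ]
  tt <- stimulus$time
  sr <- 1 / median(diff(tt))
  k <- max(1L, round(0.5 * sr))
  temp <- stimulus$temperature
  n <- length(temp)
  rate <- rep(NA_real_, n)
  idx <- (k + 1):(n - k)
  rate[idx] <- (temp[idx + k] - temp[idx - k]) / (2 * k / sr)
  win <- max(1L, round(smooth_s * sr))
  if (win %% 2 == 0) win <- win + 1L
  rate_s <- as.numeric(stats::filter(rate, rep(1 / win, win), sides = 2))
  out <- lapply(seq_len(nrow(epochs)), function(j) {
    sel <- which(tt >= epochs$start[j] & tt <= epochs$end[j] & !is.na(rate_s))
    if (!length(sel)) stop("no rate samples inside epoch ", epochs$stimulus[j])
    pk_i <- sel[which.max(rate_s[sel])]
    pk <- rate_s[pk_i]
    if (!(pk > 0)) {
      stop("no positive temperature-rate peak in epoch ", epochs$stimulus[j])
    }
    after <- sel[sel > pk_i]
    below <- after[rate_s[after] < thresh_frac * pk]
    boundary <- if (length(below)) tt[below[1]] else epochs$end[j]
    tibble::tibble(stimulus = epochs$stimulus[j],
                   dynamic_start = epochs$start[j],
                   boundary = boundary,
                   static_end = epochs$end[j])
  })
  dplyr::bind_rows(out)
}

# ---- responder classification -------------------------------------------

# average-pool a trace to the target rate (4 Hz by convention)
downsample_trace <- function(x, sample_rate, target = 4) {
  f <- max(1L, round(sample_rate / target))
  if (f == 1L) return(x)
  n <- floor(length(x) / f)
  colMeans(matrix(x[seq_len(n * f)], nrow = f))
}

# fixed feature set for one per-stimulus window (already dF/F0)
trace_features <- function(trace, time, epoch_start, epoch_end, sample_rate) {
  x <- downsample_trace(trace, sample_rate, 4)
  # light smoothing suppresses single-sample noise peaks
  x <- as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))
  x[1] <- x[2]; x[length(x)] <- x[length(x) - 1]
  tt <- seq(time[1], by = 1 / 4, length.out = length(x))
  pre <- x[tt < epoch_start]
  ine <- x[tt >= epoch_start & tt <= epoch_end]
  if (length(pre) < 4 || length(ine) < 4) {
    return(c(peak_z = 0, win_z = 0, mean_resp = 0, late_resp = 0, auc = 0))
  }
  mu0 <- mean(pre); s0 <- sd(pre) + 1e-6
  # response may start anywhere in the epoch (dynamic or late static
  # onsets): the strongest 3-s window mean is onset-agnostic
  ine_ext <- x[tt >= epoch_start & tt <= epoch_end + 3]
  wlen <- min(12L, length(ine_ext))
  roll <- stats::filter(ine_ext, rep(1 / wlen, wlen), sides = 2)
  win_z <- (max(roll, na.rm = TRUE) - mu0) / s0
  c(peak_z = (max(ine) - mu0) / s0,
    win_z = win_z,
    mean_resp = mean(ine) - mu0,
    late_resp = mean(ine[seq(ceiling(0.6 * length(ine)), length(ine))]) - mu0,
    auc = sum((x - mu0)[tt >= epoch_start & tt <= epoch_end]) / 4)
}

# feature table for all cells x stimuli of a recording
feature_table <- function(F, sample_rate, epochs, pre_s = 10, post_s = 10) {
  wins <- dff_per_stimulus(F, sample_rate, epochs, pre_s, post_s)
  rows <- list()
  for (j in seq_len(nrow(epochs))) {
    w <- wins[[epochs$stimulus[j]]]
    tt <- attr(w, "time")
    fx <- t(apply(w, 1, function(tr) {
      if (anyNA(tr)) return(c(peak_z = 0, win_z = 0, mean_resp = 0,
                              late_resp = 0, auc = 0))
      trace_features(tr, tt, epochs$start[j], epochs$end[j], sample_rate)
    }))
    rows[[j]] <- tibble::tibble(cell = seq_len(nrow(F)),
                                stimulus = epochs$stimulus[j],
                                tibble::as_tibble(fx))
  }
  dplyr::bind_rows(rows)
}

#' Train the responder classifier on labelled synthetic traces
#'
#' Builds a labelled library of per-stimulus traces (responders and
#' non-responders across a range of amplitudes and noise levels) from the
#' calcium generator and fits a logistic regression on a fixed feature set
#' (stimulus-epoch peak and strongest 3-s window z-scores against the
#' pre-stimulus baseline, and mean and late-epoch responses). The
#' trace-level classifier is deterministic
#' given its coefficients: identical inputs give identical calls.
#'
#' @param n_cells size of the labelled library (default 1000 traces'
#'   worth of cells across the three stimuli).
#' @param seed integer seed for the library.
#' @param threshold posterior-probability call threshold.
#' @return an object of class `responder_classifier`.
#' @export
train_responder_classifier <- function(n_cells = 340L, seed = 42L,
                                       threshold = 0.5) {
  cfg <- calcium_sim_config(n_cells = n_cells, frac_responders = 0.5,
                            response_prob = c(1, 1, 1),
                            include_agonists = FALSE, seed = seed)
  b <- gen_calcium_dataset(cfg)
  fc <- neuropil_correct(b$F, b$Fneu, cfg$neuropil_gain)
  feats <- feature_table(fc, cfg$sample_rate, b$epochs)
  lab <- tidyr::pivot_longer(
    b$truth[, c("cell", grep("^responds_s", names(b$truth), value = TRUE))],
    -"cell", names_to = "stim_idx", values_to = "label")
  lab$stimulus <- paste0("warm", as.integer(sub("responds_s", "", lab$stim_idx)))
  df <- dplyr::inner_join(feats, lab[, c("cell", "stimulus", "label")],
                          by = c("cell", "stimulus"))
  # auc is proportional to mean_resp over a fixed epoch, so it is left out
  fit <- glm(label ~ peak_z + win_z + mean_resp + late_resp,
             family = binomial(), data = df)
  cf <- coef(fit)
  cf[is.na(cf)] <- 0
  structure(list(coef = cf, threshold = threshold,
                 features = c("peak_z", "win_z", "mean_resp", "late_resp")),
            class = "responder_classifier")
}

#' Classify temperature-responsive cells
#'
#' Applies the trained feature-based classifier to every cell x stimulus
#' window of a recording (traces are renormalised per stimulus and
#' downsampled to 4 Hz before feature extraction).
#'
#' @param F cell x time neuropil-corrected fluorescence matrix.
#' @param sample_rate Hz.
#' @param epochs epoch table (`stimulus`, `start`, `end`).
#' @param model a trained [train_responder_classifier()] object.
#' @return tibble: cell, stimulus, prob, responder.
#' @export
classify_responders <- function(F, sample_rate, epochs, model) {
  if (!inherits(model, "responder_classifier")) {
    stop("`model` must be a trained responder_classifier")
  }
  feats <- feature_table(F, sample_rate, epochs)
  X <- cbind(1, as.matrix(feats[, model$features]))
  prob <- plogis(as.numeric(X %*% model$coef))
  tibble::tibble(cell = feats$cell, stimulus = feats$stimulus,
                 prob = prob, responder = prob >= model$threshold)
}

#' Response onset within a stimulus epoch
#'
#' The onset is the first time inside the epoch at which the trace exceeds
#' 10% of its maximum dF/F0 within that epoch; the phase label compares the
#' onset against the dynamic/static boundary from [segment_phases()].
#'
#' @param trace a single cell's dF/F0 vector.
#' @param time time axis (s) aligned to `trace`.
#' @param epoch_start,epoch_end stimulus epoch (s).
#' @param boundary optional phase boundary (s) for the phase label.
#' @param frac onset threshold as a fraction of the epoch maximum.
#' @return list: `onset` (s), `phase` (`"dynamic"`/`"static"`/`NA`).
#' @export
onset_time <- function(trace, time, epoch_start, epoch_end, boundary = NULL,
                       frac = 0.1) {
  sel <- which(time >= epoch_start & time <= epoch_end)
  if (!length(sel)) stop("epoch outside the trace")
  mx <- max(trace[sel])
  if (!(mx > 0)) stop("non-positive epoch maximum; onset undefined")
  hit <- sel[trace[sel] > frac * mx]
  onset <- time[hit[1]]
  phase <- if (!is.null(boundary)) {
    if (onset <= boundary) "dynamic" else "static"
  } else {
    NA_character_
  }
  list(onset = onset, phase = phase)
}

#' Cell ordering for response heatmaps
#'
#' Orders cells by the earliest time at which their running cumulative
#' dF/F0 crosses 10% of its total; ties keep the original cell order and
#' cells with a non-positive total sort last.
#'
#' @param dffmat cell x time dF/F0 matrix (session convention).
#' @param frac cumulative fraction defining the crossing (default 0.1).
#' @return integer permutation of the cell indices.
#' @export
heatmap_order <- function(dffmat, frac = 0.1) {
  key <- apply(dffmat, 1, function(x) {
    tot <- sum(x)
    if (!(tot > 0)) return(Inf)
    which(cumsum(x) > frac * tot)[1]
  })
  order(key) # order() is stable: ties keep original indices
}

#' Build the per-cell responder table of a recording
#'
#' Combines classifier calls over all epochs with onset timing and phase
#' labels for warm stimuli. Cells that respond to none of the applied
#' stimuli are excluded from the table (their indices are kept in attribute
#' `"excluded_cells"`). A cell is warm-sensitive if it responds to any
#' stimulus with a plateau below 43 degC and a heat responder if it
#' responds at >= 43 degC.
#'
#' @param F neuropil-corrected cell x time matrix.
#' @param sample_rate Hz.
#' @param epochs epoch table with `kind` and `plateau` columns.
#' @param model trained classifier.
#' @param phases optional [segment_phases()] result (computed onsets get
#'   phase labels when supplied).
#' @return tibble, one row per retained cell x warm stimulus, plus per-cell
#'   `capsaicin`, `kcl_viable`, `warm_sensitive`, `heat_responder` flags.
#' @export
responder_table <- function(F, sample_rate, epochs, model, phases = NULL) {
  calls <- classify_responders(F, sample_rate, epochs, model)
  wide <- tidyr::pivot_wider(calls[, c("cell", "stimulus", "responder")],
                             names_from = "stimulus", values_from = "responder")
  any_resp <- rowSums(as.matrix(wide[, -1, drop = FALSE])) > 0
  excluded <- wide$cell[!any_resp]

  warm_ep <- epochs[epochs$kind == "warm" & !is.na(epochs$plateau) &
                      epochs$plateau < 43, ]
  heat_ep <- epochs[epochs$kind == "warm" & !is.na(epochs$plateau) &
                      epochs$plateau >= 43, ]
  warm_flag <- rowSums(as.matrix(wide[, warm_ep$stimulus, drop = FALSE])) > 0
  heat_flag <- if (nrow(heat_ep)) {
    rowSums(as.matrix(wide[, heat_ep$stimulus, drop = FALSE])) > 0
  } else {
    rep(FALSE, nrow(wide))
  }
  caps_flag <- if ("capsaicin" %in% names(wide)) wide$capsaicin else
    rep(FALSE, nrow(wide))
  kcl_flag <- if ("kcl" %in% names(wide)) wide$kcl else rep(TRUE, nrow(wide))

  wins <- dff_per_stimulus(F, sample_rate, epochs)
  warm_stims <- epochs$stimulus[epochs$kind == "warm"]
  rows <- list()
  for (s in warm_stims) {
    w <- wins[[s]]
    tt <- attr(w, "time")
    ep <- epochs[epochs$stimulus == s, ]
    bnd <- if (!is.null(phases)) phases$boundary[phases$stimulus == s] else NULL
    resp_cells <- calls$cell[calls$stimulus == s & calls$responder]
    resp_cells <- setdiff(resp_cells, excluded)
    on <- rep(NA_real_, nrow(wide)); ph <- rep(NA_character_, nrow(wide))
    for (i in resp_cells) {
      o <- tryCatch(onset_time(w[i, ], tt, ep$start, ep$end, bnd),
                    error = function(e) list(onset = NA_real_, phase = NA_character_))
      on[i] <- o$onset; ph[i] <- o$phase
    }
    rows[[s]] <- tibble::tibble(
      cell = wide$cell, stimulus = s,
      responder = wide[[s]], onset = on, onset_phase = ph)
  }
  out <- dplyr::bind_rows(rows)
  out <- out[!out$cell %in% excluded, ]
  percell <- tibble::tibble(cell = wide$cell, capsaicin = caps_flag,
                            kcl_viable = kcl_flag,
                            warm_sensitive = warm_flag,
                            heat_responder = heat_flag)
  out <- dplyr::left_join(out, percell, by = "cell")
  attr(out, "excluded_cells") <- excluded
  out
}

#' Field-of-view summary statistics
#'
#' Responder proportions relative to all viable (KCl-responsive) cells and
#' the mean dF/F0 area under the curve per stimulus among that stimulus'
#' responders (trapezoidal rule over the stimulus epoch).
#'
#' @param rtable a [responder_table()] result.
#' @param F neuropil-corrected cell x time matrix (the full field of view).
#' @param sample_rate Hz.
#' @param epochs epoch table.
#' @param n_viable number of viable cells (denominator); defaults to the
#'   KCl-responsive count among all imaged cells.
#' @return list: `proportions` (per-stimulus responder proportion and the
#'   warm-sensitive proportion), `auc` (per-stimulus mean AUC, unitless*s).
#' @export
fov_stats <- function(rtable, F, sample_rate, epochs, n_viable = NULL) {
  if (is.null(n_viable)) {
    percell <- unique(rtable[, c("cell", "kcl_viable")])
    n_viable <- sum(percell$kcl_viable)
  }
  if (!(n_viable > 0)) stop("zero viable cells; proportions undefined")
  warm_stims <- unique(rtable$stimulus)
  wins <- dff_per_stimulus(F, sample_rate, epochs)
  props <- numeric(); aucs <- numeric()
  for (s in warm_stims) {
    sub <- rtable[rtable$stimulus == s & rtable$responder, ]
    props[s] <- nrow(sub) / n_viable
    w <- wins[[s]]; tt <- attr(w, "time")
    ep <- epochs[epochs$stimulus == s, ]
    sel <- tt >= ep$start & tt <= ep$end
    aucs[s] <- if (nrow(sub)) {
      mean(apply(w[sub$cell, sel, drop = FALSE], 1,
                 function(x) pracma::trapz(tt[sel], x)))
    } else {
      NA_real_
    }
  }
  warm_cells <- unique(rtable$cell[rtable$warm_sensitive])
  list(
    proportions = tibble::tibble(
      stimulus = c(warm_stims, "any_warm"),
      proportion = c(props, length(warm_cells) / n_viable)),
    auc = tibble::tibble(stimulus = warm_stims, mean_auc = aucs),
    n_viable = n_viable)
}
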