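#' Configuration for synthetic calcium imaging recordings
#'
#' Emulates the warm-stimulation imaging protocol: a 1-minute baseline
#' followed by three ascending 25-second warm stimuli (10 s temperature ramp
#' + plateau) separated by 5-minute recovery intervals, optionally followed
#' by capsaicin and high-potassium (KCl) agonist epochs. Responder cells
#' receive transients locked to the dynamic (ramp) or static (plateau)
#' phase of each stimulus according to their ground-truth label; raw
#' fluorescence is composed as cell signal + `neuropil_gain` x shared
#' neuropil + exponential bleaching + Gaussian shot noise.
#'
#' The paper-level protocol constants (60 s baseline, 25 s stimuli, 300 s
#' inter-stimulus interval, 70% neuropil contamination) are the defaults;
#' the plateau temperatures, which the protocol only constrains to ascend
#' within the warm (< 43 degC) range, default to 34/37/40 degC.
#'
#' @param n_cells number of cells.
#' @param frac_responders fraction of warm-responder cells in `[0, 1]`.
#' @param frac_dynamic_onset fraction of responders whose onsets fall in the
#'   dynamic (ramp) phase.
#' @param stimulus_plateaus plateau temperatures (degC), strictly ascending.
#' @param baseline_s,stimulus_s,isi_s protocol timing (s).
#' @param ramp_s rising-phase duration within each stimulus (s).
#' @param sample_rate acquisition rate (Hz).
#' @param neuropil_gain fraction of the neuropil trace mixed into each
#'   cell's raw fluorescence.
#' @param bleach_tau bleaching time constant (s).
#' @param noise_sd shot-noise SD (fluorescence a.u.).
#' @param baseline_temp bath temperature between stimuli (degC).
#' @param temp_noise_sd thermocouple noise SD (degC).
#' @param response_prob per-stimulus response probability of a responder
#'   (ascending; the strongest stimulus always recruits).
#' @param include_agonists append capsaicin and KCl epochs?
#' @param frac_capsaicin fraction of capsaicin-responsive (TRPV1-positive)
#'   cells.
#' @param kcl_viable_frac fraction of cells responding to KCl (viability).
#' @param seed integer seed.
#' @export
calcium_sim_config <- function(
    n_cells = 400L, frac_responders = 0.06, frac_dynamic_onset = 0.7,
    stimulus_plateaus = c(34, 37, 40), baseline_s = 60, stimulus_s = 25,
    isi_s = 300, ramp_s = 10, sample_rate = 10, neuropil_gain = 0.7,
    bleach_tau = 600, noise_sd = 2, baseline_temp = 32, temp_noise_sd = 0.05,
    response_prob = c(0.6, 0.8, 1.0), include_agonists = TRUE,
    frac_capsaicin = 0.4, kcl_viable_frac = 0.97, seed = 1L) {
  if (any(diff(stimulus_plateaus) <= 0)) stop("plateaus must be strictly ascending")
  if (!(frac_responders >= 0 && frac_responders <= 1)) {
    stop("`frac_responders` must lie in [0, 1]")
  }
  stopifnot(length(response_prob) == length(stimulus_plateaus),
            ramp_s < stimulus_s, sample_rate > 0)
  structure(as.list(environment()), class = "calcium_sim_config")
}

# epoch layout for a config (start/end in s, kind, plateau)
calcium_epochs <- function(config) {
  ns <- length(config$stimulus_plateaus)
  starts <- config$baseline_s + (seq_len(ns) - 1) * (config$stimulus_s + config$isi_s)
  ep <- tibble::tibble(
    stimulus = paste0("warm", seq_len(ns)),
    kind = "warm",
    start = starts,
    end = starts + config$stimulus_s,
    plateau = config$stimulus_plateaus)
  if (config$include_agonists) {
    t_cap <- ep$end[ns] + 120
    t_kcl <- t_cap + config$stimulus_s + 120
    ep <- dplyr::bind_rows(ep, tibble::tibble(
      stimulus = c("capsaicin", "kcl"), kind = c("capsaicin", "kcl"),
      start = c(t_cap, t_kcl), end = c(t_cap, t_kcl) + config$stimulus_s,
      plateau = NA_real_))
  }
  ep
}

# canonical calcium transient: difference of exponentials, peak-normalised
calcium_kernel <- function(t, rise = 1, decay = 8) {
  h <- ifelse(t < 0, 0, exp(-t / decay) - exp(-t / rise))
  tpk <- rise * decay / (decay - rise) * log(decay / rise)
  h / (exp(-tpk / decay) - exp(-tpk / rise))
}

#' Generate a synthetic calcium recording with known ground truth
#'
#' @param config a [calcium_sim_config()].
#' @return list with `F` and `Fneu` (cell x time matrices, a.u.),
#'   `stimulus` (tibble `time`, `temperature`), `epochs`, `time` (s),
#'   `truth` (per-cell labels: warm responder, onset phase, per-stimulus
#'   response indicators and true onset times, capsaicin and KCl flags) and
#'   `config`.
#' @export
gen_calcium_dataset <- function(config = calcium_sim_config()) {
  stopifnot(inherits(config, "calcium_sim_config"))
  set.seed(config$seed)
  sr <- config$sample_rate
  ep <- calcium_epochs(config)
  total_s <- max(ep$end) + 60
  n_t <- round(total_s * sr)
  time <- (seq_len(n_t) - 1) / sr
  ns <- length(config$stimulus_plateaus)

  # thermocouple trace: ramp + plateau per warm epoch, 10 s return ramp
  temp <- rep(config$baseline_temp, n_t)
  for (k in seq_len(ns)) {
    s0 <- ep$start[k]; plat <- ep$plateau[k]
    ramp <- time >= s0 & time < s0 + config$ramp_s
    temp[ramp] <- config$baseline_temp +
      (plat - config$baseline_temp) * (time[ramp] - s0) / config$ramp_s
    hold <- time >= s0 + config$ramp_s & time < ep$end[k]
    temp[hold] <- plat
    fall <- time >= ep$end[k] & time < ep$end[k] + 10
    temp[fall] <- plat - (plat - config$baseline_temp) * (time[fall] - ep$end[k]) / 10
  }
  temp <- temp + rnorm(n_t, 0, config$temp_noise_sd)

  nc <- config$n_cells
  responder <- runif(nc) < config$frac_responders
  dynamic <- responder & (runif(nc) < config$frac_dynamic_onset)
  capsaicin <- runif(nc) < config$frac_capsaicin
  viable <- runif(nc) < config$kcl_viable_frac
  f0 <- exp(rnorm(nc, log(100), 0.2))
  amp_dff <- exp(rnorm(nc, log(0.8), 0.4)) # peak dF/F0 at strongest stimulus

  resp_mat <- matrix(FALSE, nc, ns)
  onset_mat <- matrix(NA_real_, nc, ns)
  for (k in seq_len(ns)) {
    resp_mat[, k] <- responder & (runif(nc) < config$response_prob[k])
    on_dyn <- ep$start[k] + runif(nc, 1, config$ramp_s - 1)
    on_sta <- ep$start[k] + runif(nc, config$ramp_s + 2, config$stimulus_s - 5)
    onset_mat[, k] <- ifelse(dynamic, on_dyn, on_sta)
    onset_mat[!resp_mat[, k], k] <- NA_real_
  }

  # shared neuropil: slow wander plus a faint stimulus-coupled component
  wander <- stats::filter(rnorm(n_t, 0, 1), rep(1 / (20 * sr), 20 * sr),
                          circular = TRUE)
  stim_bump <- calcium_kernel(0) * 0
  neu_base <- 30 + 5 * as.numeric(wander) / max(abs(wander), na.rm = TRUE)
  for (k in seq_len(ns)) {
    neu_base <- neu_base + 1.5 * calcium_kernel(time - ep$start[k] - 2)
  }

  bleach <- 0.9 + 0.1 * exp(-time / config$bleach_tau)
  stim_scale <- seq(0.6, 1, length.out = ns)

  F <- matrix(0, nc, n_t)
  Fneu <- matrix(0, nc, n_t)
  clip_warn <- 0L
  for (i in seq_len(nc)) {
    sig <- numeric(n_t)
    for (k in seq_len(ns)) {
      if (resp_mat[i, k]) {
        sig <- sig + amp_dff[i] * stim_scale[k] * calcium_kernel(time - onset_mat[i, k])
      }
    }
    if (config$include_agonists) {
      if (capsaicin[i]) {
        sig <- sig + 1.2 * amp_dff[i] *
          calcium_kernel(time - (ep$start[ep$kind == "capsaicin"] + 2))
      }
      if (viable[i]) {
        sig <- sig + 2.0 * calcium_kernel(time - (ep$start[ep$kind == "kcl"] + 2))
      }
    }
    gain_i <- runif(1, 0.8, 1.2)
    Fneu[i, ] <- gain_i * neu_base + rnorm(n_t, 0, config$noise_sd / 2)
    raw <- f0[i] * bleach * (1 + sig) +
      config$neuropil_gain * Fneu[i, ] + rnorm(n_t, 0, config$noise_sd)
    if (any(raw < 0)) { clip_warn <- clip_warn + 1L; raw[raw < 0] <- 0 }
    F[i, ] <- raw
  }
  if (clip_warn > 0) {
    warning(clip_warn, " cell(s) had negative fluorescence clipped at 0")
  }

  truth <- tibble::tibble(
    cell = seq_len(nc), responder = responder,
    onset_phase = ifelse(responder, ifelse(dynamic, "dynamic", "static"), NA),
    capsaicin = capsaicin, kcl_viable = viable,
    f0 = f0, amplitude = amp_dff)
  for (k in seq_len(ns)) {
    truth[[paste0("responds_s", k)]] <- resp_mat[, k]
    truth[[paste0("onset_s", k)]] <- onset_mat[, k]
  }

  list(F = F, Fneu = Fneu,
       stimulus = tibble::tibble(time = time, temperature = temp),
       epochs = ep, time = time, truth = truth, config = config)
}

#' Write a calcium bundle as delimited text
#'
#' Writes `F.csv`, `Fneu.csv` (cells x time), `stimulus.csv` and
#' `epochs.csv` plus a `meta.csv` into a directory.
#' @param bundle a [gen_calcium_dataset()] result.
#' @param dir output directory (created if needed).
#' @export
write_calcium_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble::as_tibble(bundle$F, .name_repair = "minimal"),
                   file.path(dir, "F.csv"), col_names = FALSE)
  readr::write_csv(tibble::as_tibble(bundle$Fneu, .name_repair = "minimal"),
                   file.path(dir, "Fneu.csv"), col_names = FALSE)
  readr::write_csv(bundle$stimulus, file.path(dir, "stimulus.csv"))
  readr::write_csv(bundle$epochs, file.path(dir, "epochs.csv"))
  readr::write_csv(tibble::tibble(sample_rate = bundle$config$sample_rate,
                                  n_cells = nrow(bundle$F)),
                   file.path(dir, "meta.csv"))
  invisible(dir)
}
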