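#' Run the behaviour pipeline end to end
#'
#' Generator -> track cleaning and QC -> 1 Hz positions -> visit
#' segmentation -> descriptive summaries -> hierarchical drift/noise fit,
#' model comparison and wildtype-subtracted contrasts, written as tidy CSV
#' artifacts with a JSON manifest recording seeds, versions and QC
#' rejections. Deterministic under a fixed config.
#'
#' @param config a [behavior_sim_config()].
#' @param out_dir output directory.
#' @param fit run the hierarchical fit (skipping it leaves only the
#'   descriptive artifacts)?
#' @param sampler list of [sample_posterior()] sizes (scaled profile by
#'   default).
#' @return invisibly, a list with the artifact paths, the QC log and (when
#'   fitted) the posterior.
#' @export
run_behavior <- function(config = behavior_sim_config(), out_dir,
                         fit = TRUE,
                         sampler = list(chains = 2L, tune = 600L,
                                        draws = 400L, seed = config$seed)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sessions <- gen_behavior_sessions(config)
  qc <- list(); visit_rows <- list(); summary_rows <- list()
  for (id in names(sessions$tracks)) {
    cleaned <- clean_track(sessions$tracks[[id]])
    if (is_rejected(cleaned)) { qc[[id]] <- cleaned$reason; next }
    if (qc_climbing(cleaned)) { qc[[id]] <- "excessive climbing"; next }
    pos <- to_position(cleaned, session_length = config$session_length)
    if (is_rejected(pos)) { qc[[id]] <- pos$reason; next }
    vis <- segment_visits(pos, config$geometry)
    if (nrow(vis) == 0L) { qc[[id]] <- "no visits (tunnel only)"; next }
    meta <- sessions$animals[sessions$animals$animal == id, ]
    visit_rows[[id]] <- dplyr::mutate(vis, animal = id,
                                      genotype = meta$genotype,
                                      temp_combo = config$temp_combo,
                                      crossings = attr(vis, "crossings"),
                                      .before = 1)
    sm <- summarize_session(vis, session_length = config$session_length)
    summary_rows[[id]] <- dplyr::mutate(
      dplyr::left_join(sm$preference,
                       dplyr::rename(sm$visit_lengths, start = "window_start"),
                       by = "start"),
      animal = id, .before = 1)
  }
  if (!length(visit_rows)) stop("behaviour stage failed: all sessions rejected (",
                                paste(names(qc), collapse = ", "), ")")
  visits <- dplyr::bind_rows(visit_rows)
  readr::write_csv(visits, file.path(out_dir, "visits.csv"))
  readr::write_csv(dplyr::bind_rows(summary_rows),
                   file.path(out_dir, "summary.csv"))

  artifacts <- list(visits = file.path(out_dir, "visits.csv"),
                    summary = file.path(out_dir, "summary.csv"))
  post <- NULL
  if (fit) {
    table <- visits[, c("animal", "genotype", "temp_combo", "chamber",
                        "duration", "censored")]
    spec_full <- model_spec(v = "predictor", sv = "predictor",
                            a = fixed(config$a), z = fixed(0.9))
    spec_const <- model_spec(v = "predictor", sv = "floating",
                             a = fixed(config$a), z = fixed(0.9))
    post <- fit_ddm(table, spec_full, chains = sampler$chains,
                    tune = sampler$tune, draws = sampler$draws,
                    seed = sampler$seed)
    post_const <- fit_ddm(table, spec_const, chains = sampler$chains,
                          tune = sampler$tune, draws = sampler$draws,
                          seed = sampler$seed + 1L)
    readr::write_csv(posterior_summary(post),
                     file.path(out_dir, "posterior_summary.csv"))
    cmp <- rank_models(fits = list(full = post, constant_sv = post_const))
    readr::write_csv(cmp, file.path(out_dir, "comparison.csv"))
    ctr <- tryCatch(contrasts_vs_wildtype(post), error = function(e) NULL)
    if (!is.null(ctr)) {
      readr::write_csv(ctr, file.path(out_dir, "contrasts.csv"))
      artifacts$contrasts <- file.path(out_dir, "contrasts.csv")
    }
    artifacts$posterior <- file.path(out_dir, "posterior_summary.csv")
    artifacts$comparison <- file.path(out_dir, "comparison.csv")
  }
  manifest <- list(
    stage = "behavior", seed = config$seed,
    package_version = as.character(utils::packageVersion("thermodrift")),
    r_version = R.version.string,
    n_sessions = length(sessions$tracks),
    n_rejected = length(qc), qc_rejections = qc,
    sampler = if (fit) sampler else NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(artifacts = artifacts, qc = qc, posterior = post,
                 visits = visits))
}

#' Run the calcium pipeline end to end
#'
#' Generator -> neuropil correction -> dF/F0 -> phase segmentation ->
#' responder classification, onsets and per-FOV statistics, written as
#' tidy CSV artifacts with a JSON manifest.
#'
#' @param config a [calcium_sim_config()].
#' @param out_dir output directory.
#' @param model a trained classifier (trained on the fly when `NULL`).
#' @return invisibly, artifact paths plus the in-memory tables.
#' @export
run_calcium <- function(config = calcium_sim_config(), out_dir, model = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(model)) model <- train_responder_classifier()
  bundle <- gen_calcium_dataset(config)
  fc <- neuropil_correct(bundle$F, bundle$Fneu, config$neuropil_gain)
  d <- dff(fc, config$sample_rate, clip = TRUE)
  phases <- segment_phases(bundle$stimulus, bundle$epochs)
  rtab <- responder_table(fc, config$sample_rate, bundle$epochs, model, phases)
  stats <- fov_stats(rtab, fc, config$sample_rate, bundle$epochs)

  readr::write_csv(tibble::as_tibble(d, .name_repair = "minimal"),
                   file.path(out_dir, "dff.csv"), col_names = FALSE)
  readr::write_csv(rtab, file.path(out_dir, "responders.csv"))
  onsets <- rtab[rtab$responder & !is.na(rtab$onset),
                 c("cell", "stimulus", "onset", "onset_phase")]
  readr::write_csv(onsets, file.path(out_dir, "onsets.csv"))
  readr::write_csv(dplyr::left_join(stats$proportions, stats$auc,
                                    by = "stimulus"),
                   file.path(out_dir, "fov_stats.csv"))
  readr::write_csv(phases, file.path(out_dir, "phases.csv"))
  manifest <- list(
    stage = "calcium", seed = config$seed,
    package_version = as.character(utils::packageVersion("thermodrift")),
    r_version = R.version.string,
    n_cells = config$n_cells,
    n_excluded = length(attr(rtab, "excluded_cells")),
    n_viable = stats$n_viable)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(
    artifacts = list(dff = file.path(out_dir, "dff.csv"),
                     responders = file.path(out_dir, "responders.csv"),
                     onsets = file.path(out_dir, "onsets.csv"),
                     fov_stats = file.path(out_dir, "fov_stats.csv")),
    responders = rtab, fov = stats, phases = phases, truth = bundle$truth))
}
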