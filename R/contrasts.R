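#' Neutral-corrected, wildtype-subtracted parameter contrasts
#'
#' For every genotype and temperature combination, forms draw-wise
#' `(test chamber - neutral chamber)` differences of the drift `v` and, when
#' modelled, the across-visit drift SD `sv` (on its natural scale), and
#' subtracts the same quantity in the reference (wildtype) genotype. The
#' neutral-chamber correction removes per-condition baselines; the wildtype
#' subtraction expresses every genotype relative to the reference, whose own
#' contrast is identically zero.
#'
#' @param samples a `ddm_posterior` from a model with chamber and genotype
#'   predictors.
#' @param ref_genotype the reference level (default `"wildtype"`).
#' @param prob central interval probability (default 0.94).
#' @return tibble: genotype, temp_combo, parameter (`v`/`sv`), median,
#'   lower, upper; the draw matrices are attached as attribute `"draws"`.
#' @export
contrasts_vs_wildtype <- function(samples, ref_genotype = "wildtype",
                                  prob = 0.94) {
  stopifnot(inherits(samples, "ddm_posterior"))
  model <- samples$model
  xl <- model$xlevels
  if (!"genotype" %in% names(xl) || !"chamber" %in% names(xl)) {
    stop("contrasts need both chamber and genotype as model predictors")
  }
  if (!ref_genotype %in% xl$genotype) {
    stop("reference genotype '", ref_genotype, "' absent from the model")
  }
  grid <- expand.grid(c(xl, list(stringsAsFactors = FALSE)))
  for (nm in names(xl)) grid[[nm]] <- factor(grid[[nm]], levels = xl[[nm]])
  Xg <- model.matrix(model$formula, grid)
  if (!"temp_combo" %in% names(grid)) grid$temp_combo <- "all"

  m <- as_draws_matrix(samples)
  v_cols <- paste0("v_", colnames(Xg))
  draws_v <- m[, v_cols, drop = FALSE] %*% t(Xg)
  sv_modelled <- any(startsWith(colnames(m), "sv_")) &&
    !identical(model$spec$sv, "floating")
  draws_sv <- if (sv_modelled) {
    softplus(m[, paste0("sv_", colnames(Xg)), drop = FALSE] %*% t(Xg))
  }

  cell_id <- function(g, tc, ch) {
    which(grid$genotype == g & grid$temp_combo == tc & grid$chamber == ch)
  }
  temps <- unique(as.character(grid$temp_combo))
  genos <- unique(as.character(grid$genotype))
  rows <- list(); draw_store <- list()
  ql <- (1 - prob) / 2
  for (tc in temps) {
    ref_delta_v <- draws_v[, cell_id(ref_genotype, tc, "test")] -
      draws_v[, cell_id(ref_genotype, tc, "neutral")]
    ref_delta_sv <- if (sv_modelled) {
      draws_sv[, cell_id(ref_genotype, tc, "test")] -
        draws_sv[, cell_id(ref_genotype, tc, "neutral")]
    }
    for (g in genos) {
      d_v <- draws_v[, cell_id(g, tc, "test")] -
        draws_v[, cell_id(g, tc, "neutral")] - ref_delta_v
      params <- list(v = d_v)
      if (sv_modelled) {
        params$sv <- draws_sv[, cell_id(g, tc, "test")] -
          draws_sv[, cell_id(g, tc, "neutral")] - ref_delta_sv
      }
      for (pn in names(params)) {
        d <- params[[pn]]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          genotype = g, temp_combo = tc, parameter = pn,
          median = median(d),
          lower = quantile(d, ql, names = FALSE),
          upper = quantile(d, 1 - ql, names = FALSE))
        draw_store[[paste(g, tc, pn, sep = ".")]] <- d
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "draws") <- draw_store
  out
}
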