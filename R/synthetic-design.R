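softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(y)))

#' Configuration for a synthetic visit-level design table
#'
#' Defines the conditions of the hierarchical parameter-recovery study:
#' visit durations drawn directly from the decision process (no session or
#' keypoint layer), with cell-mean drift `v` and across-visit drift SD `sv`
#' per genotype x chamber, and a Gaussian per-animal random effect on the
#' drift. The defaults encode two genotypes whose test-chamber cells differ
#' by +0.5 in drift and +0.3 in `sv` relative to wildtype, 20 animals per
#' genotype and ~100 visits per animal, at the fitted family's fixed
#' `z = 0.9` and `a = 13` (visit lengths of a few to tens of seconds).
#'
#' @param v_cells,sv_cells named lists: per genotype, a numeric vector with
#'   entries `neutral` and `test` giving the cell means on the natural scale.
#' @param n_animals_per_genotype,n_visits_per_animal design size.
#' @param a,z fixed boundary separation and relative start.
#' @param re_sd SD of the per-animal drift intercept.
#' @param visit_horizon observation horizon per visit (s): a visit without
#'   an exit by the horizon (including paths absorbed at the lower bound,
#'   i.e. "never leaves") is recorded as censored at the horizon.
#' @param temp_combo temperature-combination label (single level here; the
#'   model formula adapts to the factors present).
#' @param seed integer seed.
#' @export
hier_sim_config <- function(
    v_cells = list(wildtype = c(neutral = 0.12, test = 0.20),
                   mutant = c(neutral = 0.12, test = 0.70)),
    sv_cells = list(wildtype = c(neutral = 0.20, test = 0.20),
                    mutant = c(neutral = 0.20, test = 0.50)),
    n_animals_per_genotype = 20L, n_visits_per_animal = 100L,
    a = 13, z = 0.9, re_sd = 0.05, visit_horizon = 120,
    temp_combo = "31v34", seed = 1L) {
  stopifnot(identical(names(v_cells), names(sv_cells)), a > 0, z > 0, z < 1,
            re_sd >= 0)
  structure(as.list(environment()), class = "hier_sim_config")
}

#' Generate a visit-level design table with known ground truth
#'
#' Draws, for every animal and visit, a drift from
#' `Normal(v_cell + b_animal, sv_cell^2)` and simulates the decision
#' process: an upper-bound passage within the observation horizon yields an
#' uncensored duration; a lower-bound absorption ("never leaves") or a
#' passage slower than the horizon yields a visit censored at the horizon.
#' Chambers alternate so both chambers contribute ~half of each animal's
#' visits.
#'
#' @param config a [hier_sim_config()].
#' @return list with `table` (tibble: animal, genotype, temp_combo, chamber,
#'   duration, censored), `truth` (true fixed-effect coefficients on the
#'   model's scales, animal effects, cell means) and `config`.
#' @export
gen_visit_table <- function(config = hier_sim_config()) {
  stopifnot(inherits(config, "hier_sim_config"))
  set.seed(config$seed)
  genos <- names(config$v_cells)
  rows <- list(); res <- list()
  for (g in genos) {
    for (i in seq_len(config$n_animals_per_genotype)) {
      id <- sprintf("%s_%02d", g, i)
      b <- rnorm(1, 0, config$re_sd)
      chambers <- rep(c("neutral", "test"),
                      length.out = config$n_visits_per_animal)
      v <- config$v_cells[[g]][chambers] + b
      sv <- config$sv_cells[[g]][chambers]
      sim <- sim_visits_censored_cpp(v, sv, config$a, config$z, 1e-3,
                                     config$visit_horizon)
      rows[[id]] <- tibble::tibble(animal = id, genotype = g,
                                   temp_combo = config$temp_combo,
                                   chamber = chambers, duration = sim$time,
                                   censored = sim$censored,
                                   drift_draw = sim$drift)
      res[[id]] <- tibble::tibble(animal = id, genotype = g, random_effect = b)
    }
  }
  table <- dplyr::bind_rows(rows)
  truth <- list(beta_v = true_cell_coefficients(config$v_cells, identity),
                beta_sv = true_cell_coefficients(config$sv_cells, softplus_inv),
                re_sd = config$re_sd,
                animals = dplyr::bind_rows(res),
                v_cells = config$v_cells, sv_cells = config$sv_cells)
  list(table = table, truth = truth, config = config)
}

# solve the treatment-coded fixed effects that reproduce the cell means
# (link applied to the cell values first)
true_cell_coefficients <- function(cells, link_inv) {
  genos <- names(cells)
  grid <- expand.grid(chamber = c("neutral", "test"), genotype = genos,
                      stringsAsFactors = FALSE)
  grid$chamber <- factor(grid$chamber, levels = c("neutral", "test"))
  grid$genotype <- factor(grid$genotype, levels = genos)
  X <- model.matrix(~ chamber * genotype, grid)
  y <- link_inv(mapply(function(g, ch) cells[[g]][[ch]],
                       as.character(grid$genotype), as.character(grid$chamber)))
  beta <- solve(X, y)
  setNames(as.numeric(beta), colnames(X))
}
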