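#' Fixed-parameter marker for model specifications
#' @param value the fixed value.
#' @export
fixed <- function(value) structure(list(value = value), class = "fixed_par")

is_fixed <- function(x) inherits(x, "fixed_par")

#' Hierarchical model specification
#'
#' Declares, for each decision-process parameter, whether it is a
#' `"predictor"` (a full-factorial linear predictor over temperature
#' combination x chamber x genotype), `"floating"` (one value for all data)
#' or [fixed()] at a value. The drift `v` always carries a per-animal random
#' intercept; `sv` is kept positive through a softplus link and `a` through
#' a log link; the starting point `z` is fixed (0.9 by default, placing the
#' start near the exit bound so the lower bound is rarely reached).
#'
#' @param v,sv,a parameter modes (see above). Defaults: `v` and `sv`
#'   predictors, `a` fixed at 13.
#' @param z a [fixed()] starting point.
#' @param priors list: `beta_sd` (normal SD of all linear-predictor
#'   coefficients, default 2), `re_sd_scale` (half-normal scale of the
#'   animal random-effect SD, default 1), `log_a_sd` (normal SD of `log a`
#'   when floating, default 1.5), and `v_lower` (optional lower truncation
#'   of every cell-mean drift, default `-Inf`, i.e. none; setting it to 0
#'   restricts drifts to accumulate towards the exit bound, which is a
#'   useful identification constraint when fitting with the conditional
#'   likelihood, whose passage densities are symmetric in the drift sign).
#' @export
model_spec <- function(v = "predictor", sv = "predictor", a = fixed(13),
                       z = fixed(0.9),
                       priors = list(beta_sd = 2, re_sd_scale = 1, log_a_sd = 1.5,
                                     v_lower = -Inf)) {
  chk <- function(x, allow_fixed = TRUE) {
    if (is_fixed(x)) { if (!allow_fixed) stop("this parameter cannot be fixed"); return() }
    if (!x %in% c("predictor", "floating")) {
      stop("parameter mode must be 'predictor', 'floating' or fixed(value)")
    }
  }
  chk(v, allow_fixed = FALSE); chk(sv); chk(a)
  if (!is_fixed(z)) stop("`z` must be fixed (use fixed(0.9))")
  if (!(z$value > 0 && z$value < 1)) stop("fixed z must lie in (0, 1)")
  modes <- list(v = v, sv = sv, a = a, z = z)
  n_pred <- sum(vapply(modes[c("v", "sv", "a")],
                       function(m) identical(m, "predictor"), logical(1)))
  if (n_pred < 1L) stop("at least one parameter must be a predictor")
  defaults <- list(beta_sd = 2, re_sd_scale = 1, log_a_sd = 1.5, v_lower = -Inf)
  priors <- utils::modifyList(defaults, priors)
  structure(list(v = v, sv = sv, a = a, z = z, priors = priors),
            class = "model_spec")
}

#' Build the hierarchical visit-length model
#'
#' Assembles design matrices for the drift `v` and (through a softplus
#' link) the across-visit drift SD `sv` with full factorial fixed effects
#' over the factors present in the data (temperature combination, chamber,
#' genotype; single-level factors drop out of the formula), plus a
#' per-animal random intercept on `v`. Treatment coding is used with
#' wildtype / neutral chamber as reference levels, so printed coefficients
#' are direct contrasts.
#'
#' @param table a visit-level design table with columns `animal`,
#'   `genotype`, `temp_combo`, `chamber` (values `neutral`/`test`),
#'   `duration` (s) and `censored` (logical).
#' @param spec a [model_spec()].
#' @return an object of class `ddm_model`.
#' @export
build_model <- function(table, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"), nrow(table) > 0)
  need <- c("animal", "genotype", "temp_combo", "chamber", "duration", "censored")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("design table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(table$duration <= 0)) stop("all durations must be > 0")
  bad_ch <- setdiff(unique(table$chamber), c("neutral", "test"))
  if (length(bad_ch)) stop("unknown chamber level(s): ", paste(bad_ch, collapse = ", "))
  one_geno <- tapply(table$genotype, table$animal, function(g) length(unique(g)))
  if (any(one_geno > 1L)) stop("every animal must map to exactly one genotype")

  genos <- unique(table$genotype)
  if ("wildtype" %in% genos) genos <- c("wildtype", setdiff(genos, "wildtype"))
  df <- data.frame(
    temp_combo = factor(table$temp_combo, levels = unique(table$temp_combo)),
    chamber = factor(table$chamber, levels = c("neutral", "test")),
    genotype = factor(table$genotype, levels = genos))
  terms <- c("temp_combo", "chamber", "genotype")
  terms <- terms[vapply(df[terms], nlevels, 0L) > 1L]
  form <- if (length(terms)) {
    stats::as.formula(paste("~", paste(terms, collapse = " * ")))
  } else {
    ~1
  }
  X <- model.matrix(form, df)
  animals <- unique(table$animal)
  structure(list(
    table = tibble::as_tibble(table),
    X = X,
    formula = form,
    xlevels = lapply(df[terms], levels),
    coef_names = colnames(X),
    animal_idx = match(table$animal, animals),
    animals = animals,
    spec = spec,
    n_obs = nrow(table)
  ), class = "ddm_model")
}

#' @export
print.ddm_model <- function(x, ...) {
  cat(sprintf("Hierarchical DDM visit model: %d visits, %d animals, %d fixed effects (%s)\n",
              x$n_obs, length(x$animals), length(x$coef_names),
              deparse(x$formula)))
  invisible(x)
}

#' Sample the posterior of a hierarchical visit-length model
#'
#' Adaptive Metropolis-within-Gibbs sampler. Because the factorial fixed
#' effects are saturated, the sampler works in cell-mean space: for every
#' design cell it updates the pair (cell drift, cell `sv` on the link
#' scale) as a 2-dimensional random-walk block whose proposal covariance is
#' adapted during tuning; cells touch disjoint observation subsets, so one
#' sweep costs a single pass over the data and the blocks are nearly
#' independent in the posterior. Animal random effects are updated
#' element-wise (the likelihood factorises by animal), and the
#' random-effect SD and, when floating, `log a` by scalar moves. Draws are
#' mapped back exactly to the treatment-coded coefficients for reporting;
#' the priors are evaluated on the coefficient scale (the map is linear, so
#' the Jacobian is constant). Pointwise log-likelihoods are stored for
#' every saved draw, aligned to the design-table rows, for
#' cross-validation.
#'
#' @param model a [build_model()] result.
#' @param chains,tune,draws MCMC size; defaults are the scaled profile
#'   (2 chains x 500 draws after 1000 tuning iterations). The full-size
#'   profile used for final inference is 4 chains x 2000 draws after 2000
#'   tuning iterations.
#' @param seed integer seed.
#' @param prior_only sample from the priors (no likelihood)?
#' @return an object of class `ddm_posterior` with elements `draws`
#'   (chain x draw x parameter array), `pointwise` (draw-stacked matrix of
#'   per-observation log-likelihoods), `diagnostics` (split R-hat and
#'   effective sample size per parameter), `flagged` (TRUE when R-hat >
#'   1.01 or ESS is very low; the result is flagged, never silently
#'   accepted) and `accept` (per-block acceptance rates).
#' @export
sample_posterior <- function(model, chains = 2L, tune = 1000L, draws = 500L,
                             seed = 1L, prior_only = FALSE) {
  stopifnot(inherits(model, "ddm_model"))
  sp <- model$spec
  gh <- gauss_hermite(21L)
  pr <- sp$priors
  X_v <- if (identical(sp$v, "floating")) {
    matrix(1, model$n_obs, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    model$X
  }
  sv_mode <- if (is_fixed(sp$sv)) "fixed" else
    if (identical(sp$sv, "floating")) "floating" else "predictor"
  n_anim <- length(model$animals)
  a_float <- !is_fixed(sp$a)
  z_val <- sp$z$value

  # design cells: unique rows of the (saturated) design matrix
  cell_key <- apply(X_v, 1, paste, collapse = "\r")
  keep <- !duplicated(cell_key)
  X_cell <- X_v[keep, , drop = FALSE]
  n_cell <- nrow(X_cell)
  if (n_cell != ncol(X_v)) {
    stop("design matrix is not saturated; cell-mean sampler requires a full factorial")
  }
  cell_of_obs <- match(cell_key, cell_key[keep])
  obs_of_cell <- split(seq_len(model$n_obs), cell_of_obs)
  A_inv <- solve(X_cell) # beta = A_inv %*% theta_cell
  sv_per_cell <- sv_mode == "predictor"

  par_names <- c(paste0("v_", colnames(X_v)),
                 if (sv_per_cell) paste0("sv_", colnames(X_v)),
                 if (sv_mode == "floating") "sv_(Intercept)",
                 if (a_float) "log_a",
                 paste0("b[", model$animals, "]"),
                 "log_re_sd")
  n_par <- length(par_names)

  dur <- model$table$duration
  cen <- as.logical(model$table$censored)
  aidx <- model$animal_idx

  a_init <- if (a_float) max(mean(dur)^0.5, 1) else sp$a$value
  v0 <- a_init * (1 - z_val) / max(mean(dur), 1e-3)

  pw_cell <- function(rows, v_cell, sv_cell, b, a) {
    visit_pointwise_loglik_cpp(dur[rows], cen[rows],
                               v_cell + b[aidx[rows]], sv_cell,
                               a, z_val, FALSE, TRUE, gh$x, gh$w, 1e-8)
  }
  all_pw <- function(th_v, th_sv, b, a) {
    v_obs <- th_v[cell_of_obs] + b[aidx]
    sv_obs <- switch(sv_mode,
                     fixed = sp$sv$value,
                     floating = softplus(th_sv[1]),
                     predictor = softplus(th_sv)[cell_of_obs])
    visit_pointwise_loglik_cpp(dur, cen, v_obs, sv_obs, a, z_val,
                               FALSE, TRUE, gh$x, gh$w, 1e-8)
  }
  # coefficient-scale prior for cell-space values
  lp_cells <- function(th) sum(dnorm(A_inv %*% th, 0, pr$beta_sd, log = TRUE))
  lp_tau <- function(lt) dnorm(exp(lt), 0, pr$re_sd_scale, log = TRUE) + log(2) + lt

  run_chain <- function(chain_id) {
    set.seed(seed + 1000L * (chain_id - 1L))
    th_v <- rep(v0, n_cell) + rnorm(n_cell, 0, 0.02 * abs(v0) + 0.005)
    th_sv <- switch(sv_mode,
                    fixed = numeric(0),
                    floating = softplus_inv(max(0.5 * abs(v0), 0.05)) + rnorm(1, 0, 0.05),
                    predictor = rep(softplus_inv(max(0.5 * abs(v0), 0.05)), n_cell) +
                      rnorm(n_cell, 0, 0.05))
    log_a <- if (a_float) log(a_init) + rnorm(1, 0, 0.01) else NA_real_
    b <- rep(0, n_anim)
    log_tau <- log(0.1) + rnorm(1, 0, 0.1)
    a_cur <- if (a_float) exp(log_a) else sp$a$value

    pw <- if (prior_only) rep(0, model$n_obs) else all_pw(th_v, th_sv, b, a_cur)
    lla <- as.numeric(rowsum(pw, aidx, reorder = TRUE))

    dim_c <- if (sv_per_cell) 2L else 1L
    chol_c <- lapply(seq_len(n_cell), function(c) diag(dim_c))
    sc <- rep(0.08, n_cell)
    sc_other <- c(sv = 0.1, a = 0.02, b = 0.1, tau = 0.3, asis = 0.3)
    hist_c <- array(NA_real_, c(tune, n_cell, dim_c))
    acc <- c(cells = 0, sv = 0, a = 0, b = 0, tau = 0, asis = 0)
    n_try <- c(cells = 0, sv = 0, a = 0, b = 0, tau = 0, asis = 0)

    out <- matrix(NA_real_, draws, n_par)
    out_pw <- matrix(NA_real_, draws, model$n_obs)

    for (it in seq_len(tune + draws)) {
      tuning <- it <= tune
      gamma <- if (tuning) min(1, 5 / it^0.6) else 0

      # --- per-cell (v, sv) blocks ---
      for (c in seq_len(n_cell)) {
        step <- sc[c] * as.numeric(chol_c[[c]] %*% rnorm(dim_c))
        v_p <- th_v; v_p[c] <- th_v[c] + step[1]
        sv_p <- th_sv
        if (sv_per_cell) sv_p[c] <- th_sv[c] + step[2]
        rows <- obs_of_cell[[c]]
        sv_row <- switch(sv_mode, fixed = sp$sv$value,
                         floating = softplus(th_sv[1]),
                         predictor = softplus(sv_p[c]))
        if (v_p[c] < pr$v_lower) {
          lr <- -Inf # truncated drift prior (identification constraint)
          pw_p <- NULL
        } else {
          pw_p <- if (prior_only) pw[rows] else
            pw_cell(rows, v_p[c], sv_row, b, a_cur)
          lr <- sum(pw_p) - sum(pw[rows]) +
            lp_cells(v_p) - lp_cells(th_v) +
            if (sv_per_cell) lp_cells(sv_p) - lp_cells(th_sv) else 0
        }
        ok <- is.finite(lr) && log(runif(1)) < lr
        if (ok) {
          th_v <- v_p; th_sv <- sv_p
          pw[rows] <- pw_p
        }
        n_try["cells"] <- n_try["cells"] + 1
        acc["cells"] <- acc["cells"] + ok
        if (tuning) {
          sc[c] <- sc[c] * exp(gamma * (ok - 0.3))
          hist_c[it, c, ] <- c(th_v[c], if (sv_per_cell) th_sv[c])
        }
      }

      # --- floating sv (global scalar) ---
      if (sv_mode == "floating") {
        sv_p <- th_sv + sc_other["sv"] * rnorm(1)
        pw_p <- if (prior_only) pw else all_pw(th_v, sv_p, b, a_cur)
        lr <- sum(pw_p) - sum(pw) +
          dnorm(sv_p, 0, pr$beta_sd, log = TRUE) -
          dnorm(th_sv, 0, pr$beta_sd, log = TRUE)
        ok <- is.finite(lr) && log(runif(1)) < lr
        if (ok) {
          th_sv <- sv_p; pw <- pw_p
          lla <- as.numeric(rowsum(pw, aidx, reorder = TRUE))
        }
        n_try["sv"] <- n_try["sv"] + 1; acc["sv"] <- acc["sv"] + ok
        if (tuning) sc_other["sv"] <- sc_other["sv"] * exp(gamma * (ok - 0.44))
      }

      # --- boundary separation ---
      if (a_float) {
        la_p <- log_a + sc_other["a"] * rnorm(1)
        pw_p <- if (prior_only) pw else all_pw(th_v, th_sv, b, exp(la_p))
        lr <- sum(pw_p) - sum(pw) +
          dnorm(la_p, 0, pr$log_a_sd, log = TRUE) -
          dnorm(log_a, 0, pr$log_a_sd, log = TRUE)
        ok <- is.finite(lr) && log(runif(1)) < lr
        if (ok) {
          log_a <- la_p; a_cur <- exp(log_a); pw <- pw_p
          lla <- as.numeric(rowsum(pw, aidx, reorder = TRUE))
        }
        n_try["a"] <- n_try["a"] + 1; acc["a"] <- acc["a"] + ok
        if (tuning) sc_other["a"] <- sc_other["a"] * exp(gamma * (ok - 0.44))
      }

      # --- animal effects (element-wise) ---
      tau <- exp(log_tau)
      b_p <- b + sc_other["b"] * rnorm(n_anim)
      pw_p <- if (prior_only) pw else all_pw(th_v, th_sv, b_p, a_cur)
      lla_p <- as.numeric(rowsum(pw_p, aidx, reorder = TRUE))
      lr_i <- (lla_p - lla) + dnorm(b_p, 0, tau, log = TRUE) -
        dnorm(b, 0, tau, log = TRUE)
      take <- is.finite(lr_i) & log(runif(n_anim)) < lr_i
      if (any(take)) {
        b[take] <- b_p[take]
        rows <- which(aidx %in% which(take))
        pw[rows] <- pw_p[rows]
        lla[take] <- lla_p[take]
      }
      n_try["b"] <- n_try["b"] + 1; acc["b"] <- acc["b"] + mean(take)
      if (tuning) sc_other["b"] <- sc_other["b"] * exp(gamma * (mean(take) - 0.44))

      # --- random-effect SD (prior-only move) ---
      lt_p <- log_tau + sc_other["tau"] * rnorm(1)
      lr <- sum(dnorm(b, 0, exp(lt_p), log = TRUE)) -
        sum(dnorm(b, 0, exp(log_tau), log = TRUE)) +
        lp_tau(lt_p) - lp_tau(log_tau)
      ok <- is.finite(lr) && log(runif(1)) < lr
      if (ok) log_tau <- lt_p
      n_try["tau"] <- n_try["tau"] + 1; acc["tau"] <- acc["tau"] + ok
      if (tuning) sc_other["tau"] <- sc_other["tau"] * exp(gamma * (ok - 0.44))

      # interweaved rescaling of (tau, b): multiplies all animal effects and
      # tau by a common factor, which breaks the funnel coupling; the
      # animal-effect prior term cancels against the Jacobian
      eps <- sc_other["asis"] * rnorm(1)
      b_p <- b * exp(eps)
      pw_p <- if (prior_only) pw else all_pw(th_v, th_sv, b_p, a_cur)
      lr <- sum(pw_p) - sum(pw) + lp_tau(log_tau + eps) - lp_tau(log_tau)
      ok <- is.finite(lr) && log(runif(1)) < lr
      if (ok) {
        b <- b_p; log_tau <- log_tau + eps; pw <- pw_p
        lla <- as.numeric(rowsum(pw, aidx, reorder = TRUE))
      }
      n_try["asis"] <- n_try["asis"] + 1; acc["asis"] <- acc["asis"] + ok
      if (tuning) sc_other["asis"] <- sc_other["asis"] * exp(gamma * (ok - 0.44))

      if (tuning && dim_c == 2L && it >= 250L && it %% 100L == 0L) {
        for (c in seq_len(n_cell)) {
          cv <- stats::cov(hist_c[max(1, it - 600):it, c, , drop = TRUE])
          chol_c[[c]] <- tryCatch(t(chol(cv / mean(diag(cv)) + 1e-6 * diag(2))),
                                  error = function(e) chol_c[[c]])
        }
      }

      if (!tuning) {
        d <- it - tune
        beta_v <- as.numeric(A_inv %*% th_v)
        beta_sv <- if (sv_per_cell) as.numeric(A_inv %*% th_sv) else th_sv
        out[d, ] <- c(beta_v, beta_sv, if (a_float) log_a, b, log_tau)
        out_pw[d, ] <- pw
      }
    }
    list(draws = out, pointwise = out_pw, accept = acc / pmax(n_try, 1))
  }

  res <- lapply(seq_len(chains), run_chain)
  arr <- array(NA_real_, c(chains, draws, n_par),
               dimnames = list(NULL, NULL, par_names))
  for (c in seq_len(chains)) arr[c, , ] <- res[[c]]$draws
  pointwise <- do.call(rbind, lapply(res, `[[`, "pointwise"))
  diag_tab <- mcmc_diagnostics(arr)
  flagged <- any(diag_tab$rhat > 1.01, na.rm = TRUE) ||
    any(diag_tab$ess < 50, na.rm = TRUE)
  structure(list(
    draws = arr, pointwise = pointwise, par_names = par_names,
    model = model, diagnostics = diag_tab, flagged = flagged,
    accept = rowMeans(vapply(res, `[[`, numeric(6), "accept")),
    chains = chains, n_draws = draws, seed = seed,
    prior_only = prior_only
  ), class = "ddm_posterior")
}

#' @export
print.ddm_posterior <- function(x, ...) {
  cat(sprintf("Posterior: %d chains x %d draws, %d parameters%s\n",
              x$chains, x$n_draws, length(x$par_names),
              if (x$flagged) " [FLAGGED: check R-hat / ESS]" else ""))
  print(posterior_summary(x), n = 12)
  invisible(x)
}

#' Stack posterior draws into a matrix
#' @param post a `ddm_posterior`.
#' @export
as_draws_matrix <- function(post) {
  m <- do.call(rbind, lapply(seq_len(post$chains), function(c) post$draws[c, , ]))
  colnames(m) <- post$par_names
  m
}

#' Posterior summary table
#' @param post a `ddm_posterior`.
#' @param prob central interval probability (default 0.94).
#' @export
posterior_summary <- function(post, prob = 0.94) {
  m <- as_draws_matrix(post)
  qs <- apply(m, 2, quantile, probs = c((1 - prob) / 2, 0.5, 1 - (1 - prob) / 2))
  tibble::tibble(param = colnames(m), median = qs[2, ],
                 lower = qs[1, ], upper = qs[3, ],
                 rhat = post$diagnostics$rhat, ess = post$diagnostics$ess)
}

# split R-hat and a crude effective sample size per parameter
mcmc_diagnostics <- function(arr) {
  chains <- dim(arr)[1]; draws <- dim(arr)[2]; npar <- dim(arr)[3]
  half <- floor(draws / 2)
  rhat <- ess <- numeric(npar)
  for (p in seq_len(npar)) {
    segs <- list()
    for (c in seq_len(chains)) {
      segs[[2 * c - 1]] <- arr[c, 1:half, p]
      segs[[2 * c]] <- arr[c, (half + 1):(2 * half), p]
    }
    mns <- vapply(segs, mean, 0); vrs <- vapply(segs, var, 0)
    m <- length(segs); n <- half
    W <- mean(vrs); B <- n * var(mns)
    rhat[p] <- if (W > 1e-12) sqrt(((n - 1) / n * W + B / n) / W) else 1
    # ESS from pooled autocorrelation (initial positive sequence, coarse)
    rho_sum <- 0
    for (c in seq_len(chains)) {
      x <- arr[c, , p]
      if (sd(x) < 1e-12) next
      r <- acf(x, lag.max = min(100, draws - 2), plot = FALSE)$acf[-1]
      pos <- which(r < 0.05)
      kmax <- if (length(pos)) pos[1] - 1 else length(r)
      rho_sum <- rho_sum + sum(r[seq_len(kmax)])
    }
    rho_bar <- rho_sum / chains
    ess[p] <- chains * draws / (1 + 2 * max(rho_bar, 0))
  }
  tibble::tibble(param = dimnames(arr)[[3]], rhat = rhat, ess = ess)
}

#' Fit a hierarchical visit-length model in one call
#'
#' Convenience wrapper: [build_model()] then [sample_posterior()].
#' @inheritParams build_model
#' @inheritParams sample_posterior
#' @param ... passed to [sample_posterior()].
#' @export
fit_ddm <- function(table, spec = model_spec(), ...) {
  sample_posterior(build_model(table, spec), ...)
}
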