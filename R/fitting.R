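#' Fitting configuration
#'
#' Controls for multi-restart dual simulated annealing. Each restart runs a
#' global annealing phase (Gaussian proposals with a geometrically cooling
#' temperature and reflecting bounds) followed by a bounded local polish
#' with `L-BFGS-B` from the annealer's best point. Restarts are seeded
#' deterministically from `seed + restart index`, so a fit is reproducible
#' given the data and the config.
#'
#' @param bounds Named list of `c(lower, upper)` per parameter. Defaults:
#'   `e_cpx` and `s_cpx` in `[0, 10]`, `alpha` and `beta` in `[1, 10]`.
#' @param n_realizations Number of independent restarts (default 1000, the
#'   convention for reported fits; use far fewer for exploration).
#' @param seed Master integer seed.
#' @param maxiter Annealing steps per restart (default 300).
#' @param t0 Initial temperature on the fitness scale (default 0.1).
#' @param t_min Final temperature (default 1e-6).
#' @return A `fit_config` list.
#' @export
fit_config <- function(bounds = list(e_cpx = c(0, 10), s_cpx = c(0, 10),
                                     alpha = c(1, 10), beta = c(1, 10)),
                       n_realizations = 1000, seed = 1,
                       maxiter = 300, t0 = 0.1, t_min = 1e-6) {
  need <- c("e_cpx", "s_cpx", "alpha", "beta")
  if (!all(need %in% names(bounds))) {
    stop("bounds must name: ", paste(need, collapse = ", "), call. = FALSE)
  }
  for (nm in need) {
    b <- bounds[[nm]]
    if (length(b) != 2L || !is.finite(b[1]) || !is.finite(b[2]) || b[1] >= b[2]) {
      stop("infeasible bounds for `", nm, "`", call. = FALSE)
    }
  }
  if (n_realizations < 1) stop("n_realizations must be >= 1", call. = FALSE)
  structure(list(bounds = bounds[need],
                 n_realizations = as.integer(n_realizations),
                 seed = as.integer(seed), maxiter = as.integer(maxiter),
                 t0 = t0, t_min = t_min),
            class = "fit_config")
}

#' Model fitness: mean squared GPSA error
#'
#' `Fit = (1/N) * sum_i (GPSA_hat_i - GPSA_i)^2`, the quantity the
#' annealer minimises: the average squared difference between the model's
#' predicted score at each unit's `(g, tom)` and the observed score.
#'
#' @param params A [gpsa_params()] object.
#' @param obs An `observation_set`.
#' @return A single non-negative number; 0 iff every prediction is exact.
#' @export
gpsa_fitness <- function(params, obs) {
  if (nrow(obs) == 0L) stop("empty observation set", call. = FALSE)
  mean((gpsa_score(params, obs$g, obs$tom) - obs$gpsa_obs)^2)
}

# Fast fitness closure over one dataset: precomputes the tanh terms, which
# depend only on the data, so each evaluation costs four powers and a mean.
# Assumes the default scale maxima (10/10) — the scales fitting operates on.
make_fitness <- function(obs) {
  g <- obs$g; tom <- obs$tom; y <- obs$gpsa_obs
  tg <- tanh(ifelse(g >= 10, Inf, g / (10 - g)))
  tt <- tanh(ifelse(tom >= 10, Inf, tom / (10 - tom)))
  function(theta) {
    e <- theta[1]; s <- theta[2]; a <- theta[3]; b <- theta[4]
    w_div <- pmax(1, 10 * tg^a)
    rhdg <- s + e / w_div - tom * (10 * tt^b) / 5
    rhdg <- pmin(20, pmax(-20, rhdg))
    mean((1 - (e + s + rhdg + 20) / 60 - y)^2)
  }
}

# One dual-annealing run: global SA phase then bounded local polish.
# Uses the current RNG stream; callers scope the seed.
dual_anneal <- function(f, lower, upper, maxiter = 300, t0 = 0.1,
                        t_min = 1e-6) {
  k <- length(lower)
  width <- upper - lower
  cur <- lower + stats::runif(k) * width
  f_cur <- f(cur)
  best <- cur; f_best <- f_cur
  cool <- (t_min / t0)^(1 / max(1, maxiter - 1))
  temp <- t0
  for (it in seq_len(maxiter)) {
    step <- 0.5 * width * sqrt(temp / t0)
    cand <- cur + stats::rnorm(k) * step
    cand <- reflect_into(cand, lower, upper)
    f_cand <- f(cand)
    if (f_cand < f_cur || stats::runif(1) < exp(-(f_cand - f_cur) / temp)) {
      cur <- cand; f_cur <- f_cand
      if (f_cur < f_best) { best <- cur; f_best <- f_cur }
    }
    temp <- temp * cool
  }
  pol <- tryCatch(
    stats::optim(best, f, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 200)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value < f_best) {
    best <- pmin(upper, pmax(lower, pol$par)); f_best <- pol$value
  }
  list(par = best, value = f_best)
}

reflect_into <- function(x, lower, upper) {
  width <- upper - lower
  y <- (x - lower) %% (2 * width)
  lower + pmin(y, 2 * width - y)
}

#' Pooled model fit by multi-restart dual simulated annealing
#'
#' Estimates one `(E_cpx, S_cpx, alpha, beta)` for a whole governance level
#' by minimising [gpsa_fitness()] within the configured bounds,
#' independently from `n_realizations` seeded restarts. The reported fit is
#' the best across restarts (first encountered wins on ties); the full
#' restart table is kept so restart-to-restart variability can be
#' summarised.
#'
#' @param obs An `observation_set`.
#' @param cfg A [fit_config()].
#' @return A `gpsa_fit`: list with `best_params` ([gpsa_params()]),
#'   `fit_value`, `per_realization` (tibble: parameters and fit per
#'   restart), `level`, `n_obs` and the `config`.
#' @export
fit_pooled <- function(obs, cfg = fit_config()) {
  if (nrow(obs) == 0L) stop("empty observation set", call. = FALSE)
  f <- make_fitness(obs)
  lower <- vapply(cfg$bounds, `[`, numeric(1), 1L)
  upper <- vapply(cfg$bounds, `[`, numeric(1), 2L)
  runs <- vector("list", cfg$n_realizations)
  for (i in seq_len(cfg$n_realizations)) {
    seed_i <- (cfg$seed + i) %% .Machine$integer.max
    runs[[i]] <- withr::with_seed(
      seed_i,
      dual_anneal(f, lower, upper, cfg$maxiter, cfg$t0, cfg$t_min))
  }
  per <- tibble::tibble(
    realization = seq_along(runs),
    e_cpx = vapply(runs, function(r) r$par[1], numeric(1)),
    s_cpx = vapply(runs, function(r) r$par[2], numeric(1)),
    alpha = vapply(runs, function(r) r$par[3], numeric(1)),
    beta = vapply(runs, function(r) r$par[4], numeric(1)),
    fit = vapply(runs, function(r) r$value, numeric(1))
  )
  k <- which.min(per$fit)
  best <- gpsa_params(per$e_cpx[k], per$s_cpx[k], per$alpha[k], per$beta[k])
  structure(list(best_params = best, fit_value = per$fit[k],
                 per_realization = per,
                 level = attr(obs, "level") %||% "unknown",
                 n_obs = nrow(obs), config = cfg),
            class = "gpsa_fit")
}

#' Per-unit model fits
#'
#' Fits the model to each unit separately as a one-observation problem —
#' the basis for within-level variability of complexity and cognitive
#' tools. With four parameters and one observation these fits are
#' underdetermined: many parameter combinations reach the same (often
#' zero) residual, so cross-unit variance partly reflects optimizer
#' multimodality, not only real heterogeneity.
#'
#' Every unit is fitted with the same config (hence the same restart seed
#' stream), so identical units yield identical fits.
#'
#' @inheritParams fit_pooled
#' @return A list of `gpsa_fit`, ordered as the input units.
#' @export
fit_per_unit <- function(obs, cfg = fit_config()) {
  if (nrow(obs) == 0L) stop("empty observation set", call. = FALSE)
  lapply(seq_len(nrow(obs)), function(i) {
    unit <- observation_set(obs[i, , drop = FALSE], attr(obs, "level"))
    fit_pooled(unit, cfg)
  })
}

#' Summarise fits across restarts or across units
#'
#' Elementwise mean and population variance (divide by n) of the best-fit
#' parameters and fitness, either over the restarts of a single pooled fit
#' (`axis = "realizations"`) or over a list of per-unit fits
#' (`axis = "units"`).
#'
#' @param results A `gpsa_fit` (for `"realizations"`) or a list of
#'   `gpsa_fit` (for `"units"`).
#' @param axis `"realizations"` or `"units"`.
#' @return A `gpsa_fit_summary`: list with named vectors `mean` and
#'   `variance` over `e_cpx`, `s_cpx`, `alpha`, `beta`, plus `mean_fit`,
#'   `n` and `axis`.
#' @export
summarize_fits <- function(results, axis = c("realizations", "units")) {
  axis <- match.arg(axis)
  cols <- c("e_cpx", "s_cpx", "alpha", "beta")
  if (axis == "realizations") {
    stopifnot(inherits(results, "gpsa_fit"))
    tab <- results$per_realization
    fit <- tab$fit
    level <- results$level
  } else {
    if (!length(results)) stop("empty result list", call. = FALSE)
    stopifnot(all(vapply(results, inherits, logical(1), "gpsa_fit")))
    tab <- do.call(rbind, lapply(results, function(r) {
      as.data.frame(r$best_params)
    }))
    fit <- vapply(results, function(r) r$fit_value, numeric(1))
    level <- results[[1]]$level
  }
  if (nrow(tab) == 0L) stop("nothing to summarise", call. = FALSE)
  pop_var <- function(x) mean((x - mean(x))^2)
  structure(list(
    mean = vapply(tab[cols], mean, numeric(1)),
    variance = vapply(tab[cols], pop_var, numeric(1)),
    mean_fit = mean(fit), n = nrow(tab), axis = axis, level = level
  ), class = "gpsa_fit_summary")
}

#' @export
print.gpsa_fit_summary <- function(x, ...) {
  cat(sprintf("<gpsa_fit_summary> level = %s, over %d %s\n",
              x$level, x$n, x$axis))
  print(round(rbind(mean = x$mean, variance = x$variance), 5))
  cat(sprintf("mean fit = %.5f\n", x$mean_fit))
  invisible(x)
}

#' @export
print.gpsa_fit <- function(x, ...) {
  cat(sprintf("<gpsa_fit> level = %s, n_obs = %d, %d restart(s)\n",
              x$level, x$n_obs, nrow(x$per_realization)))
  cat(sprintf("  best fit = %.6f at E=%.4f S=%.4f alpha=%.4f beta=%.4f\n",
              x$fit_value, x$best_params$e_cpx, x$best_params$s_cpx,
              x$best_params$alpha, x$best_params$beta))
  invisible(x)
}

#' Ordered cross-level prediction checks
#'
#' Evaluates the model's comparative hypotheses between the small-group
#' and country governance levels: complexities, alpha and beta should all
#' be strictly lower for small groups (means), and their within-level
#' variability strictly smaller (variances). Each row reports the two
#' sides and whether the strict inequality holds.
#'
#' @param pooled Named list of `gpsa_fit_summary` with entries
#'   `small_group` and `country` (means are compared; typically summaries
#'   over realizations of pooled fits).
#' @param per_unit Optional named list of `gpsa_fit_summary` over units for
#'   the same levels; its variances feed the variability predictions. When
#'   omitted, the variances of `pooled` are used.
#' @return A tibble with columns `prediction`, `lhs`, `rhs`, `holds`.
#' @export
prediction_report <- function(pooled, per_unit = NULL) {
  for (lvl in c("small_group", "country")) {
    if (is.null(pooled[[lvl]])) stop("missing level: ", lvl, call. = FALSE)
  }
  vsrc <- if (is.null(per_unit)) pooled else per_unit
  for (lvl in c("small_group", "country")) {
    if (is.null(vsrc[[lvl]])) stop("missing level: ", lvl, call. = FALSE)
  }
  cols <- c("e_cpx", "s_cpx", "alpha", "beta")
  labs <- c(e_cpx = "E_cpx", s_cpx = "S_cpx", alpha = "alpha", beta = "beta")
  mean_rows <- tibble::tibble(
    prediction = paste0(labs[cols], "_sg < ", labs[cols], "_ctr"),
    lhs = unname(pooled$small_group$mean[cols]),
    rhs = unname(pooled$country$mean[cols])
  )
  var_rows <- tibble::tibble(
    prediction = paste0("Var(", labs[cols], ")_sg < Var(", labs[cols], ")_ctr"),
    lhs = unname(vsrc$small_group$variance[cols]),
    rhs = unname(vsrc$country$variance[cols])
  )
  out <- rbind(mean_rows, var_rows)
  out$holds <- out$lhs < out$rhs
  out
}

#' Coarse-grid fitness minimum (brute-force reference)
#'
#' Exhaustive minimum of [gpsa_fitness()] over the integer parameter grid
#' (`E_cpx, S_cpx` in `0..10`, `alpha, beta` in `1..10`; 12,100
#' combinations by default). A slow, assumption-free reference the
#' annealer must never do worse than.
#'
#' @param obs An `observation_set`.
#' @param e_grid,s_grid,a_grid,b_grid Grid values per parameter.
#' @return List with `value` (the grid minimum) and `par` (the grid point
#'   attaining it, named vector).
#' @export
coarse_grid_fitness <- function(obs, e_grid = 0:10, s_grid = 0:10,
                                a_grid = 1:10, b_grid = 1:10) {
  f <- make_fitness(obs)
  best <- Inf; arg <- NULL
  for (a in a_grid) for (b in b_grid) for (e in e_grid) for (s in s_grid) {
    v <- f(c(e, s, a, b))
    if (v < best) { best <- v; arg <- c(e_cpx = e, s_cpx = s, alpha = a, beta = b) }
  }
  list(value = best, par = arg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
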