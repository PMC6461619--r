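# Multi-run replication, two-model comparison by plausibility and rank-sum
# test, and local sensitivity analysis of the reduced model.

#' Replicate optimization runs
#'
#' Runs the optimizer \code{n_runs} times with consecutive seeds
#' \code{base_seed .. base_seed + n_runs - 1} and summarises the variability
#' of the estimated parameters across feasible bests.
#'
#' @param problem a GA problem (see \code{\link{fitting_problem}}).
#' @param config a \code{\link{ga_config}}; its seed field is overridden per
#'   run.
#' @param n_runs number of independent runs (>= 1).
#' @param base_seed seed of the first run.
#' @return List of class \code{"ga_replicates"}: \code{runs} (list of
#'   \code{ga_run}), \code{parameter_cv} (per-parameter coefficient of
#'   variation of estimates across feasible runs; NA if < 2 feasible).
#' @export
run_replicates <- function(problem, config, n_runs, base_seed) {
  stopifnot(n_runs >= 1)
  runs <- lapply(seq_len(n_runs) - 1L, function(k) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + k)
    ga_optimize(problem, cfg)
  })
  feas <- Filter(function(r) isTRUE(r$best$feasible), runs)
  cv <- NULL
  if (length(feas) >= 2 && !is.null(feas[[1]]$best$values)) {
    est <- do.call(rbind, lapply(feas, function(r) r$best$values))
    cv <- apply(est, 2, function(x) stats::sd(x) / mean(x))
  }
  structure(list(runs = runs, parameter_cv = cv,
                 n_feasible = length(feas)), class = "ga_replicates")
}

#' Exact two-sided rank-sum p-value
#'
#' Wilcoxon rank-sum test on two small samples.  For at most 8 observations
#' per side (and no ties) the p-value is exact, obtained by complete
#' enumeration of rank assignments; larger samples use the normal
#' approximation.
#'
#' @param x,y numeric samples.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  exact <- length(x) <= 8 && length(y) <= 8 &&
    !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact)$p.value)
}

#' Compare two model variants fitted to the same constraints
#'
#' Uses only feasible runs (gamma = 0: the model fits all training data).
#' The representative objective per side is the median of the per-run best
#' f values by default; the plausibility ratio is
#' \code{MP(f_a) / MP(f_b) = exp(f_b - f_a)} on the representatives, and the
#' per-run f samples are compared by a two-sided rank-sum test.
#'
#' @param runs_a,runs_b lists of \code{ga_run} (or \code{ga_replicates}).
#' @param representative aggregator of per-run f values: \code{"median"}
#'   (default), \code{"min"} or \code{"mean"}.
#' @return List of class \code{"model_comparison"}: \code{f_a}, \code{f_b},
#'   \code{mp_a}, \code{mp_b}, \code{mp_ratio}, \code{rank_sum_p},
#'   \code{f_samples_a}, \code{f_samples_b}.
#' @export
compare_models <- function(runs_a, runs_b,
                           representative = c("median", "min", "mean")) {
  representative <- match.arg(representative)
  get_f <- function(runs) {
    if (inherits(runs, "ga_replicates")) runs <- runs$runs
    if (inherits(runs, "ga_run")) runs <- list(runs)
    vapply(Filter(function(r) isTRUE(r$best$feasible), runs),
           function(r) r$best$f, numeric(1))
  }
  fa <- get_f(runs_a)
  fb <- get_f(runs_b)
  if (length(fa) == 0 || length(fb) == 0)
    stop("model comparison refused: a side has no feasible run ",
         "(gamma = 0 never reached)", call. = FALSE)
  agg <- switch(representative, median = stats::median, min = min, mean = mean)
  f_a <- agg(fa); f_b <- agg(fb)
  p <- if (length(fa) >= 2 && length(fb) >= 2) rank_sum_test(fa, fb) else NA_real_
  structure(list(f_a = f_a, f_b = f_b,
                 mp_a = exp(-f_a), mp_b = exp(-f_b),
                 mp_ratio = exp(f_b - f_a), rank_sum_p = p,
                 f_samples_a = fa, f_samples_b = fb,
                 representative = representative),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "model A: f = %.4g (MP = %.3g, n = %d)\nmodel B: f = %.4g (MP = %.3g, n = %d)\nMP ratio A/B = %.3g ; rank-sum p = %.4g\n",
    x$f_a, x$mp_a, length(x$f_samples_a),
    x$f_b, x$mp_b, length(x$f_samples_b), x$mp_ratio, x$rank_sum_p))
  invisible(x)
}

#' Seeded two-model ranking experiment
#'
#' For each seed, builds the shipped two-variant scenario
#' (\code{\link{make_two_model_scenario}}), fits the active and the passive
#' transporter variant to the same observations with the genetic algorithm,
#' and records which variant attains the higher model plausibility among
#' feasible fits.
#'
#' The passive variant receives a larger evaluation budget because its
#' feasible region is a small corner of the search box; the active variant
#' converges quickly since the data were generated under active-transport
#' physics.
#'
#' @param seeds integer vector of scenario seeds (one experiment per seed).
#' @param evals_active,evals_passive GA evaluation budgets per side.
#' @param stall_generations restart trigger passed to \code{\link{ga_config}}.
#' @return Data frame with one row per seed: \code{seed}, \code{f_active},
#'   \code{gamma_active}, \code{f_passive}, \code{gamma_passive},
#'   \code{mp_ratio} (active over passive; NA unless both sides feasible),
#'   \code{active_wins} (TRUE when both feasible and f_active < f_passive).
#' @export
two_model_experiment <- function(seeds = 1:5, evals_active = 4000,
                                 evals_passive = 12000,
                                 stall_generations = 150) {
  rows <- lapply(seeds, function(s) {
    tm <- make_two_model_scenario(seed = s)
    fit <- function(side, ga_seed, evals) {
      pr <- fitting_problem(side$specs, side$constraints, side$conditions)
      cfg <- ga_config(length(pr$lower), max_evaluations = evals,
                       stall_generations = stall_generations, seed = ga_seed)
      suppressWarnings(ga_optimize(pr, cfg))
    }
    a <- fit(tm$active, 100L + s, evals_active)
    p <- fit(tm$passive, 200L + s, evals_passive)
    both <- isTRUE(a$best$feasible) && isTRUE(p$best$feasible)
    data.frame(seed = s,
               f_active = a$best$f, gamma_active = a$best$gamma,
               f_passive = p$best$f, gamma_passive = p$best$gamma,
               mp_ratio = if (both) exp(p$best$f - a$best$f) else NA_real_,
               active_wins = both && a$best$f < p$best$f)
  })
  do.call(rbind, rows)
}

#' Local log-log sensitivity analysis at steady state
#'
#' Normalized sensitivities \code{S[i, j]} = d ln(output_j) / d ln(p_i) of
#' steady-state observables with respect to the model parameters, by central
#' finite differences with relative step \code{delta}.  A steady-state
#' failure at a perturbed point flags the affected entries as \code{NA}
#' rather than zeroing them.
#'
#' @param params a \code{\link{toy_params}}.
#' @param condition a \code{\link{toy_condition}}.
#' @param outputs character vector of observable names (states or fluxes).
#' @param parameters character vector of parameter names to perturb
#'   (default: all kinetic parameters).
#' @param delta relative perturbation step (default 1e-3).
#' @return Matrix with one row per parameter and one column per output.
#' @export
sensitivity_analysis <- function(params, condition, outputs,
                                 parameters = NULL, delta = 1e-3) {
  kin <- setdiff(names(formals(toy_params)), "glnk_present")
  if (is.null(parameters)) parameters <- kin
  stopifnot(all(parameters %in% kin), delta > 0)
  base <- steady_state_toy(params, condition)   # must exist, else error here
  get_out <- function(p) {
    ss <- steady_state_toy(p, condition)
    obs <- c(ss$state, ss$fluxes)
    unlist(obs[outputs])
  }
  S <- matrix(NA_real_, nrow = length(parameters), ncol = length(outputs),
              dimnames = list(parameters, outputs))
  for (pn in parameters) {
    up <- params; up[[pn]] <- params[[pn]] * exp(delta)
    dn <- params; dn[[pn]] <- params[[pn]] * exp(-delta)
    o_up <- tryCatch(get_out(up), error = function(e) NULL)
    o_dn <- tryCatch(get_out(dn), error = function(e) NULL)
    if (!is.null(o_up) && !is.null(o_dn))
      S[pn, ] <- (log(o_up) - log(o_dn)) / (2 * delta)
  }
  S
}
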