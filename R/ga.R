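#' Configuration of the constrained genetic algorithm
#'
#' Hyperparameters of the iterative-start, stochastic-ranking, REX-star /
#' just-generation-gap optimizer.  Defaults follow the standard settings of
#' the JGG/REX and stochastic-ranking literature, scaled by the search
#' dimension \code{d}.
#'
#' @param d search dimension (number of searched parameters).
#' @param population_size number of individuals kept in the population.
#' @param n_parents parents sampled per generation (JGG replaces exactly these).
#' @param n_children children generated per generation.
#' @param pf probability of comparing by objective f (rather than violation
#'   gamma) for an infeasible pair during stochastic ranking.
#' @param expansion_rate crossover spread xi ~ N(0, expansion_rate^2 / n_parents).
#' @param star logical; weight the crossover centroid toward better-ranked
#'   parents (REX-star bias).  \code{FALSE} gives plain unbiased REX.
#' @param stall_generations generations without archive improvement before
#'   the population is restarted from scratch (iterative start).
#' @param max_evaluations evaluation budget across all restarts.
#' @param wall_clock_budget optional budget in seconds.
#' @param seed integer seed; every stochastic operation of the run derives
#'   from it, so equal seeds give bit-identical histories.
#' @return List of class \code{"ga_config"}.
#' @export
ga_config <- function(d, population_size = 10 * d, n_parents = d + 1,
                      n_children = 4 * d, pf = 0.45, expansion_rate = 1,
                      star = TRUE, stall_generations = 50 * d,
                      max_evaluations = 20000, wall_clock_budget = Inf,
                      seed = 1) {
  stopifnot(d >= 1, population_size >= 2, n_parents >= 2,
            n_parents <= population_size, n_children >= n_parents,
            pf >= 0, pf <= 1, expansion_rate > 0, stall_generations >= 1,
            max_evaluations >= 1)
  structure(list(d = d, population_size = population_size,
                 n_parents = n_parents, n_children = n_children, pf = pf,
                 expansion_rate = expansion_rate, star = isTRUE(star),
                 stall_generations = stall_generations,
                 max_evaluations = max_evaluations,
                 wall_clock_budget = wall_clock_budget,
                 seed = as.integer(seed)), class = "ga_config")
}

#' Initialize a random population
#'
#' Genomes are sampled uniformly in the (log10-space) box.  Consumes the
#' current RNG stream; seed it for reproducibility.
#'
#' @param n population size.
#' @param lower,upper bound vectors (finite, lower < upper on some axis).
#' @return n x d matrix of genomes, one row per individual.
#' @export
initialize_population <- function(n, lower, upper) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(lower <= upper))
  if (all(lower == upper))
    stop("degenerate bounds: lower equals upper on every axis", call. = FALSE)
  d <- length(lower)
  matrix(stats::runif(n * d, rep(lower, each = n), rep(upper, each = n)),
         nrow = n, ncol = d)
}

#' Reflect out-of-bounds coordinates back into the box
#'
#' Repair by reflection at the boundary rather than clipping, so probability
#' mass does not pile up on the bounds.
#'
#' @param x numeric vector (one genome).
#' @param lower,upper bound vectors.
#' @return Repaired genome inside \code{[lower, upper]}.
#' @export
reflect_bounds <- function(x, lower, upper) {
  width <- upper - lower
  fixed <- width == 0
  y <- ifelse(fixed, lower, x)
  w2 <- ifelse(fixed, 1, 2 * width)
  z <- (y - lower) %% w2
  out <- lower + pmin(z, w2 - z)
  ifelse(fixed, lower, out)
}

#' Real-coded ensemble crossover (REX / REX-star)
#'
#' Each child is the parent centroid plus a random combination of
#' parent-minus-centroid vectors, \code{xi_i ~ N(0, expansion_rate^2 /
#' n_parents)}.  With \code{parent_ranks} supplied the centroid is shifted
#' toward better-ranked parents (rank-weighted mean), which biases sampling
#' toward the good region ("star" variant); without it the crossover is
#' unbiased and the mean child equals the plain centroid.
#'
#' @param parents matrix of parent genomes (rows).
#' @param n_children number of children to generate.
#' @param expansion_rate spread multiplier.
#' @param lower,upper bounds for reflection repair.
#' @param parent_ranks optional integer ranks of the parents (1 = best);
#'   enables the star centroid shift.
#' @return n_children x d matrix of repaired child genomes.
#' @export
rex_crossover <- function(parents, n_children, expansion_rate = 1,
                          lower = NULL, upper = NULL, parent_ranks = NULL) {
  parents <- as.matrix(parents)
  np <- nrow(parents)
  if (np < 2) stop("REX needs at least 2 parents", call. = FALSE)
  centroid <- colMeans(parents)
  base <- if (!is.null(parent_ranks)) {
    w <- (np + 1 - parent_ranks)
    w <- w / sum(w)
    colSums(parents * w)
  } else centroid
  dev <- sweep(parents, 2, centroid)
  sd_xi <- expansion_rate / sqrt(np)
  d <- ncol(parents)
  children <- matrix(NA_real_, nrow = n_children, ncol = d)
  for (i in seq_len(n_children)) {
    xi <- stats::rnorm(np, 0, sd_xi)
    child <- base + colSums(dev * xi)
    if (!is.null(lower)) child <- reflect_bounds(child, lower, upper)
    children[i, ] <- child
  }
  children
}

#' Stochastic ranking of individuals by (f, gamma)
#'
#' The probabilistic bubble sort of constrained evolutionary optimization:
#' in each sweep, an adjacent pair is compared by objective f if both members
#' are feasible (gamma = 0) or, with probability \code{pf}, regardless of
#' feasibility; otherwise by violation gamma.  Sweeping stops after a pass
#' with no swap or after \code{length(f)} passes.  This trades off reducing
#' f against reducing gamma: \code{pf = 0} gives a feasibility-first sort,
#' \code{pf = 1} a pure f sort.
#'
#' @param f objective values.
#' @param gamma constraint violations (same length).
#' @param pf probability of objective-based comparison for infeasible pairs.
#' @return Integer permutation ordering individuals from best to worst.
#' @export
stochastic_rank <- function(f, gamma, pf = 0.45) {
  n <- length(f)
  stopifnot(length(gamma) == n)
  if (any(is.na(f)) || any(is.na(gamma)))
    stop("all individuals must be evaluated before ranking", call. = FALSE)
  idx <- seq_len(n)
  for (sweep in seq_len(n)) {
    swapped <- FALSE
    for (j in seq_len(n - 1)) {
      a <- idx[j]; b <- idx[j + 1]
      by_f <- (gamma[a] == 0 && gamma[b] == 0) || (stats::runif(1) < pf)
      do_swap <- if (by_f) {
        fa <- f[a]; fb <- f[b]
        if (is.infinite(gamma[a]) != is.infinite(gamma[b]))
          is.infinite(gamma[a])     # failed evaluations always rank last
        else fa > fb
      } else gamma[a] > gamma[b]
      if (isTRUE(do_swap)) {
        idx[j] <- b; idx[j + 1] <- a
        swapped <- TRUE
      }
    }
    if (!swapped) break
  }
  idx
}

# Evaluate one genome through the problem, mapping any failure to the
# infeasible sentinel gamma = +Inf (never a silent large number).
eval_genome <- function(genome, problem) {
  res <- tryCatch(problem$eval(genome), error = function(e) e)
  if (inherits(res, "error") || !is.finite(res$f) ||
      (length(res$g) && any(is.na(res$g)))) {
    msg <- if (inherits(res, "error")) conditionMessage(res) else "non-finite result"
    return(list(f = Inf, g = NULL, gamma = Inf, error = msg))
  }
  list(f = res$f, g = res$g, gamma = constraint_violation_quiet(res$g))
}

constraint_violation_quiet <- function(g) {
  if (length(g) == 0) 0 else sum(pmax(0, g)^2)
}

# lexicographic (gamma, f) comparison: TRUE if (g1, f1) better than (g2, f2)
lex_better <- function(g1, f1, g2, f2) {
  g1 < g2 || (g1 == g2 && f1 < f2)
}

#' One just-generation-gap (JGG) generation
#'
#' Samples \code{n_parents} individuals uniformly without replacement,
#' generates \code{n_children} by REX crossover, evaluates them, ranks the
#' children by stochastic ranking, and replaces the sampled parents with the
#' top-ranked children.  Population size is conserved.
#'
#' @param pop list with \code{genomes} (matrix), \code{f}, \code{gamma}
#'   (vectors).
#' @param config a \code{\link{ga_config}}.
#' @param problem list with \code{eval(genome)}, \code{lower}, \code{upper}.
#' @return Updated population list; attribute \code{"evals"} gives the number
#'   of evaluations spent.
#' @export
jgg_step <- function(pop, config, problem) {
  n <- nrow(pop$genomes)
  pidx <- sample.int(n, config$n_parents)
  parents <- pop$genomes[pidx, , drop = FALSE]
  pranks <- if (config$star) {
    ord <- order(pop$gamma[pidx], pop$f[pidx])
    r <- integer(config$n_parents); r[ord] <- seq_len(config$n_parents); r
  } else NULL
  children <- rex_crossover(parents, config$n_children, config$expansion_rate,
                            problem$lower, problem$upper, parent_ranks = pranks)
  evals <- lapply(seq_len(nrow(children)), function(i)
    eval_genome(children[i, ], problem))
  cf <- vapply(evals, `[[`, numeric(1), "f")
  cg <- vapply(evals, `[[`, numeric(1), "gamma")
  ord <- stochastic_rank(cf, cg, config$pf)
  keep <- ord[seq_len(config$n_parents)]
  pop$genomes[pidx, ] <- children[keep, , drop = FALSE]
  pop$f[pidx] <- cf[keep]
  pop$gamma[pidx] <- cg[keep]
  attr(pop, "evals") <- nrow(children)
  attr(pop, "children") <- list(f = cf, gamma = cg, genomes = children)
  pop
}

#' Constrained optimization by IS-SR-REX-star/JGG
#'
#' Runs the just-generation-gap genetic algorithm with stochastic ranking
#' under the evaluation budget, restarting from a fresh random population
#' whenever the best-so-far (gamma, f) pair has not improved for
#' \code{stall_generations} generations (iterative start).  The overall best
#' individual is archived across restarts.
#'
#' @param problem list with \code{eval(genome) -> list(f, g)}, \code{lower},
#'   \code{upper}, optional \code{names} and \code{decode(genome)}.
#' @param config a \code{\link{ga_config}} (its \code{d} must equal
#'   \code{length(problem$lower)}).
#' @return Object of class \code{"ga_run"}: \code{best} (genome, f, g, gamma,
#'   mp, feasible flag, decoded values when the problem provides a decoder),
#'   \code{history} data frame (generation, best_f, best_gamma,
#'   feasible_fraction, evaluations), \code{restarts}, \code{evaluations},
#'   \code{seed}.
#' @export
ga_optimize <- function(problem, config) {
  stopifnot(config$d == length(problem$lower))
  set.seed(config$seed)
  t_start <- Sys.time()

  new_pop <- function() {
    genomes <- initialize_population(config$population_size, problem$lower,
                                     problem$upper)
    evals <- lapply(seq_len(nrow(genomes)), function(i)
      eval_genome(genomes[i, ], problem))
    list(genomes = genomes,
         f = vapply(evals, `[[`, numeric(1), "f"),
         gamma = vapply(evals, `[[`, numeric(1), "gamma"))
  }

  best <- list(genome = NULL, f = Inf, gamma = Inf, g = NULL)
  update_best <- function(pop) {
    ord <- order(pop$gamma, pop$f)
    i <- ord[1]
    if (lex_better(pop$gamma[i], pop$f[i], best$gamma, best$f)) {
      res <- eval_genome(pop$genomes[i, ], problem)
      best <<- list(genome = pop$genomes[i, ], f = pop$f[i],
                    gamma = pop$gamma[i], g = res$g)
      TRUE
    } else FALSE
  }

  pop <- new_pop()
  evaluations <- config$population_size
  update_best(pop)
  # Stall detection uses a relative improvement margin so that vanishing
  # refinements of (gamma, f) still trigger an iterative restart.
  mark <- list(gamma = best$gamma, f = best$f)
  significant <- function() {
    margin <- function(old, new) (old - new) > 1e-3 * max(old, 1e-12)
    if (margin(mark$gamma, best$gamma) ||
        (best$gamma <= mark$gamma && margin(mark$f, best$f))) {
      mark <<- list(gamma = best$gamma, f = best$f)
      TRUE
    } else FALSE
  }
  stall <- 0
  restarts <- 0
  gen <- 0
  hist <- list()

  while (evaluations < config$max_evaluations &&
         as.numeric(Sys.time() - t_start, units = "secs") <
           config$wall_clock_budget) {
    pop <- jgg_step(pop, config, problem)
    evaluations <- evaluations + attr(pop, "evals")
    gen <- gen + 1
    update_best(pop)
    stall <- if (significant()) 0 else stall + 1
    feas <- pop$gamma == 0
    hist[[gen]] <- data.frame(
      generation = gen,
      best_f = if (any(feas)) min(pop$f[feas]) else NA_real_,
      best_gamma = min(pop$gamma),
      feasible_fraction = mean(feas),
      evaluations = evaluations)
    if (stall >= config$stall_generations) {
      if (evaluations + config$population_size > config$max_evaluations) break
      pop <- new_pop()
      evaluations <- evaluations + config$population_size
      update_best(pop)
      restarts <- restarts + 1
      stall <- 0
    }
  }

  best$feasible <- is.finite(best$gamma) && best$gamma == 0
  best$mp <- if (is.finite(best$f)) exp(-best$f) else 0
  if (!is.null(problem$decode) && !is.null(best$genome))
    best$values <- problem$decode(best$genome)
  if (!is.null(problem$names) && !is.null(best$genome))
    names(best$genome) <- problem$names
  structure(list(best = best,
                 history = do.call(rbind, hist),
                 restarts = restarts, evaluations = evaluations,
                 seed = config$seed), class = "ga_run")
}

#' @export
print.ga_run <- function(x, ...) {
  cat(sprintf(
    "GA run (seed %d): %d evaluations, %d restart(s)\n  best: f = %.6g, gamma = %.3g, MP = %.3g (%s)\n",
    x$seed, x$evaluations, x$restarts, x$best$f, x$best$gamma, x$best$mp,
    if (isTRUE(x$best$feasible)) "feasible" else "infeasible"))
  invisible(x)
}
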