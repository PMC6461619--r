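test_that("ga_config applies scaled defaults and validates", {
  cfg <- ga_config(8)
  expect_equal(cfg$population_size, 80)
  expect_equal(cfg$n_parents, 9)
  expect_equal(cfg$n_children, 32)
  expect_equal(cfg$pf, 0.45)
  expect_equal(cfg$stall_generations, 400)
  expect_error(ga_config(2, pf = 1.5), "pf")
  expect_error(ga_config(2, n_parents = 1), "n_parents")
  expect_error(ga_config(2, population_size = 3, n_parents = 4), "n_parents")
})

test_that("population initialization is uniform in the box and seeded", {
  lo <- c(-2, 0); hi <- c(1, 5)
  set.seed(3); a <- initialize_population(200, lo, hi)
  set.seed(3); b <- initialize_population(200, lo, hi)
  expect_identical(a, b)
  expect_equal(dim(a), c(200, 2))
  expect_true(all(a[, 1] >= -2 & a[, 1] <= 1))
  expect_true(all(a[, 2] >= 0 & a[, 2] <= 5))
  # roughly uniform: mean near box center
  expect_equal(colMeans(a), c(-0.5, 2.5), tolerance = 0.25)
  expect_error(initialize_population(5, c(0, 0), c(0, 0)), "degenerate")
})

test_that("reflection repair maps any point into the box, fixing interior points", {
  lo <- c(0, -1); hi <- c(1, 1)
  inside <- c(0.3, 0.5)
  expect_equal(reflect_bounds(inside, lo, hi), inside)
  expect_equal(reflect_bounds(c(1.2, 0), lo, hi), c(0.8, 0))
  expect_equal(reflect_bounds(c(-0.3, -1.5), lo, hi), c(0.3, -0.5))
  # far excursions still land inside
  set.seed(5)
  for (k in 1:50) {
    x <- runif(2, -20, 20)
    y <- reflect_bounds(x, lo, hi)
    expect_true(all(y >= lo - 1e-12 & y <= hi + 1e-12))
  }
})

test_that("REX children average to the centroid; star shifts toward the best", {
  set.seed(11)
  parents <- matrix(rnorm(8), nrow = 4, ncol = 2)
  centroid <- colMeans(parents)
  kids <- rex_crossover(parents, 4000, expansion_rate = 1)
  expect_equal(colMeans(kids), centroid, tolerance = 0.05)
  # per-child deviation variance ~ expansion_rate^2/np * sum of squared devs
  dev <- sweep(parents, 2, centroid)
  expect_equal(apply(kids, 2, var), colSums(dev^2) / 4, tolerance = 0.1)
  # star: mean child equals the rank-weighted centroid, pulled toward rank 1
  ranks <- 1:4
  kids_star <- rex_crossover(parents, 4000, expansion_rate = 1,
                             parent_ranks = ranks)
  w <- (4 + 1 - ranks); w <- w / sum(w)
  expect_equal(colMeans(kids_star), colSums(parents * w), tolerance = 0.05)
  expect_error(rex_crossover(parents[1, , drop = FALSE], 2), "2 parents")
})

test_that("stochastic ranking reduces to a plain f sort when all are feasible", {
  f <- c(3, 1, 2, 5, 4)
  g <- rep(0, 5)
  for (pf in c(0, 0.45, 1)) {
    set.seed(1)
    expect_equal(stochastic_rank(f, g, pf), order(f))
  }
})

test_that("stochastic ranking endpoints are exact at pf = 0 and pf = 1", {
  # pf = 0: feasibility-first; A(gamma=0, f=5) beats B(gamma=1, f=0)
  expect_equal(stochastic_rank(c(5, 0), c(0, 1), pf = 0), c(1, 2))
  # pf = 0 sorts infeasibles by gamma regardless of f
  f <- c(10, 1, 5); g <- c(0.1, 3, 0.5)
  expect_equal(stochastic_rank(f, g, pf = 0), order(g))
  # pf = 1: pure f sort regardless of gamma
  expect_equal(stochastic_rank(f, g, pf = 1), order(f))
  expect_error(stochastic_rank(c(1, NA), c(0, 0)), "evaluated")
})

test_that("failed evaluations (gamma = Inf) always rank last", {
  f <- c(Inf, 0.5, 1)
  g <- c(Inf, 0.2, 0.1)
  r0 <- stochastic_rank(f, g, pf = 0)
  r1 <- stochastic_rank(f, g, pf = 1)
  expect_equal(r0[3], 1)
  expect_equal(r1[3], 1)
})

test_that("jgg_step conserves population size and spends n_children evals", {
  prob <- toy2d_problem()
  cfg <- ga_config(2, seed = 9)
  set.seed(9)
  genomes <- initialize_population(cfg$population_size, prob$lower, prob$upper)
  evals <- apply(genomes, 1, function(x) prob$eval(x))
  pop <- list(genomes = genomes,
              f = vapply(evals, `[[`, numeric(1), "f"),
              gamma = vapply(evals, function(e)
                constraint_violation(e$g), numeric(1)))
  pop2 <- suppressWarnings(jgg_step(pop, cfg, prob))
  expect_equal(dim(pop2$genomes), dim(pop$genomes))
  expect_equal(attr(pop2, "evals"), cfg$n_children)
  expect_true(all(pop2$genomes >= rep(prob$lower, each = nrow(pop2$genomes))))
})

test_that("ga_optimize is bit-reproducible for equal seeds", {
  prob <- toy2d_problem()
  cfg <- ga_config(2, max_evaluations = 600, seed = 4)
  r1 <- ga_optimize(prob, cfg)
  r2 <- ga_optimize(prob, cfg)
  expect_identical(r1$best$genome, r2$best$genome)
  expect_identical(r1$history, r2$history)
  r3 <- ga_optimize(prob, ga_config(2, max_evaluations = 600, seed = 5))
  expect_false(identical(r1$best$genome, r3$best$genome))
})

test_that("the archive is lexicographically at least as good as any generation", {
  prob <- toy2d_problem()
  run <- ga_optimize(prob, ga_config(2, max_evaluations = 1500, seed = 2))
  expect_true(run$best$gamma <= min(run$history$best_gamma))
  feas_f <- run$history$best_f[!is.na(run$history$best_f)]
  if (run$best$gamma == 0 && length(feas_f))
    expect_true(run$best$f <= min(feas_f) + 1e-12)
  expect_equal(run$seed, 2)
  expect_true(all(c("generation", "best_f", "best_gamma",
                    "feasible_fraction", "evaluations") %in%
                    names(run$history)))
  expect_output(print(run), "best")
})

test_that("the GA solves the constrained 2-D toy to the grid-oracle optimum", {
  prob <- toy2d_problem()
  # grid oracle for the constrained minimum
  gx <- seq(-5, 5, length.out = 801)
  grid <- expand.grid(x = gx, y = gx)
  fg <- (grid$x - 1)^2 + (grid$y - 2)^2
  ok <- grid$x + grid$y <= 2
  f_grid <- min(fg[ok])
  expect_equal(f_grid, 0.5, tolerance = 1e-3)

  run <- ga_optimize(prob, ga_config(2, max_evaluations = 4000, seed = 7))
  expect_true(run$best$feasible)
  expect_equal(run$best$f, 0.5, tolerance = 1e-3)
  expect_equal(unname(run$best$genome), c(0.5, 1.5), tolerance = 0.05)
})

test_that("an unconstrained sphere is minimized to its center", {
  prob <- list(eval = function(g) list(f = sum((g - c(1, -2, 0.5))^2),
                                       g = numeric(0)),
               lower = rep(-4, 3), upper = rep(4, 3))
  run <- suppressWarnings(
    ga_optimize(prob, ga_config(3, max_evaluations = 6000, seed = 1)))
  expect_true(run$best$f < 1e-4)
})

test_that("evaluation failures become the gamma = +Inf sentinel, not a crash", {
  prob <- list(eval = function(g) {
    if (g[1] < 0) stop("solver exploded")
    list(f = (g[1] - 2)^2, g = c(a = g[1] - 3))
  }, lower = c(-5), upper = c(5))
  direct <- rubberband:::eval_genome(c(-1), prob)
  expect_identical(direct$gamma, Inf)
  expect_identical(direct$f, Inf)
  expect_match(direct$error, "exploded")
  run <- ga_optimize(prob, ga_config(1, max_evaluations = 800, seed = 3))
  expect_true(run$best$feasible)
  expect_equal(run$best$f, 0, tolerance = 1e-3)
})

test_that("a problem with no feasible point returns the best-gamma individual", {
  prob <- list(eval = function(g) list(f = sum(g^2), g = c(imp = 1 + g[1]^2)),
               lower = c(-2, -2), upper = c(2, 2))
  run <- ga_optimize(prob, ga_config(2, max_evaluations = 800, seed = 6))
  expect_false(run$best$feasible)
  expect_true(is.finite(run$best$gamma))
  expect_true(run$best$gamma >= 1)
})

test_that("the wall-clock budget stops the run early", {
  slow <- list(eval = function(g) { Sys.sleep(0.01); list(f = sum(g^2),
                                                          g = numeric(0)) },
               lower = c(-1), upper = c(1))
  t0 <- Sys.time()
  run <- suppressWarnings(ga_optimize(
    slow, ga_config(1, max_evaluations = 1e5, wall_clock_budget = 1,
                    seed = 1)))
  expect_true(as.numeric(Sys.time() - t0, units = "secs") < 10)
  expect_true(run$evaluations < 1e5)
})
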