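# Shared fixtures for the test suite.

# The canonical parameter/state tuple used by the hand-evaluated RHS oracle
# and the transport tests.
fixture_params <- function(...) {
  toy_params(vmax_amtb = 150, km_amtb = 0.01, p_diff = 50,
             vmax_gs = 5, km_gs = 0.02, k_glnk = 0.02, n_glnk = 2,
             mu_max = 4, k_growth = 1, k_dil = 0.05, ...)
}

fixture_condition <- function(nhx_ext = 0.1, mode = "active", ...) {
  toy_condition("fix", transport_physics(mode, delta_psi = -150,
                                         temperature = 310,
                                         ph_ext = 7.0, ph_int = 7.6),
                nhx_ext = nhx_ext, tau0 = 60, ...)
}

fixture_state <- function() c(nhx = 0.05, gln = 5, glu = 50)

# A cheap analytic GA problem: minimize (x-1)^2 + (y-2)^2 subject to
# x + y <= 2, on the box [-5, 5]^2.  The constrained optimum is the
# projection of (1, 2) on the line x + y = 2, i.e. (0.5, 1.5), f* = 0.5.
toy2d_problem <- function() {
  list(eval = function(g) list(f = (g[1] - 1)^2 + (g[2] - 2)^2,
                               g = c(lin = g[1] + g[2] - 2)),
       lower = c(-5, -5), upper = c(5, 5), names = c("x", "y"),
       decode = function(g) stats::setNames(g, c("x", "y")))
}

# Independent naive implementation of the objective/violation arithmetic,
# written as plain loops so the vectorized package code is checked against
# straightforward summation.
naive_objective <- function(values, specs, weights) {
  lam <- list(I = weights$lambda_I, II = weights$lambda_II,
              III = weights$lambda_III, US = 0)
  total <- 0
  for (i in seq_len(nrow(specs))) {
    if (specs$class[i] == "US") next
    d <- log(values[[specs$name[i]]] / specs$reference[i])
    total <- total + lam[[specs$class[i]]] * d * d
  }
  total
}

naive_residual <- function(simulated, observed, epsilon) {
  s <- 0
  for (j in seq_along(observed))
    s <- s + ((simulated[j] - observed[j]) / observed[j])^2
  s / length(observed) - epsilon^2
}

naive_gamma <- function(g) {
  total <- 0
  for (gi in g) if (gi > 0) total <- total + gi * gi
  total
}

# Exhaustive-enumeration oracle for the exact two-sided rank-sum p-value
# (no ties).  Enumerates every assignment of the pooled ranks to group x.
enum_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  stopifnot(!any(duplicated(pooled)))
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(length(pooled), n1)
  w_all <- apply(sets, 2, function(i) sum(rank(pooled)[i]))
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}
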