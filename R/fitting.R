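# Bridge between the reduced kinetic model and the constrained optimizer:
# a fitting problem evaluates one candidate parameter vector by simulating
# every condition the constraints refer to and scoring f, g and gamma.

#' Build parameters of the reduced model from a named value vector
#'
#' Names matching \code{\link{toy_params}} arguments override the defaults;
#' unknown names are an error (they indicate a spec/constraint mismatch).
#'
#' @param values named numeric vector of parameter values.
#' @return A \code{\link{toy_params}} object.
#' @export
toy_params_from_values <- function(values) {
  known <- setdiff(names(formals(toy_params)), "glnk_present")
  bad <- setdiff(names(values), known)
  if (length(bad))
    stop("unknown toy-model parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(toy_params, as.list(values))
}

#' Evaluate one parameter vector against a set of training constraints
#'
#' Simulates each referenced condition once (time courses at the union of
#' requested times; steady states by long-run integration), extracts the
#' bound observables, and returns the penalized objective f, the residual
#' vector g, the violation gamma and MP.
#'
#' @param values named numeric vector covering all searched parameters.
#' @param specs a \code{\link{param_spec}} table.
#' @param constraints list of \code{\link{training_constraint}}s.
#' @param conditions named list of \code{\link{toy_condition}}s keyed by
#'   \code{condition_id}.
#' @param weights a \code{\link{penalty_weights}}.
#' @param ss_tol,sim_rtol solver controls (steady-state convergence tolerance
#'   and integration relative tolerance).
#' @return An \code{\link{evaluation_result}}.
#' @export
evaluate_fit <- function(values, specs, constraints, conditions,
                         weights = penalty_weights(), ss_tol = 1e-7,
                         sim_rtol = 1e-8) {
  f <- objective_f(values, specs, weights)
  full <- stats::setNames(specs$reference, specs$name)
  full[names(values)] <- unlist(values)
  params <- toy_params_from_values(full)

  cond_ids <- vapply(constraints, `[[`, character(1), "condition_id")
  missing <- setdiff(unique(cond_ids), names(conditions))
  if (length(missing))
    stop("constraints reference unknown condition(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  g <- numeric(length(constraints))
  names(g) <- vapply(constraints, `[[`, character(1), "constraint_id")

  for (cid in unique(cond_ids)) {
    cond <- conditions[[cid]]      # knockout conditions are handled by the
    p <- params                    # simulators via cond$glnk_present
    sel <- which(cond_ids == cid)
    kinds <- vapply(constraints[sel], `[[`, character(1), "kind")

    if (any(kinds == "timecourse")) {
      all_times <- sort(unique(unlist(
        lapply(constraints[sel][kinds == "timecourse"], `[[`, "times"))))
      traj <- simulate_toy(p, cond, times = all_times,
                           rtol = sim_rtol, atol = sim_rtol * 1e-2)
      for (i in sel[kinds == "timecourse"]) {
        con <- constraints[[i]]
        if (!con$variable %in% names(traj))
          stop("unknown observable '", con$variable, "' in constraint ",
               con$constraint_id, call. = FALSE)
        sim <- traj[[con$variable]][match(con$times, traj$time)]
        g[i] <- constraint_residual(sim, con)
      }
    }
    if (any(kinds != "timecourse")) {
      ss <- steady_state_toy(p, cond, tol = ss_tol,
                             rtol = sim_rtol, atol = sim_rtol * 1e-2)
      obs <- c(ss$state, ss$fluxes)
      for (i in sel[kinds != "timecourse"]) {
        con <- constraints[[i]]
        if (!con$variable %in% names(obs))
          stop("unknown observable '", con$variable, "' in constraint ",
               con$constraint_id, call. = FALSE)
        g[i] <- constraint_residual(obs[[con$variable]], con)
      }
    }
  }
  evaluation_result(f, g)
}

#' Package a fitting task as a GA problem
#'
#' Returns the closure interface consumed by \code{\link{ga_optimize}}: a
#' log10-space box over the searched parameters and an \code{eval} function
#' returning f and g for one genome.
#'
#' @inheritParams evaluate_fit
#' @return List with \code{eval}, \code{lower}, \code{upper}, \code{names},
#'   \code{decode}, \code{specs}.
#' @export
fitting_problem <- function(specs, constraints, conditions,
                            weights = penalty_weights(), ss_tol = 1e-7,
                            sim_rtol = 1e-8) {
  if (length(constraints) == 0)
    stop("no training constraints: nothing to fit", call. = FALSE)
  enc <- encode_search_vector(specs)
  cond_ids <- vapply(constraints, `[[`, character(1), "condition_id")
  missing <- setdiff(unique(cond_ids), names(conditions))
  if (length(missing))
    stop("constraints reference unknown condition(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  list(
    eval = function(genome) {
      values <- decode_search_vector(genome, specs)
      res <- evaluate_fit(values[enc$names], specs, constraints, conditions,
                          weights, ss_tol = ss_tol, sim_rtol = sim_rtol)
      list(f = res$f, g = res$g)
    },
    lower = enc$lower, upper = enc$upper, names = enc$names,
    decode = function(genome) decode_search_vector(genome, specs),
    specs = specs)
}
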