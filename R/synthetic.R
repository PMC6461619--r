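# Synthetic study generator: ground-truth parameters, reference values drawn
# at class-dependent dispersion (mirroring measured values, educated guesses
# and rough guesses), and noisy multi-condition observations of the reduced
# ammonium network, so the whole estimation/ranking pipeline is testable
# without any external dataset.

#' Define a synthetic estimation scenario
#'
#' @param true_params a \code{\link{toy_params}}: the ground truth that
#'   generates the observations.
#' @param class_assignment named character vector mapping each kinetic
#'   parameter to a class in \code{c("I","II","III","US")}.
#' @param reference_dispersion named numeric vector (\code{I}, \code{II},
#'   \code{III}): lognormal sigma of reference values around the truth.
#'   Must be non-decreasing from class I to class III (references for
#'   measured parameters sit closest to the truth).
#' @param noise_cv relative noise applied to observations (multiplicative,
#'   \code{value * (1 + cv * z)}).
#' @param conditions named list of \code{\link{toy_condition}}s.
#' @param observation_plan data frame with columns \code{condition_id},
#'   \code{variable}, \code{kind}, \code{times} (semicolon-separated string,
#'   empty for steady state), \code{epsilon}.
#' @param seed mandatory integer seed; unseeded scenarios are refused.
#' @return List of class \code{"synthetic_scenario"}.
#' @export
synthetic_scenario <- function(true_params, class_assignment,
                               reference_dispersion = c(I = 0.1, II = 0.4, III = 1.0),
                               noise_cv = 0.03, conditions, observation_plan,
                               seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("scenario seed is mandatory: unseeded generation is refused",
         call. = FALSE)
  kin <- setdiff(names(formals(toy_params)), "glnk_present")
  missing_p <- setdiff(kin, names(class_assignment))
  if (length(missing_p))
    stop("class_assignment must cover: ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  if (!all(class_assignment %in% c("I", "II", "III", "US")))
    stop("classes must be I, II, III or US", call. = FALSE)
  rd <- reference_dispersion[c("I", "II", "III")]
  if (any(is.na(rd)) || any(rd < 0) || is.unsorted(rd))
    stop("reference_dispersion must be non-negative and non-decreasing ",
         "from class I to class III", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)
  needed <- unique(observation_plan$condition_id)
  if (!all(needed %in% names(conditions)))
    stop("observation plan references unknown conditions", call. = FALSE)
  structure(list(true_params = true_params,
                 class_assignment = class_assignment[kin],
                 reference_dispersion = rd, noise_cv = noise_cv,
                 conditions = conditions, observation_plan = observation_plan,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Draw reference values around the truth
#'
#' Emulates the uncertainty structure the rubber-band method assumes:
#' reference = truth * exp(sigma_class * z) with z standard normal, sigma
#' smallest for measured (class I) parameters.  Unsearched (US) parameters
#' get their reference exactly at the truth.  Consumes the current RNG
#' stream.
#'
#' @param scenario a \code{\link{synthetic_scenario}}.
#' @return A \code{\link{param_spec}} table with class defaults for bounds.
#' @export
draw_references <- function(scenario) {
  cls <- scenario$class_assignment
  truth <- unlist(scenario$true_params[names(cls)])
  sigma <- c(scenario$reference_dispersion, US = 0)[cls]
  ref <- truth * exp(sigma * stats::rnorm(length(truth)))
  param_spec(names(cls), ref, unname(cls))
}

parse_times <- function(x) {
  if (is.na(x) || !nzchar(x)) numeric(0)
  else as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Generate noisy training constraints from the truth
#'
#' Simulates the ground-truth parameters under every condition in the
#' observation plan, samples the observables, applies multiplicative
#' relative noise truncated at a positive floor (1e-9 of the true value;
#' resampled a bounded number of times if the floor is hit), and packages
#' each row of the plan as one \code{\link{training_constraint}}.
#' Consumes the current RNG stream.
#'
#' @param scenario a \code{\link{synthetic_scenario}}.
#' @return List of \code{\link{training_constraint}}s.
#' @export
generate_observations <- function(scenario) {
  plan <- scenario$observation_plan
  out <- vector("list", nrow(plan))
  ss_cache <- list()
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    cond <- scenario$conditions[[row$condition_id]]
    if (row$kind == "timecourse") {
      times <- parse_times(row$times)
      traj <- simulate_toy(scenario$true_params, cond, times = times)
      true_vals <- traj[[row$variable]][match(times, traj$time)]
    } else {
      key <- row$condition_id
      if (is.null(ss_cache[[key]]))
        ss_cache[[key]] <- steady_state_toy(scenario$true_params, cond)
      obs <- c(ss_cache[[key]]$state, ss_cache[[key]]$fluxes)
      true_vals <- obs[[row$variable]]
      times <- numeric(0)
    }
    if (any(true_vals <= 0))
      stop("observable ", row$variable, " is non-positive under the truth; ",
           "relative constraints require positive observations", call. = FALSE)
    noisy <- true_vals * (1 + scenario$noise_cv * stats::rnorm(length(true_vals)))
    floor_v <- 1e-9 * true_vals
    for (tries in 1:100) {
      bad <- noisy < floor_v
      if (!any(bad)) break
      noisy[bad] <- true_vals[bad] *
        (1 + scenario$noise_cv * stats::rnorm(sum(bad)))
    }
    noisy <- pmax(noisy, floor_v)
    out[[i]] <- training_constraint(
      constraint_id = sprintf("g%02d_%s_%s", i, row$condition_id, row$variable),
      condition_id = row$condition_id, variable = row$variable,
      kind = row$kind, times = times, values = noisy, epsilon = row$epsilon)
  }
  out
}

#' Materialize a scenario into estimation inputs
#'
#' Seeds the RNG from the scenario, draws references and observations, and
#' returns everything \code{\link{fitting_problem}} needs.
#'
#' @param scenario a \code{\link{synthetic_scenario}}.
#' @return List with \code{specs}, \code{constraints}, \code{conditions},
#'   \code{truth} (named numeric vector of true values), \code{scenario}.
#' @export
realize_scenario <- function(scenario) {
  set.seed(scenario$seed)
  specs <- draw_references(scenario)
  constraints <- generate_observations(scenario)
  kin <- setdiff(names(formals(toy_params)), "glnk_present")
  list(specs = specs, constraints = constraints,
       conditions = scenario$conditions,
       truth = unlist(scenario$true_params[kin]), scenario = scenario)
}

# The ground truth of the shipped scenarios: a nitrogen-limited E. coli-like
# cell with an electrogenic AmtB (phi ~ 275 at -150 mV, 310 K), fast NH3
# permeation, a single lumped GS assimilation flux, GlnK throttling of AmtB
# at ~20 uM internal NH4+, and glutamine-fuelled growth (doubling ~ 1 h).
default_truth <- function() {
  toy_params(vmax_amtb = 150, km_amtb = 0.01, p_diff = 50,
             vmax_gs = 5, km_gs = 0.02, k_glnk = 0.02, n_glnk = 2,
             mu_max = 4, k_growth = 1, k_dil = 0.05)
}

default_classes <- function() {
  c(vmax_amtb = "II", km_amtb = "I", p_diff = "II", vmax_gs = "II",
    km_gs = "I", k_glnk = "II", n_glnk = "US", mu_max = "I",
    k_growth = "III", k_dil = "US")
}

#' The shipped default estimation scenario
#'
#' Three experimental designs on the active-transporter truth: an N-upshift
#' time course (cells adapted to 4 uM external ammonium, stepped to 100 uM
#' at t = 0), a low-ammonium steady state (4 uM), and a GlnK-removal steady
#' state at 100 uM in which futile cycling is unchecked.  Observables cover
#' internal ammonium, glutamine, growth rate and membrane fluxes.
#'
#' @param seed integer seed.
#' @param noise_cv relative observation noise (default 0.03, well below the
#'   smallest allowable error so the truth itself is feasible).
#' @return A \code{\link{synthetic_scenario}}.
#' @export
default_scenario <- function(seed, noise_cv = 0.03) {
  phys <- transport_physics("active", delta_psi = -150, temperature = 310,
                            ph_ext = 7.0, ph_int = 7.6)
  low_state <- c(nhx = 0.063, gln = 6.4, glu = 69)  # near the low-N steady state
  conditions <- list(
    upshift = toy_condition("upshift", phys, 0.1,
                            initial_state = low_state, tau0 = 60),
    low_ss = toy_condition("low_ss", phys, 0.004, tau0 = 60),
    ko_ss = toy_condition("ko_ss", phys, 0.1, tau0 = 60,
                          glnk_present = FALSE))
  plan <- rbind(
    data.frame(condition_id = "upshift", variable = "nh4_int",
               kind = "timecourse", times = "1;2;5;10;20", epsilon = 0.2),
    data.frame(condition_id = "upshift", variable = "gln",
               kind = "timecourse", times = "1;2;5;10;20", epsilon = 0.2),
    data.frame(condition_id = "low_ss", variable = "nh4_int",
               kind = "steady_state", times = "", epsilon = 0.1),
    data.frame(condition_id = "low_ss", variable = "gln",
               kind = "steady_state", times = "", epsilon = 0.1),
    data.frame(condition_id = "low_ss", variable = "growth_rate",
               kind = "scalar", times = "", epsilon = 0.1),
    data.frame(condition_id = "low_ss", variable = "v_net",
               kind = "scalar", times = "", epsilon = 0.2),
    data.frame(condition_id = "ko_ss", variable = "nh4_int",
               kind = "steady_state", times = "", epsilon = 0.2),
    data.frame(condition_id = "ko_ss", variable = "v_amtb",
               kind = "scalar", times = "", epsilon = 0.2))
  synthetic_scenario(default_truth(), default_classes(),
                     noise_cv = noise_cv, conditions = conditions,
                     observation_plan = plan, seed = seed)
}

#' Matched scenarios for two-model ranking
#'
#' Generates one observation set from the active-transporter truth and
#' packages it identically for the active and the passive model variants:
#' the ranking then asks which transport mechanism explains the same data
#' with the smaller parameter deviation.  Observables are restricted to
#' quantities both mechanisms can in principle reproduce (glutamine, growth
#' rate and net nitrogen uptake at two ammonium levels), so the comparison
#' is decided by plausibility, not by brute feasibility.
#'
#' @param seed integer seed.
#' @param noise_cv relative observation noise.
#' @return List with elements \code{active} and \code{passive}, each a list
#'   of \code{specs}, \code{constraints}, \code{conditions}, \code{truth};
#'   the constraints are identical between the two.
#' @export
make_two_model_scenario <- function(seed, noise_cv = 0.03) {
  phys_a <- transport_physics("active", delta_psi = -150, temperature = 310,
                              ph_ext = 7.0, ph_int = 7.6)
  phys_p <- transport_physics("passive", ph_ext = 7.0, ph_int = 7.6)
  make_conds <- function(phys) list(
    n50 = toy_condition("n50", phys, 0.05, tau0 = 60),
    n100 = toy_condition("n100", phys, 0.1, tau0 = 60))
  plan <- rbind(
    data.frame(condition_id = "n50", variable = "gln",
               kind = "steady_state", times = "", epsilon = 0.3),
    data.frame(condition_id = "n50", variable = "growth_rate",
               kind = "scalar", times = "", epsilon = 0.15),
    data.frame(condition_id = "n50", variable = "v_net",
               kind = "scalar", times = "", epsilon = 0.3),
    data.frame(condition_id = "n100", variable = "gln",
               kind = "steady_state", times = "", epsilon = 0.3),
    data.frame(condition_id = "n100", variable = "growth_rate",
               kind = "scalar", times = "", epsilon = 0.15),
    data.frame(condition_id = "n100", variable = "v_net",
               kind = "scalar", times = "", epsilon = 0.3))
  scen <- synthetic_scenario(default_truth(), default_classes(),
                             noise_cv = noise_cv,
                             conditions = make_conds(phys_a),
                             observation_plan = plan, seed = seed)
  real <- realize_scenario(scen)
  list(active = list(specs = real$specs, constraints = real$constraints,
                     conditions = make_conds(phys_a), truth = real$truth),
       passive = list(specs = real$specs, constraints = real$constraints,
                      conditions = make_conds(phys_p), truth = real$truth))
}
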