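#' Parameter specification table
#'
#' A parameter specification describes one model parameter entering the
#' constrained estimation: its name, the reference value the "rubber band"
#' pulls towards, its uncertainty class, and box bounds for the search.
#'
#' Classes encode how well a parameter is known:
#' \describe{
#'   \item{I}{experimentally measured ("informed guess"); strongest penalty,
#'     default bounds reference / 10 .. reference * 10.}
#'   \item{II}{educated guess; intermediate penalty, default bounds
#'     reference / 100 .. reference * 100.}
#'   \item{III}{rough guess; zero penalty by default, default bounds
#'     reference / 1000 .. reference * 1000.}
#'   \item{US}{unsearched: fixed at the reference value, excluded from the
#'     search vector.}
#' }
#'
#' @param name character vector of parameter names (unique).
#' @param reference positive reference values, one per parameter.
#' @param class character vector in \code{c("I","II","III","US")}.
#' @param lower,upper optional positive bounds; \code{NA} entries are filled
#'   with the class defaults above.  Bounds must bracket the reference.
#' @return A data frame of class \code{"param_spec"} with columns
#'   \code{name}, \code{reference}, \code{class}, \code{lower}, \code{upper}.
#' @examples
#' param_spec(c("vmax", "km"), c(100, 0.01), c("I", "II"))
#' @export
param_spec <- function(name, reference, class, lower = NA_real_, upper = NA_real_) {
  name <- as.character(name)
  n <- length(name)
  if (anyDuplicated(name)) stop("parameter names must be unique", call. = FALSE)
  reference <- as.numeric(reference)
  class <- as.character(class)
  stopifnot(length(reference) == n, length(class) == n)
  if (!all(class %in% c("I", "II", "III", "US")))
    stop("param class must be one of I, II, III, US", call. = FALSE)
  if (any(!is.finite(reference) | reference <= 0))
    stop("reference values must be positive and finite", call. = FALSE)
  lower <- rep_len(as.numeric(lower), n)
  upper <- rep_len(as.numeric(upper), n)
  span <- c(I = 10, II = 100, III = 1000, US = 1)[class]
  lower <- ifelse(is.na(lower), reference / span, lower)
  upper <- ifelse(is.na(upper), reference * span, upper)
  if (any(lower <= 0)) stop("lower bounds must be positive", call. = FALSE)
  if (any(lower > reference | reference > upper))
    stop("bounds must satisfy lower <= reference <= upper", call. = FALSE)
  out <- data.frame(name = name, reference = reference, class = class,
                    lower = lower, upper = upper, stringsAsFactors = FALSE)
  class(out) <- c("param_spec", "data.frame")
  out
}

#' Class-dependent penalty weights
#'
#' Weights applied to squared log-deviations of each parameter class in the
#' objective \code{\link{objective_f}}.  Defaults are the published constants
#' for measured (I), educated-guess (II) and rough-guess (III) parameters.
#'
#' @param lambda_I,lambda_II,lambda_III non-negative weights with
#'   \code{lambda_I > lambda_II > lambda_III >= 0}.
#' @return A named list of class \code{"penalty_weights"}.
#' @export
penalty_weights <- function(lambda_I = 1.0407, lambda_II = 0.1930, lambda_III = 0) {
  if (!(lambda_I > lambda_II && lambda_II > lambda_III && lambda_III >= 0))
    stop("weights must satisfy lambda_I > lambda_II > lambda_III >= 0", call. = FALSE)
  structure(list(lambda_I = lambda_I, lambda_II = lambda_II,
                 lambda_III = lambda_III), class = "penalty_weights")
}

#' Rubber-band objective function
#'
#' The penalized objective
#' \deqn{f(p) = \sum_{c \in \{I,II,III\}} \lambda_c \sum_{i \in c}
#'   \left(\ln \frac{p_i}{p_i^*}\right)^2}
#' measuring how far a candidate parameter vector is pulled away from the
#' reference values, weighted by how well each parameter is known.
#' Unsearched (US) parameters contribute nothing.
#'
#' @param values named numeric vector or list of positive parameter values;
#'   must cover every searched (non-US) parameter in \code{specs}.
#' @param specs a \code{\link{param_spec}} table.
#' @param weights a \code{\link{penalty_weights}} object.
#' @return Non-negative scalar \code{f}; zero iff every penalized parameter
#'   equals its reference.
#' @export
objective_f <- function(values, specs, weights = penalty_weights()) {
  values <- unlist(values)
  searched <- specs[specs$class != "US", , drop = FALSE]
  missing <- setdiff(searched$name, names(values))
  if (length(missing))
    stop("missing value for searched parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  v <- values[searched$name]
  if (any(!is.finite(v) | v <= 0))
    stop("parameter values must be positive and finite", call. = FALSE)
  lam <- c(I = weights$lambda_I, II = weights$lambda_II, III = weights$lambda_III)
  dev2 <- (log(v / searched$reference))^2
  sum(lam[searched$class] * dev2)
}

#' Model plausibility
#'
#' Converts an objective value into the plausibility score
#' \eqn{MP = e^{-f}}, the quantity by which competing model variants are
#' ranked: minimizing \code{f} maximizes MP.
#'
#' @param f_value non-negative objective value(s).
#' @return MP in (0, 1], strictly decreasing in \code{f_value}.
#' @examples
#' model_plausibility(8.4)   # 2.2e-4 to two significant figures
#' model_plausibility(13.3)  # 1.7e-6
#' @export
model_plausibility <- function(f_value) {
  if (any(!is.finite(f_value) | f_value < 0))
    stop("f must be finite and non-negative", call. = FALSE)
  exp(-f_value)
}

#' Plausibility ratio of two models
#'
#' \code{MP(f_a) / MP(f_b) = exp(f_b - f_a)}: how many times more plausible
#' model A is than model B given their objective values.
#'
#' @param f_a,f_b non-negative objective values for models A and B.
#' @return Positive ratio; > 1 favours model A.
#' @export
plausibility_ratio <- function(f_a, f_b) {
  model_plausibility(f_a) / model_plausibility(f_b)
}

#' Training constraint
#'
#' One inequality constraint g_i tying a simulated observable to observed
#' data.  \code{kind = "timecourse"} compares a trajectory at \code{times};
#' \code{"steady_state"} compares the simulated steady-state value;
#' \code{"scalar"} compares a named derived quantity (e.g. a flux or growth
#' rate) at steady state.
#'
#' @param constraint_id unique identifier.
#' @param condition_id which experimental condition to simulate.
#' @param variable observable name in the model.
#' @param kind one of \code{"timecourse"}, \code{"steady_state"}, \code{"scalar"}.
#' @param times sampling times in minutes (timecourse only).
#' @param values positive observed values, one per time point (one value for
#'   steady_state/scalar).
#' @param epsilon allowable relative error (dimensionless).
#' @return A list of class \code{"training_constraint"}.
#' @export
training_constraint <- function(constraint_id, condition_id, variable, kind,
                                times = numeric(0), values, epsilon) {
  kind <- match.arg(kind, c("timecourse", "steady_state", "scalar"))
  values <- as.numeric(values)
  times <- as.numeric(times)
  if (kind == "timecourse") {
    if (length(times) != length(values))
      stop("timecourse constraint needs one value per time point", call. = FALSE)
    if (is.unsorted(times)) stop("times must be ordered", call. = FALSE)
  } else {
    if (length(values) != 1)
      stop(kind, " constraint needs exactly one observed value", call. = FALSE)
    times <- numeric(0)
  }
  if (any(values <= 0))
    stop("observed values must be positive (relative residual divides by them)",
         call. = FALSE)
  if (epsilon < 0) stop("epsilon must be non-negative", call. = FALSE)
  structure(list(constraint_id = as.character(constraint_id),
                 condition_id = as.character(condition_id),
                 variable = as.character(variable), kind = kind,
                 times = times, values = values, epsilon = as.numeric(epsilon)),
            class = "training_constraint")
}

#' Relative fit residual of one constraint
#'
#' \deqn{g_i = \frac{1}{n}\sum_{j=1}^{n}
#'   \left(\frac{x_j^{sim} - x_j^{exp}}{x_j^{exp}}\right)^2 - \varepsilon_i^2}
#' A non-positive value means the simulated observable matches the data
#' within the allowable relative error.
#'
#' @param simulated simulated values aligned with the constraint's observations.
#' @param constraint a \code{\link{training_constraint}}.
#' @return Scalar residual g_i.
#' @export
constraint_residual <- function(simulated, constraint) {
  obs <- constraint$values
  if (length(simulated) != length(obs))
    stop("simulated length ", length(simulated), " != observed length ",
         length(obs), " for constraint ", constraint$constraint_id, call. = FALSE)
  if (any(obs <= 0)) stop("observed values must be positive", call. = FALSE)
  mean(((simulated - obs) / obs)^2) - constraint$epsilon^2
}

#' Constraint violation
#'
#' \eqn{\gamma = \sum_i [\max(0, g_i)]^2}.  Zero iff every residual is
#' non-positive, i.e. the model fits all training data within the allowable
#' errors.
#'
#' @param g_values numeric vector of constraint residuals.
#' @return Non-negative scalar.
#' @export
constraint_violation <- function(g_values) {
  if (length(g_values) == 0) {
    warning("empty constraint vector: gamma is trivially 0", call. = FALSE)
    return(0)
  }
  sum(pmax(0, g_values)^2)
}

#' Encode the search vector
#'
#' Extracts the searched (non-US) parameters in their input order and returns
#' the log10-space box in which the genetic algorithm operates.  Parameter
#' values span orders of magnitude and the penalty acts on log-ratios, so the
#' search is conducted in log10 space.
#'
#' @param specs a \code{\link{param_spec}} table.
#' @return List with \code{names}, \code{lower}, \code{upper} (log10 scale).
#' @export
encode_search_vector <- function(specs) {
  stopifnot(nrow(specs) > 0)
  searched <- specs[specs$class != "US", , drop = FALSE]
  if (nrow(searched) == 0)
    stop("all parameters are unsearched (US): nothing to optimize", call. = FALSE)
  list(names = searched$name,
       lower = log10(searched$lower),
       upper = log10(searched$upper))
}

#' Decode a log10-space genome into named parameter values
#'
#' Inverse of the encoding in \code{\link{encode_search_vector}}; unsearched
#' parameters are filled in at their reference values.
#'
#' @param genome numeric vector in log10 space, ordered as
#'   \code{encode_search_vector(specs)$names}.
#' @param specs a \code{\link{param_spec}} table.
#' @return Named numeric vector over all parameters in \code{specs}.
#' @export
decode_search_vector <- function(genome, specs) {
  enc <- encode_search_vector(specs)
  stopifnot(length(genome) == length(enc$names))
  values <- stats::setNames(specs$reference, specs$name)
  values[enc$names] <- 10^genome
  values
}

#' Bundle an evaluation of one parameter vector
#'
#' @param f_value objective value.
#' @param g_values named vector of constraint residuals.
#' @return List of class \code{"evaluation_result"} with \code{f}, \code{g},
#'   \code{gamma} and \code{mp}.
#' @export
evaluation_result <- function(f_value, g_values) {
  gam <- if (length(g_values)) sum(pmax(0, g_values)^2) else 0
  structure(list(f = f_value, g = g_values, gamma = gam,
                 mp = exp(-f_value)), class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("f = %.6g, gamma = %.6g, MP = %.3g (%s)\n", x$f, x$gamma, x$mp,
              if (x$gamma == 0) "feasible" else "infeasible"))
  invisible(x)
}
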