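FARADAY <- 96485      # C/mol
GAS_CONSTANT <- 8.314 # J/(mol K)

#' Accumulation factor of an active (electrogenic) ammonium transporter
#'
#' If NH4+ (or NH3 + H+) is transported with net positive charge, the
#' membrane potential (inside negative) allows intracellular accumulation up
#' to the ratio
#' \deqn{\varphi = \exp\left(\frac{-F \Delta\psi}{R T}\right).}
#'
#' @param delta_psi transmembrane potential in mV (negative = inside negative).
#' @param temperature absolute temperature in K.
#' @return The equilibrium ratio NH4_int / NH4_ext (dimensionless, > 0).
#' @examples
#' accumulation_factor_active(-150, 310)  # ~275
#' accumulation_factor_active(-150, 303)  # ~313
#' @export
accumulation_factor_active <- function(delta_psi, temperature) {
  if (any(temperature <= 0)) stop("temperature must be positive (K)", call. = FALSE)
  exp(-FARADAY * (delta_psi / 1000) / (GAS_CONSTANT * temperature))
}

#' Accumulation factor of a passive NH3-facilitating transporter
#'
#' If only NH3 crosses the membrane, NH3 equilibrates across it and the
#' NH4+ ratio at equilibrium is set by the pH difference alone:
#' \deqn{\varphi = 10^{pH_{ext} - pH_{int}}.}
#'
#' @param ph_ext,ph_int extracellular and intracellular pH.
#' @return The equilibrium ratio NH4_int / NH4_ext (dimensionless, > 0).
#' @examples
#' accumulation_factor_passive(7.0, 7.6)  # 0.25
#' accumulation_factor_passive(7.4, 7.6)  # 0.63
#' @export
accumulation_factor_passive <- function(ph_ext, ph_int) {
  10^(ph_ext - ph_int)
}

#' Transport physics of a condition
#'
#' @param mode \code{"active"} (electrogenic NH4+ uniport driven by the
#'   membrane potential) or \code{"passive"} (NH3 facilitation driven by the
#'   NH3 gradient).
#' @param delta_psi membrane potential in mV (used in active mode).
#' @param temperature absolute temperature in K.
#' @param ph_ext,ph_int extracellular / intracellular pH.
#' @return List of class \code{"transport_physics"}.
#' @export
transport_physics <- function(mode = c("active", "passive"), delta_psi = -150,
                              temperature = 310, ph_ext = 7.0, ph_int = 7.6) {
  mode <- match.arg(mode)
  structure(list(mode = mode, delta_psi = delta_psi, temperature = temperature,
                 ph_ext = ph_ext, ph_int = ph_int), class = "transport_physics")
}

#' Accumulation factor implied by a physics object
#' @param physics a \code{\link{transport_physics}}.
#' @return Equilibrium NH4 ratio for the given transport mode.
#' @export
accumulation_factor <- function(physics) {
  if (physics$mode == "active")
    accumulation_factor_active(physics$delta_psi, physics$temperature)
  else
    accumulation_factor_passive(physics$ph_ext, physics$ph_int)
}

#' NH4+/NH3 speciation of a total ammonium pool
#'
#' Henderson-Hasselbalch partition of total ammonium into NH4+ and NH3 at a
#' given pH, assuming instantaneous protonation equilibrium
#' (NH3 / NH4+ = 10^(pH - pKa)).
#'
#' @param nhx_total total NH4+ + NH3 concentration (mM), non-negative.
#' @param ph pH of the compartment.
#' @param pka acid dissociation constant of NH4+ (default 9.25).
#' @return List with components \code{nh4} and \code{nh3} (mM), summing to
#'   \code{nhx_total}.
#' @export
speciate <- function(nhx_total, ph, pka = 9.25) {
  if (any(nhx_total < 0)) stop("total ammonium must be non-negative", call. = FALSE)
  ratio <- 10^(ph - pka)          # nh3 / nh4
  nh4 <- nhx_total / (1 + ratio)
  list(nh4 = nh4, nh3 = nhx_total - nh4)
}

#' Parameters of the reduced ammonium transport/assimilation network
#'
#' A deliberately small stand-in for a genome-scale ammonium assimilation
#' network, keeping the features the estimation method is demonstrated on:
#' thermodynamically limited AmtB transport, unfacilitated NH3 membrane
#' diffusion, a single lumped assimilation flux (GS), GlnK-like inhibition
#' of AmtB by internal NH4+, and glutamine-fuelled growth.
#'
#' @param vmax_amtb maximal AmtB transport rate (mM/min).
#' @param km_amtb AmtB half-saturation for its external substrate (mM).
#' @param p_diff membrane NH3 permeation rate coefficient (1/min).
#' @param vmax_gs maximal assimilation (GS) rate (mM/min).
#' @param km_gs GS half-saturation for internal NH4+ (mM).
#' @param k_glnk internal NH4+ at half-maximal GlnK blocking of AmtB (mM).
#' @param n_glnk Hill coefficient of the GlnK inhibition.
#' @param mu_max maximal glutamine consumption into biomass (mM/min).
#' @param k_growth glutamine half-saturation of growth (mM).
#' @param k_dil dilution rate of internal metabolite pools (1/min).
#' @param glnk_present logical; \code{FALSE} models a GlnK-removal mutant in
#'   which AmtB inhibition is absent.
#' @return Named list of class \code{"toy_params"}.
#' @export
toy_params <- function(vmax_amtb = 150, km_amtb = 0.01, p_diff = 50,
                       vmax_gs = 5, km_gs = 0.02, k_glnk = 0.02,
                       n_glnk = 2, mu_max = 4, k_growth = 1,
                       k_dil = 0.05, glnk_present = TRUE) {
  p <- list(vmax_amtb = vmax_amtb, km_amtb = km_amtb, p_diff = p_diff,
            vmax_gs = vmax_gs, km_gs = km_gs, k_glnk = k_glnk,
            n_glnk = n_glnk, mu_max = mu_max, k_growth = k_growth,
            k_dil = k_dil, glnk_present = isTRUE(glnk_present))
  num <- unlist(p[setdiff(names(p), "glnk_present")])
  if (any(!is.finite(num) | num <= 0))
    stop("all kinetic parameters must be positive", call. = FALSE)
  class(p) <- "toy_params"
  p
}

#' Remove GlnK inhibition from a parameter set
#'
#' Models the in-silico removal of all GlnK protein: the Hill blocking term
#' on AmtB is forced to zero, leaving every other parameter untouched.  The
#' input object is not modified.  Idempotent.
#'
#' @param params a \code{\link{toy_params}}.
#' @return A new parameter set with \code{glnk_present = FALSE}.
#' @export
glnk_knockout <- function(params) {
  params$glnk_present <- FALSE
  params
}

#' Experimental condition for the reduced model
#'
#' @param condition_id identifier.
#' @param physics a \code{\link{transport_physics}}.
#' @param nhx_ext total extracellular ammonium (mM).  Either a scalar held
#'   constant, or a two-column matrix / data frame \code{(t, value)}
#'   describing step changes applied at the listed times (a step N-upshift
#'   is \code{rbind(c(0, low), c(t_shift, high))}).
#' @param pka NH4+/NH3 pKa (default 9.25).
#' @param initial_state named vector of initial concentrations (mM) for
#'   \code{nhx} (total internal ammonium), \code{gln}, \code{glu}.
#' @param tau0 minimal doubling time proxy (min); sets the ceiling of the
#'   specific growth-rate observable.
#' @param glnk_present logical; \code{FALSE} simulates this condition as a
#'   GlnK-removal mutant (see \code{\link{glnk_knockout}}).
#' @return List of class \code{"toy_condition"}.
#' @export
toy_condition <- function(condition_id, physics, nhx_ext,
                          pka = 9.25,
                          initial_state = c(nhx = 0.001, gln = 0.1, glu = 1),
                          tau0 = 60, glnk_present = TRUE) {
  if (is.data.frame(nhx_ext)) nhx_ext <- as.matrix(nhx_ext)
  if (is.matrix(nhx_ext)) {
    stopifnot(ncol(nhx_ext) == 2)
    if (any(nhx_ext[, 2] < 0)) stop("nhx_ext must be non-negative", call. = FALSE)
  } else if (any(nhx_ext < 0)) stop("nhx_ext must be non-negative", call. = FALSE)
  needed <- c("nhx", "gln", "glu")
  if (!all(needed %in% names(initial_state)))
    stop("initial_state must name ", paste(needed, collapse = ", "), call. = FALSE)
  if (any(initial_state < 0)) stop("initial concentrations must be >= 0", call. = FALSE)
  if (tau0 <= 0) stop("tau0 must be positive", call. = FALSE)
  structure(list(condition_id = as.character(condition_id), physics = physics,
                 nhx_ext = nhx_ext, pka = pka,
                 initial_state = initial_state[needed], tau0 = tau0,
                 glnk_present = isTRUE(glnk_present)),
            class = "toy_condition")
}

external_nhx_at <- function(condition, t) {
  x <- condition$nhx_ext
  if (!is.matrix(x)) return(x)
  idx <- findInterval(t, x[, 1])
  if (idx < 1) x[1, 2] else x[idx, 2]
}

#' Right-hand side and fluxes of the reduced network
#'
#' States (mM): \code{nhx} (total internal ammonium, speciated into NH4+/NH3
#' algebraically at each call), \code{gln}, \code{glu}.  Fluxes (mM/min):
#' \code{v_amtb} AmtB transport with thermodynamic drive toward the
#' accumulation ratio phi (exactly zero at transporter equilibrium),
#' \code{v_diff} unfacilitated NH3 diffusion (negative = outward back
#' diffusion), \code{v_gs} assimilation, \code{v_growth} glutamine
#' consumption into biomass.
#'
#' @param state named numeric vector (\code{nhx}, \code{gln}, \code{glu}), mM.
#' @param params a \code{\link{toy_params}}.
#' @param condition a \code{\link{toy_condition}}.
#' @param t time (min), used to resolve step inputs; default 0.
#' @return List with \code{derivatives} (named, mM/min) and \code{fluxes}
#'   (named: v_amtb, v_diff, v_net, v_gs, v_growth, growth_rate, theta_glnk).
#' @export
toy_rhs <- function(state, params, condition, t = 0) {
  if (any(state < 0)) stop("state concentrations must be non-negative", call. = FALSE)
  phys <- condition$physics
  ext <- speciate(external_nhx_at(condition, t), phys$ph_ext, condition$pka)
  int <- speciate(state[["nhx"]], phys$ph_int, condition$pka)
  phi <- accumulation_factor(phys)

  theta <- if (params$glnk_present) {
    h <- int$nh4^params$n_glnk
    h / (params$k_glnk^params$n_glnk + h)
  } else 0

  v_amtb <- if (phys$mode == "active") {
    if (ext$nh4 > 0)
      params$vmax_amtb * (1 - theta) * ext$nh4 / (params$km_amtb + ext$nh4) *
        (1 - int$nh4 / (phi * ext$nh4))
    else 0
  } else {
    if (ext$nh3 > 0)
      params$vmax_amtb * (1 - theta) * ext$nh3 / (params$km_amtb + ext$nh3) *
        (1 - int$nh3 / ext$nh3)
    else 0
  }
  v_diff <- params$p_diff * (ext$nh3 - int$nh3)
  v_gs <- params$vmax_gs * int$nh4 / (params$km_gs + int$nh4)
  v_growth <- params$mu_max * state[["gln"]] / (params$k_growth + state[["gln"]])
  growth_rate <- log(2) / condition$tau0 *
    state[["gln"]] / (params$k_growth + state[["gln"]])

  list(derivatives = c(nhx = v_amtb + v_diff - v_gs,
                       gln = v_gs - v_growth - params$k_dil * state[["gln"]],
                       glu = v_growth - params$k_dil * state[["glu"]]),
       fluxes = c(v_amtb = v_amtb, v_diff = v_diff, v_net = v_amtb + v_diff,
                  v_gs = v_gs, v_growth = v_growth, growth_rate = growth_rate,
                  nh4_int = unname(int$nh4), nh3_int = unname(int$nh3),
                  theta_glnk = theta))
}

toy_observables <- function(state, params, condition, t = 0) {
  r <- toy_rhs(state, params, condition, t)
  c(state, r$fluxes)
}

# Parameter vector consumed by the compiled right-hand side; the NH4+
# fractions fold the instantaneous protonation equilibrium into constants.
toy_parms_vector <- function(params, condition, nhx_ext) {
  glnk_on <- params$glnk_present && condition$glnk_present
  c(params$vmax_amtb, params$km_amtb, params$p_diff, params$vmax_gs,
    params$km_gs, params$k_glnk, params$n_glnk, params$mu_max,
    params$k_growth, params$k_dil,
    as.numeric(glnk_on),
    as.numeric(condition$physics$mode == "passive"),
    accumulation_factor(condition$physics),
    nhx_ext,
    1 / (1 + 10^(condition$physics$ph_ext - condition$pka)),
    1 / (1 + 10^(condition$physics$ph_int - condition$pka)))
}

# Integrate with the compiled RHS, splitting at step-input times so the
# external ammonium is piecewise constant within each solver call.
ode_toy <- function(y, times, params, condition, rtol, atol,
                    compiled = TRUE) {
  seg_bounds <- if (is.matrix(condition$nhx_ext)) {
    b <- condition$nhx_ext[, 1]
    sort(unique(b[b > times[1] & b < times[length(times)]]))
  } else numeric(0)
  cuts <- c(times[1], seg_bounds, times[length(times)])
  rows <- NULL
  y0 <- y
  for (k in seq_len(length(cuts) - 1)) {
    seg_t <- sort(unique(c(cuts[k], times[times > cuts[k] & times < cuts[k + 1]],
                           cuts[k + 1])))
    if (compiled) {
      pv <- toy_parms_vector(params, condition,
                             external_nhx_at(condition, cuts[k]))
      out <- deSolve::ode(y = y0, times = seg_t, func = "toy_derivs",
                          parms = pv, dllname = "rubberband",
                          initfunc = "toy_initmod", method = "lsoda",
                          rtol = rtol, atol = atol)
    } else {
      deriv <- function(t, yy, p) {
        list(toy_rhs(pmax(yy, 0), params, condition, t)$derivatives)
      }
      out <- deSolve::ode(y = y0, times = seg_t, func = deriv, parms = NULL,
                          method = "lsoda", rtol = rtol, atol = atol)
    }
    if (attr(out, "istate")[1] < 0)
      stop("integration failed for condition ", condition$condition_id,
           call. = FALSE)
    y0 <- pmax(out[nrow(out), -1], 0)
    rows <- rbind(rows, if (k == 1) out else out[-1, , drop = FALSE])
  }
  rows[rows[, 1] %in% times, , drop = FALSE]
}

#' Simulate the reduced network
#'
#' Integrates the ODE system (lsoda, compiled right-hand side by default)
#' and reports states and fluxes along the trajectory.
#'
#' @param params a \code{\link{toy_params}}.
#' @param condition a \code{\link{toy_condition}}.
#' @param t_end end time (min), or \code{times} for explicit output times.
#' @param times optional vector of output times (min); overrides \code{t_end}.
#' @param rtol,atol solver tolerances.
#' @param compiled use the compiled right-hand side (\code{FALSE} integrates
#'   the plain-R \code{\link{toy_rhs}}; useful for cross-checking).
#' @return Data frame with columns \code{time}, the states and all fluxes.
#' @export
simulate_toy <- function(params, condition, t_end = 20, times = NULL,
                         rtol = 1e-8, atol = 1e-10, compiled = TRUE) {
  if (is.null(times)) {
    stopifnot(t_end > 0)
    times <- seq(0, t_end, length.out = 101)
  }
  if (times[1] > 0) times <- c(0, times)
  p_eff <- if (condition$glnk_present) params else glnk_knockout(params)
  out <- ode_toy(condition$initial_state, times, p_eff, condition,
                 rtol, atol, compiled = compiled)
  out <- as.data.frame(out)
  names(out)[1] <- "time"
  flux <- t(vapply(seq_len(nrow(out)), function(i) {
    toy_rhs(pmax(unlist(out[i, c("nhx", "gln", "glu")]), 0), p_eff,
            condition, out$time[i])$fluxes
  }, numeric(9)))
  cbind(out, flux)
}

#' Steady state of the reduced network
#'
#' Integrates from the condition's initial state until the right-hand side
#' norm drops below tolerance, then reports the state and the flux
#' decomposition at the membrane (v_net = v_amtb + v_diff = v_gs).
#'
#' @param params a \code{\link{toy_params}}.
#' @param condition a \code{\link{toy_condition}}.
#' @param tol convergence tolerance on the max absolute derivative, relative
#'   to max(state, 1e-6) per component (1/min).
#' @param t_max integration horizon (min); exceeding it without convergence
#'   is an explicit failure.
#' @param rtol,atol solver tolerances.
#' @param compiled use the compiled right-hand side.
#' @return List with \code{state}, \code{fluxes}, \code{t_converged}.
#' @export
steady_state_toy <- function(params, condition, tol = 1e-9, t_max = 2e5,
                             rtol = 1e-10, atol = 1e-12, compiled = TRUE) {
  p_eff <- if (condition$glnk_present) params else glnk_knockout(params)
  y <- condition$initial_state
  t0 <- 0
  chunk <- 500
  # step inputs: integrate past the last step time first
  t0_min <- if (is.matrix(condition$nhx_ext)) max(condition$nhx_ext[, 1]) else 0
  repeat {
    t1 <- max(t0 + chunk, t0_min + chunk)
    out <- ode_toy(y, c(t0, t1), p_eff, condition, rtol, atol,
                   compiled = compiled)
    y <- pmax(out[nrow(out), -1], 0)
    d <- toy_rhs(y, p_eff, condition, t1)$derivatives
    if (max(abs(d) / pmax(abs(y), 1e-6)) < tol) {
      fx <- toy_rhs(y, p_eff, condition, t1)$fluxes
      return(list(state = y, fluxes = fx, t_converged = t1))
    }
    t0 <- t1
    chunk <- chunk * 2
    if (t0 > t_max)
      stop("no steady state within t_max = ", t_max, " min for condition ",
           condition$condition_id, call. = FALSE)
  }
}

#' ATP-equivalent cost of ammonium/ammonia futile cycling
#'
#' AmtB-mediated inward transport plus outward NH3 back diffusion dissipate
#' proton motive force.  With \code{h_per_nh3} protons co-transported per
#' NH3 and an H+/ATP coupling ratio \code{h_per_atp}, a back-diffusion flux
#' J (mM/min) costs J * h_per_nh3 / h_per_atp mM/min of ATP equivalents.
#'
#' @param back_diffusion outward NH3 back-diffusion magnitude (mM/min, >= 0).
#' @param h_per_nh3 protons symported per NH3 (default 1).
#' @param h_per_atp H+/ATP coupling ratio of the ATP synthase (default 3).
#' @return ATP-equivalent drain (mM/min).
#' @examples
#' futile_cycle_atp_equivalent(1300)  # > 400 mM/min
#' @export
futile_cycle_atp_equivalent <- function(back_diffusion, h_per_nh3 = 1,
                                        h_per_atp = 3) {
  if (any(back_diffusion < 0))
    stop("pass the outward back-diffusion magnitude (>= 0)", call. = FALSE)
  if (h_per_nh3 < 0 || h_per_atp <= 0)
    stop("stoichiometries must be positive", call. = FALSE)
  back_diffusion * h_per_nh3 / h_per_atp
}
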