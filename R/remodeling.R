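#' Four-parameter cell-activity law
#'
#' Parameters of the piecewise-linear osteoblast/osteoclast activity law.
#' Activities are deviations from the homeostatic baseline: zero at the
#' homeostatic energy \code{W0}, linear in \code{W - W0} with slopes \code{k1}
#' (formation, positive) and \code{k2} (resorption, negative as printed), and
#' capped at \code{A1} above \code{W1} and at \code{A2} above \code{W3}. The
#' defaults satisfy \code{A1 = k1*(W1-W0)} and \code{A2 = k2*(W3-W0)} to the
#' printed precision, which is asserted at construction.
#'
#' @param k1 Osteoblast slope, mg/(mJ mm^3 56 d).
#' @param k2 Osteoclast slope, same units, negative.
#' @param A1 Osteoblast cap, mg/(mm^3 56 d).
#' @param A2 Osteoclast cap, same units, negative.
#' @param W0,W1,W2,W3 Energy thresholds, mJ. \code{W2} (the unstable balance
#'   point where formation and resorption cancel) may be \code{NULL}, in which
#'   case it is derived with [derive_w2()].
#' @param rho_bone_ini Homeostatic baseline density (bookkeeping only; the
#'   baseline-offset form already encodes "no remodeling at W0").
#' @return An object of class \code{activity_params}.
#' @export
activity_params <- function(k1 = 386.64e5, k2 = -375e5,
                            A1 = 1992.36, A2 = -2232.38,
                            W0 = 3.1847e-4, W1 = 3.7e-4,
                            W2 = NULL, W3 = 3.78e-4,
                            rho_bone_ini = 0.56) {
  stopifnot(k1 > 0, k2 < 0, A1 > 0, A2 < 0, W0 > 0, W0 < W1, W1 < W3)
  if (abs(A1 - k1 * (W1 - W0)) / A1 > 1e-3)
    stop("inconsistent parameters: A1 must equal k1*(W1-W0) within 0.1%")
  if (abs(A2 - k2 * (W3 - W0)) / abs(A2) > 1e-3)
    stop("inconsistent parameters: A2 must equal k2*(W3-W0) within 0.1%")
  p <- structure(list(k1 = k1, k2 = k2, A1 = A1, A2 = A2,
                      W0 = W0, W1 = W1, W2 = W2, W3 = W3,
                      rho_bone_ini = rho_bone_ini),
                 class = "activity_params")
  if (is.null(p$W2))
    p$W2 <- tryCatch(derive_w2(p), error = function(e) NA_real_)
  if (!is.na(p$W2) && !(p$W2 > W1 && p$W2 < W3))
    stop("W2 must lie strictly between W1 and W3")
  p
}

#' Osteoblast activity at an energy level
#'
#' Zero at and below the homeostatic energy, rising linearly with slope
#' \code{k1} and saturating at \code{A1} from \code{W1} upward (the cap
#' applies at exactly \code{W1}).
#'
#' @param W Elastic energy, mJ (vectorized, non-negative).
#' @param params An [activity_params()] object.
#' @return Formation activity, mg/(mm^3 56 d).
#' @export
osteoblast_activity <- function(W, params = activity_params()) {
  stopifnot(all(W >= 0))
  pmin(pmax(params$k1 * (W - params$W0), 0), params$A1)
}

#' Osteoclast activity at an energy level
#'
#' Zero at and below the homeostatic energy, falling linearly with slope
#' \code{k2 < 0} and saturating at \code{A2 < 0} from \code{W3} upward.
#'
#' @inheritParams osteoblast_activity
#' @return Resorption activity, mg/(mm^3 56 d), non-positive.
#' @export
osteoclast_activity <- function(W, params = activity_params()) {
  stopifnot(all(W >= 0))
  pmax(pmin(params$k2 * (W - params$W0), 0), params$A2)
}

#' Net cell activity
#'
#' Sum of formation and resorption activities: positive on \code{(W0, W2)},
#' zero at \code{W0} and \code{W2}, negative above \code{W2}, and constant
#' \code{A1 + A2} from \code{W3} upward.
#'
#' @inheritParams osteoblast_activity
#' @return Net activity, mg/(mm^3 56 d).
#' @export
combined_activity <- function(W, params = activity_params()) {
  osteoblast_activity(W, params) + osteoclast_activity(W, params)
}

#' Interface modulation parameters
#'
#' Parameters of the \eqn{(\alpha - \rho)^n} cell-intensity law that
#' concentrates remodeling on the trabecular side of the cortical-trabecular
#' interface: the factor is maximal where density is low (where the marrow
#' cells live) and vanishes as density approaches \eqn{\alpha}. Separate
#' \eqn{\alpha} values are tabulated for each cell type at the formation
#' (\code{W1}) and overload (\code{W3}) energy levels, with a single power
#' \code{n} per level; between the levels both are interpolated in energy.
#'
#' @param alpha_ob_W1,alpha_oc_W1 Osteoblast/osteoclast ceilings at W1.
#' @param alpha_ob_W3,alpha_oc_W3 Ceilings at W3.
#' @param n_W1,n_W3 Powers at the two levels.
#' @param n_interpolation \code{"linear"} or \code{"quadratic"} blending in
#'   energy between W1 and W3.
#' @return An object of class \code{modulation_params}.
#' @export
modulation_params <- function(alpha_ob_W1 = 1.0009, alpha_oc_W1 = 1.0,
                              alpha_ob_W3 = 1.0007, alpha_oc_W3 = 1.0,
                              n_W1 = 13.6, n_W3 = 5,
                              n_interpolation = c("linear", "quadratic")) {
  n_interpolation <- match.arg(n_interpolation)
  alphas <- c(alpha_ob_W1, alpha_oc_W1, alpha_ob_W3, alpha_oc_W3)
  stopifnot(all(alphas >= 1 - 1e-12), n_W1 > 0, n_W3 > 0)
  structure(list(alpha_ob_W1 = alpha_ob_W1, alpha_oc_W1 = alpha_oc_W1,
                 alpha_ob_W3 = alpha_ob_W3, alpha_oc_W3 = alpha_oc_W3,
                 n_W1 = n_W1, n_W3 = n_W3,
                 n_interpolation = n_interpolation),
            class = "modulation_params")
}

#' Cell-intensity modulation factor
#'
#' \eqn{(\alpha - \rho)^n}: strictly decreasing in density, equal to 1 at zero
#' density when \eqn{\alpha = 1}, and 0 at \eqn{\rho = \alpha}. Densities
#' above \eqn{\alpha} clamp to 0 (with a warning) rather than erroring, since
#' they can only arise from the integrator's own ceiling.
#'
#' @param density Dimensionless density (vectorized).
#' @param alpha Ceiling density, near 1.
#' @param n Positive power.
#' @return Dimensionless factor in \code{[0, alpha^n]}.
#' @export
modulation <- function(density, alpha, n) {
  over <- density > alpha
  if (any(over)) {
    warning(sprintf("%d densities above alpha clamped to zero modulation",
                    sum(over)))
    density[over] <- alpha
  }
  (alpha - density)^n
}

#' Energy-interpolated modulation power and ceilings
#'
#' Returns the power \code{n} (and the per-cell-type \eqn{\alpha} ceilings)
#' at an energy level: the W1 values at and below W1, the W3 values at and
#' above W3, and a linear (default) or quadratic blend in energy between.
#'
#' @param W Elastic energy, mJ (vectorized).
#' @param params A [modulation_params()] object.
#' @param activity_params An [activity_params()] object supplying W1 and W3.
#' @return List with vectors \code{n}, \code{alpha_ob}, \code{alpha_oc}.
#' @export
interpolate_n <- function(W, params = modulation_params(),
                          activity_params = osteoremod::activity_params()) {
  stopifnot(all(W > 0))
  W1 <- activity_params$W1; W3 <- activity_params$W3
  t <- pmin(pmax((W - W1) / (W3 - W1), 0), 1)
  if (params$n_interpolation == "quadratic") t <- t^2
  list(
    n = (1 - t) * params$n_W1 + t * params$n_W3,
    alpha_ob = (1 - t) * params$alpha_ob_W1 + t * params$alpha_ob_W3,
    alpha_oc = (1 - t) * params$alpha_oc_W1 + t * params$alpha_oc_W3
  )
}

#' Activation-delay parameters
#'
#' The measured cell response lags the mechanical stimulus. The lag is a
#' first-order filter on the activity fields,
#' \deqn{a \leftarrow a + \lambda (a_{target} - a)\, dt,}
#' with \eqn{\lambda} (1/day) proportional to the published unitless delay
#' coefficients: \code{rate_per_day = 14 * coefficient}. The single
#' proportionality constant is fixed by the retardation the delayed overload
#' run must show (about 1\% mean-density loss over 30 days, versus more than
#' 1.5\% within 7 days undelayed); \code{rate_per_day} can also be given
#' directly.
#'
#' @param mode \code{"none"}, \code{"slow"} (coefficient 1e-5) or \code{"low"}
#'   (coefficient 1e-8).
#' @param coefficient Unitless delay coefficient; defaults by mode.
#' @param rate_per_day Optional explicit filter rate, 1/day.
#' @return An object of class \code{delay_params}.
#' @export
delay_params <- function(mode = c("none", "slow", "low"),
                         coefficient = NULL, rate_per_day = NULL) {
  mode <- match.arg(mode)
  if (is.null(coefficient))
    coefficient <- switch(mode, none = NA_real_, slow = 1e-5, low = 1e-8)
  if (mode != "none" && !(coefficient > 0))
    stop("delay coefficient must be positive for slow/low modes")
  if (is.null(rate_per_day))
    rate_per_day <- if (mode == "none") Inf else 14 * coefficient
  structure(list(mode = mode, coefficient = coefficient,
                 rate_per_day = rate_per_day),
            class = "delay_params")
}

#' First-order lag of a cell activity
#'
#' One explicit step of the activation-delay filter. With mode
#' \code{"none"} the target is passed through unchanged; otherwise the
#' filtered activity approaches the target monotonically with rate
#' \code{rate_per_day}.
#'
#' @param target_activity Instantaneous activity implied by the energy field.
#' @param current_filtered Activity carried from the previous step.
#' @param delay A [delay_params()] object.
#' @param dt Time step, days (positive).
#' @return Updated filtered activity.
#' @export
delayed_activity <- function(target_activity, current_filtered,
                             delay = delay_params(), dt) {
  stopifnot(dt > 0)
  if (delay$mode == "none") return(target_activity)
  step <- min(delay$rate_per_day * dt, 1)
  current_filtered + step * (target_activity - current_filtered)
}

# internal: element energy field for a mechanics solution, in the normalized
# scenario frame. global: the structure energy ratio, uniform over elements;
# local: per-element SED against the initial volume-mean SED.
scenario_energy_field <- function(scenario_energy, sol, ref_total, ref_sed,
                                  mode) {
  if (mode == "global") {
    rep(scenario_energy * sol$total_energy / ref_total, length(sol$sed))
  } else {
    scenario_energy * sol$sed / ref_sed
  }
}

#' One explicit-Euler remodeling step
#'
#' Advances the density field by \code{dt} days: per element, the energy level
#' selects target osteoblast/osteoclast activities (Eq.-style piecewise law),
#' the activation delay filters them, the \eqn{(\alpha-\rho)^n} factors
#' modulate them, and
#' \deqn{d\rho/dt = (m_{ob} a_{ob} + m_{oc} a_{oc}) / (\rho_{ref} \cdot 56\,d)}
#' updates the density, clamped to \code{[floor, alpha_ob]}. The mass ledger
#' accumulates formed and resorbed mass (mg) from the clamped increments.
#'
#' @param state A remodeling state as produced by [run_scenario()] internals:
#'   list with \code{time}, \code{density}, \code{activity_ob},
#'   \code{activity_oc}, \code{W} (per-element energy, mJ), and ledger fields.
#' @param dt Time step, days; must not exceed 0.5.
#' @param mesh A [build_mesh()] mesh.
#' @param act An [activity_params()] object.
#' @param mod A [modulation_params()] object.
#' @param delay A [delay_params()] object.
#' @param material A [material_params()] object (supplies rho_ref).
#' @param density_floor Lower clamp for density.
#' @return The advanced state.
#' @export
step_density <- function(state, dt, mesh, act = activity_params(),
                         mod = modulation_params(), delay = delay_params(),
                         material = material_params(), density_floor = 0.01) {
  if (!(dt > 0 && dt <= 0.5))
    stop("dt must lie in (0, 0.5] days for a stable explicit step")
  W <- state$W
  a_ob_t <- osteoblast_activity(W, act)
  a_oc_t <- osteoclast_activity(W, act)
  a_ob <- delayed_activity(a_ob_t, state$activity_ob, delay, dt)
  a_oc <- delayed_activity(a_oc_t, state$activity_oc, delay, dt)
  blend <- interpolate_n(W, mod, act)
  m_ob <- (pmax(blend$alpha_ob - state$density, 0))^blend$n
  m_oc <- (pmax(blend$alpha_oc - state$density, 0))^blend$n
  rate <- (m_ob * a_ob + m_oc * a_oc) / (material$rho_ref * 56)  # 1/day
  if (any(!is.finite(rate)))
    stop("unstable remodeling step: non-finite rate at t = ", state$time,
         " days (elements ",
         paste(utils::head(which(!is.finite(rate)), 5), collapse = ", "), ")")
  new_density <- pmin(pmax(state$density + rate * dt, density_floor),
                      blend$alpha_ob)
  d_rho <- new_density - state$density
  d_mass <- d_rho * mesh$elem_volume * material$rho_ref
  state$formed_mass <- state$formed_mass + sum(d_mass[d_mass > 0])
  state$resorbed_mass <- state$resorbed_mass + sum(d_mass[d_mass < 0])
  state$net_mass <- state$net_mass + sum(d_mass)
  state$density <- new_density
  state$activity_ob <- a_ob
  state$activity_oc <- a_oc
  state$time <- state$time + dt
  state
}
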