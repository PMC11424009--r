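#' Solve the static fiber-tendon equilibrium
#'
#' Finds the fiber state of a Hill-type muscle-tendon unit at a given
#' muscle-tendon length and activation. In `rigid` mode the tendon is held
#' at its slack length and the fiber length follows from geometry (with a
#' fixed-height pennation model, fiber width `l_opt * sin(alpha_opt)` is
#' constant). In `compliant` mode the normalized tendon force is found by a
#' safeguarded scalar root-find so that the fiber force projected along the
#' tendon equals the tendon force.
#'
#' Velocities are taken as zero (static equilibrium); the returned
#' `v_norm` is 0.
#'
#' @param l_mt Muscle-tendon length, m.
#' @param activation Activation in `[0, 1]`.
#' @param params One-row `muscle_params` table (or equivalent list).
#' @param mode `"rigid"` or `"compliant"`.
#' @param constants Curve constants.
#' @param tol Relative equilibrium tolerance (default `1e-9`).
#' @return A tibble with `lm_norm`, `v_norm`, `fiber_force` (N),
#'   `tendon_force` (N), `cos_pennation`, `residual`.
#' @export
solve_fiber_equilibrium <- function(l_mt, activation, params,
                                    mode = c("compliant", "rigid"),
                                    constants = default_curve_constants(),
                                    tol = 1e-9) {
  mode <- match.arg(mode)
  stopifnot(length(l_mt) == 1, is.finite(l_mt))
  if (activation < 0 || activation > 1) {
    stop("activation must lie in [0, 1]", call. = FALSE)
  }
  if (l_mt <= 0.5 * params$l_slack) {
    stop("l_mt is implausibly short (<= half the tendon slack length)", call. = FALSE)
  }
  h <- params$l_opt * sin(params$alpha_opt)

  fiber_from_lt <- function(l_t) {
    u <- l_mt - l_t
    l_m <- sqrt(u^2 + h^2)
    list(l_m = l_m, lm_norm = l_m / params$l_opt, cosa = u / l_m)
  }

  if (mode == "rigid") {
    st <- fiber_from_lt(params$l_slack)
    f_l <- eval_active_force_length(st$lm_norm, constants)
    f_pas <- eval_passive_force(st$lm_norm, params)
    fiber_force <- params$fmax * (activation * f_l + f_pas)
    return(tibble::tibble(
      lm_norm = st$lm_norm, v_norm = 0,
      fiber_force = fiber_force,
      tendon_force = fiber_force * st$cosa,
      cos_pennation = st$cosa, residual = 0
    ))
  }

  # compliant: root of  f_m(lt) * cos(alpha) - f_t(lt)  in normalized force
  balance <- function(ft_norm) {
    lt_norm <- tendon_length_from_force(ft_norm, params$k_t, constants)
    st <- fiber_from_lt(lt_norm * params$l_slack)
    f_l <- eval_active_force_length(st$lm_norm, constants)
    f_pas <- eval_passive_force(st$lm_norm, params)
    (activation * f_l + f_pas) * st$cosa - ft_norm
  }
  lo <- 0
  hi <- max(2, activation * 2 + 1)
  flo <- balance(lo)
  fhi <- balance(hi)
  tries <- 0
  while (flo * fhi > 0 && tries < 30) {
    hi <- hi * 2
    fhi <- balance(hi)
    tries <- tries + 1
  }
  if (flo * fhi > 0) {
    stop(sprintf(
      "no fiber-tendon equilibrium bracketed for l_mt = %.4f m, a = %.3f (f(0) = %.3g)",
      l_mt, activation, flo
    ), call. = FALSE)
  }
  root <- stats::uniroot(balance, c(lo, hi), tol = tol * max(1, abs(hi)))
  ft_norm <- root$root
  lt_norm <- tendon_length_from_force(ft_norm, params$k_t, constants)
  st <- fiber_from_lt(lt_norm * params$l_slack)
  f_l <- eval_active_force_length(st$lm_norm, constants)
  f_pas <- eval_passive_force(st$lm_norm, params)
  fiber_force <- params$fmax * (activation * f_l + f_pas)
  tibble::tibble(
    lm_norm = st$lm_norm, v_norm = 0,
    fiber_force = fiber_force,
    tendon_force = params$fmax * ft_norm,
    cos_pennation = st$cosa,
    residual = fiber_force * st$cosa - params$fmax * ft_norm
  )
}

#' First-order activation dynamics
#'
#' Rate of change of activation toward excitation, with a faster time
#' constant during activation than deactivation and a smooth blend between
#' the two branches.
#'
#' @param excitation,activation Values in `[0, 1]`; vectorized.
#' @param tau_act Activation time constant, s (default 0.015).
#' @param tau_deact Deactivation time constant, s (default 0.060).
#' @param blend Smoothing width of the branch switch (default 0.01).
#' @return `da/dt` in 1/s.
#' @export
activation_dynamics_rate <- function(excitation, activation,
                                     tau_act = 0.015, tau_deact = 0.060,
                                     blend = 0.01) {
  if (tau_act <= 0 || tau_deact <= 0) {
    stop("time constants must be positive", call. = FALSE)
  }
  if (any(excitation < 0 | excitation > 1) || any(activation < 0 | activation > 1)) {
    stop("excitation and activation must lie in [0, 1]", call. = FALSE)
  }
  d <- excitation - activation
  w <- 0.5 * (1 + tanh(d / blend))
  d * (w / tau_act + (1 - w) / tau_deact)
}

# inverse of the (unblended) first-order law: the excitation that produces a
# given activation trajectory slope. Used by the redundancy solver, where
# activation and its derivative are algebraic functions of the tendon-force
# states.
excitation_from_activation <- function(activation, adot,
                                       tau_act = 0.015, tau_deact = 0.060) {
  tau <- ifelse(adot >= 0, tau_act, tau_deact)
  activation + tau * adot
}
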