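#' Passive force-length multiplier
#'
#' Exponential passive force-length curve of the contractile element,
#' `(exp(k_pe * (lm_norm - s0) / s_m) - 1) / (exp(k_pe) - 1)`.
#' `s0` is the normalized fiber length where passive force starts to rise
#' and `s_m` the additional normalized strain at which the passive force
#' reaches the maximum isometric force. Below `s0` the curve is clamped at
#' zero (the raw expression is slightly negative there, which would mean a
#' compressive passive fiber force).
#'
#' @param lm_norm Normalized fiber length (> 0); vectorized.
#' @param params A one-row `muscle_params` table, or any list with
#'   `k_pe`, `s0`, `s_m`.
#' @param clamp Clamp negative values to zero (default `TRUE`).
#' @return Passive force multiplier (unitless, fraction of `fmax`).
#' @export
eval_passive_force <- function(lm_norm, params, clamp = TRUE) {
  if (any(!is.finite(lm_norm))) stop("lm_norm must be finite", call. = FALSE)
  if (any(lm_norm <= 0)) stop("lm_norm must be > 0", call. = FALSE)
  f <- passive_force_raw(lm_norm, params$k_pe, params$s0, params$s_m)
  if (clamp) f <- pmax(f, 0)
  f
}

passive_force_raw <- function(lm_norm, k_pe, s0, s_m) {
  expm1(k_pe * (lm_norm - s0) / s_m) / expm1(k_pe)
}

# d f_pas / d lm_norm (0 below the onset length when clamped)
passive_force_deriv <- function(lm_norm, k_pe, s0, s_m, clamp = TRUE) {
  d <- (k_pe / s_m) * exp(k_pe * (lm_norm - s0) / s_m) / expm1(k_pe)
  if (clamp) d[lm_norm < s0] <- 0
  d
}

#' Active force-length multiplier
#'
#' Sum-of-Gaussians active force-length curve, maximal near the optimal
#' fiber length.
#'
#' @param lm_norm Normalized fiber length; vectorized.
#' @param constants Curve constants from [default_curve_constants()].
#' @return Active force-length multiplier in `[0, ~1]`.
#' @export
eval_active_force_length <- function(lm_norm, constants = default_curve_constants()) {
  b <- constants$active_fl
  f <- 0 * lm_norm
  for (i in seq_len(nrow(b))) {
    den <- b[[i, "b3"]] + b[[i, "b4"]] * lm_norm
    f <- f + b[[i, "b1"]] * exp(-0.5 * (lm_norm - b[[i, "b2"]])^2 / den^2)
  }
  if (is.null(dim(f))) names(f) <- NULL
  f
}

active_force_length_deriv <- function(lm_norm, constants = default_curve_constants()) {
  b <- constants$active_fl
  d <- 0 * lm_norm
  for (i in seq_len(nrow(b))) {
    den <- b[[i, "b3"]] + b[[i, "b4"]] * lm_norm
    z <- (lm_norm - b[[i, "b2"]]) / den
    g <- b[[i, "b1"]] * exp(-0.5 * z^2)
    # d/dl of z = (den - (l - b2) b4)/den^2
    dz <- (den - (lm_norm - b[[i, "b2"]]) * b[[i, "b4"]]) / den^2
    d <- d - g * z * dz
  }
  if (is.null(dim(d))) names(d) <- NULL
  d
}

#' Force-velocity multiplier
#'
#' Inverse-hyperbolic-sine force-velocity curve. The argument is the fiber
#' velocity normalized by the maximum shortening velocity, so `v_norm = -1`
#' is maximal shortening (multiplier ~ 0), `v_norm = 0` is isometric
#' (multiplier exactly 1) and positive values are lengthening (eccentric
#' plateau ~ 1.8).
#'
#' @param v_norm Normalized fiber velocity (units of `vmax`); vectorized.
#' @param constants Curve constants from [default_curve_constants()].
#' @return Force-velocity multiplier (>= 0).
#' @export
eval_force_velocity <- function(v_norm, constants = default_curve_constants()) {
  d <- constants$fv
  pmax(d[["d1"]] * asinh(d[["d2"]] * v_norm + d[["d3"]]) + d[["d4"]], 0)
}

force_velocity_deriv <- function(v_norm, constants = default_curve_constants()) {
  d <- constants$fv
  u <- d[["d2"]] * v_norm + d[["d3"]]
  raw <- d[["d1"]] * asinh(u) + d[["d4"]]
  out <- d[["d1"]] * d[["d2"]] / sqrt(u^2 + 1) + 0 * u
  out[raw < 0] <- 0
  out
}

#' Tendon force-length multiplier
#'
#' Exponential tendon curve `c1 * exp(k_t * (lt_norm - c2)) - c3`, with
#' `c2 = 1 - log(c3 / c1) / k_t` so that the force is exactly zero at unit
#' normalized tendon length (slack) for any stiffness factor `k_t`.
#' Larger `k_t` means a stiffer tendon: more force at the same strain.
#'
#' @param lt_norm Normalized tendon length (> 0); vectorized.
#' @param k_t Tendon shape (stiffness) factor.
#' @param constants Curve constants from [default_curve_constants()].
#' @param clamp Clamp negative (slack) values to zero (default `TRUE`).
#' @return Tendon force multiplier (fraction of `fmax`).
#' @export
eval_tendon_force <- function(lt_norm, k_t = NULL, constants = default_curve_constants(),
                              clamp = TRUE) {
  if (any(!is.finite(lt_norm))) stop("lt_norm must be finite", call. = FALSE)
  if (any(lt_norm <= 0)) stop("lt_norm must be > 0", call. = FALSE)
  c1 <- constants$tendon[["c1"]]
  c3 <- constants$tendon[["c3"]]
  if (is.null(k_t)) k_t <- constants$tendon[["k_t"]]
  c2 <- 1 - log(c3 / c1) / k_t
  f <- c1 * exp(k_t * (lt_norm - c2)) - c3
  if (clamp) f <- pmax(f, 0)
  f
}

# inverse of the (unclamped) tendon curve: normalized length at a given
# normalized force (force > -c3; in practice force >= 0)
tendon_length_from_force <- function(ft_norm, k_t, constants = default_curve_constants()) {
  c1 <- constants$tendon[["c1"]]
  c3 <- constants$tendon[["c3"]]
  c2 <- 1 - log(c3 / c1) / k_t
  c2 + log((ft_norm + c3) / c1) / k_t
}

# d lt_norm / d ft_norm along the inverse tendon curve
tendon_inverse_deriv <- function(ft_norm, k_t, constants = default_curve_constants()) {
  c3 <- constants$tendon[["c3"]]
  1 / (k_t * (ft_norm + c3))
}

#' Evaluate all contraction curves at once
#'
#' @param lm_norm Normalized fiber length.
#' @param v_norm Normalized fiber velocity (units of `vmax`).
#' @param constants Curve constants from [default_curve_constants()].
#' @param lt_norm Normalized tendon length (default 1).
#' @param k_t Tendon shape factor (default generic).
#' @return A tibble with columns `f_l`, `f_v`, `f_t`.
#' @export
eval_contraction_curves <- function(lm_norm, v_norm,
                                    constants = default_curve_constants(),
                                    lt_norm = 1, k_t = NULL) {
  tibble::tibble(
    f_l = eval_active_force_length(lm_norm, constants),
    f_v = eval_force_velocity(v_norm, constants),
    f_t = eval_tendon_force(lt_norm, k_t, constants)
  )
}
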