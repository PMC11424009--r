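#' Construct a muscle-tendon parameter table
#'
#' One row per muscle-tendon unit of a Hill-type model: architecture
#' (maximum isometric force, optimal fiber length, tendon slack length,
#' pennation at optimal fiber length, maximum shortening velocity),
#' energetic properties (slow-twitch fraction, muscle mass), the passive
#' force-length parameters of the exponential passive curve
#' (`k_pe`, `s0`, `s_m`), and the tendon stiffness shape factor `k_t`.
#'
#' @param name Muscle names (character).
#' @param fmax Maximum isometric force, N (> 0).
#' @param l_opt Optimal fiber length, m (> 0).
#' @param l_slack Tendon slack length, m (>= 0).
#' @param alpha_opt Pennation angle at optimal fiber length, rad.
#' @param vmax Maximum shortening velocity, optimal fiber lengths per second.
#' @param slow_twitch_fraction Fraction of slow-twitch fibers, in `[0, 1]`.
#' @param muscle_mass Muscle mass, kg (> 0; required by all metabolic models
#'   except LW07).
#' @param k_pe Passive exponential shape factor (> 0).
#' @param s0 Normalized fiber length at passive force onset (> 0).
#' @param s_m Normalized strain span from onset to maximum passive force (> 0).
#' @param k_t Tendon curve shape (stiffness) factor.
#' @param joints_spanned List of character vectors, the joints each muscle
#'   spans (used to attribute biarticular energy between joints).
#'
#' @return A tibble of class `muscle_params`, one row per muscle.
#' @export
muscle_tendon_params <- function(name,
                                 fmax,
                                 l_opt,
                                 l_slack,
                                 alpha_opt = 0,
                                 vmax = 10,
                                 slow_twitch_fraction = 0.5,
                                 muscle_mass = NA_real_,
                                 k_pe = 4,
                                 s0 = 1,
                                 s_m = 0.6,
                                 k_t = 35,
                                 joints_spanned = NULL) {
  params <- tibble::tibble(
    name = as.character(name),
    fmax = as.numeric(fmax),
    l_opt = as.numeric(l_opt),
    l_slack = as.numeric(l_slack),
    alpha_opt = as.numeric(alpha_opt),
    vmax = as.numeric(vmax),
    slow_twitch_fraction = as.numeric(slow_twitch_fraction),
    muscle_mass = as.numeric(muscle_mass),
    k_pe = as.numeric(k_pe),
    s0 = as.numeric(s0),
    s_m = as.numeric(s_m),
    k_t = as.numeric(k_t)
  )
  if (is.null(joints_spanned)) {
    joints_spanned <- vector("list", nrow(params))
  }
  params$joints_spanned <- joints_spanned
  validate_muscle_params(params)
  class(params) <- c("muscle_params", class(params))
  params
}

validate_muscle_params <- function(params) {
  stopifnot(is.data.frame(params))
  required <- c(
    "name", "fmax", "l_opt", "l_slack", "alpha_opt", "vmax",
    "slow_twitch_fraction", "k_pe", "s0", "s_m", "k_t"
  )
  missing <- setdiff(required, names(params))
  if (length(missing) > 0) {
    stop("muscle parameter table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  with(params, {
    if (any(!is.finite(fmax)) || any(fmax <= 0)) stop("fmax must be > 0", call. = FALSE)
    if (any(l_opt <= 0)) stop("l_opt must be > 0", call. = FALSE)
    if (any(l_slack < 0)) stop("l_slack must be >= 0", call. = FALSE)
    if (any(slow_twitch_fraction < 0 | slow_twitch_fraction > 1)) {
      stop("slow_twitch_fraction must lie in [0, 1]", call. = FALSE)
    }
    if (any(k_pe <= 0) || any(s0 <= 0) || any(s_m <= 0)) {
      stop("k_pe, s0 and s_m must be > 0", call. = FALSE)
    }
    if (any(vmax <= 0)) stop("vmax must be > 0", call. = FALSE)
  })
  invisible(params)
}

#' Generic force curve constants
#'
#' Coefficients of the normalized Hill-type force curves: a sum of three
#' Gaussians for the active force-length curve, an inverse-hyperbolic-sine
#' force-velocity curve, and an exponential tendon force-length curve.
#' The force-velocity offset/scale coefficients (`d1`, `d4`) are solved so
#' that the curve is exactly 1 at zero velocity and essentially 0 at the
#' maximum shortening velocity; the tendon curve reference strain `c2` is
#' derived from the shape factor so that tendon force is exactly zero at
#' unit normalized tendon length for any stiffness.
#'
#' @param fv_at_vmax Residual force multiplier at maximum shortening
#'   velocity (default `1e-4`).
#' @return A list with elements `active_fl` (matrix of Gaussian
#'   coefficients), `fv` (named vector `d1..d4`), and `tendon`
#'   (`c1`, `c3`, generic `k_t`).
#' @export
default_curve_constants <- function(fv_at_vmax = 1e-4) {
  # Gaussian centers carry a common shift (-0.015074) so the summed curve
  # attains its maximum exactly at unit normalized fiber length
  fl_shift <- 0.015074397621
  active_fl <- rbind(
    c(b1 = 0.814483478343008, b2 = 1.055033428970575 - fl_shift,
      b3 = 0.162384573599574, b4 = 0.063303448465465),
    c(b1 = 0.433004984392647, b2 = 0.716775413397760 - fl_shift,
      b3 = -0.029947116970696, b4 = 0.200356847296188),
    c(b1 = 0.100, b2 = 1.000 - fl_shift, b3 = 0.5 * sqrt(0.5), b4 = 0.000)
  )
  d2 <- -8.149
  d3 <- -0.374
  d1 <- (fv_at_vmax - 1) / (asinh(-d2 + d3) - asinh(d3))
  d4 <- 1 - d1 * asinh(d3)
  list(
    active_fl = active_fl,
    fv = c(d1 = d1, d2 = d2, d3 = d3, d4 = d4),
    tendon = c(c1 = 0.200, c3 = 0.250, k_t = 35)
  )
}
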