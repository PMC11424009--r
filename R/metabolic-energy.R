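#' Negative-rate modification of the shortening/lengthening heat
#'
#' When the unmodified total metabolic rate `w_ce + h_am + h_sl` would be
#' negative (eccentric work exceeding the heat rates), the
#' shortening/lengthening heat is replaced by `-w_ce - h_am`, i.e. the
#' negative balance is assumed to be dissipated as heat, which pins the
#' total rate at exactly zero. Rates that are already non-negative are
#' returned untouched.
#'
#' @param w_ce Contractile element work rate, W (positive when shortening).
#' @param h_am Combined activation + maintenance heat rate, W.
#' @param h_sl Shortening/lengthening heat rate, W.
#' @return Modified `h_sl`, W; vectorized over all arguments.
#' @export
apply_negative_rate_modification <- function(w_ce, h_am, h_sl) {
  total <- w_ce + h_am + h_sl
  ifelse(total < 0, -w_ce - h_am, h_sl)
}

#' Muscle efficiency
#'
#' Ratio of contractile element work rate to total metabolic rate. Guarded
#' to 0 when the metabolic rate is at or below `floor` (the ratio is not
#' meaningful for a vanishing denominator).
#'
#' @param w_ce Contractile element work rate, W.
#' @param e_dot Total metabolic rate, W.
#' @param floor Denominator guard (default `1e-9` W).
#' @return Efficiency (unitless); vectorized.
#' @export
energy_efficiency <- function(w_ce, e_dot, floor = 1e-9) {
  ifelse(e_dot <= floor, 0, w_ce / e_dot)
}

# effective fast-twitch fraction under orderly recruitment (UC16): slow
# fibers are recruited first, so at submaximal excitation the active pool
# contains proportionally fewer fast fibers.
recruited_fast_fraction <- function(fast_fraction, excitation) {
  u_s <- sin(pi / 2 * excitation)
  u_f <- 1 - cos(pi / 2 * excitation)
  den <- (1 - fast_fraction) * u_s + fast_fraction * u_f
  out <- ifelse(den > 0, fast_fraction * u_f / den, 0)
  out
}

# Core per-muscle metabolic rate computation on aligned vectors.
# v_lopt: fiber velocity in optimal fiber lengths / s, negative = shortening.
# Returns a tibble with w_ce, h_a, h_m, h_sl (post-modification), e_dot, modified.
metabolic_rate_core <- function(model, excitation, activation, lm_norm, v_lopt,
                                params, constants = NULL,
                                curve_constants = default_curve_constants()) {
  cc <- constants %||% metabolic_model_constants(model)
  stopifnot(cc$model == model)
  n <- length(activation)
  excitation <- pmin(pmax(excitation, 0), 1)
  activation <- pmin(pmax(activation, 0), 1)

  f_l <- eval_active_force_length(lm_norm, curve_constants)
  v_norm <- v_lopt / params$vmax
  f_v <- eval_force_velocity(v_norm, curve_constants)
  v_mps <- v_lopt * params$l_opt
  f_ce <- activation * params$fmax * f_l * f_v     # contractile element force, N
  f_iso <- activation * params$fmax * f_l          # isometric force at (a, l)
  w_ce <- -f_ce * v_mps                            # > 0 when shortening

  mass <- params$muscle_mass
  if (cc$mass_dependent && (is.null(mass) || !is.finite(mass) || mass <= 0)) {
    stop(sprintf("muscle_mass is required by the %s model", model), call. = FALSE)
  }
  fast <- 1 - params$slow_twitch_fraction
  shortening <- v_lopt < 0

  if (model %in% c("UM03", "UM10", "UC16")) {
    S <- cc$aerobic_scale
    A <- ifelse(excitation > activation, excitation,
                (excitation + activation) / 2)
    ft_frac <- if (model == "UC16") recruited_fast_fraction(fast, excitation) else fast
    pct_ft <- 100 * ft_frac
    h_am0 <- cc$am_intercept + cc$am_ft_slope * pct_ft      # W/kg
    # fiber-length scaling above optimal length: 40% activation portion
    # unscaled, 60% maintenance portion scaled by f_l
    lscale <- ifelse(lm_norm > 1, 0.4 + 0.6 * f_l, 1)
    h_am <- h_am0 * A^cc$am_exponent * S * lscale
    vmax_slow <- params$vmax / cc$vmax_slow_ratio
    a_st <- cc$alpha_short_slow_num / vmax_slow
    a_ft <- cc$alpha_short_fast_num / params$vmax
    a_len <- cc$alpha_lengthen_factor * a_st
    h_sl <- ifelse(
      shortening,
      -(a_st * (1 - ft_frac) + a_ft * ft_frac) * v_lopt * A^cc$s_exponent * S,
      a_len * v_lopt * A * S
    )
    h_sl <- h_sl * ifelse(lm_norm > 1, f_l, 1)
    # total heat floor (W/kg)
    heat <- h_am + h_sl
    h_sl <- h_sl + pmax(cc$heat_floor - heat, 0)
    h_a <- h_am * mass    # combined activation+maintenance reported as h_a
    h_m <- rep(0, n)
    h_sl <- h_sl * mass
    # UM10 counts only concentric work; UM03 and UC16 keep the signed work
    # (UC16's non-negativity clamp is what removes eccentric "energy gain")
    w <- if (model == "UM10") pmax(w_ce, 0) else w_ce
  } else if (model == "BH04") {
    u_s <- sin(pi / 2 * activation)
    u_f <- 1 - cos(pi / 2 * activation)
    h_a <- mass * cc$decay * ((1 - fast) * cc$act_slow * u_s + fast * cc$act_fast * u_f)
    lfac <- bh04_length_factor(lm_norm)
    h_m <- mass * lfac * ((1 - fast) * cc$maint_slow * u_s + fast * cc$maint_fast * u_f)
    alpha <- ifelse(shortening,
                    cc$alpha_short_iso * f_iso + cc$alpha_short_force * f_ce,
                    cc$alpha_lengthen_force * f_ce)
    h_sl <- -alpha * v_mps
    w <- w_ce
  } else if (model == "HO06") {
    sr <- cc$specific_tension / cc$density            # J/kg
    h_a <- rep(0, n)
    h_m <- mass * cc$maint_coef * sr * params$vmax * activation * f_l
    h_sl <- ifelse(shortening,
                   -mass * cc$alpha_short * sr * activation * f_l * v_lopt,
                   cc$eccentric_heat)
    w <- w_ce
  } else if (model == "LW07") {
    G <- cc$curvature
    vmax_mps <- params$vmax * params$l_opt
    h_a <- rep(0, n)
    h_m <- activation * f_l * params$fmax * vmax_mps / G^2
    h_sl <- ifelse(shortening,
                   -activation * f_l * params$fmax * v_mps / G,
                   cc$eccentric_heat_fraction * pmax(-w_ce, 0))
    w <- w_ce
  } else {
    stop("unknown metabolic model: ", model, call. = FALSE)
  }

  h_am_total <- h_a + h_m
  modified <- rep(FALSE, n)
  if (cc$sl_modification) {
    total <- w + h_am_total + h_sl
    modified <- total < 0
    h_sl <- apply_negative_rate_modification(w, h_am_total, h_sl)
  }
  e_dot <- w + h_am_total + h_sl
  if (cc$clamp_nonnegative) {
    neg <- e_dot < 0
    h_sl <- ifelse(neg, -w - h_am_total, h_sl)
    modified <- modified | neg
    e_dot <- w + h_am_total + h_sl
  }
  tibble::tibble(
    w_ce = w, h_a = h_a, h_m = h_m, h_sl = h_sl,
    e_dot = e_dot, modified = modified
  )
}

bh04_length_factor <- function(lm_norm) {
  ifelse(lm_norm < 0.5, 0.5,
         ifelse(lm_norm <= 1, lm_norm,
                ifelse(lm_norm <= 1.5, -2 * lm_norm + 3, 0)))
}

#' Compute per-muscle metabolic rate trajectories
#'
#' Evaluates one metabolic energy model on the muscle-tendon states of a
#' redundancy solution, returning the contractile work rate and heat rate
#' components per muscle and time point. The contractile element work rate
#' is `-F_CE * v_M` (positive when the fiber shortens). For `BH04`, `HO06`
#' and `UM03` the shortening/lengthening heat is modified wherever the
#' unmodified total rate is negative; `UC16` clamps the total rate at zero;
#' `LW07` and `UM10` are left as formulated.
#'
#' @param model One of [metabolic_model_ids()].
#' @param solution A `gaitmet_solution` from [solve_redundancy()], or a tidy
#'   tibble with columns `time`, `muscle`, `excitation`, `activation`,
#'   `lm_norm`, `v_lopt` (fiber velocity, optimal fiber lengths/s,
#'   negative = shortening).
#' @param muscles `muscle_params` table covering all muscles in `solution`.
#' @param constants Optional constants override from
#'   [metabolic_model_constants()].
#' @return A tibble of class `metabolic_trajectory` with columns `time`,
#'   `muscle`, `model`, `w_ce`, `h_a`, `h_m`, `h_sl`, `e_dot` (all W) and
#'   `modified`. For the UM-family models the combined
#'   activation+maintenance heat is reported in `h_a` (and `h_m` is 0).
#' @export
compute_metabolic_rates <- function(model, solution, muscles, constants = NULL) {
  model <- match.arg(model, metabolic_model_ids())
  states <- if (inherits(solution, "gaitmet_solution")) solution$states else solution
  needed <- c("time", "muscle", "excitation", "activation", "lm_norm", "v_lopt")
  missing <- setdiff(needed, names(states))
  if (length(missing) > 0) {
    stop("solution states lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(states$muscle), muscles$name)
  if (length(unknown) > 0) {
    stop("no parameters for muscles: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- states |>
    dplyr::group_by(.data$muscle) |>
    dplyr::group_modify(function(df, key) {
      p <- muscles[muscles$name == key$muscle, ]
      rates <- metabolic_rate_core(model, df$excitation, df$activation,
                                   df$lm_norm, df$v_lopt, p, constants)
      dplyr::bind_cols(dplyr::select(df, "time"), rates)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(model = model, .after = "muscle") |>
    dplyr::relocate("time")
  class(out) <- c("metabolic_trajectory", class(out))
  out
}

#' Characterize a metabolic model over state grids
#'
#' Tabulates the total metabolic rate and efficiency of one muscle over
#' grids of activation, normalized fiber length and normalized fiber
#' velocity (excitation taken equal to activation). Used for model
#' comparison plots and ordering checks.
#'
#' @param model One of [metabolic_model_ids()].
#' @param params One-row `muscle_params` table.
#' @param activation Activation grid.
#' @param lm_norm Normalized fiber length grid.
#' @param v_norm Normalized fiber velocity grid (units of `vmax`,
#'   negative = shortening).
#' @param constants Optional constants override.
#' @return A tibble with the grid columns plus `w_ce`, `h_a`, `h_m`,
#'   `h_sl`, `e_dot`, `efficiency`.
#' @export
characterize_model_surfaces <- function(model, params,
                                        activation = c(0.25, 0.5, 0.75, 1),
                                        lm_norm = 1,
                                        v_norm = seq(-1, 1, by = 0.1),
                                        constants = NULL) {
  model <- match.arg(model, metabolic_model_ids())
  grid <- tidyr::expand_grid(activation = activation, lm_norm = lm_norm,
                             v_norm = v_norm)
  rates <- metabolic_rate_core(
    model, grid$activation, grid$activation, grid$lm_norm,
    grid$v_norm * params$vmax, params, constants
  )
  dplyr::bind_cols(grid, rates) |>
    dplyr::mutate(model = model,
                  efficiency = energy_efficiency(.data$w_ce, .data$e_dot))
}
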