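#' Metabolic energy model identifiers
#'
#' Six Hill-model-based metabolic energy models are implemented. All share
#' the same decomposition of the muscle metabolic rate into contractile
#' element work rate plus activation, maintenance and shortening/lengthening
#' heat rates, and differ in how the heat rates are parameterized and how
#' eccentric (negative) work is treated:
#'
#' * `UM03` - combined activation+maintenance heat scaled by fiber-type
#'   composition and activation^0.6, velocity-proportional shortening and
#'   lengthening heats, full (signed) contractile work.
#' * `BH04` - separate activation and maintenance heats with sinusoidal
#'   recruitment weighting of slow/fast fiber pools, force-scaled
#'   shortening/lengthening heat, full work.
#' * `HO06` - Hill-heat formulation: no separate activation heat, a small
#'   force-scaled maintenance heat, force-scaled shortening heat, zero
#'   eccentric heat, full work.
#' * `LW07` - mass-independent Hill-heat model whose every term is linear in
#'   activation; during lengthening half of the (negative) contractile work
#'   is dissipated as heat, so the total rate may remain negative.
#' * `UM10` - as UM03 but only concentric (positive) contractile work counts.
#' * `UC16` - as UM10 with orderly-recruitment weighting of the fiber-type
#'   composition and an explicit non-negativity clamp on the total rate.
#'
#' Negative total rates of `UM03`, `BH04` and `HO06` are additionally
#' removed by the shortening/lengthening-heat modification (see
#' [apply_negative_rate_modification()]).
#'
#' @return Character vector of the six model ids.
#' @export
metabolic_model_ids <- function() c("UM03", "BH04", "HO06", "LW07", "UM10", "UC16")

#' Metabolic model constants
#'
#' Returns the coefficient block of one metabolic energy model. All heat
#' coefficients that multiply muscle mass are in W/kg (per unit of their
#' scaling variable); force-scaled coefficients are dimensionless ratios.
#'
#' @param model One of [metabolic_model_ids()].
#' @param aerobic Logical; use the aerobic scaling factor (1.5) of the
#'   UM-family models, appropriate for walking (default `TRUE`).
#' @return A named list of constants, including `mass_dependent` and the
#'   combined activation-maintenance flag `combined_am`.
#' @export
metabolic_model_constants <- function(model = metabolic_model_ids(),
                                      aerobic = TRUE) {
  model <- match.arg(model)
  # shared physical conventions
  base <- list(
    model = model,
    density = 1059.7,         # muscle density, kg/m^3
    specific_tension = 6e5,   # Pa, used by the HO06 reconstruction
    mass_dependent = model != "LW07",
    combined_am = model %in% c("UM03", "UM10", "UC16"),
    heat_floor = 0,
    clamp_nonnegative = model == "UC16",
    sl_modification = model %in% c("UM03", "BH04", "HO06")
  )
  um <- list(
    # activation+maintenance heat: 1.28 * %FT + 25  [W/kg], x A^0.6 x S
    am_intercept = 25, am_ft_slope = 1.28,
    am_exponent = 0.6, s_exponent = 2.0,
    # shortening coefficients per (l_opt/s): 4*25 / vmax_slow and 153 / vmax_fast
    alpha_short_slow_num = 100, alpha_short_fast_num = 153,
    vmax_slow_ratio = 2.5,        # vmax_slow = vmax / 2.5
    alpha_lengthen_factor = 4,    # alpha_L = 4 * alpha_short_slow
    aerobic_scale = if (aerobic) 1.5 else 1.0,
    heat_floor = 1.0              # minimum total heat rate, W/kg muscle
  )
  consts <- switch(model,
    UM03 = um,
    UM10 = um,
    UC16 = um,
    BH04 = list(
      # activation and maintenance heats, W/kg, recruitment-weighted
      act_slow = 40, act_fast = 133,
      maint_slow = 74, maint_fast = 111,
      decay = 1,                     # activation-heat decay function (constant)
      alpha_short_iso = 0.16,        # x isometric force at current (a, l)
      alpha_short_force = 0.18,      # x contractile element force
      alpha_lengthen_force = 0.157   # x contractile element force, lengthening
    ),
    HO06 = list(
      # reconstruction: Hill-heat structure, coefficients relative to
      # specific_tension/density (J/kg of muscle)
      maint_coef = 0.010,            # x (sigma/rho) * vmax  -> W/kg at full drive
      alpha_short = 0.16,            # x (sigma/rho) * |v| per kg
      eccentric_heat = 0
    ),
    LW07 = list(
      curvature = 4,                 # Hill force-velocity curvature G
      # maintenance = a * f_l * fmax * vmax_mps / G^2
      # shortening heat = a * f_l * fmax * |v_mps| / G
      eccentric_heat_fraction = 0.5  # fraction of |work| dissipated as heat
    )
  )
  utils::modifyList(base, consts)
}
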