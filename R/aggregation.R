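#' @importFrom rlang .data %||%
NULL

# trapezoidal integral on a (possibly non-uniform) grid
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(t)) / 2
}

#' Whole-body metabolic power from gas exchange (Brockway)
#'
#' Linear combination of oxygen uptake and carbon dioxide output rates.
#' Default coefficients 16.58 and 4.51 J/mL.
#'
#' @param vo2 Oxygen uptake, mL/s.
#' @param vco2 Carbon dioxide output, mL/s.
#' @param coef_o2,coef_co2 Energy equivalents, J/mL.
#' @return Metabolic power, W; vectorized.
#' @export
brockway_rate <- function(vo2, vco2, coef_o2 = 16.58, coef_co2 = 4.51) {
  if (any(vo2 < 0) || any(vco2 < 0)) {
    stop("gas exchange rates must be non-negative", call. = FALSE)
  }
  coef_o2 * vo2 + coef_co2 * vco2
}

#' Representative gas-exchange value of a steady trial
#'
#' Mean oxygen and carbon dioxide rates over the final window (default the
#' last 3 minutes) of a constant-speed trial, when gas exchange has
#' plateaued.
#'
#' @param series Tibble with columns `time` (s), `vo2`, `vco2`
#'   (any consistent rate unit).
#' @param window Averaging window, s (default 180).
#' @return One-row tibble with mean `vo2` and `vco2` over the window.
#' @export
representative_gas_value <- function(series, window = 180) {
  stopifnot(all(c("time", "vo2", "vco2") %in% names(series)))
  span <- diff(range(series$time))
  if (span < window) {
    stop(sprintf("series spans %.1f s, shorter than the %.1f s averaging window",
                 span, window), call. = FALSE)
  }
  cut <- max(series$time) - window
  tail <- series[series$time >= cut, ]
  tibble::tibble(vo2 = mean(tail$vo2), vco2 = mean(tail$vco2))
}

#' Whole-body average metabolic rate from one simulated leg
#'
#' Integrates the summed muscle metabolic rates over the gait cycle,
#' divides by cycle duration and body mass, doubles the result to account
#' for both legs (one leg is simulated), and adds the basal rate.
#'
#' @param met A `metabolic_trajectory` (per-muscle rates in W for one leg).
#' @param body_mass Body mass, kg.
#' @param basal Basal metabolic rate, W/kg (default 1.2).
#' @param cycle_duration Optional cycle duration, s; default the time span
#'   of `met`.
#' @return Whole-body average metabolic rate, W/kg.
#' @export
whole_body_average <- function(met, body_mass, basal = 1.2, cycle_duration = NULL) {
  stopifnot(all(c("time", "muscle", "e_dot") %in% names(met)))
  if (!is.finite(body_mass) || body_mass <= 0) {
    stop("body_mass must be positive", call. = FALSE)
  }
  total <- met |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(e_dot = sum(.data$e_dot), .groups = "drop") |>
    dplyr::arrange(.data$time)
  T_cycle <- cycle_duration %||% diff(range(total$time))
  if (!is.finite(T_cycle) || T_cycle <= 0) {
    stop("cycle duration must be positive", call. = FALSE)
  }
  2 * trapz(total$time, total$e_dot) / T_cycle / body_mass + basal
}

#' Attribute biarticular muscle energy to joints
#'
#' At each instant, a muscle's metabolic rate is apportioned to each joint
#' it spans in proportion to the absolute moment arms,
#' `|r_joint| / sum(|r_spanned|)`; uniarticular muscles assign everything
#' to their only joint. Instants where all spanned moment arms are below
#' `eps` fall back to the muscle's cycle-average ratio (flagged).
#'
#' @param met A `metabolic_trajectory` (or tibble with `time`, `muscle`,
#'   `e_dot`).
#' @param moment_arms Tibble with columns `time`, `muscle`, `joint`, `arm`
#'   (m), covering every muscle in `met` at the same time grid.
#' @param eps Degeneracy threshold on the summed absolute arms, m.
#' @return Tibble with `time`, `muscle`, `joint`, `e_dot` (attributed W)
#'   and `fallback` (logical).
#' @export
split_biarticular <- function(met, moment_arms, eps = 1e-6) {
  stopifnot(all(c("time", "muscle", "joint", "arm") %in% names(moment_arms)))
  unknown <- setdiff(unique(met$muscle), unique(moment_arms$muscle))
  if (length(unknown) > 0) {
    stop("no moment arms for muscles: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  arms <- moment_arms |>
    dplyr::group_by(.data$muscle, .data$joint) |>
    dplyr::mutate(mean_abs_arm = mean(abs(.data$arm))) |>
    dplyr::group_by(.data$muscle, .data$time) |>
    dplyr::mutate(
      tot = sum(abs(.data$arm)),
      fallback = .data$tot < eps,
      share = dplyr::if_else(.data$fallback,
                             .data$mean_abs_arm / sum(.data$mean_abs_arm),
                             abs(.data$arm) / .data$tot)
    ) |>
    dplyr::ungroup()
  met |>
    dplyr::select("time", "muscle", "e_dot") |>
    dplyr::inner_join(arms, by = c("time", "muscle"),
                      relationship = "many-to-many") |>
    dplyr::transmute(.data$time, .data$muscle, .data$joint,
                     e_dot = .data$e_dot * .data$share, .data$fallback)
}

#' Muscle-group metabolic rates and energy shares
#'
#' Sums joint-attributed muscle rates into functional groups (e.g. ankle
#' plantarflexors, knee extensors, hip abductors) and reports each group's
#' share of the total cycle energy.
#'
#' @param attributed Output of [split_biarticular()].
#' @param groups Tibble with columns `muscle`, `joint`, `group` mapping
#'   every muscle-joint pair present in `attributed` to exactly one group.
#' @return List with `series` (tibble `time`, `group`, `e_dot`) and
#'   `shares` (tibble `group`, `energy` J, `share` summing to 100).
#' @export
muscle_group_rates <- function(attributed, groups) {
  stopifnot(all(c("muscle", "joint", "group") %in% names(groups)))
  pairs <- dplyr::distinct(attributed, .data$muscle, .data$joint)
  unmapped <- dplyr::anti_join(pairs, groups, by = c("muscle", "joint"))
  if (nrow(unmapped) > 0) {
    stop("unmapped muscle-joint pairs: ",
         paste(paste(unmapped$muscle, unmapped$joint, sep = "@"), collapse = ", "),
         call. = FALSE)
  }
  dup <- groups |>
    dplyr::count(.data$muscle, .data$joint) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("muscle-joint pairs mapped to more than one group", call. = FALSE)
  }
  series <- attributed |>
    dplyr::inner_join(groups, by = c("muscle", "joint")) |>
    dplyr::group_by(.data$time, .data$group) |>
    dplyr::summarise(e_dot = sum(.data$e_dot), .groups = "drop")
  shares <- series |>
    dplyr::group_by(.data$group) |>
    dplyr::arrange(.data$time, .by_group = TRUE) |>
    dplyr::summarise(energy = trapz(.data$time, .data$e_dot), .groups = "drop") |>
    dplyr::mutate(share = 100 * .data$energy / sum(.data$energy))
  list(series = series, shares = shares)
}

#' Relative energy cost of stance and swing
#'
#' Integrates the total metabolic rate over stance (initial contact to
#' toe-off) and swing (toe-off to the next contact) and normalizes by the
#' whole-cycle energy.
#'
#' @param time Time grid, s, covering one cycle starting at initial contact.
#' @param e_dot Total metabolic rate, W, on `time`.
#' @param toe_off Toe-off time, s, strictly inside the cycle.
#' @return One-row tibble with `stance` and `swing` shares in percent
#'   (summing to 100).
#' @export
phase_relative_cost <- function(time, e_dot, toe_off) {
  stopifnot(length(time) == length(e_dot))
  t0 <- min(time); t1 <- max(time)
  if (!(toe_off > t0 && toe_off < t1)) {
    stop("toe-off must lie strictly inside the cycle", call. = FALSE)
  }
  e_to <- stats::approx(time, e_dot, xout = toe_off)$y
  in_stance <- time <= toe_off
  ts <- c(time[in_stance], toe_off)
  ys <- c(e_dot[in_stance], e_to)
  tw <- c(toe_off, time[!in_stance])
  yw <- c(e_to, e_dot[!in_stance])
  stance <- trapz(ts, ys)
  swing <- trapz(tw, yw)
  total <- stance + swing
  if (total <= 0) stop("total cycle energy must be positive", call. = FALSE)
  tibble::tibble(stance = 100 * stance / total, swing = 100 * swing / total)
}

#' Anthropometric maximum isometric forces and muscle masses
#'
#' Estimates each muscle's volume from a linear regression of total
#' lower-limb muscle volume on body mass times height, distributes it by a
#' per-muscle fraction table, and converts to maximum isometric force via
#' the physiological cross-sectional area (PCSA = volume / optimal fiber
#' length) and specific tension, and to muscle mass via density.
#'
#' @param body_mass Body mass, kg.
#' @param height Height, m.
#' @param fractions Tibble with columns `name` and `fraction` (fractions of
#'   the total modeled volume; should sum to <= 1).
#' @param l_opt Named vector or tibble column of optimal fiber lengths, m,
#'   aligned with `fractions$name`.
#' @param specific_tension Specific tension, N/m^2 (default 6e5 = 60 N/cm^2).
#' @param density Muscle density, kg/m^3 (default 1059.7).
#' @param volume_coef,volume_intercept Regression coefficients of total
#'   volume in cm^3 on mass*height (defaults 47.0 and 1285).
#' @return Tibble with `name`, `volume_cm3`, `pcsa_cm2`, `fmax`,
#'   `muscle_mass`.
#' @export
compute_max_isometric_force <- function(body_mass, height, fractions, l_opt,
                                        specific_tension = 6e5,
                                        density = 1059.7,
                                        volume_coef = 47.0,
                                        volume_intercept = 1285) {
  if (body_mass <= 0 || height <= 0) {
    stop("anthropometry must be positive", call. = FALSE)
  }
  stopifnot(all(c("name", "fraction") %in% names(fractions)))
  if (any(is.na(fractions$fraction))) stop("missing volume fraction", call. = FALSE)
  total_cm3 <- volume_coef * body_mass * height + volume_intercept
  vol_m3 <- fractions$fraction * total_cm3 * 1e-6
  l_opt <- if (is.data.frame(l_opt)) l_opt$l_opt else unname(l_opt)
  pcsa <- vol_m3 / l_opt
  tibble::tibble(
    name = fractions$name,
    volume_cm3 = fractions$fraction * total_cm3,
    pcsa_cm2 = pcsa * 1e4,
    fmax = specific_tension * pcsa,
    muscle_mass = vol_m3 * density
  )
}
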