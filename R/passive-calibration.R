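#' Simulate a passive joint moment-angle curve
#'
#' Net joint moment generated at zero activation by the passive fiber
#' forces of all muscles crossing a joint, over an angle grid with the
#' remaining joints fixed at a posture. Fibers are resolved with a rigid
#' tendon (passive trials are quasi-static).
#'
#' @param subject A `virtual_subject` (or any object with the same
#'   `geometry`/`l_ref`/`q_ref` fields) providing muscle-tendon lengths and
#'   moment arms.
#' @param muscles `muscle_params` table.
#' @param joint Joint to sweep.
#' @param angles Angle grid, rad (strictly increasing).
#' @param posture Named fixed angles of the other joints (default the
#'   subject's reference posture).
#' @return Tibble `joint`, `angle`, `moment` (N*m).
#' @export
simulate_passive_joint_moment <- function(subject, muscles, joint, angles,
                                          posture = NULL) {
  if (!joint %in% subject$dofs) stop("unknown joint: ", joint, call. = FALSE)
  if (is.unsorted(angles, strictly = TRUE)) {
    stop("angle grid must be strictly increasing", call. = FALSE)
  }
  posture <- posture %||% subject$q_ref
  q <- matrix(rep(unlist(posture[subject$dofs]), each = length(angles)),
              length(angles), length(subject$dofs),
              dimnames = list(NULL, subject$dofs))
  q[, joint] <- angles
  lmt <- subject_lmt(subject, q)
  arms <- subject_arms(subject, q)[[joint]]
  moment <- numeric(length(angles))
  for (i in seq_len(nrow(muscles))) {
    p <- muscles[i, ]
    u <- lmt[, p$name] - p$l_slack
    h <- p$l_opt * sin(p$alpha_opt)
    l_m <- sqrt(u^2 + h^2)
    cosa <- u / l_m
    fp <- eval_passive_force(l_m / p$l_opt, p)
    moment <- moment + arms[, p$name] * p$fmax * fp * cosa
  }
  tibble::tibble(joint = joint, angle = angles, moment = moment)
}

#' Calibrate passive force-length parameters to joint moment targets
#'
#' Adjusts the passive-curve parameters `k_pe` (shape) and `s0` (onset
#' length) so that simulated passive joint moment-angle curves match target
#' curves, minimizing the summed squared moment error over all targets.
#' `s_m` is held fixed. Parameters are shared within calibration groups
#' (default: all calibrated muscles in one group), which keeps the problem
#' well posed; a seeded multi-start avoids local minima.
#'
#' @param targets Tibble with columns `joint`, `angle` (rad), `moment`
#'   (N*m), and optionally `posture` (a list-column of named fixed angles).
#' @param subject The geometry provider (see
#'   [simulate_passive_joint_moment()]).
#' @param muscles `muscle_params` with the initial (generic) parameters.
#' @param groups Optional tibble `muscle`, `group`; muscles absent from it
#'   keep their initial parameters. Default: every muscle in one group.
#' @param bounds List with `k_pe` and `s0` ranges (defaults `c(1, 10)` and
#'   `c(0.8, 1.4)`).
#' @param n_starts Multi-start count (default 5).
#' @param seed Seed for the extra starts.
#' @return List with `muscles` (updated table), `parameters` (per group),
#'   `report` (per-target rmse before/after), `objective` trace.
#' @export
calibrate_passive_params <- function(targets, subject, muscles, groups = NULL,
                                     bounds = list(k_pe = c(1, 10), s0 = c(0.8, 1.4)),
                                     n_starts = 5, seed = 1) {
  stopifnot(all(c("joint", "angle", "moment") %in% names(targets)))
  if (is.null(groups)) {
    groups <- tibble::tibble(muscle = muscles$name, group = "all")
  }
  gnames <- unique(groups$group)
  tg <- dplyr::group_split(dplyr::group_by(targets, .data$joint))

  apply_pars <- function(par) {
    mm <- muscles
    for (gi in seq_along(gnames)) {
      members <- groups$muscle[groups$group == gnames[gi]]
      idx <- mm$name %in% members
      mm$k_pe[idx] <- par[2 * gi - 1]
      mm$s0[idx] <- par[2 * gi]
    }
    mm
  }
  sim_all <- function(mm) {
    lapply(tg, function(df) {
      simulate_passive_joint_moment(subject, mm, df$joint[1], df$angle)$moment
    })
  }
  objective <- function(par) {
    sims <- sim_all(apply_pars(par))
    sum(vapply(seq_along(tg), function(i) {
      sum((sims[[i]] - tg[[i]]$moment)^2)
    }, numeric(1)))
  }

  par0 <- unlist(lapply(gnames, function(g) {
    members <- groups$muscle[groups$group == g]
    c(mean(muscles$k_pe[muscles$name %in% members]),
      mean(muscles$s0[muscles$name %in% members]))
  }))
  lower <- rep(c(bounds$k_pe[1], bounds$s0[1]), length(gnames))
  upper <- rep(c(bounds$k_pe[2], bounds$s0[2]), length(gnames))

  set.seed(derive_seed(seed, 42))
  starts <- rbind(
    par0,
    matrix(stats::runif((n_starts - 1) * length(par0), lower, upper),
           n_starts - 1, length(par0), byrow = TRUE)
  )
  fits <- apply(starts, 1, function(p0) {
    stats::nlminb(p0, objective, lower = lower, upper = upper,
                  control = list(iter.max = 300))
  })
  best <- fits[[which.min(vapply(fits, function(f) f$objective, numeric(1)))]]

  rmse_of <- function(par) {
    sims <- sim_all(apply_pars(par))
    vapply(seq_along(tg), function(i) {
      sqrt(mean((sims[[i]] - tg[[i]]$moment)^2))
    }, numeric(1))
  }
  report <- tibble::tibble(
    joint = vapply(tg, function(df) df$joint[1], character(1)),
    rmse_before = rmse_of(par0),
    rmse_after = rmse_of(best$par)
  )
  parameters <- tibble::tibble(
    group = gnames,
    k_pe = best$par[seq(1, by = 2, length.out = length(gnames))],
    s0 = best$par[seq(2, by = 2, length.out = length(gnames))]
  )
  list(
    muscles = apply_pars(best$par),
    parameters = parameters,
    report = report,
    objective = best$objective,
    objective_before = objective(par0),
    convergence = best$convergence
  )
}
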