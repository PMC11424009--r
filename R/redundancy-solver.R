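# Muscle redundancy over a gait cycle by direct collocation.
#
# The transcription uses the normalized tendon force of every muscle at N
# periodic mesh nodes as the only decision states. Given prescribed
# muscle-tendon kinematics, all other quantities are algebraic consequences:
# the inverse (exponential) tendon curve gives tendon length, geometry gives
# fiber length and pennation, a periodic central difference of the tendon
# force gives tendon and fiber velocities, the Hill equilibrium gives the
# activation required to produce the tendon force, and inverted first-order
# activation dynamics give the excitation. Joint moment balance is linear in
# the tendon forces; reserve actuators are the (penalized) moment residuals.
# The resulting bounded nonlinear least-squares problem
#   minimize  sum_k sum_i a_ik^2 h  +  w_res sum_k sum_j tres_jk^2 h
#             + bound penalties (+ EMG tracking corridor penalties)
# is solved with a Levenberg-Marquardt method; periodicity holds by
# construction of the wrapped difference operators.

solver_default_opts <- function() {
  list(
    n_mesh = 50,        # periodic mesh nodes per cycle (multiple of 5)
    w_res = 1000,       # weight on squared normalized reserve moments
    w_pen = 1e4,        # weight on bound-violation hinge penalties
    w_emg = 1e4,        # weight on EMG corridor hinge penalties
    emg_bound = 0.01,   # half-width of the EMG tracking corridor
    tau_act = 0.015, tau_deact = 0.060,
    k_t = NULL,         # named per-muscle tendon stiffness overrides
    x_lower = 1e-5, x_upper = 2.2,
    gain_bounds = c(0.05, 5),
    maxiter = 80, ftol = 1e-9, ptol = 1e-10,
    x0 = NULL, gains0 = NULL,
    generic_passive = c(k_pe = 4, s0 = 1, s_m = 0.6)
  )
}

# periodic linear interpolation of trial series onto the mesh
interp_periodic <- function(t_grid, y, t_out, period) {
  stats::approx(t_grid, y, xout = t_out %% period, rule = 2)$y
}

wide_matrix <- function(df, value, t_nodes, period, cols) {
  out <- sapply(cols, function(cn) {
    sub <- df[df[[if ("muscle" %in% names(df)) "muscle" else "joint"]] == cn, ]
    interp_periodic(sub$time, sub[[value]], t_nodes, period)
  })
  matrix(out, nrow = length(t_nodes), dimnames = list(NULL, cols))
}

# assemble the static problem data for one trial
build_ocp_data <- function(trial, muscles, opts, constants) {
  N <- opts$n_mesh
  if (N %% 5 != 0) N <- 5 * ceiling(N / 5)
  T_cycle <- trial$cycle_duration
  t_nodes <- (seq_len(N) - 1) * T_cycle / N
  mnames <- muscles$name
  dofs <- unique(trial$moments$joint)
  LMT <- wide_matrix(trial$lmt, "l_mt", t_nodes, T_cycle, mnames)
  VMT <- wide_matrix(trial$lmt, "v_mt", t_nodes, T_cycle, mnames)
  TAU <- wide_matrix(trial$moments, "moment", t_nodes, T_cycle, dofs)
  R <- lapply(dofs, function(j) {
    sub <- trial$arms[trial$arms$joint == j, ]
    Rj <- matrix(0, N, length(mnames), dimnames = list(NULL, mnames))
    for (mus in unique(sub$muscle)) {
      s2 <- sub[sub$muscle == mus, ]
      Rj[, mus] <- interp_periodic(s2$time, s2$arm, t_nodes, T_cycle)
    }
    Rj
  })
  names(R) <- dofs
  # reserves are normalized by 10% of each dof's peak moment, so the unit
  # reserve penalty corresponds to a reserve of that size
  scale <- pmax(0.1 * apply(abs(TAU), 2, max), 1)
  rep_row <- function(v) matrix(v, N, length(v), byrow = TRUE)
  list(
    N = N, h = T_cycle / N, t_nodes = t_nodes, T_cycle = T_cycle,
    dofs = dofs, mnames = mnames, m = length(mnames), d = length(dofs),
    LMT = LMT, VMT = VMT, TAU = TAU, R = R, scale = scale,
    FMAX = rep_row(muscles$fmax), LOPT = rep_row(muscles$l_opt),
    LS = rep_row(pmax(muscles$l_slack, 1e-4)),
    H2 = rep_row((muscles$l_opt * sin(muscles$alpha_opt))^2),
    VMAX = rep_row(muscles$vmax), KT = rep_row(muscles$k_t),
    KPE = rep_row(muscles$k_pe), S0 = rep_row(muscles$s0),
    SM = rep_row(muscles$s_m),
    constants = constants
  )
}

# algebraic state reconstruction from the tendon-force node matrix
ocp_states <- function(X, dat, opts) {
  N <- dat$N
  c1 <- dat$constants$tendon[["c1"]]; c3 <- dat$constants$tendon[["c3"]]
  ip <- c(2:N, 1); im <- c(N, 1:(N - 1))
  Z <- (X[ip, , drop = FALSE] - X[im, , drop = FALSE]) / (2 * dat$h)
  C2 <- 1 - log(c3 / c1) / dat$KT
  ltn <- C2 + log((X + c3) / c1) / dat$KT
  lt <- dat$LS * ltn
  u <- dat$LMT - lt
  lM <- sqrt(u^2 + dat$H2)
  cosa <- u / lM
  lmn <- lM / dat$LOPT
  vt <- dat$LS * Z / (dat$KT * (X + c3))
  vM <- cosa * (dat$VMT - vt)
  vn <- vM / (dat$LOPT * dat$VMAX)
  fl <- eval_active_force_length(lmn, dat$constants)
  fp <- pmax(passive_force_raw(lmn, dat$KPE, dat$S0, dat$SM), 0)
  fv <- pmax(eval_force_velocity(vn, dat$constants), 5e-3)
  a <- (X / cosa - fp) / (fl * fv + 1e-9)
  adot <- (a[ip, , drop = FALSE] - a[im, , drop = FALSE]) / (2 * dat$h)
  e <- a + ifelse(adot >= 0, opts$tau_act, opts$tau_deact) * adot
  tau_mus <- sapply(dat$dofs, function(j) rowSums(dat$R[[j]] * X * dat$FMAX))
  tau_mus <- matrix(tau_mus, N, dat$d, dimnames = list(NULL, dat$dofs))
  list(X = X, lmn = lmn, vn = vn, cosa = cosa, fl = fl, fp = fp, fv = fv,
       a = a, e = e, tau_mus = tau_mus,
       res_tau = sweep(dat$TAU - tau_mus, 2, dat$scale, "/"))
}

# smooth hinge: ~ max(z, 0) with curvature width eps, so the least-squares
# penalties stay differentiable at the constraint boundary
soft_hinge <- function(z, eps = 1e-3) 0.5 * (z + sqrt(z^2 + eps^2))

ocp_residuals <- function(par, dat, opts, emg_env = NULL, track_idx = integer(0)) {
  nx <- dat$N * dat$m
  X <- matrix(par[seq_len(nx)], dat$N, dat$m)
  gains <- par[-seq_len(nx)]
  st <- ocp_states(X, dat, opts)
  sh <- sqrt(dat$h)
  r1 <- sh * as.vector(st$a)
  r2 <- sqrt(opts$w_res) * sh * as.vector(st$res_tau)
  r3 <- sqrt(opts$w_pen) * sh *
    as.vector(soft_hinge(-st$a) + soft_hinge(st$a - 1) + soft_hinge(-st$vn - 0.98))
  r4 <- sqrt(opts$w_pen) * sh * as.vector(soft_hinge(-st$e) + soft_hinge(st$e - 1))
  r5 <- numeric(0)
  if (length(track_idx) > 0) {
    dev <- st$e[, track_idx, drop = FALSE] - sweep(emg_env, 2, gains, "*")
    r5 <- sqrt(opts$w_emg) * sh *
      as.vector(soft_hinge(dev - opts$emg_bound) +
                  soft_hinge(-dev - opts$emg_bound))
  }
  c(r1, r2, r3, r4, r5)
}

# residual sparsity coloring: columns of one muscle at nodes spaced 5 apart
# influence disjoint residual bands (max band half-width 2), so the full
# Jacobian is recovered from 5 * m forward-difference sweeps plus one per
# EMG gain.
build_coloring <- function(dat, track_idx) {
  N <- dat$N; m <- dat$m; d <- dat$d
  o2 <- N * m; o3 <- o2 + N * d; o4 <- o3 + N * m; o5 <- o4 + N * m
  groups <- list()
  for (mi in seq_len(m)) {
    ti <- match(mi, track_idx)
    for (r in 0:4) {
      kcols <- which((seq_len(N) - 1) %% 5 == r)
      rows <- integer(0); cols <- integer(0)
      for (kp in kcols) {
        col <- (mi - 1) * N + kp
        band1 <- ((kp - 1 + c(-1, 0, 1)) %% N) + 1
        band2 <- ((kp - 1 + c(-2, -1, 0, 1, 2)) %% N) + 1
        rws <- c(
          (mi - 1) * N + band1,                       # effort rows
          o2 + (seq_len(d) - 1) * N + kp,             # reserve rows
          o3 + (mi - 1) * N + band1,                  # a / v hinge rows
          o4 + (mi - 1) * N + band2                   # e hinge rows
        )
        if (!is.na(ti)) rws <- c(rws, o5 + (ti - 1) * N + band2)
        rows <- c(rows, rws)
        cols <- c(cols, rep(col, length(rws)))
      }
      groups[[length(groups) + 1]] <- list(rows = rows, cols = cols,
                                           xcols = (mi - 1) * N + kcols)
    }
  }
  groups
}

ocp_jacobian <- function(par, dat, opts, emg_env, track_idx, coloring, f0) {
  n_res <- length(f0)
  J <- matrix(0, n_res, length(par))
  delta <- 1e-6
  for (g in coloring) {
    p2 <- par
    p2[g$xcols] <- p2[g$xcols] + delta
    f2 <- ocp_residuals(p2, dat, opts, emg_env, track_idx)
    df <- (f2 - f0) / delta
    J[cbind(g$rows, g$cols)] <- df[g$rows]
  }
  nx <- dat$N * dat$m
  if (length(par) > nx) {
    for (ci in seq_along(track_idx)) {
      p2 <- par
      p2[nx + ci] <- p2[nx + ci] + delta
      f2 <- ocp_residuals(p2, dat, opts, emg_env, track_idx)
      J[, nx + ci] <- (f2 - f0) / delta
    }
  }
  J
}

# rigid-tendon static-optimization warm start
ocp_warm_start <- function(dat, muscles, opts) {
  N <- dat$N
  u <- dat$LMT - dat$LS
  lM <- sqrt(u^2 + dat$H2)
  cosa <- u / lM
  lmn <- lM / dat$LOPT
  vn <- cosa * dat$VMT / (dat$LOPT * dat$VMAX)
  fl <- eval_active_force_length(lmn, dat$constants)
  fp <- pmax(passive_force_raw(lmn, dat$KPE, dat$S0, dat$SM), 0)
  fv <- pmax(eval_force_velocity(vn, dat$constants), 5e-3)
  X0 <- matrix(0, N, dat$m)
  for (k in seq_len(N)) {
    G <- t(sapply(dat$dofs, function(j) {
      dat$R[[j]][k, ] * dat$FMAX[k, ] * fl[k, ] * fv[k, ] * cosa[k, ]
    }))
    G <- matrix(G, dat$d, dat$m)
    pmom <- vapply(dat$dofs, function(j) {
      sum(dat$R[[j]][k, ] * dat$FMAX[k, ] * fp[k, ] * cosa[k, ])
    }, numeric(1))
    a <- static_redundancy_ridge(G, dat$TAU[k, ] - pmom)
    X0[k, ] <- (a * fl[k, ] * fv[k, ] + fp[k, ]) * cosa[k, ]
  }
  pmin(pmax(X0, opts$x_lower * 2), opts$x_upper * 0.9)
}

#' Solve the muscle redundancy problem over a gait cycle
#'
#' Computes muscle excitations, activations, fiber and tendon states and
#' reserve moments that reproduce the trial's inverse-dynamics joint
#' moments while minimizing the summed squared activations (plus penalized
#' squared reserve moments), under one of four individualization workflows:
#'
#' * `GEN` - generic passive force-length parameters;
#' * `PAS` - the calibrated passive parameters carried by `muscles`;
#' * `TEN` - additionally, personalized tendon stiffness values supplied
#'   via `opts$k_t` (see [personalize_tendon_stiffness()]);
#' * `EMG` - additionally, excitations of measured muscles must stay within
#'   a tracking corridor around the recorded envelopes, which are scaled by
#'   per-channel gains optimized jointly with the states.
#'
#' @param trial A `gait_trial` (from [make_gait_trial()] or built from
#'   motion files).
#' @param muscles `muscle_params` table.
#' @param workflow One of `"GEN"`, `"PAS"`, `"TEN"`, `"EMG"`.
#' @param emg Long tibble `time`, `muscle`, `envelope` (required for
#'   `EMG`).
#' @param opts Named list of solver options overriding the defaults
#'   (mesh size `n_mesh`, weights `w_res`, `w_pen`, `w_emg`, corridor
#'   `emg_bound`, stiffness overrides `k_t`, warm start `x0`, ...).
#' @param constants Curve constants.
#' @return A `gaitmet_solution`: list with `states` (long tibble per muscle
#'   and node: `excitation`, `activation`, `lm_norm`, `v_norm`, `v_lopt`,
#'   `ft_norm`, `fiber_force`, `tendon_force`), `reserves` (per dof:
#'   `tau_id`, `tau_mus`, `tau_res`, `flagged`), `objective` (component
#'   breakdown), `k_t`, `emg_gains`, `status`, `trial_info`.
#' @export
solve_redundancy <- function(trial, muscles, workflow = c("PAS", "GEN", "TEN", "EMG"),
                             emg = NULL, opts = list(),
                             constants = default_curve_constants()) {
  workflow <- match.arg(workflow)
  opts <- utils::modifyList(solver_default_opts(), opts)
  muscles <- as_solver_muscles(muscles, workflow, opts)
  if (workflow == "EMG" && is.null(emg)) emg <- trial$emg
  if (workflow == "EMG" && is.null(emg)) {
    stop("workflow EMG requires EMG envelopes", call. = FALSE)
  }

  dat <- build_ocp_data(trial, muscles, opts, constants)
  track_idx <- integer(0); emg_env <- NULL; gains0 <- numeric(0)
  X0 <- opts$x0
  if (workflow == "EMG") {
    channels <- intersect(muscles$name, unique(emg$muscle))
    if (length(channels) == 0) stop("no EMG channel matches a modeled muscle", call. = FALSE)
    track_idx <- match(channels, muscles$name)
    emg_env <- wide_matrix(emg, "envelope", dat$t_nodes, dat$T_cycle, channels)
    if (is.null(X0)) {
      # warm start from the minimal-effort solution of the same problem
      pre <- solve_redundancy(trial, muscles, "PAS",
                              opts = utils::modifyList(opts, list(k_t = NULL, x0 = NULL)))
      X0 <- matrix(pre$states$ft_norm, dat$N, dat$m)
      if (is.null(opts$gains0)) {
        e_ws <- matrix(pre$states$excitation, dat$N, dat$m)[, track_idx, drop = FALSE]
        gains0 <- vapply(seq_along(track_idx), function(ci) {
          g <- sum(e_ws[, ci] * emg_env[, ci]) / max(sum(emg_env[, ci]^2), 1e-9)
          min(max(g, opts$gain_bounds[1]), opts$gain_bounds[2])
        }, numeric(1))
      } else {
        gains0 <- opts$gains0
      }
    } else {
      gains0 <- opts$gains0 %||% rep(1, length(track_idx))
    }
  }

  X0 <- X0 %||% ocp_warm_start(dat, muscles, opts)
  par0 <- c(as.vector(X0), gains0)
  lower <- c(rep(opts$x_lower, dat$N * dat$m),
             rep(opts$gain_bounds[1], length(gains0)))
  upper <- c(rep(opts$x_upper, dat$N * dat$m),
             rep(opts$gain_bounds[2], length(gains0)))
  coloring <- build_coloring(dat, track_idx)

  # the iteration cap is an accepted stopping rule (progress per iteration
  # is negligible well before it); the lmder info=-1 warning is therefore
  # folded into the returned status instead of being raised
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = par0,
    fn = function(p) ocp_residuals(p, dat, opts, emg_env, track_idx),
    jac = function(p, ...) {
      f0 <- ocp_residuals(p, dat, opts, emg_env, track_idx)
      ocp_jacobian(p, dat, opts, emg_env, track_idx, coloring, f0)
    },
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(
      maxiter = opts$maxiter, ftol = opts$ftol, ptol = opts$ptol
    )
  ))

  nx <- dat$N * dat$m
  X <- matrix(fit$par[seq_len(nx)], dat$N, dat$m)
  gains <- fit$par[-seq_len(nx)]
  st <- ocp_states(X, dat, opts)
  h <- dat$h
  obj <- list(
    effort = h * sum(st$a^2),
    reserve = opts$w_res * h * sum(st$res_tau^2),
    penalty = opts$w_pen * h *
      (sum((soft_hinge(-st$a) + soft_hinge(st$a - 1) + soft_hinge(-st$vn - 0.98))^2) +
         sum((soft_hinge(-st$e) + soft_hinge(st$e - 1))^2)),
    deviance = fit$deviance
  )
  obj$emg_tracking <- obj$deviance - obj$effort - obj$reserve - obj$penalty

  states <- tibble::tibble(
    time = rep(dat$t_nodes, dat$m),
    muscle = rep(dat$mnames, each = dat$N),
    excitation = as.vector(pmin(pmax(st$e, 0), 1)),
    activation = as.vector(pmin(pmax(st$a, 0), 1)),
    lm_norm = as.vector(st$lmn),
    v_norm = as.vector(st$vn),
    v_lopt = as.vector(st$vn * dat$VMAX),
    ft_norm = as.vector(X),
    fiber_force = as.vector(dat$FMAX * (pmin(pmax(st$a, 0), 1) * st$fl * st$fv + st$fp)),
    tendon_force = as.vector(dat$FMAX * X)
  )
  tau_res <- dat$TAU - st$tau_mus
  reserves <- tibble::tibble(
    time = rep(dat$t_nodes, dat$d),
    joint = rep(dat$dofs, each = dat$N),
    tau_id = as.vector(dat$TAU),
    tau_mus = as.vector(st$tau_mus),
    tau_res = as.vector(tau_res)
  )
  peak_share <- reserves |>
    dplyr::group_by(.data$joint) |>
    dplyr::summarise(
      reserve_share = max(abs(.data$tau_res)) / max(max(abs(.data$tau_id)), 1e-9),
      .groups = "drop"
    ) |>
    dplyr::mutate(flagged = .data$reserve_share > 0.05)

  if (length(gains) > 0) names(gains) <- dat$mnames[track_idx]
  k_t <- stats::setNames(muscles$k_t, muscles$name)
  structure(
    list(states = states, reserves = reserves, reserve_report = peak_share,
         objective = obj, k_t = k_t, emg_gains = gains,
         status = list(converged = fit$info %in% 1:4, info = fit$info,
                       capped = fit$info == -1,
                       message = fit$message, iterations = fit$niter,
                       deviance = fit$deviance),
         workflow = workflow, n_mesh = dat$N,
         trial_info = list(cycle_duration = dat$T_cycle,
                           toe_off = trial$events$toe_off,
                           speed = trial$speed, body_mass = trial$body_mass)),
    class = "gaitmet_solution"
  )
}

# apply workflow-specific parameter handling
as_solver_muscles <- function(muscles, workflow, opts) {
  validate_muscle_params(muscles)
  muscles <- tibble::as_tibble(muscles)
  if (workflow == "GEN") {
    gp <- opts$generic_passive
    muscles$k_pe <- gp[["k_pe"]]; muscles$s0 <- gp[["s0"]]; muscles$s_m <- gp[["s_m"]]
  }
  if (!is.null(opts$k_t)) {
    idx <- match(names(opts$k_t), muscles$name)
    if (any(is.na(idx))) stop("k_t override names unknown", call. = FALSE)
    muscles$k_t[idx] <- as.numeric(opts$k_t)
  }
  muscles
}

#' Moment balance residual of a solution
#'
#' Recomputes, per degree of freedom and node, the inverse-dynamics moment
#' minus the muscle-generated moment (tendon forces rebuilt from the Hill
#' model states) minus the reserve moment.
#'
#' @param solution A `gaitmet_solution`.
#' @param trial The trial it was solved on.
#' @param muscles The `muscle_params` used (with any `k_t` overrides
#'   applied, i.e. `solution$k_t`).
#' @return Tibble `joint`, `max_abs_residual` (N*m) plus the full residual
#'   curves in the `curves` attribute.
#' @export
moment_balance_residual <- function(solution, trial, muscles) {
  st <- solution$states
  muscles <- tibble::as_tibble(muscles)
  muscles$k_t <- as.numeric(solution$k_t[muscles$name])
  # rebuild tendon force from the Hill states
  st <- st |>
    dplyr::group_by(.data$muscle) |>
    dplyr::group_modify(function(df, key) {
      p <- muscles[muscles$name == key$muscle, ]
      sina0 <- sin(p$alpha_opt)
      cosa <- sqrt(pmax(1 - (sina0 / df$lm_norm)^2, 0))
      fl <- eval_active_force_length(df$lm_norm)
      fv <- eval_force_velocity(df$v_lopt / p$vmax)
      fp <- eval_passive_force(df$lm_norm, p)
      df$ft_rebuilt <- p$fmax * (df$activation * fl * fv + fp) * cosa
      df
    }) |>
    dplyr::ungroup()
  arms <- trial$arms
  res <- solution$reserves
  dofs <- unique(res$joint)
  out <- lapply(dofs, function(j) {
    rj <- arms[arms$joint == j, ]
    sub <- st[st$muscle %in% unique(rj$muscle), ]
    sub$arm <- mapply(function(tt, mus) {
      s2 <- rj[rj$muscle == mus, ]
      stats::approx(s2$time, s2$arm, xout = tt, rule = 2)$y
    }, sub$time, sub$muscle)
    mus_mom <- sub |>
      dplyr::group_by(.data$time) |>
      dplyr::summarise(tau_mus = sum(.data$arm * .data$ft_rebuilt), .groups = "drop")
    rj2 <- res[res$joint == j, ]
    merged <- dplyr::left_join(rj2, mus_mom, by = "time", suffix = c("", "_rebuilt"))
    tibble::tibble(
      joint = j, time = merged$time,
      residual = merged$tau_id - merged$tau_mus_rebuilt - merged$tau_res
    )
  })
  curves <- dplyr::bind_rows(out)
  summary <- curves |>
    dplyr::group_by(.data$joint) |>
    dplyr::summarise(max_abs_residual = max(abs(.data$residual)), .groups = "drop")
  attr(summary, "curves") <- curves
  summary
}

#' Personalize tendon stiffness from one or more gait trials
#'
#' Treats the tendon stiffness shape factor of each tendon group (by
#' default the Achilles group `gastroc`/`soleus` and the quadriceps group
#' `vasti`/`recfem`) as a design variable shared across all trials, and
#' minimizes the total redundancy objective (all trials simultaneously).
#' Muscles outside the groups keep their generic stiffness. With EMG
#' supplied the inner solves run the EMG-tracking workflow, which is what
#' makes the stiffness identifiable.
#'
#' @param trials List of `gait_trial` objects.
#' @param muscles `muscle_params` table.
#' @param emg Optional list of EMG envelope tibbles matched to `trials`.
#' @param groups Named list of muscle groups sharing one `k_t`.
#' @param bounds Stiffness bounds (default `c(15, 45)`).
#' @param opts Solver options passed to [solve_redundancy()].
#' @param sweeps Coordinate-descent sweeps over the groups (default 1).
#' @param tol Absolute tolerance of the 1-D searches (default 0.5).
#' @return List with `k_t` (per group), `k_t_muscle` (per muscle),
#'   `linear_stiffness_n_mm` (at one-third of maximum isometric force),
#'   `solutions` (final per-trial solutions), `objective`, `pinned`.
#' @export
personalize_tendon_stiffness <- function(trials, muscles, emg = NULL,
                                         groups = list(
                                           achilles = c("gastroc", "soleus"),
                                           quadriceps = c("vasti", "recfem")
                                         ),
                                         bounds = c(15, 45), opts = list(),
                                         sweeps = 1, tol = 0.5) {
  if (inherits(trials, "gait_trial")) trials <- list(trials)
  groups <- lapply(groups, intersect, y = muscles$name)
  groups <- groups[lengths(groups) > 0]
  workflow <- if (is.null(emg)) "PAS" else "EMG"
  warm <- new.env(parent = emptyenv())
  k_group <- vapply(groups, function(g) {
    stats::median(muscles$k_t[muscles$name %in% g])
  }, numeric(1))

  solve_all <- function(kg) {
    k_t <- stats::setNames(muscles$k_t, muscles$name)
    for (gn in names(groups)) k_t[groups[[gn]]] <- kg[[gn]]
    total <- 0
    sols <- vector("list", length(trials))
    for (i in seq_along(trials)) {
      o <- utils::modifyList(opts, list(k_t = k_t))
      key <- paste0("x", i)
      if (!is.null(warm[[key]])) {
        o$x0 <- warm[[key]]$x0
        o$gains0 <- warm[[key]]$gains0
      }
      sol <- solve_redundancy(trials[[i]], muscles, workflow,
                              emg = if (is.null(emg)) NULL else emg[[i]],
                              opts = o)
      warm[[key]] <- list(
        x0 = matrix(sol$states$ft_norm, sol$n_mesh, nrow(muscles)),
        gains0 = if (length(sol$emg_gains) > 0) sol$emg_gains else NULL
      )
      total <- total + sol$objective$deviance
      sols[[i]] <- sol
    }
    list(total = total, sols = sols)
  }

  trace <- list()
  for (sw in seq_len(sweeps)) {
    for (gn in names(groups)) {
      f1 <- function(k) {
        kg <- k_group; kg[[gn]] <- k
        solve_all(kg)$total
      }
      # coarse-to-fine grid search: robust to the small path dependence of
      # warm-started inner solves, which can stall a golden-section search
      coarse <- unique(sort(c(seq(bounds[1], bounds[2], length.out = 7),
                              k_group[[gn]])))
      vc <- vapply(coarse, f1, numeric(1))
      kc <- coarse[which.min(vc)]
      span <- (bounds[2] - bounds[1]) / 6
      fine <- seq(max(bounds[1], kc - span * 0.7),
                  min(bounds[2], kc + span * 0.7), by = max(tol, span / 4))
      fine <- setdiff(round(fine, 6), round(coarse, 6))
      vf <- if (length(fine) > 0) vapply(fine, f1, numeric(1)) else numeric(0)
      ks <- c(coarse, fine); vs <- c(vc, vf)
      ord <- order(ks); ks <- ks[ord]; vs <- vs[ord]
      ib <- which.min(vs)
      k_best <- ks[ib]
      # parabolic refinement through the best point and its neighbors
      if (ib > 1 && ib < length(ks)) {
        x <- ks[(ib - 1):(ib + 1)]; y <- vs[(ib - 1):(ib + 1)]
        den <- (x[2] - x[1]) * (y[2] - y[3]) - (x[2] - x[3]) * (y[2] - y[1])
        if (abs(den) > 1e-12) {
          kv <- x[2] - 0.5 * ((x[2] - x[1])^2 * (y[2] - y[3]) -
                                (x[2] - x[3])^2 * (y[2] - y[1])) / den
          if (kv > min(x) && kv < max(x)) k_best <- kv
        }
      }
      k_group[[gn]] <- k_best
      trace[[paste(sw, gn, sep = ".")]] <- list(grid = ks, objective = vs,
                                                k = k_best)
    }
  }
  final <- solve_all(k_group)
  pinned <- abs(k_group - bounds[1]) < tol | abs(k_group - bounds[2]) < tol
  if (any(pinned)) {
    warning("tendon stiffness pinned at a bound for: ",
            paste(names(k_group)[pinned], collapse = ", "))
  }
  k_t_muscle <- stats::setNames(muscles$k_t, muscles$name)
  for (gn in names(groups)) k_t_muscle[groups[[gn]]] <- k_group[[gn]]
  # equivalent linear stiffness dF/dl_T at one-third of fmax, N/mm
  cc <- default_curve_constants()
  lin <- vapply(muscles$name, function(mn) {
    p <- muscles[muscles$name == mn, ]
    kt <- k_t_muscle[[mn]]
    ft <- 1 / 3
    p$fmax * kt * (ft + cc$tendon[["c3"]]) / (p$l_slack * 1000)
  }, numeric(1))
  list(k_t = k_group, k_t_muscle = k_t_muscle,
       linear_stiffness_n_mm = lin,
       solutions = final$sols, objective = final$total,
       pinned = pinned, trace = trace)
}
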