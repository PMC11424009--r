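# Synthetic virtual subject and gait trials
#
# The generator emulates the data streams a gait lab produces for one leg
# (sagittal hip, knee, ankle): periodic joint kinematics, inverse-dynamics
# joint moments consistent with a known set of muscle forces, muscle-tendon
# lengths and moment arms consistent with each other by construction
# (the moment arm is minus the partial derivative of the muscle-tendon
# length), EMG envelopes proportional to the true excitations with hidden
# per-channel gains, and gas-exchange series whose Brockway energy equals a
# prescribed whole-body rate. Everything is deterministic under a fixed
# seed; sub-seeds for trials and signal noise are derived from the subject
# seed.

derive_seed <- function(seed, k) as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)

#' Generate a virtual subject
#'
#' Builds a nine-muscle, three-joint (hip, knee, ankle; sagittal) virtual
#' subject: muscle-tendon parameters with anthropometric maximum isometric
#' forces and masses, and linear-in-angle moment arm polynomials from which
#' muscle-tendon lengths are integrated exactly.
#'
#' @param seed Integer seed; the subject is deterministic given the seed.
#' @param body_mass Body mass, kg (default 71.3).
#' @param height Height, m (default 1.74).
#' @param jitter Relative jitter applied to nominal architecture (default
#'   0.05; 0 gives the nominal subject).
#' @return A list of class `virtual_subject` with `muscles`
#'   (a `muscle_params` table), `geometry` (tibble `muscle`, `joint`, `r0`,
#'   `r1`), `l_ref`, `q_ref`, `dofs`, `body_mass`, `height`, `seed`.
#' @export
make_virtual_subject <- function(seed = 1, body_mass = 71.3, height = 1.74,
                                 jitter = 0.05) {
  set.seed(derive_seed(seed, 1))
  dofs <- c("hip", "knee", "ankle")
  nominal <- tibble::tibble(
    name = c("iliopsoas", "glutmax", "hamstrings", "recfem", "vasti",
             "bfsh", "gastroc", "soleus", "tibant"),
    l_opt = c(0.110, 0.150, 0.090, 0.076, 0.097, 0.110, 0.051, 0.044, 0.068),
    l_slack = c(0.100, 0.125, 0.330, 0.340, 0.220, 0.100, 0.400, 0.280, 0.240),
    alpha_opt = c(0.14, 0.38, 0.20, 0.24, 0.08, 0.21, 0.21, 0.44, 0.17),
    slow_twitch_fraction = c(0.50, 0.55, 0.55, 0.40, 0.50, 0.55, 0.55, 0.80, 0.70),
    fraction = c(0.050, 0.120, 0.100, 0.035, 0.200, 0.015, 0.060, 0.065, 0.020)
  )
  jit <- function(x, rel = jitter) x * (1 + stats::runif(length(x), -rel, rel))
  nominal$l_opt <- jit(nominal$l_opt)
  nominal$l_slack <- jit(nominal$l_slack)

  anthro <- compute_max_isometric_force(
    body_mass, height,
    fractions = nominal[, c("name", "fraction")],
    l_opt = nominal$l_opt
  )

  joints_map <- list(
    iliopsoas = "hip", glutmax = "hip", hamstrings = c("hip", "knee"),
    recfem = c("hip", "knee"), vasti = "knee", bfsh = "knee",
    gastroc = c("knee", "ankle"), soleus = "ankle", tibant = "ankle"
  )
  muscles <- muscle_tendon_params(
    name = nominal$name,
    fmax = anthro$fmax,
    l_opt = nominal$l_opt,
    l_slack = nominal$l_slack,
    alpha_opt = nominal$alpha_opt,
    vmax = 10,
    slow_twitch_fraction = nominal$slow_twitch_fraction,
    muscle_mass = anthro$muscle_mass,
    joints_spanned = joints_map[nominal$name]
  )

  # moment arm polynomials r(q) = r0 + r1 q  [m]; flexion-positive joints,
  # flexor arms positive
  geometry <- tibble::tibble(
    muscle = c("iliopsoas", "glutmax", "hamstrings", "hamstrings", "recfem",
               "recfem", "vasti", "bfsh", "gastroc", "gastroc", "soleus",
               "tibant"),
    joint = c("hip", "hip", "hip", "knee", "hip", "knee", "knee", "knee",
              "knee", "ankle", "ankle", "ankle"),
    r0 = c(0.040, -0.055, -0.060, 0.030, 0.035, -0.040, -0.042, 0.028,
           0.018, -0.048, -0.042, 0.038),
    r1 = c(0.004, -0.004, -0.003, 0.004, 0.003, -0.005, -0.006, 0.003,
           0.002, -0.004, -0.003, 0.003)
  )
  geometry$r0 <- jit(geometry$r0, jitter)

  # reference posture (cycle-mean-ish); l_ref places the normalized fiber
  # length near 1 under a nominal operating load (tendon force ~ 15% of
  # maximum isometric force), i.e. fibers are tuned to work near their
  # optimum at the muscle's own tendon stiffness, as real architecture is
  q_ref <- c(hip = 0.15, knee = 0.35, ankle = 0.02)
  lmn_ref <- stats::runif(nrow(muscles), 0.97, 1.03)
  strain_ref <- log((0.15 + 0.25) / 0.25) / muscles$k_t
  l_ref <- muscles$l_slack * (1 + strain_ref) +
    muscles$l_opt * cos(muscles$alpha_opt) * lmn_ref

  structure(
    list(muscles = muscles, geometry = geometry, l_ref = l_ref, q_ref = q_ref,
         dofs = dofs, body_mass = body_mass, height = height, seed = seed),
    class = "virtual_subject"
  )
}

# muscle-tendon lengths for a matrix of joint angles (rows = time).
# l_mt(q) = l_ref - sum_j [ r0 (q_j - qref_j) + r1/2 (q_j^2 - qref_j^2) ],
# so that the moment arm equals -d l_mt / d q exactly.
subject_lmt <- function(subject, q) {
  q <- as.matrix(q)
  m <- nrow(subject$muscles)
  out <- matrix(rep(subject$l_ref, each = nrow(q)), nrow(q), m)
  colnames(out) <- subject$muscles$name
  for (i in seq_len(nrow(subject$geometry))) {
    g <- subject$geometry[i, ]
    qj <- q[, g$joint]
    qr <- subject$q_ref[[g$joint]]
    out[, g$muscle] <- out[, g$muscle] -
      (g$r0 * (qj - qr) + g$r1 / 2 * (qj^2 - qr^2))
  }
  out
}

# moment arms at joint angles: list of (n x m) matrices per joint
subject_arms <- function(subject, q) {
  q <- as.matrix(q)
  m <- nrow(subject$muscles)
  res <- lapply(subject$dofs, function(j) {
    R <- matrix(0, nrow(q), m, dimnames = list(NULL, subject$muscles$name))
    gg <- subject$geometry[subject$geometry$joint == j, ]
    for (i in seq_len(nrow(gg))) {
      R[, gg$muscle[i]] <- gg$r0[i] + gg$r1[i] * q[, j]
    }
    R
  })
  names(res) <- subject$dofs
  res
}

# muscle-tendon shortening velocity: v_mt = -sum_j r_j(q_j) qdot_j
subject_vmt <- function(subject, q, qd) {
  arms <- subject_arms(subject, q)
  v <- 0
  for (j in subject$dofs) v <- v - arms[[j]] * as.matrix(qd)[, j]
  v
}

# periodic joint-angle templates over one cycle (tau in [0, 1), contact at 0)
gait_kinematics <- function(tau, speed) {
  s <- pmin(pmax(speed / 1.3, 0.4), 1.7)
  amp <- 0.75 + 0.25 * s
  cbind(
    hip = 0.12 + amp * 0.32 * cos(2 * pi * tau) + 0.03 * sin(4 * pi * tau),
    knee = 0.40 + amp * (0.34 * cos(2 * pi * (tau - 0.72)) +
                           0.10 * cos(4 * pi * (tau - 0.60))),
    ankle = 0.02 + amp * (0.10 * cos(2 * pi * (tau - 0.35)) +
                            0.10 * sin(4 * pi * (tau - 0.10)))
  )
}

gait_kinematics_deriv <- function(tau, speed, T_cycle) {
  eps <- 1e-6
  (gait_kinematics((tau + eps) %% 1, speed) -
      gait_kinematics((tau - eps) %% 1, speed)) / (2 * eps) / T_cycle
}

# smooth periodic non-negative excitation bumps
excitation_bumps <- function(tau, centers, widths, amps) {
  e <- 0
  for (i in seq_along(centers)) {
    e <- e + amps[i] * exp(widths[i] * (cos(2 * pi * (tau - centers[i])) - 1))
  }
  pmin(e, 1)
}

# default bump pattern per muscle (centers in fraction of cycle)
default_excitation_pattern <- function() {
  list(
    iliopsoas = list(c = c(0.62), w = c(12), a = c(0.30)),
    glutmax = list(c = c(0.02), w = c(10), a = c(0.25)),
    hamstrings = list(c = c(0.95), w = c(10), a = c(0.30)),
    recfem = list(c = c(0.63), w = c(14), a = c(0.15)),
    vasti = list(c = c(0.08), w = c(12), a = c(0.30)),
    bfsh = list(c = c(0.90), w = c(12), a = c(0.12)),
    gastroc = list(c = c(0.45), w = c(9), a = c(0.45)),
    soleus = list(c = c(0.47), w = c(8), a = c(0.55)),
    tibant = list(c = c(0.97, 0.65), w = c(10, 10), a = c(0.35, 0.25))
  )
}

# integrate activation dynamics over the periodic excitation (RK4, cyclic)
integrate_activation <- function(e_fun, T_cycle, n = 400, tau_act = 0.015,
                                 tau_deact = 0.060, cycles = 3) {
  h <- T_cycle / n
  a <- e_fun(0)
  traj <- numeric(n)
  for (cyc in seq_len(cycles)) {
    for (k in seq_len(n)) {
      t0 <- (k - 1) * h
      f <- function(t, a) {
        activation_dynamics_rate(e_fun((t / T_cycle) %% 1),
                                 pmin(pmax(a, 0), 1),
                                 tau_act, tau_deact)
      }
      k1 <- f(t0, a); k2 <- f(t0 + h / 2, a + h / 2 * k1)
      k3 <- f(t0 + h / 2, a + h / 2 * k2); k4 <- f(t0 + h, a + h * k3)
      a <- a + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      a <- pmin(pmax(a, 0), 1)
      if (cyc == cycles) traj[k] <- a
    }
  }
  # trajectory at nodes 1..n corresponds to times h..T; rotate so index 1 is t=0
  c(traj[n], traj[-n])
}

# forward muscle dynamics with compliant tendon: integrate the normalized
# tendon force state given activation and muscle-tendon kinematics (RK4 on a
# fixed grid, repeated for periodicity)
integrate_tendon_force <- function(a_fun, lmt_fun, vmt_fun, params,
                                   T_cycle, n = 400, cycles = 3,
                                   constants = default_curve_constants()) {
  h_step <- T_cycle / n
  hgt <- params$l_opt * sin(params$alpha_opt)
  fvc <- constants$fv
  rate <- function(t, ft) {
    ft <- max(ft, 1e-5)
    a <- a_fun(t)
    lmt <- lmt_fun(t); vmt <- vmt_fun(t)
    ltn <- tendon_length_from_force(ft, params$k_t, constants)
    u <- lmt - ltn * params$l_slack
    l_m <- sqrt(u^2 + hgt^2)
    cosa <- u / l_m
    lmn <- l_m / params$l_opt
    fl <- eval_active_force_length(lmn, constants)
    fp <- eval_passive_force(lmn, params)
    fv_req <- (ft / cosa - fp) / max(a * fl, 1e-4)
    fv_req <- min(max(fv_req, 1e-3), 1.78)
    # invert the asinh force-velocity curve
    vn <- (sinh((fv_req - fvc[["d4"]]) / fvc[["d1"]]) - fvc[["d3"]]) / fvc[["d2"]]
    vn <- min(max(vn, -1), 1)
    v_m <- vn * params$vmax * params$l_opt
    v_t <- vmt - v_m / cosa
    params$k_t * (ft + constants$tendon[["c3"]]) * v_t / params$l_slack
  }
  ft <- 0.05
  traj <- numeric(n)
  for (cyc in seq_len(cycles)) {
    for (k in seq_len(n)) {
      t0 <- (k - 1) * h_step
      k1 <- rate(t0, ft); k2 <- rate(t0 + h_step / 2, ft + h_step / 2 * k1)
      k3 <- rate(t0 + h_step / 2, ft + h_step / 2 * k2)
      k4 <- rate(t0 + h_step, ft + h_step * k3)
      ft <- ft + h_step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      ft <- min(max(ft, 1e-5), 2.5)
      if (cyc == cycles) traj[k] <- ft
    }
  }
  c(traj[n], traj[-n])
}

#' Generate a synthetic gait trial with known ground truth
#'
#' Builds one gait cycle at a given walking speed: periodic kinematics from
#' truncated Fourier templates, ground-truth excitations as smooth bump
#' trains, activations and compliant-tendon fiber states by forward
#' integration, and inverse-dynamics joint moments computed forward from
#' the ground-truth tendon forces (so the redundancy truth has zero
#' reserves). EMG envelopes are the true excitations scaled by hidden
#' log-uniform gains plus additive noise.
#'
#' @param subject A `virtual_subject`.
#' @param speed Walking speed, m/s (0.5 to 2.2).
#' @param seed Trial seed.
#' @param n_grid Stored grid resolution over the cycle (default 101).
#' @param excitation Optional named list overriding the bump pattern, or
#'   a function `(muscle, tau) -> excitation`.
#' @param emg_noise_sd Additive envelope noise SD (default 0.01).
#' @param emg_channels Muscles with EMG (default all).
#' @param truth `"bumps"` (default) keeps the forward-simulated bump
#'   excitations as ground truth; `"minimal_effort"` re-derives the ground
#'   truth as the minimal-effort redundancy solution of the bump trial and
#'   rebuilds the joint moments from that solution's tendon forces, so the
#'   stored truth is exactly recoverable by the solver (used for recovery
#'   experiments).
#' @param truth_opts Solver options for the `minimal_effort` mode.
#' @return A list of class `gait_trial`: `time`, `angles` (long tibble),
#'   `moments`, `lmt`, `arms`, `events`, `speed`, `cycle_duration`,
#'   `body_mass`, `height`, `emg` (long tibble with hidden-gain envelopes),
#'   and `truth` (states, gains).
#' @export
make_gait_trial <- function(subject, speed = 1.3, seed = 1, n_grid = 101,
                            excitation = NULL, emg_noise_sd = 0.01,
                            emg_channels = NULL, truth = c("bumps", "minimal_effort"),
                            truth_opts = list()) {
  truth <- match.arg(truth)
  if (speed < 0.5 || speed > 2.2) {
    stop("speed outside the generator range [0.5, 2.2] m/s", call. = FALSE)
  }
  set.seed(derive_seed(subject$seed, 100 + seed))
  muscles <- subject$muscles
  m <- nrow(muscles)
  T_cycle <- max(0.8, min(1.4, 1.4 - 0.25 * speed))
  toe_frac <- max(0.55, min(0.68, 0.60 + 0.05 * (1.3 - speed) / 1.3))
  tau <- seq(0, 1, length.out = n_grid)
  time <- tau * T_cycle

  q <- gait_kinematics(tau, speed)
  qd <- gait_kinematics_deriv(tau, speed, T_cycle)
  lmt <- subject_lmt(subject, q)
  arms <- subject_arms(subject, q)
  vmt <- subject_vmt(subject, q, qd)

  pattern <- default_excitation_pattern()
  if (is.list(excitation)) pattern <- utils::modifyList(pattern, excitation)
  e_of <- function(mus, tt) {
    if (is.function(excitation)) return(excitation(mus, tt))
    p <- pattern[[mus]]
    0.02 + excitation_bumps(tt, p$c, p$w, p$a)
  }

  n_int <- 400
  tau_int <- seq(0, 1 - 1 / n_int, length.out = n_int)
  states <- vector("list", m)
  FT <- matrix(0, n_grid, m, dimnames = list(NULL, muscles$name))
  for (i in seq_len(m)) {
    mus <- muscles$name[i]
    p <- muscles[i, ]
    e_tr <- e_of(mus, tau_int)
    a_tr <- integrate_activation(function(tt) e_of(mus, tt), T_cycle, n = n_int)
    a_fun <- stats::approxfun(tau_int * T_cycle, a_tr, rule = 2)
    lmt_i <- stats::approxfun(time, lmt[, i], rule = 2)
    vmt_i <- stats::approxfun(time, vmt[, i], rule = 2)
    ft_tr <- integrate_tendon_force(
      function(t) a_fun(t %% T_cycle), function(t) lmt_i(t %% T_cycle),
      function(t) vmt_i(t %% T_cycle), p, T_cycle, n = n_int
    )
    # resample to the stored grid (periodic)
    res <- function(vv) stats::approx(c(tau_int, 1), c(vv, vv[1]), xout = tau)$y
    ftg <- res(ft_tr)
    FT[, i] <- ftg
    ltn <- tendon_length_from_force(pmax(ftg, 1e-5), p$k_t)
    u <- lmt[, i] - ltn * p$l_slack
    hgt <- p$l_opt * sin(p$alpha_opt)
    l_m <- sqrt(u^2 + hgt^2)
    lmn <- l_m / p$l_opt
    v_lopt <- c(diff(l_m) / diff(time), NA)
    v_lopt[n_grid] <- v_lopt[1]
    states[[i]] <- tibble::tibble(
      time = time, muscle = mus,
      excitation = res(e_tr), activation = res(a_tr),
      lm_norm = lmn, v_lopt = v_lopt / p$l_opt,
      ft_norm = ftg, tendon_force = ftg * p$fmax
    )
  }
  truth_states <- dplyr::bind_rows(states)

  moments <- lapply(subject$dofs, function(j) {
    tibble::tibble(time = time, joint = j,
                   moment = rowSums(arms[[j]] * FT %*% diag(muscles$fmax)))
  })
  moments <- dplyr::bind_rows(moments)

  arms_long <- dplyr::bind_rows(lapply(subject$dofs, function(j) {
    tidyr::pivot_longer(
      dplyr::bind_cols(tibble::tibble(time = time),
                       tibble::as_tibble(arms[[j]])),
      -"time", names_to = "muscle", values_to = "arm"
    ) |>
      dplyr::mutate(joint = j)
  }))
  # keep only spanned pairs
  spanned <- dplyr::distinct(subject$geometry, .data$muscle, .data$joint)
  arms_long <- dplyr::inner_join(arms_long, spanned, by = c("muscle", "joint"))

  emg_channels <- emg_channels %||% muscles$name
  gains <- exp(stats::runif(length(emg_channels), log(0.3), log(3)))
  names(gains) <- emg_channels
  emg <- truth_states |>
    dplyr::filter(.data$muscle %in% emg_channels) |>
    dplyr::group_by(.data$muscle) |>
    dplyr::mutate(envelope = pmax(
      .data$excitation * gains[[unique(.data$muscle)]] +
        stats::rnorm(dplyr::n(), 0, emg_noise_sd), 0)) |>
    dplyr::ungroup() |>
    dplyr::select("time", "muscle", "envelope")

  angles_long <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(time = time), tibble::as_tibble(q)),
    -"time", names_to = "joint", values_to = "q"
  )
  qd_long <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(time = time), tibble::as_tibble(qd)),
    -"time", names_to = "joint", values_to = "qd"
  )
  angles_long <- dplyr::left_join(angles_long, qd_long, by = c("time", "joint"))

  lmt_long <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(time = time), tibble::as_tibble(lmt)),
    -"time", names_to = "muscle", values_to = "l_mt"
  )
  vmt_long <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(time = time), tibble::as_tibble(vmt)),
    -"time", names_to = "muscle", values_to = "v_mt"
  )
  lmt_long <- dplyr::left_join(lmt_long, vmt_long, by = c("time", "muscle"))

  trial <- structure(
    list(
      time = time, angles = angles_long, moments = moments, lmt = lmt_long,
      arms = arms_long,
      events = list(initial_contact = 0, toe_off = toe_frac * T_cycle),
      speed = speed, cycle_duration = T_cycle,
      body_mass = subject$body_mass, height = subject$height,
      emg = emg, truth = list(states = truth_states, emg_gains = gains),
      seed = seed
    ),
    class = "gait_trial"
  )
  if (truth == "minimal_effort") {
    trial <- refine_trial_truth(trial, subject, truth_opts, emg_noise_sd,
                                emg_channels)
  }
  trial
}

# replace the bump ground truth by the minimal-effort solution of the trial
# and rebuild the joint moments from that solution's tendon forces, so the
# stored truth is an exact zero-reserve optimum of the discretized problem
refine_trial_truth <- function(trial, subject, truth_opts, emg_noise_sd,
                               emg_channels) {
  sol <- solve_redundancy(trial, subject$muscles, "PAS", opts = truth_opts)
  muscles <- subject$muscles
  T_cycle <- trial$cycle_duration
  time <- trial$time
  n_grid <- length(time)
  # periodic linear interpolation from mesh nodes to the stored grid
  nodes <- sort(unique(sol$states$time))
  per_muscle <- function(mus, col) {
    s2 <- sol$states[sol$states$muscle == mus, ]
    s2 <- s2[order(s2$time), ]
    stats::approx(c(nodes, T_cycle), c(s2[[col]], s2[[col]][1]),
                  xout = time)$y
  }
  FT <- sapply(muscles$name, function(m) per_muscle(m, "ft_norm"))
  states <- lapply(muscles$name, function(m) {
    tibble::tibble(
      time = time, muscle = m,
      excitation = per_muscle(m, "excitation"),
      activation = per_muscle(m, "activation"),
      lm_norm = per_muscle(m, "lm_norm"),
      v_lopt = per_muscle(m, "v_lopt"),
      ft_norm = FT[, m],
      tendon_force = FT[, m] * muscles$fmax[muscles$name == m]
    )
  })
  trial$truth$states <- dplyr::bind_rows(states)
  # moments from the truth tendon forces (zero-reserve by construction)
  FMAX <- matrix(muscles$fmax, n_grid, nrow(muscles), byrow = TRUE)
  trial$moments <- dplyr::bind_rows(lapply(unique(trial$moments$joint), function(j) {
    rj <- trial$arms[trial$arms$joint == j, ]
    Rj <- matrix(0, n_grid, nrow(muscles), dimnames = list(NULL, muscles$name))
    for (mus in unique(rj$muscle)) Rj[, mus] <- rj$arm[rj$muscle == mus]
    tibble::tibble(time = time, joint = j, moment = rowSums(Rj * FT * FMAX))
  }))
  set.seed(derive_seed(subject$seed, 300 + trial$seed))
  gains <- trial$truth$emg_gains
  trial$emg <- trial$truth$states |>
    dplyr::filter(.data$muscle %in% emg_channels) |>
    dplyr::group_by(.data$muscle) |>
    dplyr::mutate(envelope = pmax(
      .data$excitation * gains[[unique(.data$muscle)]] +
        stats::rnorm(dplyr::n(), 0, emg_noise_sd), 0)) |>
    dplyr::ungroup() |>
    dplyr::select("time", "muscle", "envelope")
  trial
}

#' Process a raw EMG signal into an envelope
#'
#' Standard surface-EMG chain: zero-lag Butterworth band-pass 20-400 Hz
#' (2nd order, applied forward and backward, hence 4th-order effective),
#' full-wave rectification, and a zero-lag 6 Hz low-pass of the same
#' construction.
#'
#' @param x Raw signal.
#' @param fs Sampling frequency, Hz (must exceed 800 Hz so that the 400 Hz
#'   band edge is below Nyquist).
#' @param band Band-pass edges, Hz (default `c(20, 400)`).
#' @param lowpass Envelope low-pass cut-off, Hz (default 6).
#' @return Envelope, same length as `x`.
#' @export
process_emg <- function(x, fs, band = c(20, 400), lowpass = 6) {
  if (fs <= 2 * band[2]) {
    stop("sampling rate too low for the band-pass (need fs > 800 Hz)", call. = FALSE)
  }
  bp <- signal::butter(2, band / (fs / 2), type = "pass")
  rect <- abs(signal::filtfilt(bp, x))
  lp <- signal::butter(2, lowpass / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(lp, rect))
}

#' Synthesize a breath-by-breath gas-exchange series
#'
#' Inverse of the Brockway computation: given a true whole-body metabolic
#' rate, oxygen uptake is chosen so that the Brockway energy of the
#' noiseless series equals the rate exactly at a fixed respiratory exchange
#' ratio, then multiplicative breath noise is applied.
#'
#' @param rate_w True whole-body metabolic power, W (> 0).
#' @param duration Trial duration, s (default 360).
#' @param seed Seed for breath timing and noise.
#' @param rer Respiratory exchange ratio VCO2/VO2 (default 0.85).
#' @param noise_sd Multiplicative breath noise SD (default 0.05; 0 for a
#'   noiseless series).
#' @param breath_interval Mean breath spacing, s (default 4).
#' @return Tibble `time` (s), `vo2`, `vco2` (mL/s).
#' @export
make_gas_exchange <- function(rate_w, duration = 360, seed = 1, rer = 0.85,
                              noise_sd = 0.05, breath_interval = 4) {
  if (rate_w <= 0) stop("rate must be positive", call. = FALSE)
  set.seed(derive_seed(seed, 7))
  vo2 <- rate_w / (16.58 + 4.51 * rer)   # mL/s
  n <- ceiling(duration / breath_interval) + 1
  t <- cumsum(c(0, stats::runif(n - 1, 0.7, 1.3) * breath_interval))
  t <- t[t <= duration]
  noise <- if (noise_sd > 0) stats::rnorm(length(t), 1, noise_sd) else rep(1, length(t))
  tibble::tibble(
    time = t,
    vo2 = pmax(vo2 * noise, 0),
    vco2 = pmax(rer * vo2 * noise, 0)
  )
}
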