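test_that("virtual subjects are deterministic in the seed and vary across seeds", {
  s1 <- make_virtual_subject(5)
  s2 <- make_virtual_subject(5)
  s3 <- make_virtual_subject(6)
  expect_equal(s1$muscles, s2$muscles)
  expect_equal(s1$geometry, s2$geometry)
  expect_false(isTRUE(all.equal(s1$muscles$l_opt, s3$muscles$l_opt)))
})

test_that("moment arms equal minus the length partial derivative", {
  sub <- test_subject()
  q0 <- c(hip = 0.3, knee = 0.5, ankle = -0.1)
  arms <- gaitmet:::subject_arms(sub, rbind(q0))
  eps <- 1e-6
  for (j in sub$dofs) {
    qp <- q0; qp[j] <- qp[j] + eps
    qm <- q0; qm[j] <- qm[j] - eps
    dl <- (gaitmet:::subject_lmt(sub, rbind(qp)) -
             gaitmet:::subject_lmt(sub, rbind(qm))) / (2 * eps)
    expect_equal(as.numeric(-dl), as.numeric(arms[[j]]), tolerance = 1e-7)
  }
})

test_that("every dof is actuated by at least two muscles", {
  sub <- test_subject()
  counts <- table(sub$geometry$joint)
  expect_true(all(counts >= 2))
})

test_that("gait kinematics are cycle-periodic and trials deterministic", {
  sub <- test_subject()
  q0 <- gaitmet:::gait_kinematics(0, 1.3)
  q1 <- gaitmet:::gait_kinematics(1, 1.3)
  expect_equal(as.numeric(q0), as.numeric(q1), tolerance = 1e-10)
  tr <- test_trial()
  tr2 <- make_gait_trial(sub, 1.3, seed = 1)
  expect_equal(tr$moments, tr2$moments)
  expect_equal(tr$truth$emg_gains, tr2$truth$emg_gains)
  expect_error(make_gait_trial(sub, 3.0), "range")
})

test_that("trial moments equal the ground-truth muscle moments (zero reserves)", {
  sub <- test_subject()
  tr <- test_trial()
  FT <- tidyr::pivot_wider(tr$truth$states[, c("time", "muscle", "tendon_force")],
                           names_from = "muscle", values_from = "tendon_force")
  for (j in sub$dofs) {
    mj <- tr$moments[tr$moments$joint == j, ]
    arm_j <- tr$arms[tr$arms$joint == j, ]
    recomputed <- rep(0, length(tr$time))
    for (mus in unique(arm_j$muscle)) {
      recomputed <- recomputed + arm_j$arm[arm_j$muscle == mus] * FT[[mus]]
    }
    expect_equal(mj$moment, recomputed, tolerance = 1e-9)
  }
})

test_that("EMG envelopes are gain-scaled excitations plus noise", {
  tr <- test_trial()
  gains <- tr$truth$emg_gains
  st <- tr$truth$states
  for (mus in c("soleus", "vasti")) {
    env <- tr$emg$envelope[tr$emg$muscle == mus]
    e <- st$excitation[st$muscle == mus]
    expect_lt(sqrt(mean((env - gains[[mus]] * e)^2)), 0.05)
  }
})

test_that("EMG processing chain attenuates out-of-band content", {
  fs <- 2000
  t <- seq(0, 2, by = 1 / fs)
  expect_equal(process_emg(rep(0, length(t)), fs), rep(0, length(t)))
  # 5 Hz sits below the band-pass; 100 Hz passes
  low <- process_emg(sin(2 * pi * 5 * t), fs)
  carrier <- process_emg(sin(2 * pi * 100 * t), fs)
  mid <- seq(round(0.5 * fs), round(1.5 * fs))
  expect_lt(20 * log10(mean(low[mid]) / mean(carrier[mid])), -20)
  # amplitude-modulated carrier: envelope tracks the modulator
  mod <- 0.5 + 0.3 * sin(2 * pi * 1 * t)
  env <- process_emg(mod * sin(2 * pi * 100 * t), fs)
  scale <- mean(env[mid]) / mean(mod[mid])
  expect_lt(max(abs(env[mid] / scale - mod[mid]) / mod[mid]), 0.05)
  expect_error(process_emg(t, 500), "sampling")
})

test_that("minimal-effort truth is exactly consistent with the trial moments", {
  tr <- test_trial_me()
  sub <- test_subject()
  FT <- tidyr::pivot_wider(tr$truth$states[, c("time", "muscle", "tendon_force")],
                           names_from = "muscle", values_from = "tendon_force")
  for (j in sub$dofs) {
    mj <- tr$moments[tr$moments$joint == j, ]
    arm_j <- tr$arms[tr$arms$joint == j, ]
    recomputed <- rep(0, length(tr$time))
    for (mus in unique(arm_j$muscle)) {
      recomputed <- recomputed + arm_j$arm[arm_j$muscle == mus] * FT[[mus]]
    }
    expect_equal(mj$moment, recomputed, tolerance = 1e-9)
  }
})
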