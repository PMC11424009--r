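# Dynamic redundancy solver tests. The heavier fixtures (subject, trial with
# minimal-effort truth, and its solution) are cached across files.

test_that("zero moments with no passive force range give floor activations", {
  sub <- test_subject()
  tr <- test_trial()
  tr$moments$moment <- 0
  mus <- sub$muscles
  mus$s0 <- 3   # passive onset far beyond the operating range
  s <- solve_redundancy(tr, mus, "PAS", opts = list(maxiter = 150))
  # activations sit at the floor except where the fiber-velocity limit
  # during fast swing motion demands a little tendon-force modulation
  expect_lt(stats::median(s$states$activation), 0.005)
  expect_lt(stats::quantile(s$states$activation, 0.99), 0.05)
  expect_lt(max(abs(s$reserves$tau_res)), 1)   # N*m, on ~100 N*m demands
})

test_that("minimal-effort truth is recovered on the synthetic trial", {
  tr <- test_trial_me()
  s <- test_solution()
  expect_true(s$status$converged || s$status$capped)
  nodes <- sort(unique(s$states$time))
  truth <- tr$truth$states |>
    dplyr::group_by(.data$muscle) |>
    dplyr::reframe(a_true = stats::approx(.data$time, .data$activation,
                                          xout = nodes)$y,
                   time = nodes)
  cmp <- dplyr::inner_join(s$states, truth, by = c("time", "muscle"))
  expect_lt(sqrt(mean((cmp$activation - cmp$a_true)^2)), 0.03)
  # moments reproduced without leaning on reserves
  expect_lt(max(s$reserve_report$reserve_share), 0.01)
})

test_that("moment balance residual is tiny for a converged solution and reacts to perturbation", {
  sub <- test_subject()
  tr <- test_trial_me()
  s <- test_solution()
  mb <- moment_balance_residual(s, tr, sub$muscles)
  peak <- max(abs(s$reserves$tau_id))
  expect_lt(max(mb$max_abs_residual), 0.02 * peak)
  s2 <- s
  soleus <- s2$states$muscle == "soleus"
  s2$states$activation[soleus] <- pmin(s2$states$activation[soleus] + 0.1, 1)
  mb2 <- moment_balance_residual(s2, tr, sub$muscles)
  expect_gt(mb2$max_abs_residual[mb2$joint == "ankle"],
            mb$max_abs_residual[mb$joint == "ankle"])
})

test_that("solutions are stable under mesh refinement from 50 to 100 intervals", {
  sub <- test_subject()
  tr <- test_trial_me()
  s50 <- test_solution()
  s100 <- solve_redundancy(tr, sub$muscles, "PAS", opts = list(n_mesh = 100))
  a100 <- s100$states |>
    dplyr::group_by(.data$muscle) |>
    dplyr::reframe(a100 = stats::approx(.data$time, .data$activation,
                                        xout = sort(unique(s50$states$time)))$y,
                   time = sort(unique(s50$states$time)))
  cmp <- dplyr::inner_join(s50$states, a100, by = c("time", "muscle"))
  expect_lt(sqrt(mean((cmp$activation - cmp$a100)^2)), 0.03)
})

test_that("freeing tendon stiffness cannot worsen the optimum", {
  sub <- test_subject()
  tr <- test_trial_me()
  gen <- test_solution()   # k_t frozen at the generic value
  per <- personalize_tendon_stiffness(list(tr), sub$muscles,
                                      groups = list(achilles = c("gastroc", "soleus")),
                                      sweeps = 1, tol = 2)
  expect_lte(per$objective, gen$objective$deviance * (1 + 1e-6))
  expect_true(all(per$k_t >= 15 & per$k_t <= 45))
  expect_true(all(c("gastroc", "soleus") %in% names(per$k_t_muscle)))
})

test_that("EMG workflow keeps tracked excitations inside the scaled corridor", {
  sub <- test_subject()
  tr <- test_trial_me()
  s <- cached("emg_solution",
              solve_redundancy(tr, sub$muscles, "EMG", emg = tr$emg))
  env <- tr$emg |>
    dplyr::group_by(.data$muscle) |>
    dplyr::reframe(env = stats::approx(.data$time, .data$envelope,
                                       xout = sort(unique(s$states$time)),
                                       rule = 2)$y,
                   time = sort(unique(s$states$time)))
  cmp <- dplyr::inner_join(s$states, env, by = c("time", "muscle"))
  cmp$gain <- s$emg_gains[cmp$muscle]
  dev <- abs(cmp$excitation - cmp$gain * cmp$env)
  # the corridor is enforced by penalty; excess beyond the bound should be
  # on the order of the envelope noise, not of the excitations themselves
  expect_lt(mean(pmax(dev - 0.01, 0)), 0.005)
  expect_lt(max(dev), 0.06)
  expect_error(solve_redundancy(tr, sub$muscles, "EMG", emg = tr$emg[0, ]),
               "EMG channel")
})

test_that("solution accessors and tidiers expose consistent views", {
  s <- test_solution()
  td <- tidy(s)
  expect_identical(td, s$states)
  gl <- glance(s)
  expect_equal(gl$workflow, "PAS")
  expect_s3_class(autoplot(s), "ggplot")
})
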