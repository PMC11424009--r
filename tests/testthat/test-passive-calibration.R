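calibration_grids <- list(
  hip = seq(-0.4, 1.0, length.out = 15),
  knee = seq(0.0, 1.6, length.out = 15),
  ankle = seq(-0.5, 0.5, length.out = 15)
)

make_targets <- function(subject, muscles) {
  dplyr::bind_rows(lapply(subject$dofs, function(j) {
    simulate_passive_joint_moment(subject, muscles, j, calibration_grids[[j]])
  }))
}

test_that("passive joint moments superpose over muscles and vanish without passive force", {
  sub <- test_subject()
  mus <- sub$muscles
  # push the onset length beyond the operating range: no passive force
  mus0 <- mus; mus0$s0 <- 3
  m0 <- simulate_passive_joint_moment(sub, mus0, "knee", calibration_grids$knee)
  expect_equal(m0$moment, rep(0, 15))
  # superposition: sum of single-muscle curves equals the full curve
  full <- simulate_passive_joint_moment(sub, mus, "ankle", calibration_grids$ankle)
  parts <- Reduce(`+`, lapply(seq_len(nrow(mus)), function(i) {
    simulate_passive_joint_moment(sub, mus[i, ], "ankle", calibration_grids$ankle)$moment
  }))
  expect_equal(full$moment, parts, tolerance = 1e-12)
  expect_error(simulate_passive_joint_moment(sub, mus, "elbow", 0:1), "unknown joint")
  expect_error(simulate_passive_joint_moment(sub, mus, "knee", c(1, 0)), "increasing")
})

test_that("single-muscle rigid-tendon moment equals the pointwise product", {
  sub <- test_subject()
  p <- sub$muscles[sub$muscles$name == "soleus", ]
  angles <- c(0.1, 0.3, 0.5)
  out <- simulate_passive_joint_moment(sub, p, "ankle", angles)
  q <- matrix(rep(unlist(sub$q_ref), each = 3), 3, 3,
              dimnames = list(NULL, sub$dofs))
  q[, "ankle"] <- angles
  lmt <- gaitmet:::subject_lmt(sub, q)[, "soleus"]
  r <- gaitmet:::subject_arms(sub, q)$ankle[, "soleus"]
  u <- lmt - p$l_slack
  l_m <- sqrt(u^2 + (p$l_opt * sin(p$alpha_opt))^2)
  expected <- r * p$fmax * eval_passive_force(l_m / p$l_opt, p) * (u / l_m)
  expect_equal(out$moment, expected, tolerance = 1e-12)
})

test_that("calibration is self-consistent and recovers known parameters", {
  sub <- test_subject()
  mus <- sub$muscles
  # self-consistency: targets from the generic defaults themselves
  targets <- make_targets(sub, mus)
  cal0 <- calibrate_passive_params(targets, sub, mus, n_starts = 2, seed = 1)
  expect_lt(abs(cal0$parameters$k_pe - 4) / 4, 0.01)
  expect_lt(abs(cal0$parameters$s0 - 1) / 1, 0.01)
  # recovery of shifted parameters
  truth <- mus; truth$k_pe <- 3.2; truth$s0 <- 1.08
  targets2 <- make_targets(sub, truth)
  cal <- calibrate_passive_params(targets2, sub, mus, n_starts = 3, seed = 2)
  expect_lt(abs(cal$parameters$k_pe - 3.2) / 3.2, 0.05)
  expect_lt(abs(cal$parameters$s0 - 1.08) / 1.08, 0.05)
  expect_true(all(cal$report$rmse_after <= cal$report$rmse_before + 1e-9))
  expect_lte(cal$objective, cal$objective_before)
})

test_that("calibration tolerates target noise (Monte-Carlo)", {
  sub <- test_subject()
  mus <- sub$muscles
  truth <- mus; truth$k_pe <- 3.2; truth$s0 <- 1.08
  targets <- make_targets(sub, truth)
  peak <- max(abs(targets$moment))
  set.seed(33)
  errs <- t(vapply(1:20, function(i) {
    noisy <- targets
    noisy$moment <- noisy$moment + stats::rnorm(nrow(noisy), 0, 0.02 * peak)
    cal <- calibrate_passive_params(noisy, sub, mus, n_starts = 2, seed = i)
    c(abs(cal$parameters$k_pe - 3.2) / 3.2, abs(cal$parameters$s0 - 1.08) / 1.08)
  }, numeric(2)))
  expect_lt(stats::median(errs[, 1]), 0.10)
  expect_lt(stats::median(errs[, 2]), 0.10)
})

test_that("muscles in one calibration group share parameters", {
  sub <- test_subject()
  mus <- sub$muscles
  groups <- tibble::tibble(muscle = mus$name,
                           group = ifelse(mus$name %in% c("soleus", "gastroc", "tibant"),
                                          "ankle", "proximal"))
  truth <- mus; truth$k_pe <- 3.5; truth$s0 <- 1.05
  targets <- make_targets(sub, truth)
  cal <- calibrate_passive_params(targets, sub, mus, groups = groups,
                                  n_starts = 2, seed = 3)
  upd <- cal$muscles
  for (g in unique(groups$group)) {
    members <- groups$muscle[groups$group == g]
    expect_equal(length(unique(upd$k_pe[upd$name %in% members])), 1L)
    expect_equal(length(unique(upd$s0[upd$name %in% members])), 1L)
  }
})
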