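test_that("Brockway rate is the configured linear combination", {
  expect_equal(brockway_rate(0, 0), 0)
  expect_equal(brockway_rate(5, 4.1667), 16.58 * 5 + 4.51 * 4.1667)
  expect_equal(brockway_rate(2, 1.7), 2 * brockway_rate(1, 0.85))
  expect_error(brockway_rate(-1, 0), "non-negative")
})

test_that("representative gas value averages the final window", {
  s <- tibble::tibble(time = seq(0, 360, by = 2), vo2 = 5, vco2 = 4)
  expect_equal(representative_gas_value(s)$vo2, 5)
  # step series: only the final plateau enters the window
  s2 <- tibble::tibble(time = seq(0, 360, by = 1),
                       vo2 = ifelse(seq(0, 360, by = 1) < 180, 300, 400),
                       vco2 = 0)
  expect_equal(representative_gas_value(s2)$vo2, 400)
  # linear ramp: closed-form mean over [180, 360]
  s3 <- tibble::tibble(time = seq(0, 360, by = 1), vo2 = seq(0, 360, by = 1),
                       vco2 = 0)
  expect_equal(representative_gas_value(s3)$vo2, mean(180:360))
  expect_error(representative_gas_value(s[s$time < 100, ]), "window")
})

test_that("whole-body average doubles one leg, normalizes, adds basal", {
  tgrid <- seq(0, 1, by = 0.01)
  met0 <- tibble::tibble(time = tgrid, muscle = "m", e_dot = 0)
  expect_equal(whole_body_average(met0, body_mass = 70), 1.2)
  # one-leg sum at 1.5 W/kg -> 2 * 1.5 + 1.2
  met1 <- tibble::tibble(time = tgrid, muscle = "m", e_dot = 1.5 * 70)
  expect_equal(whole_body_average(met1, 70), 4.2)
  # quadrature vs closed-form integral of a sinusoid
  tg <- seq(0, 1, length.out = 1000)
  met2 <- tibble::tibble(time = tg, muscle = "m", e_dot = 50 * (1 + sin(2 * pi * tg)))
  expect_equal(whole_body_average(met2, 70, basal = 0), 2 * 50 / 70,
               tolerance = 1e-6)
  expect_error(whole_body_average(met1, 0), "positive")
})

test_that("biarticular attribution follows the moment-arm ratio and conserves energy", {
  tgrid <- c(0, 0.5, 1)
  met <- tibble::tibble(time = rep(tgrid, 2),
                        muscle = rep(c("gastroc", "soleus"), each = 3),
                        e_dot = rep(c(10, 8), each = 3))
  arms <- tidyr::expand_grid(time = tgrid,
                             tibble::tribble(
                               ~muscle, ~joint, ~arm,
                               "gastroc", "ankle", -0.05,
                               "gastroc", "knee", 0.02,
                               "soleus", "ankle", -0.042
                             ))
  att <- split_biarticular(met, arms)
  g_ankle <- att$e_dot[att$muscle == "gastroc" & att$joint == "ankle"]
  g_knee <- att$e_dot[att$muscle == "gastroc" & att$joint == "knee"]
  expect_equal(g_ankle, rep(10 * 0.05 / 0.07, 3), tolerance = 1e-12)
  expect_equal(g_knee, rep(10 * 0.02 / 0.07, 3), tolerance = 1e-12)
  expect_equal(att$e_dot[att$muscle == "soleus"], rep(8, 3))
  # conservation: attributed shares sum to each muscle's rate
  sums <- att |>
    dplyr::group_by(.data$time, .data$muscle) |>
    dplyr::summarise(tot = sum(.data$e_dot), .groups = "drop")
  expect_equal(sums$tot, met$e_dot[order(met$time, met$muscle)], tolerance = 1e-12)
})

test_that("near-zero arms fall back to the cycle-average ratio", {
  tgrid <- c(0, 1)
  met <- tibble::tibble(time = tgrid, muscle = "biart", e_dot = c(6, 6))
  arms <- tibble::tibble(
    time = rep(tgrid, each = 2),
    muscle = "biart",
    joint = rep(c("a", "b"), 2),
    arm = c(0.03, 0.01, 0, 0)   # degenerate at t = 1
  )
  att <- split_biarticular(met, arms)
  expect_true(all(att$fallback[att$time == 1]))
  expect_equal(sum(att$e_dot[att$time == 1]), 6, tolerance = 1e-12)
  expect_equal(att$e_dot[att$time == 1 & att$joint == "a"], 6 * 0.75)
})

test_that("group rates sum members, shares sum to 100, order-invariant", {
  tgrid <- seq(0, 1, by = 0.25)
  att <- tidyr::expand_grid(time = tgrid,
                            tibble::tribble(
                              ~muscle, ~joint, ~e_dot,
                              "soleus", "ankle", 5,
                              "gastroc", "ankle", 3,
                              "vasti", "knee", 4
                            ))
  groups <- tibble::tribble(
    ~muscle, ~joint, ~group,
    "soleus", "ankle", "plantarflexors",
    "gastroc", "ankle", "plantarflexors",
    "vasti", "knee", "knee extensors"
  )
  out <- muscle_group_rates(att, groups)
  expect_equal(sum(out$shares$share), 100)
  pf <- out$series$e_dot[out$series$group == "plantarflexors"]
  expect_equal(pf, rep(8, length(tgrid)))
  out2 <- muscle_group_rates(att[order(att$muscle), ], groups)
  expect_equal(dplyr::arrange(out$shares, .data$group),
               dplyr::arrange(out2$shares, .data$group))
  expect_error(muscle_group_rates(att, groups[-1, ]), "unmapped")
})

test_that("phase costs integrate stance and swing and sum to 100", {
  tgrid <- seq(0, 1, by = 0.001)
  # uniform rate: shares proportional to durations
  ph <- phase_relative_cost(tgrid, rep(2, length(tgrid)), toe_off = 0.6)
  expect_equal(ph$stance, 60, tolerance = 1e-9)
  expect_equal(ph$stance + ph$swing, 100, tolerance = 1e-9)
  # piecewise-constant 2 W stance / 1 W swing, toe-off 60% -> 75 / 25
  e <- ifelse(tgrid <= 0.6, 2, 1)
  ph2 <- phase_relative_cost(tgrid, e, 0.6)
  expect_equal(ph2$stance, 75, tolerance = 0.1)
  # rate only during swing
  e3 <- ifelse(tgrid > 0.6, 1, 0)
  ph3 <- phase_relative_cost(tgrid, e3, 0.6)
  expect_equal(ph3$swing, 100, tolerance = 1e-9)
  expect_error(phase_relative_cost(tgrid, e, 1.5), "inside")
})

test_that("anthropometric forces follow the configured regression", {
  fr <- tibble::tibble(name = c("a", "b"), fraction = c(0.1, 0.2))
  lo <- c(0.05, 0.1)
  out <- compute_max_isometric_force(71.3, 1.74, fr, lo)
  total <- 47.0 * 71.3 * 1.74 + 1285
  expect_equal(out$volume_cm3, c(0.1, 0.2) * total)
  expect_equal(out$fmax, 6e5 * (c(0.1, 0.2) * total * 1e-6) / lo)
  expect_equal(out$muscle_mass, c(0.1, 0.2) * total * 1e-6 * 1059.7)
  # doubling specific tension doubles every fmax; zero fraction -> zero force
  out2 <- compute_max_isometric_force(71.3, 1.74, fr, lo, specific_tension = 1.2e6)
  expect_equal(out2$fmax, 2 * out$fmax)
  fr0 <- tibble::tibble(name = "a", fraction = 0)
  expect_equal(compute_max_isometric_force(70, 1.7, fr0, 0.05)$fmax, 0)
  expect_error(compute_max_isometric_force(-1, 1.7, fr, lo), "positive")
})

test_that("gas-exchange round trip recovers a known rate", {
  # noiseless: exact inverse of the Brockway computation
  g <- make_gas_exchange(300, duration = 360, seed = 3, noise_sd = 0)
  rep_g <- representative_gas_value(g)
  expect_equal(brockway_rate(rep_g$vo2, rep_g$vco2), 300, tolerance = 1e-9)
  # noisy: 3-minute averaging keeps most replicates within 2%
  ok <- vapply(1:100, function(i) {
    g <- make_gas_exchange(300, seed = i, noise_sd = 0.05)
    r <- representative_gas_value(g)
    abs(brockway_rate(r$vo2, r$vco2) - 300) / 300 < 0.02
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  # linearity at fixed exchange ratio
  g2 <- make_gas_exchange(600, duration = 360, seed = 3, noise_sd = 0)
  expect_equal(g2$vo2[1], 2 * g$vo2[1], tolerance = 1e-12)
})
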