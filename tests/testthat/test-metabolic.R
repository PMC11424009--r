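test_that("negative-rate modification zeroes negative totals and leaves others", {
  # eccentric balance: -5 + 2 + 0 < 0 -> heat raised to 3, total 0
  expect_equal(apply_negative_rate_modification(-5, 2, 0), 3)
  # already non-negative: untouched
  expect_equal(apply_negative_rate_modification(4, 2, 1), 1)
  set.seed(11)
  w <- stats::runif(1e4, -100, 100)
  h_am <- stats::runif(1e4, 0, 50)
  h_sl <- stats::runif(1e4, -50, 50)
  mod <- apply_negative_rate_modification(w, h_am, h_sl)
  total <- w + h_am + mod
  expect_true(all(total >= -1e-12))
  ok <- (w + h_am + h_sl) >= 0
  expect_identical(mod[ok], h_sl[ok])
})

test_that("efficiency is the guarded work-to-rate ratio", {
  expect_equal(energy_efficiency(0, 50), 0)
  expect_equal(energy_efficiency(10, 40), 0.25)
  expect_equal(energy_efficiency(5, 0), 0)
})

test_that("total rate decomposes additively for every model", {
  p <- soleus_params()
  for (mo in metabolic_model_ids()) {
    s <- characterize_model_surfaces(mo, p, activation = c(0.2, 0.7),
                                     lm_norm = c(0.9, 1.1),
                                     v_norm = seq(-0.8, 0.8, by = 0.2))
    expect_equal(s$e_dot, s$w_ce + s$h_a + s$h_m + s$h_sl, tolerance = 1e-12)
  }
})

test_that("soleus model ordering during shortening, isometric and lengthening", {
  p <- soleus_params()
  rate <- function(mo, v) {
    characterize_model_surfaces(mo, p, activation = 0.5, lm_norm = 1,
                                v_norm = v)$e_dot
  }
  short <- vapply(metabolic_model_ids(), rate, numeric(1), v = -0.5)
  iso <- vapply(metabolic_model_ids(), rate, numeric(1), v = 0)
  leng <- vapply(metabolic_model_ids(), rate, numeric(1), v = 0.5)
  # shortening: LW07 > BH04 > HO06 > UC16, with UM03 = UM10
  expect_true(short[["LW07"]] > short[["BH04"]])
  expect_true(short[["BH04"]] > short[["HO06"]])
  expect_true(short[["HO06"]] > short[["UC16"]])
  expect_equal(short[["UM03"]], short[["UM10"]], tolerance = 1e-12)
  # isometric: LW07 > BH04 > UM03 = UM10 > UC16 > HO06
  expect_true(iso[["LW07"]] > iso[["BH04"]])
  expect_true(iso[["BH04"]] > iso[["UM03"]])
  expect_equal(iso[["UM03"]], iso[["UM10"]], tolerance = 1e-12)
  expect_true(iso[["UM03"]] > iso[["UC16"]])
  expect_true(iso[["UC16"]] > iso[["HO06"]])
  # lengthening: zero for the modified models, positive UM10, negative LW07
  for (mo in c("UM03", "BH04", "HO06", "UC16")) {
    expect_equal(leng[[mo]], 0, tolerance = 1e-9)
  }
  expect_gt(leng[["UM10"]], 0)
  expect_lt(leng[["LW07"]], 0)
})

test_that("isometric states have zero work and shortening heat", {
  p <- soleus_params()
  for (mo in metabolic_model_ids()) {
    cc <- metabolic_model_constants(mo)
    s <- gaitmet:::metabolic_rate_core(mo, 0.6, 0.6, 1, 0, p)
    expect_equal(s$w_ce, 0)
    if (mo %in% c("UM03", "UM10", "UC16")) {
      # heat floor may lift h_sl; below the floor assertion is on the raw term
      expect_gte(s$h_sl, 0)
    } else {
      expect_equal(s$h_sl, 0)
    }
    expect_equal(s$e_dot, s$h_a + s$h_m + s$h_sl)
  }
})

test_that("heats scale with muscle mass except for LW07", {
  p1 <- soleus_params()
  p2 <- p1; p2$muscle_mass <- 2 * p1$muscle_mass
  for (mo in metabolic_model_ids()) {
    a <- gaitmet:::metabolic_rate_core(mo, 0.6, 0.6, 1.0, 0, p1)
    b <- gaitmet:::metabolic_rate_core(mo, 0.6, 0.6, 1.0, 0, p2)
    if (mo == "LW07") {
      expect_equal(b$e_dot, a$e_dot)
    } else {
      # isometric state: all heat terms are mass-proportional
      expect_equal(b$h_a + b$h_m + b$h_sl, 2 * (a$h_a + a$h_m + a$h_sl),
                   tolerance = 1e-12)
    }
  }
})

test_that("LW07 efficiency is activation-invariant; mass-dependent models need mass", {
  p <- soleus_params()
  eff <- vapply(c(0.2, 0.5, 1), function(a) {
    s <- gaitmet:::metabolic_rate_core("LW07", a, a, 1, -3, p)
    energy_efficiency(s$w_ce, s$e_dot)
  }, numeric(1))
  expect_lt(diff(range(eff)), 1e-12)
  p_nomass <- p; p_nomass$muscle_mass <- NA_real_
  expect_error(gaitmet:::metabolic_rate_core("UM03", 0.5, 0.5, 1, 0, p_nomass),
               "muscle_mass")
  expect_silent(gaitmet:::metabolic_rate_core("LW07", 0.5, 0.5, 1, 0, p_nomass))
})

test_that("compute_metabolic_rates maps a solution to per-muscle trajectories", {
  states <- tidyr::expand_grid(
    time = seq(0, 1, by = 0.1), muscle = "soleus"
  ) |>
    dplyr::mutate(excitation = 0.5, activation = 0.5, lm_norm = 1,
                  v_lopt = sin(2 * pi * time))
  met <- compute_metabolic_rates("BH04", states, soleus_params())
  expect_s3_class(met, "metabolic_trajectory")
  expect_equal(nrow(met), 11)
  expect_equal(met$e_dot, met$w_ce + met$h_a + met$h_m + met$h_sl)
  expect_error(compute_metabolic_rates("BH04", states, soleus_params()[0, ]),
               "no parameters")
})
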