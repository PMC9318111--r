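# Frozen reference values computed with an independent fixed-step RK4
# integration (1e5 steps per phase) of the two clearance equations for
# measured (Kp, K, Cv) triples under the standard in-use configuration.
caf_stratm <- list(Kp = 1.23e-3, K = 0.422, Cv = 1.00e4,
                   Mteva = 85.74863658, M1 = 14.25136342,
                   Msc_teva = 6.673907163, Msc_end = 6.528753e-06,
                   M2 = 6.673900634, ratio = 0.2092526405)
mp_stratm <- list(Kp = 5.20e-3, K = 3.08, Cv = 1.39e3,
                  M2 = 2.766067301, ratio = 0.6769518708)
ka_porcine <- list(Kp = 1.30e-3, K = 0.108, Cv = 1.04e4,
                   ratio = 0.1679560509)

test_that("phase-1 depletion matches identities and the reference value", {
  cfg <- std_cfg()
  expect_equal(msur_sc_at(0, 100, 1.23e-3, cfg), 100)          # t = 0
  expect_equal(msur_sc_at(1.2, 100, 0, cfg), 100)              # Kp = 0
  expect_equal(msur_sc_at(1.5, 100, caf_stratm$Kp, cfg),
               caf_stratm$Mteva, tolerance = 1e-8)
  expect_error(msur_sc_at(2.0, 100, 1e-3, cfg), "within")      # t > Teva
})

test_that("M1 vanishes without permeation or evaporation window", {
  expect_equal(m1_absorbed(100, 0, std_cfg()), 0)
  expect_equal(m1_absorbed(100, 1e-3, std_cfg(Teva = 0)), 0)
  expect_equal(m1_absorbed(100, caf_stratm$Kp, std_cfg()),
               caf_stratm$M1, tolerance = 1e-8)
})

test_that("SC depot at Teva follows the K-weighted partition split", {
  cfg <- std_cfg()
  expect_equal(msc_at_teva(100, 1e-3, 0, cfg), 0)              # K = 0
  expect_equal(msc_at_teva(100, 1e-3, Inf, cfg),               # K -> Inf
               msur_sc_at(cfg$Teva, 100, 1e-3, cfg))
  expect_equal(msc_at_teva(100, caf_stratm$Kp, caf_stratm$K, cfg),
               caf_stratm$Msc_teva, tolerance = 1e-8)
})

test_that("phase-2 clearance of the SC depot", {
  expect_equal(msc_at_end(5, 1e-3, std_cfg(Teva = 24, t_end = 24)), 5)
  expect_equal(msc_at_end(5, 0, std_cfg()), 5)
  expect_equal(msc_at_end(caf_stratm$Msc_teva, caf_stratm$Kp, std_cfg()),
               caf_stratm$Msc_end, tolerance = 1e-6)
  # huge exponent underflows cleanly to complete clearance
  expect_equal(msc_at_end(5, 0.2, std_cfg()), 0)
})

test_that("M2 equals the depot difference and the reference values", {
  cfg <- std_cfg()
  expect_equal(m2_absorbed(100, 1e-3, 0.5, std_cfg(Teva = 24, t_end = 24)), 0)
  expect_equal(m2_absorbed(100, 1e-3, 0, cfg), 0)
  expect_equal(m2_absorbed(100, caf_stratm$Kp, caf_stratm$K, cfg),
               caf_stratm$M2, tolerance = 1e-8)
  M0 <- 0.01 * mp_stratm$Cv
  expect_equal(m2_absorbed(M0, mp_stratm$Kp, mp_stratm$K, cfg),
               mp_stratm$M2, tolerance = 1e-8)
  msc <- msc_at_teva(M0, mp_stratm$Kp, mp_stratm$K, cfg)
  expect_identical(m2_absorbed(M0, mp_stratm$Kp, mp_stratm$K, cfg),
                   msc - msc_at_end(msc, mp_stratm$Kp, cfg))
})

test_that("absorption prediction reproduces reference ratios", {
  for (case in list(caf_stratm, mp_stratm, ka_porcine)) {
    p <- predict_absorption(case$Kp, case$K, case$Cv)
    expect_equal(p$ratio, case$ratio, tolerance = 1e-8)
    expect_equal(p$M0, 0.01 * case$Cv)
  }
})

test_that("prediction accepts a fitted permeation model", {
  prof <- simulate_permeation_profile(Kp = 1e-2, K = 1.5, Cv = 1.83e3,
                                      L = 0.03, times = c(4, 6, 8))
  fit <- fit_permeation(prof)
  p <- predict_absorption(fit)
  expect_equal(p$ratio,
               predict_absorption(fit$Kp, fit$K, 1.83e3)$ratio)
})

test_that("zero permeability gives zero absorption and full conservation", {
  p <- predict_absorption(0, 0.5, 1e4)
  expect_equal(p$ratio, 0)
  expect_equal(p$total, 0)
  expect_equal(p$Msc_at_end + p$surface_residue, p$M0)
})

test_that("mass balance closes exactly on a parameter grid", {
  g <- absorption_grid()
  for (i in seq_len(nrow(g))) {
    cfg <- std_cfg(Teva = g$Teva[i])
    p <- predict_absorption(g$Kp[i], g$K[i], 1e4, cfg)
    expect_lt(abs(p$M1 + p$M2 + p$Msc_at_end + p$surface_residue - p$M0) /
                p$M0, 1e-9)
    expect_true(p$ratio >= 0 && p$ratio <= 1)
    expect_true(all(c(p$M1, p$M2, p$Msc_at_end, p$surface_residue) >= 0))
  }
})

test_that("absorption is monotone in Kp and K", {
  kps <- 10^seq(-5, log10(5e-2), length.out = 8)
  ks <- 10^seq(-3, log10(5), length.out = 8)
  for (te in c(0.5, 1.5, 6)) {
    cfg <- std_cfg(Teva = te)
    tot_kp <- vapply(kps, function(kp)
      predict_absorption(kp, 0.5, 1e4, cfg)$total, 0)
    expect_true(all(diff(tot_kp) > 0))
    tot_k <- vapply(ks, function(k)
      predict_absorption(1e-3, k, 1e4, cfg)$total, 0)
    expect_true(all(diff(tot_k) >= 0))
  }
})

test_that("the K -> Inf limit sends the partition fraction to one", {
  cfg <- std_cfg()
  p <- predict_absorption(1e-3, Inf, 1e4, cfg)
  M0 <- p$M0
  rate1 <- 1e-3 * cfg$A / (cfg$V + cfg$Vsc)
  rate2 <- 1e-3 * cfg$A / cfg$Vsc
  expect_equal(p$surface_residue, 0)
  expect_equal(p$total,
               M0 * (1 - exp(-rate1 * cfg$Teva) *
                       exp(-rate2 * (cfg$t_end - cfg$Teva))))
})

test_that("numerical integrator is convergent and matches closed form", {
  a <- ode_absorption(1.23e-3, 0.422, 1e4, n_steps = 4000)
  b <- ode_absorption(1.23e-3, 0.422, 1e4, n_steps = 2000)
  expect_lt(rel_diff(a$ratio, b$ratio), 1e-8)        # 4th-order convergence
  z <- ode_absorption(0, 0.5, 1e4)
  expect_equal(z$total, 0)
  expect_equal(z$ratio, 0)
  p <- predict_absorption(1.23e-3, 0.422, 1e4)
  expect_lt(rel_diff(p$ratio, a$ratio), 1e-6)
})

test_that("configuration validation rejects impossible setups", {
  expect_error(finite_dose_config(Teva = 30, t_end = 24), "exceed")
  expect_error(finite_dose_config(Vsc = 0), "positive")
  expect_error(predict_absorption(-1e-3, 0.5, 1e4), "non-negative")
  expect_error(predict_absorption(1e-3, -0.5, 1e4), "non-negative")
})
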