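skin <- membrane_spec("porcine_skin", L = 0.10)
stratm <- membrane_spec("strat_m", L = 0.03)

test_that("steady-state fit recovers slope and x-intercept exactly on a line", {
  p <- permeation_profile(c(2, 4, 6, 8), c(5, 15, 25, 35), Cv = 1e4,
                          membrane = skin)
  ss <- fit_steady_state(p)
  expect_equal(ss$Flux, 5.0)
  expect_equal(ss$Tlag, 1.0)
  expect_equal(ss$r2, 1.0)
  expect_equal(ss$n_points, 4L)
})

test_that("steady-state flux from a series-solution profile approaches Kp*Cv", {
  prof <- simulate_permeation_profile(Kp = 2.0e-3, K = 0.5, Cv = 1.0e4,
                                      membrane = stratm, times = c(4, 6, 8))
  ss <- fit_steady_state(prof)     # strat_m default keeps t >= 4
  expect_lt(abs(ss$Flux - 20) / 20, 0.02)
})

test_that("degenerate and invalid windows are rejected", {
  flat <- permeation_profile(c(2, 4), c(10, 10), Cv = 1e4, membrane = skin)
  expect_error(fit_steady_state(flat), "no positive steady-state flux")
  p <- permeation_profile(c(2, 4, 6, 8), c(5, 15, 25, 35), Cv = 1e4,
                          membrane = skin)
  expect_error(fit_steady_state(p, window = 2L), "at least two")
  expect_error(fit_steady_state(p, window = c(1L, 9L)), "out of range")
})

test_that("parameter relations match hand arithmetic", {
  expect_equal(compute_kp(23.2, 1.00e4), 2.32e-3)
  expect_equal(compute_kp(0, 1e4), 0)
  expect_equal(compute_kp(1.83, 1.83e3), 1.0e-3)
  expect_error(compute_kp(1, 0), "positive")

  expect_equal(compute_D(0.03, 1.0), 1.5e-4)
  expect_equal(compute_D(0.10, 1.3846), 1.2037170e-3, tolerance = 1e-7)
  expect_equal(compute_D(0.06, 1.0) / compute_D(0.03, 1.0), 4)  # L^2 scaling
  expect_error(compute_D(0.03, 0), "non-positive")
  expect_error(compute_D(0.03, -1), "non-positive")

  expect_equal(compute_K(1.3846, 1.30e-3, 0.10), 0.1079988, tolerance = 1e-7)
  expect_equal(compute_K(0, 1e-3, 0.1), 0)
  expect_error(compute_K(1, 1e-3, 0), "positive")
})

test_that("Kp = K*D/L identity holds for any positive inputs", {
  set.seed(11)
  for (i in 1:25) {
    Tlag <- runif(1, 0.1, 3); F <- runif(1, 1, 50)
    Cv <- runif(1, 1e3, 1e4); L <- runif(1, 0.02, 0.2)
    Kp <- compute_kp(F, Cv)
    expect_equal(compute_K(Tlag, Kp, L) * compute_D(L, Tlag) / L, Kp,
                 tolerance = 1e-12)
  }
})

test_that("full fit recovers generating parameters from a noiseless profile", {
  prof <- simulate_permeation_profile(Kp = 1.0e-2, K = 1.5, Cv = 1.83e3,
                                      membrane = stratm, times = c(4, 6, 8))
  fit <- fit_permeation(prof)
  expect_s3_class(fit, "perm_fit")
  expect_lt(abs(fit$Kp - 1.0e-2) / 1.0e-2, 0.02)
  expect_lt(abs(fit$K - 1.5) / 1.5, 0.05)
  expect_lt(abs(fit$D - 1.0e-2 * 0.03 / 1.5) / (1.0e-2 * 0.03 / 1.5), 0.05)
  expect_equal(fit$Flux, fit$Kp * prof$Cv, tolerance = 1e-9)
  expect_equal(fit$Kp, fit$K * fit$D / stratm$L, tolerance = 1e-12)
})

test_that("a through-origin line yields Tlag = 0, K = 0 and undefined D", {
  p <- permeation_profile(c(2, 4, 6, 8), c(10, 20, 30, 40), Cv = 1e4,
                          membrane = skin)
  expect_warning(fit_permeation(p), "undefined")
  fit <- suppressWarnings(fit_permeation(p))
  expect_equal(fit$Tlag, 0)
  expect_equal(fit$K, 0)
  expect_true(is.na(fit$D))
  expect_error(compute_D(skin$L, fit$Tlag), "non-positive")
})

test_that("negative lag time is flagged and retained, not clamped", {
  p <- permeation_profile(c(2, 4, 6, 8), c(10, 20, 30, 40) + 5, Cv = 1e4,
                          membrane = skin)
  expect_warning(expect_warning(fit_permeation(p), "undefined"),
                 "negative lag time")
  fit <- suppressWarnings(fit_permeation(p))
  expect_lt(fit$Tlag, 0)
  expect_true(fit$negative_tlag)
  expect_lt(fit$K, 0)               # anomaly propagates visibly
})

test_that("fitting is deterministic: same data and window, same result", {
  prof <- simulate_permeation_profile(Kp = 2e-3, K = 0.3, Cv = 5e3,
                                      membrane = skin)
  f1 <- fit_permeation(prof); f2 <- fit_permeation(prof)
  expect_identical(coef(f1), coef(f2))
})

test_that("perm_fit methods are coherent", {
  prof <- simulate_permeation_profile(Kp = 2e-3, K = 0.5, Cv = 1e4,
                                      membrane = stratm,
                                      times = c(2, 4, 6, 8))
  fit <- fit_permeation(prof)                # window drops the 2 h point
  expect_equal(fit$window, 2:4)
  expect_named(coef(fit), c("Flux", "Tlag", "Kp", "D", "K"))
  # tangent prediction matches the fitted line on the window
  expect_equal(predict(fit, times = prof$times[fit$window]),
               fit$Flux * (prof$times[fit$window] - fit$Tlag))
  # series prediction reproduces a noiseless profile closely
  expect_equal(predict(fit, type = "series"), prof$cumulative,
               tolerance = 0.02)
  expect_length(residuals(fit), 3L)
  # noiseless series points are near-linear over the window
  expect_lt(max(abs(residuals(fit))), 0.01 * max(prof$cumulative))
  sims <- simulate(fit, nsim = 3, seed = 1, sigma_rel = 0.1)
  expect_equal(dim(sims), c(4L, 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1, sigma_rel = 0.1))
  expect_output(print(summary(fit)), "standard error")
})

test_that("replicate aggregation reports mean and standard error", {
  fits <- lapply(1:4, function(s)
    fit_permeation(simulate_permeation_profile(
      Kp = 1e-3, K = 0.2, Cv = 1e4, membrane = skin,
      sigma_rel = 0.03, seed = s)))
  agg <- summarize_replicates(fits)
  expect_setequal(agg$parameter, c("Flux", "Tlag", "Kp", "D", "K"))
  expect_true(all(agg$n == 4L))
  kp <- agg[agg$parameter == "Kp", ]
  expect_equal(kp$mean, mean(vapply(fits, function(f) f$Kp, 0)))
  expect_gt(kp$se, 0)
})
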