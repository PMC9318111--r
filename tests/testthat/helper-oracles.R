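# Independent brute-force oracles used to check package computations.

# Pearson r and two-sided p straight from the covariance/variance
# definition and the t transform, independent of cor.test().
brute_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df = n - 2))
}

# factor-2 agreement by explicit pairwise enumeration
brute_factor2 <- function(pred, obs) {
  hits <- 0L
  for (i in seq_along(pred))
    if (pred[i] / obs[i] <= 2 && obs[i] / pred[i] <= 2) hits <- hits + 1L
  hits / length(pred)
}

# mass balance of the withdrawal correction: analyte in the receiver now
# plus everything removed with earlier aliquots must equal A * Q_n
withdrawal_mass_accounted <- function(conc, scheme) {
  vapply(seq_along(conc), function(n) {
    conc[n] * scheme$receiver_volume +
      sum(conc[seq_len(n - 1)] * scheme$aliquot_volume)
  }, 0)
}

std_cfg <- function(...) finite_dose_config(...)

# grid shared by the closed-form/integrator agreement checks
absorption_grid <- function() {
  expand.grid(Kp = 10^seq(log10(1e-5), log10(5e-2), length.out = 5),
              K = 10^seq(log10(1e-3), log10(5), length.out = 5),
              Teva = c(0, 0.5, 1.5, 6, 24))
}

rel_diff <- function(a, b, scale = 1) {
  abs(a - b) / max(abs(b), .Machine$double.eps * scale)
}
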