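# Independent oracles used across the suite.

# Hand-coded inverse-variance DerSimonian-Laird pooling (textbook formulas),
# kept independent of the package's metafor-backed implementation.
dl_pool_oracle <- function(yi, sei) {
  vi <- sei^2
  w <- 1 / vi
  mu_fe <- sum(w * yi) / sum(w)
  Q <- sum(w * (yi - mu_fe)^2)
  df <- length(yi) - 1
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - df) / C)
  w_re <- 1 / (vi + tau2)
  mu_re <- sum(w_re * yi) / sum(w_re)
  se_re <- sqrt(1 / sum(w_re))
  list(mu_fe = mu_fe, Q = Q, df = df, tau2 = tau2,
       I2 = if (Q > 0) max(0, (Q - df) / Q) * 100 else 0,
       mu_re = mu_re, se_re = se_re)
}

# High-accuracy numerical integration of the two-compartment mass balance
# (amounts A1, A2; cumulative AUC as a third state) under constant-rate
# infusion.  Requires deSolve.
ode_oracle <- function(p, dose, t_inf, times) {
  rhs <- function(t, y, parms) {
    rate <- if (t < t_inf) dose / t_inf else 0
    dA1 <- rate - (p$k10 + p$k12) * y[1] + p$k21 * y[2]
    dA2 <- p$k12 * y[1] - p$k21 * y[2]
    list(c(dA1, dA2, y[1] / p$V1))
  }
  out <- deSolve::ode(c(0, 0, 0), sort(unique(c(0, t_inf, times))), rhs, NULL,
                      rtol = 1e-11, atol = 1e-13)
  idx <- match(times, out[, 1])
  list(conc = out[idx, 2] / p$V1, auc = out[idx, 4])
}

# Reference typical-value set printed by the pooled analysis (CL mL/min,
# V1 L, K12/K21 1/min) and the frozen fraction of the 24-h window AUC in the
# total AUC for that set, computed once with ode_oracle at rtol 1e-12.
REF_TYPICAL <- list(CL = 131.8, V1 = 15.39, k12 = 0.002, k21 = 0.003)
F24_FROZEN <- 0.985907932933

ref_pk <- function() pk_params(REF_TYPICAL$CL, REF_TYPICAL$V1,
                               REF_TYPICAL$k12, REF_TYPICAL$k21)

# Minimal cohort builder for dosing/attainment tests: renal metrics given
# directly, demographics omitted.
toy_cohort <- function(egfr_abs, target_auc = 5, crcl = egfr_abs) {
  as_cohort(data.frame(egfr_normalized = egfr_abs * 1.73 / 1.6,
                       bsa = 1.6, crcl = crcl, target_auc = target_auc))
}
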