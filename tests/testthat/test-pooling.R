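test_that("reported uncertainties harmonize to standard errors on either scale", {
  expect_equal(to_standard_error(8.33, 19.1, "RSE_percent", "linear"), 1.59103)
  expect_equal(to_standard_error(6.99, 0.74, "SE", "linear"), 0.74)
  expect_equal(to_standard_error(8.38, 1.41, "RSE_percent", "log"), 0.0141)
  # delta method: log SE of an SE-reported estimate is SE/estimate
  expect_equal(to_standard_error(6.99, 0.74, "SE", "log"), 0.74 / 6.99)
  expect_error(to_standard_error(-1, 5, "SE"), "positive")
  expect_error(to_standard_error(1, 0, "SE"), "positive")
})

test_that("I-squared follows the truncated closed form", {
  expect_equal(heterogeneity(8, 1), 87.5)
  expect_equal(heterogeneity(3, 3), 0)
  expect_equal(heterogeneity(0.5, 1), 0)
  expect_equal(heterogeneity(0, 5), 0)
  expect_error(heterogeneity(-1, 1), "nonnegative")
})

two_study <- data.frame(study_id = c("a", "b"), parameter = "CL",
                        estimate = c(1, 3), uncertainty_value = c(0.5, 0.5),
                        uncertainty_kind = "SE")

test_that("DL pooling matches hand inverse-variance arithmetic", {
  hand <- dl_pool_oracle(yi = c(1, 3), sei = c(0.5, 0.5))
  expect_equal(hand$mu_fe, 2)
  expect_equal(hand$Q, 8)
  expect_equal(hand$I2, 87.5)
  expect_equal(hand$tau2, 1.75)
  res <- pool_random_effects(two_study, scale = "linear", tau2_method = "DL")
  expect_equal(res$estimate, hand$mu_re, tolerance = 1e-12)
  expect_equal(res$Q_stat, hand$Q, tolerance = 1e-12)
  expect_equal(res$tau2, hand$tau2, tolerance = 1e-12)
  expect_equal(res$I2_percent, hand$I2, tolerance = 1e-12)

  # random 3-study sets against the oracle
  set.seed(42)
  for (i in 1:10) {
    est <- runif(3, 1, 20)
    se <- runif(3, 0.1, 3)
    d <- data.frame(study_id = letters[1:3], parameter = "V1",
                    estimate = est, uncertainty_value = se,
                    uncertainty_kind = "SE")
    hand <- dl_pool_oracle(est, se)
    res <- pool_random_effects(d, scale = "linear", tau2_method = "DL")
    expect_equal(res$estimate, hand$mu_re, tolerance = 1e-12)
    expect_equal(res$tau2, hand$tau2, tolerance = 1e-12)
  }
})

test_that("degenerate homogeneous input pools to itself", {
  d <- data.frame(study_id = c("a", "b", "c"), parameter = "CL",
                  estimate = 5, uncertainty_value = 0.4,
                  uncertainty_kind = "SE")
  for (w in c("inverse_variance", "equal")) {
    res <- pool_random_effects(d, scale = "linear", tau2_method = "DL",
                               weighting = w)
    expect_equal(res$estimate, 5)
    expect_equal(res$Q_stat, 0)
    expect_equal(res$I2_percent, 0)
  }
})

test_that("pooled estimate is convex: always inside the study range", {
  set.seed(7)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    d <- data.frame(study_id = paste0("s", 1:k), parameter = "CL",
                    estimate = runif(k, 0.5, 30),
                    uncertainty_value = runif(k, 1, 40),
                    uncertainty_kind = "RSE_percent")
    for (sc in c("log", "linear")) for (w in c("inverse_variance", "equal")) {
      res <- pool_random_effects(d, scale = sc, tau2_method = "DL",
                                 weighting = w)
      expect_gte(res$estimate, min(d$estimate) - 1e-12)
      expect_lte(res$estimate, max(d$estimate) + 1e-12)
    }
  }
})

test_that("dominant heterogeneity drives the RE estimate to the unweighted mean", {
  # spread huge relative to the within-study errors => tau2 >> vi
  d <- data.frame(study_id = c("a", "b", "c"), parameter = "CL",
                  estimate = c(1, 5, 9), uncertainty_value = 1e-3,
                  uncertainty_kind = "SE")
  res <- pool_random_effects(d, scale = "linear", tau2_method = "REML")
  expect_equal(res$estimate, 5, tolerance = 1e-6)
  eq <- pool_random_effects(d, scale = "linear", weighting = "equal")
  expect_equal(eq$estimate, 5, tolerance = 1e-12)
})

test_that("log-scale pooling of identical-CV studies is the geometric mean", {
  d <- data.frame(study_id = c("a", "b", "c"), parameter = "K12",
                  estimate = c(0.08, 0.12, 0.2), uncertainty_value = 15,
                  uncertainty_kind = "RSE_percent")
  gm <- exp(mean(log(d$estimate)))
  for (w in c("inverse_variance", "equal")) {
    res <- pool_random_effects(d, scale = "log", tau2_method = "DL",
                               weighting = w)
    expect_equal(res$estimate, gm, tolerance = 1e-12)
  }
})

test_that("a single study passes through with its own CI", {
  d <- data.frame(study_id = "only", parameter = "V2", estimate = 24.8,
                  uncertainty_value = 0.46, uncertainty_kind = "SE")
  res <- pool_random_effects(d, scale = "linear")
  expect_equal(res$estimate, 24.8)
  expect_equal(res$ci95_low, 24.8 - qnorm(0.975) * 0.46)
  expect_equal(res$tau2, 0)
  expect_true(is.na(res$I2_percent))
  expect_equal(res$k_studies, 1)
})

test_that("invalid pooling inputs are rejected", {
  expect_error(pool_random_effects(two_study[0, ]), "empty")
  mixed <- two_study
  mixed$parameter <- c("CL", "V1")
  expect_error(pool_random_effects(mixed), "share one parameter")
})

test_that("unit standardization applies the exact conversion factors", {
  s <- standardize_units(7.91, 15.39, 0.12, 0.18)
  expect_equal(s$CL_ml_min, 7.91 * 1000 / 60)
  expect_equal(round(s$CL_ml_min, 1), 131.8)
  expect_equal(s$k12_per_min, 0.002)
  expect_equal(s$k21_per_min, 0.003)
  expect_equal(s$V1_L, 15.39)
  expect_error(standardize_units(0, 1, 1, 1), "positive")
})

test_that("the fitted model pools every parameter and exposes typical values", {
  fit <- carbo_pool(carbo_studies())
  expect_s3_class(fit, "carbo_pk")
  tab <- fit$parameters
  expect_setequal(tab$parameter, c("CL", "V1", "V2", "Q", "K12", "K21"))
  expect_equal(tab$k_studies[tab$parameter == "CL"], 3)
  expect_equal(tab$k_studies[tab$parameter == "V2"], 1)
  cf_min <- coef(fit)
  cf_h <- coef(fit, units = "h")
  expect_equal(cf_min[["CL"]], cf_h[["CL"]] * 1000 / 60)
  expect_equal(cf_min[["K12"]], cf_h[["K12"]] / 60)
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= tab$estimate[match(rownames(ci), tab$parameter)]))
  expect_output(print(fit), "Typical values")
  expect_output(print(summary(fit)), "Pooled parameters")
})

test_that("pooled parameter sets survive a JSON round trip", {
  fit <- carbo_pool()
  path <- tempfile(fileext = ".json")
  write_pooled_json(fit, path)
  back <- read_pooled_json(path)
  expect_equal(back$typical$CL_ml_min, fit$typical$CL_ml_min)
  expect_equal(back$settings$scale, fit$settings$scale)
  p1 <- as.list(coef(fit))
  pk1 <- pk_params(p1$CL, p1$V1, p1$K12, p1$K21)
  pk2 <- carbodose:::as_pk_params(back)
  expect_equal(pk2$k10, pk1$k10)
})
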