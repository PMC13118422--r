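#' Two-compartment PK parameter set
#'
#' Builds and validates the typical-value parameter set of the two-compartment
#' model in the package's canonical internal units (minutes, mg, mL):
#' clearance CL in mL/min, central volume V1 in L (held as mL internally),
#' transfer constants k12/k21 in 1/min.  The elimination constant is derived
#' as \eqn{k_{10} = CL/V_1}.
#'
#' @param CL_ml_min Clearance, mL/min.
#' @param V1_L Central volume of distribution, L.
#' @param k12_per_min,k21_per_min Transfer rate constants, 1/min.
#' @return A list of class \code{"pk_params"} with fields \code{CL} (mL/min),
#'   \code{V1} (mL), \code{k10}, \code{k12}, \code{k21} (1/min).
#' @examples
#' pk_params(131.8, 15.39, 0.002, 0.003)
#' @export
pk_params <- function(CL_ml_min, V1_L, k12_per_min, k21_per_min) {
  vals <- c(CL_ml_min, V1_L, k21_per_min)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("CL, V1 and k21 must be positive and finite")
  if (!is.finite(k12_per_min) || k12_per_min < 0)
    stop("k12 must be nonnegative and finite")
  p <- list(CL = CL_ml_min, V1 = V1_L * 1000,
            k10 = CL_ml_min / (V1_L * 1000),
            k12 = k12_per_min, k21 = k21_per_min)
  disc <- (p$k10 + p$k12 + p$k21)^2 - 4 * p$k10 * p$k21
  if (disc <= 1e-12 * (p$k10 + p$k12 + p$k21)^2)
    stop("repeated hybrid rate constants (degenerate biexponential); ",
         "this parameter set is not supported")
  structure(p, class = "pk_params")
}

as_pk_params <- function(x) {
  if (inherits(x, "pk_params")) return(x)
  if (inherits(x, "carbo_pk")) {
    tv <- x$typical
    return(pk_params(tv$CL_ml_min, tv$V1_L, tv$k12_per_min, tv$k21_per_min))
  }
  if (is.list(x) && !is.null(x$typical)) {  # read_pooled_json() output
    tv <- x$typical
    return(pk_params(tv$CL_ml_min, tv$V1_L, tv$k12_per_min, tv$k21_per_min))
  }
  stop("cannot interpret 'params' as a PK parameter set")
}

#' Hybrid rate constants of the two-compartment model
#'
#' The exponents \eqn{\lambda_1 > \lambda_2 > 0} of the biexponential
#' disposition, i.e. the roots of
#' \eqn{\lambda^2 - (k_{10}+k_{12}+k_{21})\lambda + k_{10}k_{21} = 0}.
#'
#' @param p A [pk_params()] object.
#' @return Named vector \code{c(lambda1, lambda2)} in 1/min.
#' @export
hybrid_constants <- function(p) {
  p <- as_pk_params(p)
  s <- p$k10 + p$k12 + p$k21
  prod <- p$k10 * p$k21
  disc <- s^2 - 4 * prod
  root <- sqrt(disc)
  # subtractive cancellation avoided: lambda2 via the product
  lambda1 <- (s + root) / 2
  lambda2 <- prod / lambda1
  c(lambda1 = lambda1, lambda2 = lambda2)
}

#' Constant-rate infusion regimen
#'
#' @param dose Total dose, mg (nonnegative).
#' @param t_inf Infusion duration, minutes (default 180: a single 3-h
#'   infusion).
#' @param horizon Simulation horizon, minutes (default 1440 = 24 h, anchored
#'   at infusion start).
#' @return A list of class \code{"infusion_regimen"} with \code{dose},
#'   \code{t_inf}, \code{rate} (mg/min) and \code{horizon}.
#' @export
infusion_regimen <- function(dose, t_inf = 180, horizon = 1440) {
  if (!is.finite(dose) || dose < 0) stop("dose must be nonnegative")
  if (!is.finite(t_inf) || t_inf <= 0) stop("t_inf must be positive")
  if (!is.finite(horizon) || horizon < t_inf)
    stop("horizon must be at least t_inf")
  structure(list(dose = dose, t_inf = t_inf, rate = dose / t_inf,
                 horizon = horizon),
            class = "infusion_regimen")
}

# Biexponential coefficients of the unit-impulse central concentration:
# C_delta(t) = (1/V1) * (A1 e^{-l1 t} + A2 e^{-l2 t}), A1 + A2 = 1.
biexp_coefs <- function(p) {
  l <- hybrid_constants(p)
  A1 <- (l["lambda1"] - p$k21) / (l["lambda1"] - l["lambda2"])
  A2 <- (p$k21 - l["lambda2"]) / (l["lambda1"] - l["lambda2"])
  list(l1 = unname(l["lambda1"]), l2 = unname(l["lambda2"]),
       A1 = unname(A1), A2 = unname(A2))
}

#' Central-compartment concentration under constant-rate infusion
#'
#' Closed-form piecewise biexponential solution of the two-compartment model
#' with a zero-order infusion into the central compartment: during the
#' infusion each exponential accumulates as \eqn{(1 - e^{-\lambda t})}; after
#' the end of infusion the accumulated terms decay.  Continuous at the end of
#' infusion and zero at \eqn{t = 0}.
#'
#' @param t Time(s) since infusion start, minutes (vectorized).
#' @param regimen An [infusion_regimen()].
#' @param p A [pk_params()] object (or a fitted [carbo_pool()] model).
#' @return Concentration(s) in mg/mL.
#' @examples
#' p <- pk_params(131.8, 15.39, 0.002, 0.003)
#' r <- infusion_regimen(660)
#' concentration(c(0, 90, 180, 720, 1440), r, p)
#' @export
concentration <- function(t, regimen, p) {
  p <- as_pk_params(p)
  stopifnot(inherits(regimen, "infusion_regimen"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be nonnegative")
  b <- biexp_coefs(p)
  R0 <- regimen$rate
  Tinf <- regimen$t_inf
  term <- function(A, l) {
    during <- A / l * (1 - exp(-l * pmin(t, Tinf)))
    decay <- exp(-l * pmax(t - Tinf, 0))
    during * decay
  }
  (R0 / p$V1) * (term(b$A1, b$l1) + term(b$A2, b$l2))
}

#' Analytic AUC of the infusion concentration profile
#'
#' Exact piecewise integral of the closed-form concentration from time zero
#' (infusion start) to \code{t_end}.  \code{t_end = Inf} returns the total
#' exposure \eqn{AUC_{0-\infty} = dose/CL} (mass balance), which the
#' truncated integral approaches monotonically from below.
#'
#' @param regimen An [infusion_regimen()].
#' @param p A [pk_params()] object (or a fitted [carbo_pool()] model).
#' @param t_end End of the integration window, minutes; defaults to the
#'   regimen horizon. \code{Inf} allowed.
#' @return AUC in mg·min/mL.
#' @examples
#' p <- pk_params(131.8, 15.39, 0.002, 0.003)
#' auc(infusion_regimen(659), p, t_end = Inf)  # 659/131.8 = 5.0
#' @export
auc <- function(regimen, p, t_end = regimen$horizon) {
  p <- as_pk_params(p)
  stopifnot(inherits(regimen, "infusion_regimen"))
  if (!(length(t_end) == 1 && (is.infinite(t_end) || (is.finite(t_end) && t_end > 0))))
    stop("t_end must be a single positive time (Inf allowed)")
  if (is.infinite(t_end)) return(regimen$dose / p$CL)
  b <- biexp_coefs(p)
  R0 <- regimen$rate
  Tinf <- regimen$t_inf
  # integral of one exponential term up to time t
  int_term <- function(A, l, t) {
    t1 <- pmin(t, Tinf)
    # during infusion: A/l * (t1 - (1 - e^{-l t1})/l)
    during <- A / l * (t1 - (1 - exp(-l * t1)) / l)
    # after infusion: accumulated amplitude decays from Tinf to t
    t2 <- pmax(t - Tinf, 0)
    post <- A / l * (1 - exp(-l * Tinf)) * (1 - exp(-l * t2)) / l
    during + post
  }
  (R0 / p$V1) * (int_term(b$A1, b$l1, t_end) + int_term(b$A2, b$l2, t_end))
}

#' Fraction of total exposure captured in a finite window
#'
#' \eqn{f = AUC_{0-t}/AUC_{0-\infty}} for the given regimen and parameters; a
#' deterministic constant that makes attainment results auditable by hand
#' (predicted AUC = dose × f / CL).
#'
#' @inheritParams auc
#' @return The fraction in (0, 1).
#' @export
auc_fraction <- function(regimen, p, t_end = regimen$horizon) {
  auc(regimen, p, t_end) / auc(regimen, p, Inf)
}

#' Predicted exposure for one administered dose
#'
#' Runs the closed-form infusion model for a single dose and summarizes the
#' exposure: the truncated AUC over the horizon, the total AUC, and the
#' attainment category of the truncated AUC.
#'
#' @param dose Dose, mg.
#' @param p A [pk_params()] object (or fitted [carbo_pool()] model).
#' @param t_inf Infusion duration, minutes.
#' @param horizon AUC window, minutes.
#' @param profile_times Optional vector of times (minutes) at which to attach
#'   a concentration profile.
#' @return A list of class \code{"exposure_result"}: \code{dose},
#'   \code{auc_0_horizon}, \code{auc_inf}, \code{category}, and optionally
#'   \code{profile} (data frame of t, concentration).
#' @export
exposure <- function(dose, p, t_inf = 180, horizon = 1440,
                     profile_times = NULL) {
  p <- as_pk_params(p)
  r <- infusion_regimen(dose, t_inf = t_inf, horizon = horizon)
  a24 <- auc(r, p)
  res <- list(dose = dose,
              auc_0_horizon = a24,
              auc_inf = auc(r, p, Inf),
              category = classify(a24))
  if (!is.null(profile_times))
    res$profile <- data.frame(t = profile_times,
                              concentration = concentration(profile_times, r, p))
  structure(res, class = "exposure_result")
}

#' @exportS3Method base::print
print.exposure_result <- function(x, ...) {
  cat(sprintf("Dose %.1f mg: AUC(0-horizon) %.3f, AUC(0-Inf) %.3f mg.min/mL [%s]\n",
              x$dose, x$auc_0_horizon, x$auc_inf, x$category))
  invisible(x)
}
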