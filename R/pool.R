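#' I-squared heterogeneity statistic
#'
#' Computes Higgins' I-squared from Cochran's Q and its degrees of freedom:
#' \eqn{I^2 = \max(0, (Q - df)/Q) \cdot 100}, the percentage of total
#' variability attributable to between-study heterogeneity.
#'
#' @param Q Cochran's Q statistic (nonnegative).
#' @param df Degrees of freedom (number of studies minus one).
#' @return I-squared in percent, in \[0, 100\]; 0 when \code{Q = 0}.
#' @examples
#' heterogeneity(8, 1)   # 87.5
#' heterogeneity(0.5, 1) # truncated to 0
#' @export
heterogeneity <- function(Q, df) {
  if (!is.numeric(Q) || !is.finite(Q) || Q < 0) stop("'Q' must be nonnegative")
  if (!is.numeric(df) || df < 0) stop("'df' must be nonnegative")
  if (Q == 0) return(0)
  max(0, (Q - df) / Q) * 100
}

#' Pool study estimates with an inverse-variance random-effects model
#'
#' Pools fixed-effect parameter estimates from several studies under the
#' standard random-effects model \eqn{y_i \sim N(\mu, v_i + \tau^2)}.  Pooling
#' may be done on the log scale (delta-method standard errors, back-transformed
#' results; natural for strictly positive PK parameters whose reported
#' confidence intervals are multiplicatively symmetric) or on the linear
#' scale.  The between-study variance \eqn{\tau^2} is estimated by
#' DerSimonian-Laird or REML (via \pkg{metafor}).
#'
#' \code{weighting = "equal"} gives the \eqn{\tau^2}-dominant limit of the
#' random-effects model: when between-study variance dwarfs the within-study
#' variances (I-squared near 100\%), the inverse-variance weights
#' \eqn{1/(v_i + \tau^2)} become equal and the pooled estimate is the
#' unweighted mean on the pooling scale, with variance estimated by the sample
#' variance of the study effects over \eqn{k}.  Heterogeneity statistics (Q,
#' I-squared, \eqn{\tau^2}) are still computed from the reported
#' uncertainties.
#'
#' A single study (\eqn{k = 1}) is passed through: the pooled value is the
#' study estimate with its own Wald 95\% CI, \eqn{\tau^2 = 0} and I-squared
#' not applicable.
#'
#' @param estimates Data frame of study estimates for a single parameter
#'   (columns as in [read_study_table()]).
#' @param scale Pooling scale, \code{"log"} (default) or \code{"linear"}.
#' @param tau2_method \code{"REML"} (default) or \code{"DL"}.
#' @param weighting \code{"inverse_variance"} (default) or \code{"equal"}.
#' @param se_mode \code{"reported"} (default) uses the published RSE/SE as the
#'   within-study standard error; \code{"se_over_sqrt_n"} additionally divides
#'   by the square root of the study size (experimental sensitivity mode,
#'   requires \code{n_subjects}).
#' @return A one-row data frame (a pooled-parameter record) with the pooled
#'   estimate, 95\% CI, \code{tau2}, \code{Q_stat}, \code{df},
#'   \code{I2_percent}, \code{k_studies}, and the configuration used.
#' @examples
#' cl <- subset(carbo_studies(), parameter == "CL")
#' pool_random_effects(cl, scale = "log", tau2_method = "REML")
#' @export
pool_random_effects <- function(estimates,
                                scale = c("log", "linear"),
                                tau2_method = c("REML", "DL"),
                                weighting = c("inverse_variance", "equal"),
                                se_mode = c("reported", "se_over_sqrt_n")) {
  scale <- match.arg(scale)
  tau2_method <- match.arg(tau2_method)
  weighting <- match.arg(weighting)
  se_mode <- match.arg(se_mode)
  estimates <- as.data.frame(estimates)
  if (nrow(estimates) == 0) stop("'estimates' is empty")
  estimates <- validate_study_table(estimates)
  par <- unique(estimates$parameter)
  if (length(par) != 1)
    stop("all estimates must share one parameter; got: ",
         paste(par, collapse = ", "))

  se_lin <- mapply(to_standard_error, estimates$estimate,
                   estimates$uncertainty_value, estimates$uncertainty_kind,
                   MoreArgs = list(scale = "linear"))
  if (se_mode == "se_over_sqrt_n") {
    if (any(is.na(estimates$n_subjects)))
      stop("se_mode = 'se_over_sqrt_n' requires n_subjects for every study")
    se_lin <- se_lin / sqrt(estimates$n_subjects)
  }
  if (scale == "log") {
    yi <- log(estimates$estimate)
    sei <- se_lin / estimates$estimate
  } else {
    yi <- estimates$estimate
    sei <- se_lin
  }
  k <- length(yi)
  back <- if (scale == "log") exp else identity

  if (k == 1) {
    mu <- yi
    half <- stats::qnorm(0.975) * sei
    out <- list(mu = mu, lo = mu - half, hi = mu + half,
                tau2 = 0, Q = 0, df = 0L, I2 = NA_real_)
  } else {
    fit <- metafor::rma(yi = yi, sei = sei, method = tau2_method)
    Q <- as.numeric(fit$QE)
    df <- k - 1L
    if (weighting == "inverse_variance") {
      mu <- as.numeric(fit$b)
      out <- list(mu = mu, lo = fit$ci.lb, hi = fit$ci.ub,
                  tau2 = fit$tau2, Q = Q, df = df,
                  I2 = heterogeneity(Q, df))
    } else {
      mu <- mean(yi)
      se_mu <- stats::sd(yi) / sqrt(k)
      half <- stats::qnorm(0.975) * se_mu
      out <- list(mu = mu, lo = mu - half, hi = mu + half,
                  tau2 = fit$tau2, Q = Q, df = df,
                  I2 = heterogeneity(Q, df))
    }
  }
  data.frame(parameter = par,
             estimate = back(out$mu),
             ci95_low = back(out$lo),
             ci95_high = back(out$hi),
             tau2 = out$tau2,
             Q_stat = out$Q,
             df = out$df,
             I2_percent = out$I2,
             k_studies = k,
             pooling_scale = scale,
             tau2_method = tau2_method,
             weighting = weighting,
             stringsAsFactors = FALSE)
}

#' Standardize pooled PK parameters to Calvert-formula units
#'
#' Converts a pooled parameter set reported in the literature's units (CL in
#' L/h, V1 in L, rate constants in 1/h) to the units in which the Calvert
#' formula and the exposure simulation operate: clearance in mL/min
#' (\eqn{\times 1000/60}), volume unchanged in L, rate constants in 1/min
#' (\eqn{\div 60}).
#'
#' @param cl_l_per_h Clearance, L/h.
#' @param v1_l Central volume of distribution, L.
#' @param k12_per_h,k21_per_h First-order transfer rate constants, 1/h.
#' @return A list with \code{CL_ml_min}, \code{V1_L}, \code{k12_per_min},
#'   \code{k21_per_min}.
#' @examples
#' standardize_units(7.91, 15.39, 0.12, 0.18)  # CL 131.83 mL/min
#' @export
standardize_units <- function(cl_l_per_h, v1_l, k12_per_h, k21_per_h) {
  vals <- c(cl_l_per_h, v1_l, k12_per_h, k21_per_h)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all parameters must be positive and finite")
  list(CL_ml_min = cl_l_per_h * 1000 / 60,
       V1_L = v1_l,
       k12_per_min = k12_per_h / 60,
       k21_per_min = k21_per_h / 60)
}

#' Fit a meta-analytic carboplatin PK model
#'
#' The central fitting function of the package.  Pools published fixed-effect
#' (typical-value) estimates of the two-compartment carboplatin parameters CL,
#' V1, K12 and K21 across studies with an inverse-variance random-effects
#' meta-analysis, and standardizes the pooled typical values to the units used
#' by the Calvert formula and the exposure simulation (mL/min, L, 1/min).
#'
#' Only parameters reported directly by at least one study are pooled;
#' micro-constants are never imputed from Q and V2.  Parameters reported by a
#' single study (here V2 and Q) are carried through with their own CI for
#' provenance but take no part in the exposure simulation, which needs only
#' CL, V1, K12 and K21.
#'
#' @param studies Study-estimate table as returned by [carbo_studies()] or
#'   [read_study_table()].
#' @inheritParams pool_random_effects
#' @return An object of class \code{"carbo_pk"}: a fitted pooled-parameter
#'   model with \code{print}, \code{summary}, \code{coef}, \code{confint},
#'   \code{predict} and \code{plot} methods.
#' @examples
#' fit <- carbo_pool(carbo_studies())
#' coef(fit)
#' coef(fit, units = "h")
#' @seealso [predict.carbo_pk()] for dose and exposure prediction,
#'   [alpha_sweep()] for formula optimization.
#' @export
carbo_pool <- function(studies = carbo_studies(),
                       scale = c("log", "linear"),
                       tau2_method = c("REML", "DL"),
                       weighting = c("inverse_variance", "equal"),
                       se_mode = c("reported", "se_over_sqrt_n")) {
  scale <- match.arg(scale)
  tau2_method <- match.arg(tau2_method)
  weighting <- match.arg(weighting)
  se_mode <- match.arg(se_mode)
  studies <- validate_study_table(as.data.frame(studies))

  pooled <- do.call(rbind, lapply(split(studies, studies$parameter),
                                  pool_random_effects,
                                  scale = scale, tau2_method = tau2_method,
                                  weighting = weighting, se_mode = se_mode))
  pooled <- pooled[match(intersect(PK_PARAMETERS, pooled$parameter),
                         pooled$parameter), ]
  rownames(pooled) <- NULL

  need <- c("CL", "V1", "K12", "K21")
  miss <- setdiff(need, pooled$parameter)
  if (length(miss))
    stop("study table lacks the structural parameters: ",
         paste(miss, collapse = ", "))
  est <- function(p) pooled$estimate[pooled$parameter == p]
  typical <- standardize_units(est("CL"), est("V1"), est("K12"), est("K21"))

  structure(list(parameters = pooled,
                 typical = typical,
                 settings = list(scale = scale, tau2_method = tau2_method,
                                 weighting = weighting, se_mode = se_mode),
                 studies = studies,
                 call = match.call()),
            class = "carbo_pk")
}

#' @exportS3Method base::print
print.carbo_pk <- function(x, digits = 4, ...) {
  cat("Meta-analytic carboplatin PK model (two-compartment, typical values)\n")
  s <- x$settings
  cat(sprintf("Pooling: random effects, %s scale, tau2 = %s, %s weights\n",
              s$scale, s$tau2_method, gsub("_", "-", s$weighting)))
  cat(sprintf("Studies: %d rows, %d distinct sources\n\n",
              nrow(x$studies), length(unique(x$studies$study_id))))
  tv <- x$typical
  cat(sprintf("Typical values: CL %.4g mL/min, V1 %.4g L, K12 %.4g 1/min, K21 %.4g 1/min\n",
              tv$CL_ml_min, tv$V1_L, tv$k12_per_min, tv$k21_per_min))
  invisible(x)
}

#' @exportS3Method base::summary
summary.carbo_pk <- function(object, ...) {
  structure(list(fit = object), class = "summary.carbo_pk")
}

#' @exportS3Method base::print
print.summary.carbo_pk <- function(x, digits = 4, ...) {
  print(x$fit)
  cat("\nPooled parameters (literature units):\n")
  tab <- x$fit$parameters
  tab$I2_percent <- round(tab$I2_percent, 1)
  print(tab[, c("parameter", "k_studies", "estimate", "ci95_low", "ci95_high",
                "tau2", "Q_stat", "df", "I2_percent")],
        digits = digits, row.names = FALSE)
  invisible(x)
}

#' Extract pooled typical values
#'
#' @param object A fitted [carbo_pool()] model.
#' @param units \code{"min"} (default; CL mL/min, V1 L, K12/K21 1/min — the
#'   simulation units) or \code{"h"} (CL L/h, V1 L, K12/K21 1/h — the units of
#'   the source literature).
#' @param ... Unused.
#' @return Named numeric vector \code{c(CL, V1, K12, K21)}.
#' @export
coef.carbo_pk <- function(object, units = c("min", "h"), ...) {
  units <- match.arg(units)
  tv <- object$typical
  if (units == "min")
    c(CL = tv$CL_ml_min, V1 = tv$V1_L,
      K12 = tv$k12_per_min, K21 = tv$k21_per_min)
  else
    c(CL = tv$CL_ml_min * 60 / 1000, V1 = tv$V1_L,
      K12 = tv$k12_per_min * 60, K21 = tv$k21_per_min * 60)
}

#' @export
confint.carbo_pk <- function(object, parm, level = 0.95, ...) {
  if (level != 0.95)
    stop("only the 95% interval computed at fit time is available")
  tab <- object$parameters
  if (missing(parm)) parm <- tab$parameter
  tab <- tab[tab$parameter %in% parm, ]
  m <- cbind(`2.5 %` = tab$ci95_low, `97.5 %` = tab$ci95_high)
  rownames(m) <- tab$parameter
  m
}

#' Write / read a pooled parameter set as JSON
#'
#' Serializes the typical values and per-parameter pooling provenance of a
#' fitted model so downstream exposure simulation can run from a file, and
#' reads such a file back into the list structure the simulator consumes.
#'
#' @param fit A fitted [carbo_pool()] model.
#' @param path Output (input) JSON path.
#' @return \code{write_pooled_json}: \code{path}, invisibly.
#'   \code{read_pooled_json}: a list with \code{typical}, \code{settings} and
#'   \code{parameters}.
#' @export
write_pooled_json <- function(fit, path) {
  stopifnot(inherits(fit, "carbo_pk"))
  obj <- list(typical = fit$typical,
              settings = fit$settings,
              parameters = fit$parameters)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_pooled_json
#' @export
read_pooled_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$parameters <- as.data.frame(obj$parameters)
  obj
}
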