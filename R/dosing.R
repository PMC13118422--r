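#' Calvert-type dose formula
#'
#' Specifies which renal metric and additive constant the dose calculation
#' uses.  Three kinds:
#' \describe{
#'   \item{crcl_conventional}{Dose = target AUC × (CrCL + 25)}
#'   \item{egfr_conventional}{Dose = target AUC × (eGFR_abs + 25)}
#'   \item{egfr_modified}{Dose = target AUC × (eGFR_abs + 25 + α)}
#' }
#' where eGFR_abs is the BSA-readjusted absolute eGFR (mL/min).  With
#' \eqn{\alpha = 1} the modified formula is Dose = target AUC × (eGFR_abs +
#' 26).
#'
#' @param kind Formula kind (see above); partial matching of
#'   \code{"crcl"}, \code{"egfr"}, \code{"modified"} accepted.
#' @param alpha Additive constant α, mL/min (only meaningful for the modified
#'   formula; must be 0 otherwise).
#' @param gfr_cap Optional cap (mL/min) applied to the renal metric before
#'   dosing; default none.
#' @return An object of class \code{"dose_formula"}.
#' @examples
#' dose_formula("egfr")
#' dose_formula("modified", alpha = 1)
#' @export
dose_formula <- function(kind = c("crcl_conventional", "egfr_conventional",
                                  "egfr_modified", "crcl", "egfr", "modified"),
                         alpha = 0, gfr_cap = NULL) {
  kind <- match.arg(kind)
  kind <- switch(kind, crcl = "crcl_conventional", egfr = "egfr_conventional",
                 modified = "egfr_modified", kind)
  if (!is.finite(alpha)) stop("alpha must be finite")
  if (kind != "egfr_modified" && alpha != 0)
    stop("alpha must be 0 unless kind = 'egfr_modified'")
  if (!is.null(gfr_cap) && (!is.finite(gfr_cap) || gfr_cap <= 0))
    stop("gfr_cap must be positive")
  structure(list(kind = kind, alpha = alpha, gfr_cap = gfr_cap),
            class = "dose_formula")
}

#' @exportS3Method base::print
print.dose_formula <- function(x, ...) {
  lbl <- switch(x$kind,
                crcl_conventional = "Dose = AUC x (CrCL + 25)",
                egfr_conventional = "Dose = AUC x (eGFR_abs + 25)",
                egfr_modified = sprintf("Dose = AUC x (eGFR_abs + 25 + %g)",
                                        x$alpha))
  cat(lbl, "\n")
  invisible(x)
}

#' Carboplatin dose under a Calvert-type formula
#'
#' @param cohort A cohort data frame (see [as_cohort()]); needs \code{crcl}
#'   or \code{egfr_abs} depending on the formula, and \code{target_auc}.
#' @param formula A [dose_formula()].
#' @return Vector of doses, mg (full floating precision; see
#'   \code{round_dose} in the reporting layer for 1-mg rounding).
#' @examples
#' pt <- data.frame(crcl = 100, egfr_normalized = 100, bsa = 1.73,
#'                  target_auc = 5)
#' calvert_dose(as_cohort(pt), dose_formula("crcl"))  # 625
#' @export
calvert_dose <- function(cohort, formula) {
  stopifnot(inherits(formula, "dose_formula"), is.data.frame(cohort))
  metric_col <- switch(formula$kind,
                       crcl_conventional = "crcl",
                       egfr_conventional = ,
                       egfr_modified = "egfr_abs")
  if (!metric_col %in% names(cohort))
    stop("cohort lacks the renal metric '", metric_col,
         "' required by this formula")
  metric <- cohort[[metric_col]]
  if (!is.null(formula$gfr_cap)) metric <- pmin(metric, formula$gfr_cap)
  eff <- metric + 25 + formula$alpha
  if (any(eff <= 0))
    stop("nonpositive effective clearance term for alpha = ", formula$alpha)
  cohort$target_auc * eff
}

#' Predict doses and exposures for a cohort
#'
#' The prediction method of the fitted meta-analytic PK model: computes each
#' patient's dose under the requested Calvert-type formula, runs the
#' closed-form two-compartment infusion simulation at the pooled typical
#' values, and classifies the predicted 24-h AUC against the attainment
#' bands.
#'
#' @param object A fitted [carbo_pool()] model.
#' @param newdata A cohort data frame ([as_cohort()] layout).
#' @param formula A [dose_formula()], or a kind string passed to
#'   [dose_formula()].
#' @param alpha α (mL/min) when \code{formula} is given as a string.
#' @param t_inf Infusion duration, minutes (default 180).
#' @param horizon AUC window, minutes (default 1440).
#' @param ... Unused.
#' @return A data frame: the cohort's \code{id}, \code{dataset_label},
#'   \code{target_auc} plus \code{dose_mg}, \code{auc_pred} (mg·min/mL over
#'   the horizon), \code{auc_inf} and \code{category}.
#' @examples
#' fit <- carbo_pool()
#' cohort <- generate_cohort(seed = 1001)
#' head(predict(fit, cohort, formula = "egfr"))
#' @export
predict.carbo_pk <- function(object, newdata, formula = "egfr", alpha = 0,
                             t_inf = 180, horizon = 1440, ...) {
  if (!inherits(formula, "dose_formula"))
    formula <- dose_formula(formula, alpha = alpha)
  p <- as_pk_params(object)
  dose <- calvert_dose(newdata, formula)
  # AUC is linear in dose: one unit-dose run scales to the whole cohort
  f_h <- auc_fraction(infusion_regimen(1, t_inf = t_inf, horizon = horizon), p)
  auc_pred <- dose * f_h / p$CL
  data.frame(id = newdata$id,
             dataset_label = newdata$dataset_label,
             target_auc = newdata$target_auc,
             dose_mg = dose,
             auc_pred = auc_pred,
             auc_inf = dose / p$CL,
             category = classify(auc_pred),
             stringsAsFactors = FALSE)
}
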