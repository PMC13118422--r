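ATTAINMENT_LEVELS <- c("under", "target", "gap", "over")

#' Classify a predicted AUC against the attainment bands
#'
#' Four bands: \code{under} (< 4, reduced efficacy), \code{target}
#' (4–6 inclusive), \code{gap} (6–7 exclusive; between the target ceiling and
#' the toxicity threshold, reported separately so the four bands are
#' exhaustive), and \code{over} (>= 7 mg·min/mL, increased myelotoxicity).
#'
#' @param auc Predicted AUC(s), mg·min/mL (nonnegative).
#' @return Factor with levels \code{under}, \code{target}, \code{gap},
#'   \code{over}.
#' @examples
#' classify(c(3.9, 4, 6, 6.5, 7))
#' @export
classify <- function(auc) {
  if (any(!is.finite(auc)) || any(auc < 0)) stop("auc must be nonnegative")
  factor(ifelse(auc < 4, "under",
         ifelse(auc <= 6, "target",
         ifelse(auc < 7, "gap", "over"))),
         levels = ATTAINMENT_LEVELS)
}

#' Attainment proportions of a cohort under one formula
#'
#' Doses every patient, predicts exposure at the pooled typical values, and
#' tabulates the four attainment bands as percentages (raw counts retained).
#'
#' @param cohort A cohort data frame.
#' @param formula A [dose_formula()] (or kind string).
#' @param params A fitted [carbo_pool()] model (or [pk_params()] /
#'   [read_pooled_json()] output).
#' @param alpha α when \code{formula} is a string.
#' @inheritParams predict.carbo_pk
#' @return A one-row data frame: \code{n}, counts \code{n_under} ...
#'   \code{n_over}, and unrounded percentages \code{pct_under},
#'   \code{pct_target}, \code{pct_gap}, \code{pct_over} (summing to 100).
#' @export
cohort_proportions <- function(cohort, formula, params, alpha = 0,
                               t_inf = 180, horizon = 1440) {
  if (nrow(cohort) == 0) stop("cohort is empty")
  if (!inherits(formula, "dose_formula"))
    formula <- dose_formula(formula, alpha = alpha)
  p <- as_pk_params(params)
  dose <- calvert_dose(cohort, formula)
  f_h <- auc_fraction(infusion_regimen(1, t_inf = t_inf, horizon = horizon), p)
  cat_counts <- table(classify(dose * f_h / p$CL))
  n <- nrow(cohort)
  out <- data.frame(n = n)
  for (lv in ATTAINMENT_LEVELS) {
    out[[paste0("n_", lv)]] <- as.integer(cat_counts[[lv]])
    out[[paste0("pct_", lv)]] <- 100 * cat_counts[[lv]] / n
  }
  out
}

#' Sweep the additive constant of the modified Calvert formula
#'
#' Evaluates the modified formula Dose = AUC × (eGFR_abs + 25 + α) over a
#' grid of α values (default −25 to +25 mL/min in 1 mL/min steps), recording
#' the four attainment-band percentages at each α, marking which α values
#' qualify against the α = 0 (conventional eGFR formula) baseline, and
#' selecting the optimal α.
#'
#' @param cohort A cohort data frame.
#' @param params A fitted [carbo_pool()] model (or parameter set).
#' @param alphas Integer α grid, mL/min.
#' @inheritParams predict.carbo_pk
#' @return An object of class \code{"alpha_sweep"}: a data frame with one row
#'   per α (columns \code{alpha}, \code{n}, counts, percentages,
#'   \code{qualifies}), with attributes \code{baseline} (the α = 0 row),
#'   \code{selected_alpha} and \code{selection_rule}.  \code{print} and
#'   \code{plot} methods are provided.
#' @examples
#' fit <- carbo_pool()
#' sw <- alpha_sweep(generate_cohort(seed = 1001), fit, alphas = -3:3)
#' sw
#' @export
alpha_sweep <- function(cohort, params, alphas = -25:25,
                        t_inf = 180, horizon = 1440) {
  if (length(alphas) == 0) stop("alpha grid is empty")
  rows <- lapply(alphas, function(a)
    cbind(alpha = a,
          cohort_proportions(cohort, dose_formula("modified", alpha = a),
                             params, t_inf = t_inf, horizon = horizon)))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!0 %in% alphas) {
    baseline <- cbind(alpha = 0,
                      cohort_proportions(cohort, dose_formula("egfr"), params,
                                         t_inf = t_inf, horizon = horizon))
  } else {
    baseline <- tab[tab$alpha == 0, , drop = FALSE]
  }
  tab$qualifies <- qualifies_vs_baseline(tab, baseline)
  out <- structure(tab,
                   baseline = baseline,
                   selection_rule = paste(
                     "under <= baseline, target >= baseline, over <= baseline,",
                     "at least one strict; tie-break smallest |alpha|, then positive"),
                   class = c("alpha_sweep", "data.frame"))
  attr(out, "selected_alpha") <- select_alpha(out)
  out
}

qualifies_vs_baseline <- function(tab, baseline) {
  with(tab,
       pct_under <= baseline$pct_under &
       pct_target >= baseline$pct_target &
       pct_over <= baseline$pct_over &
       (pct_under < baseline$pct_under |
        pct_target > baseline$pct_target |
        pct_over < baseline$pct_over))
}

#' Select the optimal additive constant from a sweep
#'
#' An α qualifies when, against the α = 0 baseline, under-exposure does not
#' increase, target attainment does not decrease, over-exposure does not
#' increase, and at least one of the three strictly improves.  Among
#' qualifying α the one with smallest \eqn{|\alpha|} is selected (ties broken
#' toward the positive value) — the minimal perturbation of the established
#' formula.  Selection uses unrounded percentages.
#'
#' @param sweep An [alpha_sweep()] result (or a data frame with the same
#'   columns).
#' @param baseline Baseline row; defaults to the sweep's stored baseline.
#' @return The selected integer α, or \code{NA} if no α qualifies.
#' @export
select_alpha <- function(sweep, baseline = attr(sweep, "baseline")) {
  if (is.null(baseline)) stop("no baseline available")
  q <- qualifies_vs_baseline(sweep, baseline)
  if (!any(q)) return(NA_integer_)
  cand <- sweep$alpha[q]
  cand <- cand[order(abs(cand), -sign(cand))]
  as.integer(cand[1])
}

#' @exportS3Method base::print
print.alpha_sweep <- function(x, digits = 1, ...) {
  sel <- attr(x, "selected_alpha")
  b <- attr(x, "baseline")
  cat(sprintf("Alpha sweep over [%d, %d] (n = %d patients)\n",
              min(x$alpha), max(x$alpha), x$n[1]))
  cat(sprintf("Baseline (alpha = 0): target %.1f%%, under %.1f%%, gap %.1f%%, over %.2f%%\n",
              b$pct_target, b$pct_under, b$pct_gap, b$pct_over))
  if (is.na(sel)) cat("No alpha qualifies against the baseline\n")
  else {
    r <- x[x$alpha == sel, ]
    cat(sprintf("Selected alpha = %d: target %.1f%%, under %.1f%%, gap %.1f%%, over %.2f%%\n",
                sel, r$pct_target, r$pct_under, r$pct_gap, r$pct_over))
  }
  invisible(x)
}

#' Plot attainment curves across the α grid
#'
#' Base-graphics rendering of the sweep: target-attainment, under-exposure
#' and over-exposure percentages against α, with the selected α marked.
#'
#' @param x An [alpha_sweep()] result.
#' @param ... Passed to [graphics::matplot()].
#' @return \code{x}, invisibly.
#' @export
plot.alpha_sweep <- function(x, ...) {
  m <- as.matrix(x[, c("pct_target", "pct_under", "pct_over")])
  graphics::matplot(x$alpha, m, type = "l", lty = 1, lwd = 2,
                    col = c("firebrick", "forestgreen", "steelblue"),
                    xlab = expression(alpha ~ "(mL/min)"),
                    ylab = "patients (%)", ...)
  sel <- attr(x, "selected_alpha")
  if (!is.na(sel)) graphics::abline(v = sel, col = "grey40", lty = 2)
  graphics::legend("right", c("target 4-6", "under < 4", "over >= 7"),
                   lty = 1, lwd = 2,
                   col = c("firebrick", "forestgreen", "steelblue"),
                   bty = "n")
  invisible(x)
}
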