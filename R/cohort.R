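#' Read a patient cohort CSV
#'
#' Reads a per-patient table with renal function, body size and first-cycle
#' target AUC.  Two layouts are accepted and may be mixed:
#' \itemize{
#'   \item precomputed metrics: columns \code{crcl} (mL/min),
#'     \code{egfr_normalized} (mL/min/1.73 m\eqn{^2}) and \code{bsa}
#'     (m\eqn{^2}) are taken verbatim (retrospective datasets usually already
#'     carry them);
#'   \item raw covariates: \code{sex}, \code{age}, \code{weight_kg},
#'     \code{height_cm}, \code{scr} (with optional \code{scr_unit},
#'     \code{"mg_dl"} default or \code{"umol_l"}, converted by /88.4), from
#'     which any missing metric is computed with [cockcroft_gault()],
#'     [ckd_epi()] and [bsa()].
#' }
#' \code{target_auc} (mg·min/mL) is required; \code{id} and
#' \code{dataset_label} are carried through (defaults supplied if absent).
#'
#' @param path CSV path.
#' @param ckd_epi_version CKD-EPI version used when eGFR must be computed.
#' @param bsa_method BSA formula used when BSA must be computed.
#' @return A validated cohort data frame.
#' @export
read_cohort <- function(path, ckd_epi_version = 2021,
                        bsa_method = "mosteller") {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_cohort(df, ckd_epi_version = ckd_epi_version, bsa_method = bsa_method)
}

#' Validate (and complete) a cohort data frame
#'
#' @param df Data frame in either layout of [read_cohort()].
#' @inheritParams read_cohort
#' @return A cohort data frame with columns \code{id}, \code{dataset_label},
#'   \code{target_auc}, \code{bsa}, \code{crcl}, \code{egfr_normalized},
#'   \code{egfr_abs}, plus any raw covariates supplied.
#' @export
as_cohort <- function(df, ckd_epi_version = 2021, bsa_method = "mosteller") {
  df <- as.data.frame(df)
  if (nrow(df) == 0) stop("cohort is empty")
  if (!"target_auc" %in% names(df)) stop("cohort needs a 'target_auc' column")
  if (any(!is.finite(df$target_auc)) || any(df$target_auc <= 0))
    stop("target_auc must be positive")
  if (!"id" %in% names(df)) df$id <- sprintf("pt%03d", seq_len(nrow(df)))
  if (!"dataset_label" %in% names(df)) df$dataset_label <- "cohort"

  if ("scr" %in% names(df)) {
    if ("scr_unit" %in% names(df)) {
      if (!all(df$scr_unit %in% c("mg_dl", "umol_l")))
        stop("scr_unit must be 'mg_dl' or 'umol_l'")
      df$scr <- ifelse(df$scr_unit == "umol_l", df$scr / 88.4, df$scr)
      df$scr_unit <- "mg_dl"
    }
  }
  has_raw <- all(c("sex", "age", "weight_kg", "height_cm", "scr") %in% names(df))
  need <- function(col) !col %in% names(df) || any(!is.finite(df[[col]]))
  if (need("bsa")) {
    if (!has_raw) stop("'bsa' missing and raw covariates incomplete")
    df$bsa <- bsa(df$height_cm, df$weight_kg, bsa_method)
  }
  if (need("crcl")) {
    if (!has_raw) stop("'crcl' missing and raw covariates incomplete")
    df$crcl <- cockcroft_gault(df$age, df$weight_kg, df$scr, df$sex)
  }
  if (need("egfr_normalized")) {
    if (!has_raw) stop("'egfr_normalized' missing and raw covariates incomplete")
    df$egfr_normalized <- ckd_epi(df$scr, df$age, df$sex, ckd_epi_version)
  }
  for (col in c("bsa", "crcl", "egfr_normalized"))
    if (any(!is.finite(df[[col]])) || any(df[[col]] <= 0))
      stop("column '", col, "' must be positive and finite")
  df$egfr_abs <- bsa_readjust_egfr(df$egfr_normalized, df$bsa)
  df
}

#' Apply the preserved-renal-function inclusion filter
#'
#' Drops patients with Cockcroft-Gault creatinine clearance below the cutoff
#' (default 55 mL/min, the lower bound of the renal-function range covered by
#' the pooled source models), reporting how many were excluded.
#'
#' @param cohort A cohort data frame with a \code{crcl} column.
#' @param crcl_min Exclusion cutoff, mL/min.
#' @return The filtered cohort; the number excluded is attached as attribute
#'   \code{"n_excluded"} and reported via \code{message()}.
#' @export
apply_exclusion <- function(cohort, crcl_min = 55) {
  stopifnot(is.data.frame(cohort), "crcl" %in% names(cohort))
  keep <- cohort$crcl >= crcl_min
  out <- cohort[keep, , drop = FALSE]
  n_excl <- sum(!keep)
  message(sprintf("excluded %d of %d patients with CrCL < %g mL/min",
                  n_excl, nrow(cohort), crcl_min))
  if (nrow(out) == 0)
    warning("all patients fell below the CrCL cutoff; cohort is empty")
  attr(out, "n_excluded") <- n_excl
  out
}
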