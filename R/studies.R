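#' Read a table of published population-PK parameter estimates
#'
#' Reads a CSV of fixed-effect ("typical value") parameter estimates extracted
#' from published population-pharmacokinetic models, one row per study and
#' parameter, with the uncertainty reported either as a relative standard
#' error (percent coefficient of variation) or as an absolute standard error.
#'
#' Expected columns: \code{study_id}, \code{parameter} (one of CL, V1, V2, Q,
#' K12, K21), \code{estimate}, \code{uncertainty_value},
#' \code{uncertainty_kind} (\code{"RSE_percent"} or \code{"SE"}), and
#' optionally \code{n_subjects}.
#'
#' @param path Path to the CSV file.
#' @return A data frame of validated study estimates.
#' @seealso [carbo_studies()] for the packaged table of literature values.
#' @export
read_study_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_study_table(df)
}

#' Packaged table of published carboplatin PopPK estimates
#'
#' Returns the packaged study-parameter table: fixed-effect estimates of
#' clearance (CL, L/h), central and peripheral volumes (V1, V2, L),
#' intercompartmental clearance (Q, L/h) and first-order transfer rate
#' constants (K12, K21, 1/h) from three published two-compartment carboplatin
#' models in adult oncology populations, with their reported RSE% or SE.
#'
#' @return A data frame with one row per study and parameter.
#' @examples
#' head(carbo_studies())
#' @export
carbo_studies <- function() {
  path <- system.file("extdata", "pk_study_estimates.csv",
                      package = "carbodose", mustWork = TRUE)
  read_study_table(path)
}

PK_PARAMETERS <- c("CL", "V1", "V2", "Q", "K12", "K21")
UNCERTAINTY_KINDS <- c("RSE_percent", "SE")

validate_study_table <- function(df) {
  req <- c("study_id", "parameter", "estimate",
           "uncertainty_value", "uncertainty_kind")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("study table is missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$parameter %in% PK_PARAMETERS))
    stop("unknown parameter name(s): ",
         paste(unique(setdiff(df$parameter, PK_PARAMETERS)), collapse = ", "))
  if (!all(df$uncertainty_kind %in% UNCERTAINTY_KINDS))
    stop("uncertainty_kind must be one of: ",
         paste(UNCERTAINTY_KINDS, collapse = ", "))
  if (any(!is.finite(df$estimate)) || any(df$estimate <= 0))
    stop("all estimates must be finite and positive")
  if (any(!is.finite(df$uncertainty_value)) || any(df$uncertainty_value <= 0))
    stop("all uncertainty values must be finite and positive")
  if (!"n_subjects" %in% names(df)) df$n_subjects <- rep(NA_integer_, nrow(df))
  df
}

#' Harmonize a reported uncertainty to a standard error
#'
#' Published PopPK tables mix relative standard errors (RSE, percent CV) and
#' absolute standard errors.  This converts either to a standard error on the
#' requested pooling scale: on the linear scale \eqn{SE = estimate \cdot
#' RSE/100} (or the SE itself); on the log scale the delta method gives
#' \eqn{SE_{log} = SE_{linear}/estimate}, i.e. RSE/100 directly.
#'
#' @param estimate Positive parameter estimate.
#' @param uncertainty_value Positive RSE (in percent) or SE.
#' @param uncertainty_kind \code{"RSE_percent"} or \code{"SE"}.
#' @param scale \code{"linear"} or \code{"log"}.
#' @return Standard error on the requested scale.
#' @examples
#' to_standard_error(8.33, 19.1, "RSE_percent", "linear")  # 1.591
#' to_standard_error(6.99, 0.74, "SE", "linear")           # 0.74
#' to_standard_error(8.38, 1.41, "RSE_percent", "log")     # 0.0141
#' @export
to_standard_error <- function(estimate, uncertainty_value,
                              uncertainty_kind = c("RSE_percent", "SE"),
                              scale = c("linear", "log")) {
  uncertainty_kind <- match.arg(uncertainty_kind)
  scale <- match.arg(scale)
  if (!is.numeric(estimate) || any(!is.finite(estimate)) || any(estimate <= 0))
    stop("'estimate' must be positive and finite")
  if (!is.numeric(uncertainty_value) || any(!is.finite(uncertainty_value)) ||
      any(uncertainty_value <= 0))
    stop("'uncertainty_value' must be positive and finite")
  se_lin <- switch(uncertainty_kind,
                   SE = uncertainty_value,
                   RSE_percent = estimate * uncertainty_value / 100)
  switch(scale, linear = se_lin, log = se_lin / estimate)
}
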