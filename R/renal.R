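#' Cockcroft-Gault creatinine clearance
#'
#' \eqn{CrCL = (140 - age) \cdot weight / (72 \cdot S_{cr})}, multiplied by
#' 0.85 for women.  Serum creatinine in mg/dL; result in mL/min.
#'
#' @param age Age in years, in (0, 140).
#' @param weight Body weight in kg.
#' @param scr Serum creatinine in mg/dL.
#' @param sex \code{"female"} or \code{"male"}.
#' @return Creatinine clearance, mL/min.
#' @examples
#' cockcroft_gault(60, 70, 0.8, "female")  # 82.64
#' cockcroft_gault(60, 70, 0.8, "male")    # 97.22
#' @export
cockcroft_gault <- function(age, weight, scr, sex = c("female", "male")) {
  sex <- match_sex(sex, length(age))
  stopifnot(is.numeric(age), is.numeric(weight), is.numeric(scr))
  if (any(!is.finite(scr)) || any(scr <= 0))
    stop("serum creatinine must be positive")
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("weight must be positive")
  if (any(!is.finite(age)) || any(age <= 0) || any(age >= 140))
    stop("age must lie in (0, 140) years")
  crcl <- (140 - age) * weight / (72 * scr)
  crcl * ifelse(sex == "female", 0.85, 1)
}

# CKD-EPI creatinine equations (females/males), without race coefficient.
# 2009: 141 * min(Scr/k,1)^a * max(Scr/k,1)^-1.209 * 0.993^age * 1.018[F]
# 2021: 142 * min(Scr/k,1)^a * max(Scr/k,1)^-1.200 * 0.9938^age * 1.012[F]
ckd_epi_coefs <- function(version) {
  version <- as.character(version)
  switch(version,
         "2009" = list(intercept = 141, exp_high = -1.209, age_decay = 0.993,
                       female_factor = 1.018, kappa = c(female = 0.7, male = 0.9),
                       alpha = c(female = -0.329, male = -0.411)),
         "2021" = list(intercept = 142, exp_high = -1.200, age_decay = 0.9938,
                       female_factor = 1.012, kappa = c(female = 0.7, male = 0.9),
                       alpha = c(female = -0.241, male = -0.302)),
         stop("unknown CKD-EPI version: ", version, " (use 2009 or 2021)"))
}

match_sex <- function(sex, n = length(sex)) {
  sex <- as.character(sex)
  if (!all(sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'")
  rep_len(sex, n)
}

#' CKD-EPI estimated glomerular filtration rate
#'
#' The CKD-EPI creatinine equation (2009 or 2021 race-free refit; the 2009
#' form is used here without a race coefficient).  Result is normalized to
#' 1.73 m\eqn{^2} body surface area; see [bsa_readjust_egfr()] to convert to
#' an absolute mL/min value for dosing.
#'
#' @param scr Serum creatinine, mg/dL.
#' @param age Age in years.
#' @param sex \code{"female"} or \code{"male"}.
#' @param version \code{2021} (default) or \code{2009}.
#' @return eGFR in mL/min/1.73 m\eqn{^2}.
#' @examples
#' ckd_epi(0.7, 55, "female")
#' @export
ckd_epi <- function(scr, age, sex = c("female", "male"), version = 2021) {
  sex <- match_sex(sex, length(scr))
  co <- ckd_epi_coefs(version)
  stopifnot(is.numeric(scr), is.numeric(age))
  if (any(!is.finite(scr)) || any(scr <= 0)) stop("scr must be positive")
  if (any(!is.finite(age)) || any(age <= 0)) stop("age must be positive")
  kappa <- co$kappa[sex]
  alpha <- co$alpha[sex]
  ratio <- scr / kappa
  egfr <- co$intercept *
    pmin(ratio, 1)^alpha *
    pmax(ratio, 1)^co$exp_high *
    co$age_decay^age *
    ifelse(sex == "female", co$female_factor, 1)
  unname(egfr)
}

#' Invert the CKD-EPI equation for serum creatinine
#'
#' Solves for the unique serum creatinine giving a requested normalized eGFR
#' at a given age and sex (the equation is strictly decreasing in creatinine,
#' so the root is unique).  Used by the cohort generator to back-solve
#' creatinine from a sampled eGFR.
#'
#' @param egfr Target eGFR, mL/min/1.73 m\eqn{^2}.
#' @param age Age in years.
#' @param sex \code{"female"} or \code{"male"}.
#' @param version CKD-EPI version, \code{2021} (default) or \code{2009}.
#' @return Serum creatinine, mg/dL.
#' @examples
#' scr <- invert_ckd_epi(95, 60, "female")
#' ckd_epi(scr, 60, "female")  # 95
#' @export
invert_ckd_epi <- function(egfr, age, sex = c("female", "male"),
                           version = 2021) {
  sex <- match_sex(sex, length(egfr))
  stopifnot(is.numeric(egfr), is.numeric(age))
  if (any(!is.finite(egfr)) || any(egfr <= 0)) stop("egfr must be positive")
  age <- rep_len(age, length(egfr))
  lo <- 0.01; hi <- 60
  mapply(function(g, a, s) {
    f <- function(x) ckd_epi(x, a, s, version) - g
    if (f(lo) < 0 || f(hi) > 0)
      stop(sprintf("eGFR %.4g outside the attainable range for age %.4g (%s)",
                   g, a, s))
    stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  }, egfr, age, sex)
}

#' Body surface area
#'
#' Mosteller: \eqn{\sqrt{W \cdot H / 3600}}; Du Bois:
#' \eqn{0.007184 \cdot W^{0.425} \cdot H^{0.725}} (weight kg, height cm).
#'
#' @param height Height, cm.
#' @param weight Weight, kg.
#' @param method \code{"mosteller"} (default) or \code{"dubois"}.
#' @return Body surface area, m\eqn{^2}.
#' @examples
#' bsa(170, 65)             # 1.752
#' bsa(170, 65, "dubois")   # 1.754
#' @export
bsa <- function(height, weight, method = c("mosteller", "dubois")) {
  method <- match.arg(method)
  stopifnot(is.numeric(height), is.numeric(weight))
  if (any(!is.finite(height)) || any(height <= 0) ||
      any(!is.finite(weight)) || any(weight <= 0))
    stop("height and weight must be positive")
  switch(method,
         mosteller = sqrt(weight * height / 3600),
         dubois = 0.007184 * weight^0.425 * height^0.725)
}

#' De-normalize eGFR by body surface area
#'
#' Converts a BSA-normalized eGFR (mL/min/1.73 m\eqn{^2}) into the absolute
#' filtration rate entering the Calvert formula:
#' \eqn{eGFR_{abs} = eGFR \cdot BSA / 1.73} (mL/min).
#'
#' @param egfr_normalized eGFR, mL/min/1.73 m\eqn{^2}.
#' @param bsa Body surface area, m\eqn{^2}.
#' @return Absolute eGFR, mL/min.
#' @examples
#' bsa_readjust_egfr(100, 1.73)   # 100
#' bsa_readjust_egfr(98.3, 1.60)  # 90.91
#' @export
bsa_readjust_egfr <- function(egfr_normalized, bsa) {
  stopifnot(is.numeric(egfr_normalized), is.numeric(bsa))
  if (any(!is.finite(egfr_normalized)) || any(egfr_normalized <= 0))
    stop("egfr_normalized must be positive")
  if (any(!is.finite(bsa)) || any(bsa <= 0))
    stop("bsa must be positive")
  egfr_normalized * bsa / 1.73
}
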