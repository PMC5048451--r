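#' Construct UKPDS risk-engine coefficients
#'
#' @param q0 Baseline annual hazard intercept (> 0).
#' @param d Per-year hazard time-evolution ratio (> 0).
#' @param factors data.frame with columns \code{name}, \code{coefficient},
#'   \code{center}, \code{scale}, \code{type}; see
#'   \linkS4class{UkpdsCoefficients} for the fixed factor names.
#' @return A validated \linkS4class{UkpdsCoefficients}.
#' @export
UkpdsCoefficients <- function(q0, d, factors) {
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  rownames(factors) <- NULL
  new("UkpdsCoefficients", q0 = as.numeric(q0), d = as.numeric(d),
      factors = factors)
}

setMethod("show", "UkpdsCoefficients", function(object) {
  cat("UkpdsCoefficients: q0 =", object@q0, ", d =", object@d, "\n")
  print(object@factors, row.names = FALSE)
  invisible(NULL)
})

#' Read / write UKPDS coefficients as JSON
#'
#' The JSON layout is \code{{"q0": ..., "d": ..., "factors": [...]}} with
#' one object per factor. The round trip is lossless (numbers serialised at
#' full precision).
#'
#' @param path File path.
#' @return [readUkpdsCoefficients()]: an \linkS4class{UkpdsCoefficients};
#'   [writeUkpdsCoefficients()]: \code{path}, invisibly.
#' @export
readUkpdsCoefficients <- function(path) {
  if (!file.exists(path)) stop("coefficients file not found: ", path)
  x <- jsonlite::fromJSON(path)
  if (!all(c("q0", "d", "factors") %in% names(x)))
    stop("coefficients JSON needs fields q0, d, factors")
  UkpdsCoefficients(x$q0, x$d, x$factors)
}

#' @rdname readUkpdsCoefficients
#' @param coeffs An \linkS4class{UkpdsCoefficients}.
#' @export
writeUkpdsCoefficients <- function(coeffs, path) {
  stopifnot(is(coeffs, "UkpdsCoefficients"))
  jsonlite::write_json(
    list(q0 = coeffs@q0, d = coeffs@d, factors = coeffs@factors),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Published UKPDS risk-engine coefficients
#'
#' The coefficient set of the published UKPDS Risk Engine for 10-year CHD
#' risk in type 2 diabetes (Stevens et al. 2001, UKPDS 56), transcribed
#' into the bundled \code{ukpds56_coefficients.json}: intercept
#' q0 = 0.0112; hazard ratio per year d = 1.078; age at diagnosis 1.059
#' (centred at 55 years); female sex 0.525; Afro-Caribbean ethnicity 0.390;
#' smoking 1.350; HbA1c 1.183 (centred at 6.72 \%); systolic blood pressure
#' 1.088 per 10 mmHg (centred at 135.7); log lipid ratio
#' ln(total/HDL cholesterol) 3.845 (centred at 1.59).
#'
#' @return An \linkS4class{UkpdsCoefficients}.
#' @references Stevens RJ, Kothari V, Adler AI, Stratton IM (2001). The
#'   UKPDS risk engine: a model for the risk of coronary heart disease in
#'   type II diabetes (UKPDS 56). Clinical Science 101(6), 671-679.
#' @export
defaultUkpdsCoefficients <- function() {
  path <- system.file("extdata", "ukpds56_coefficients.json",
                      package = "chdrisk", mustWork = TRUE)
  readUkpdsCoefficients(path)
}

#' Validate a clinical-profile table
#'
#' Checks the nine UKPDS inputs: \code{subject_id}, \code{age_at_diagnosis}
#' (years), \code{duration_t2d} (years, >= 0), \code{sex} ("male"/"female"),
#' \code{afro_caribbean} (logical; mixed ethnicity is coded FALSE, as the
#' engine's developers advise), \code{smoker} (logical), \code{hba1c} (\%,
#' > 0), \code{sbp} (mmHg, > 0), \code{total_cholesterol} and
#' \code{hdl_cholesterol} (mmol/l, HDL > 0). Current age is always derived
#' as \code{age_at_diagnosis + duration_t2d}, never stored.
#'
#' @param profiles A data.frame of clinical profiles.
#' @return The validated data.frame (columns coerced), invisibly usable.
#' @export
validateClinical <- function(profiles) {
  req <- c("subject_id", "age_at_diagnosis", "duration_t2d", "sex",
           "afro_caribbean", "smoker", "hba1c", "sbp",
           "total_cholesterol", "hdl_cholesterol")
  missing_cols <- setdiff(req, names(profiles))
  if (length(missing_cols) > 0)
    stop("clinical table lacks column(s): ", paste(missing_cols, collapse = ", "))
  p <- profiles
  p$sex <- tolower(as.character(p$sex))
  if (!all(p$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  for (col in c("afro_caribbean", "smoker")) {
    v <- p[[col]]
    if (is.character(v)) v <- tolower(v) %in% c("true", "t", "1", "yes")
    p[[col]] <- as.logical(v)
  }
  num <- c("age_at_diagnosis", "duration_t2d", "hba1c", "sbp",
           "total_cholesterol", "hdl_cholesterol")
  for (col in num) p[[col]] <- as.numeric(p[[col]])
  if (any(!is.finite(as.matrix(p[num]))))
    stop("non-finite value in clinical columns")
  if (any(p$duration_t2d < 0)) stop("duration_t2d must be >= 0")
  if (any(p$hdl_cholesterol <= 0)) stop("hdl_cholesterol must be > 0")
  if (any(p$total_cholesterol <= 0)) stop("total_cholesterol must be > 0")
  if (any(p$hba1c <= 0)) stop("hba1c must be > 0")
  if (any(p$sbp <= 0)) stop("sbp must be > 0")
  p
}

#' Read clinical profiles from CSV
#'
#' One row per subject with the nine UKPDS inputs (see
#' [validateClinical()]). Lines starting with \code{#} are ignored.
#'
#' @param path CSV path.
#' @return A validated data.frame.
#' @export
readClinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  validateClinical(utils::read.csv(path, stringsAsFactors = FALSE,
                                   comment.char = "#"))
}

#' Subject-specific annual hazard term q
#'
#' The UKPDS engine's hazard intercept scaled by one positive multiplier
#' per risk factor: \code{q = q0 * prod(coefficient^exposure)}, where the
#' exposure of a continuous factor is \code{(value - center) / scale} and
#' of a binary factor is 0/1. The lipid exposure is
#' \code{log(total_cholesterol / hdl_cholesterol)}. A profile sitting
#' exactly at all centring constants (male, non-Afro-Caribbean, non-smoker)
#' therefore has \code{q = q0}.
#'
#' @param profiles Clinical data.frame (see [validateClinical()]).
#' @param coeffs An \linkS4class{UkpdsCoefficients}.
#' @return Named numeric vector of q values, one per subject.
#' @export
computeQ <- function(profiles, coeffs) {
  stopifnot(is(coeffs, "UkpdsCoefficients"))
  p <- validateClinical(profiles)
  values <- cbind(
    age_at_diagnosis = p$age_at_diagnosis,
    female = as.numeric(p$sex == "female"),
    afro_caribbean = as.numeric(p$afro_caribbean),
    smoker = as.numeric(p$smoker),
    hba1c = p$hba1c,
    sbp = p$sbp,
    lipid_ratio = log(p$total_cholesterol / p$hdl_cholesterol))
  f <- coeffs@factors
  q <- rep(coeffs@q0, nrow(p))
  for (i in seq_len(nrow(f))) {
    x <- values[, f$name[i]]
    expo <- if (f$type[i] == "continuous") (x - f$center[i]) / f$scale[i] else x
    q <- q * f$coefficient[i]^expo
  }
  stats::setNames(q, p$subject_id)
}

#' Cumulative CHD risk over a horizon from an annual hazard
#'
#' The UKPDS engine evolves the annual hazard geometrically with time since
#' diagnosis: the hazard in year t after diagnosis is \code{q * d^t}. The
#' probability of an event within \code{horizon} years for a subject
#' already \code{duration} years from diagnosis is
#' \deqn{R = 1 - \exp\left(-q\, d^{dur} \frac{1 - d^{T}}{1 - d}\right),}
#' the complement of the survival over the geometric sum of yearly hazards.
#' At \code{d = 1} the analytic limit (geometric sum = horizon) is used.
#'
#' @param q Annual hazard(s), >= 0 (vectorised).
#' @param duration Years since T2D diagnosis (vectorised, >= 0).
#' @param horizon Risk horizon in years (>= 0; default 10).
#' @param d Per-year hazard ratio (> 0).
#' @return Probabilities in [0, 1].
#' @examples
#' cumulativeRisk(0.02, duration = 0, horizon = 10, d = 1)  # 1 - exp(-0.2)
#' @export
cumulativeRisk <- function(q, duration, horizon = 10, d) {
  if (any(!is.finite(q)) || any(q < 0)) stop("q must be finite and >= 0")
  if (any(duration < 0)) stop("duration must be >= 0")
  if (length(horizon) != 1L || horizon < 0) stop("horizon must be a single value >= 0")
  if (length(d) != 1L || !is.finite(d) || d <= 0) stop("d must be a single positive number")
  gsum <- if (d == 1) horizon else (1 - d^horizon) / (1 - d)
  r <- 1 - exp(-q * d^duration * gsum)
  pmin(pmax(r, 0), 1)
}

#' 10-year CHD risk for T2D subjects (UKPDS engine)
#'
#' Composes [computeQ()] and [cumulativeRisk()] for a table of clinical
#' profiles.
#'
#' @inheritParams computeQ
#' @param horizon Risk horizon in years (default 10).
#' @return A data.frame with columns \code{subject_id}, \code{q},
#'   \code{horizon}, \code{risk}, \code{risk_pct} (percentage, 2 decimals)
#'   and \code{kind = "clinical_only"}.
#' @examples
#' coeffs <- defaultUkpdsCoefficients()
#' prof <- data.frame(subject_id = "s1", age_at_diagnosis = 55,
#'                    duration_t2d = 5, sex = "male",
#'                    afro_caribbean = FALSE, smoker = FALSE, hba1c = 7.5,
#'                    sbp = 140, total_cholesterol = 5.2,
#'                    hdl_cholesterol = 1.1)
#' ukpdsRisk(prof, coeffs)
#' @export
ukpdsRisk <- function(profiles, coeffs, horizon = 10) {
  p <- validateClinical(profiles)
  q <- computeQ(p, coeffs)
  r <- cumulativeRisk(q, p$duration_t2d, horizon = horizon, d = coeffs@d)
  data.frame(subject_id = p$subject_id,
             q = unname(q),
             horizon = horizon,
             risk = unname(r),
             risk_pct = round(100 * unname(r), 2),
             kind = "clinical_only",
             stringsAsFactors = FALSE)
}
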