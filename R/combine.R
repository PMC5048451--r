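#' Configuration for combining genetic and clinical risk
#'
#' @param p0 Baseline ten-year CHD incidence anchoring the odds-ratio to
#'   relative-risk conversion (default 0.3).
#' @param reference_gene_score Gene score at which the relative odds ratio
#'   is 1. \code{NULL} (default) means: use the panel's Hardy-Weinberg
#'   population expectation at combination time; a cohort mean may be
#'   supplied instead.
#' @return A validated \linkS4class{CombinationConfig}.
#' @export
combinationConfig <- function(p0 = 0.3, reference_gene_score = NULL) {
  new("CombinationConfig", p0 = as.numeric(p0),
      reference_gene_score = reference_gene_score)
}

setMethod("show", "CombinationConfig", function(object) {
  cat("CombinationConfig: p0 =", object@p0, ", reference gene score =",
      if (is.null(object@reference_gene_score)) "HWE panel expectation"
      else object@reference_gene_score, "\n")
  invisible(NULL)
})

#' Relative odds ratio implied by a gene score
#'
#' Gene scores are sums of per-allele log odds ratios, so the odds ratio of
#' a subject relative to the reference score is
#' \code{exp(gs - reference)}: 1 at the reference, 2 at reference + ln 2.
#'
#' @param gs Numeric vector of gene scores.
#' @param reference Reference gene score (scalar).
#' @return Positive numeric vector.
#' @export
relativeOddsRatio <- function(gs, reference) {
  if (any(!is.finite(gs))) stop("gene scores must be finite")
  if (length(reference) != 1L || !is.finite(reference))
    stop("reference must be a single finite number")
  exp(gs - reference)
}

#' Convert an odds ratio to a relative risk at a baseline incidence
#'
#' The standard epidemiological conversion
#' \deqn{RR = \frac{OR}{1 - p_0 + p_0\, OR}} at baseline incidence
#' \code{p0}. RR = 1 when OR = 1; RR approaches OR as \code{p0} approaches
#' 0; RR always lies between 1 and OR.
#'
#' @param odds_ratio Positive numeric vector.
#' @param p0 Baseline incidence in (0, 1).
#' @return Numeric vector of relative risks.
#' @examples
#' orToRr(2, p0 = 0.3)  # 2 / 1.3
#' @export
orToRr <- function(odds_ratio, p0) {
  if (any(!is.finite(odds_ratio)) || any(odds_ratio <= 0))
    stop("odds_ratio must be positive")
  if (length(p0) != 1L || !is.finite(p0) || p0 <= 0 || p0 >= 1)
    stop("p0 must be a single number strictly between 0 and 1")
  odds_ratio / (1 - p0 + p0 * odds_ratio)
}

#' Combined genetic + clinical ten-year CHD risk
#'
#' Fuses the gene score with the UKPDS engine: the gene score's relative
#' odds ratio (centred at the reference score) is converted to a relative
#' risk at baseline incidence \code{p0} and multiplied into the subject's
#' annual hazard \code{q} before the cumulative-risk step. A subject at the
#' reference score therefore has combined risk identical to the
#' clinical-only UKPDS risk; a higher score strictly raises it.
#'
#' @param profiles Clinical data.frame (see [validateClinical()]); one row
#'   per subject, aligned with \code{gene_scores} by \code{subject_id}.
#' @param gene_scores Either a numeric vector (in profile row order, or
#'   named by subject id) or a data.frame from [computeGeneScore()].
#' @param coeffs An \linkS4class{UkpdsCoefficients}.
#' @param config A \linkS4class{CombinationConfig}; if its reference score
#'   is \code{NULL}, \code{panel} must be supplied (with weights) so the
#'   HWE expectation can be used.
#' @param panel Optional \linkS4class{SnpPanel}, only needed to derive the
#'   default reference score.
#' @param horizon Risk horizon in years (default 10).
#' @return A data.frame with columns \code{subject_id}, \code{gene_score},
#'   \code{or_rel}, \code{rr}, \code{ukpds_risk}, \code{combined_risk},
#'   \code{combined_risk_pct} and \code{kind = "combined"}.
#' @export
combinedRisk <- function(profiles, gene_scores, coeffs,
                         config = combinationConfig(), panel = NULL,
                         horizon = 10) {
  stopifnot(is(coeffs, "UkpdsCoefficients"), is(config, "CombinationConfig"))
  p <- validateClinical(profiles)
  if (is.data.frame(gene_scores)) {
    idx <- match(p$subject_id, gene_scores$subject_id)
    if (anyNA(idx))
      stop("no gene score for subject(s): ",
           paste(p$subject_id[is.na(idx)], collapse = ", "))
    gs <- gene_scores$gene_score[idx]
  } else if (!is.null(names(gene_scores))) {
    idx <- match(p$subject_id, names(gene_scores))
    if (anyNA(idx))
      stop("no gene score for subject(s): ",
           paste(p$subject_id[is.na(idx)], collapse = ", "))
    gs <- unname(gene_scores[idx])
  } else {
    if (length(gene_scores) != nrow(p))
      stop("unnamed gene_scores must match profiles row for row")
    gs <- as.numeric(gene_scores)
  }
  reference <- config@reference_gene_score
  if (is.null(reference)) {
    if (is.null(panel))
      stop("config has no reference gene score: supply `panel` so the HWE ",
           "population expectation can be used")
    reference <- expectedGeneScore(panel)
  }
  or_rel <- relativeOddsRatio(gs, reference)
  rr <- orToRr(or_rel, config@p0)
  q <- computeQ(p, coeffs)
  clin <- cumulativeRisk(q, p$duration_t2d, horizon = horizon, d = coeffs@d)
  comb <- cumulativeRisk(unname(q) * rr, p$duration_t2d, horizon = horizon,
                         d = coeffs@d)
  data.frame(subject_id = p$subject_id,
             gene_score = gs,
             or_rel = or_rel,
             rr = rr,
             ukpds_risk = unname(clin),
             combined_risk = comb,
             combined_risk_pct = round(100 * comb, 2),
             kind = "combined",
             stringsAsFactors = FALSE)
}
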