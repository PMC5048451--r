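#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' SnpPanel: a weighted SNP score definition
#'
#' An ordered panel of biallelic SNPs defining a weighted CHD gene score.
#' Each SNP carries a risk allele, the other allele, the population risk
#' allele frequency (RAF), a per-allele effect weight on the natural-log
#' odds-ratio scale, and an inheritance model (\code{"additive"} or
#' \code{"recessive"}).
#'
#' @slot snps A \code{data.frame} with one row per SNP and columns
#'   \code{rsid}, \code{gene}, \code{chromosome}, \code{risk_allele},
#'   \code{other_allele}, \code{raf}, \code{weight}, \code{model}.
#'
#' @details Validity requires unique rsIDs, \code{raf} in [0, 1], distinct
#'   single-character allele codes per SNP, and
#'   \code{model \%in\% c("additive", "recessive")}. Weights may be
#'   \code{NA} (they are a required user input for scoring; the bundled
#'   default panel ships without them).
#'
#' @seealso [readPanel()], [defaultPanel()], [computeGeneScore()]
#' @export
setClass("SnpPanel", representation(snps = "data.frame"))

setValidity("SnpPanel", function(object) {
  s <- object@snps
  req <- c("rsid", "gene", "chromosome", "risk_allele", "other_allele",
           "raf", "weight", "model")
  missing_cols <- setdiff(req, names(s))
  if (length(missing_cols) > 0)
    return(paste("missing panel columns:", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(s$rsid))
    return(paste("duplicate rsid(s):",
                 paste(unique(s$rsid[duplicated(s$rsid)]), collapse = ", ")))
  if (any(!is.finite(s$raf)) || any(s$raf < 0) || any(s$raf > 1))
    return("raf must lie in [0, 1] for every SNP")
  if (any(nchar(s$risk_allele) != 1L) || any(nchar(s$other_allele) != 1L))
    return("allele codes must be single characters")
  if (any(s$risk_allele == s$other_allele))
    return("risk_allele and other_allele must differ")
  bad_model <- setdiff(unique(s$model), c("additive", "recessive"))
  if (length(bad_model) > 0)
    return(paste("unknown inheritance model:", paste(bad_model, collapse = ", ")))
  TRUE
})

#' GenotypeSet: subject-by-SNP genotype calls
#'
#' Genotype calls for a set of subjects across the SNPs of a panel, stored
#' as two aligned character matrices of allele codes (subjects in rows,
#' SNPs in columns). A missing call has \code{NA} in both matrices; half
#' calls are invalid.
#'
#' @slot allele1,allele2 Character matrices with identical dimnames
#'   (rownames = subject identifiers, colnames = rsIDs).
#'
#' @seealso [readGenotypes()], [simulateGenotypes()], [dosageMatrix()]
#' @export
setClass("GenotypeSet",
         representation(allele1 = "matrix", allele2 = "matrix"))

setValidity("GenotypeSet", function(object) {
  a1 <- object@allele1; a2 <- object@allele2
  if (!identical(dim(a1), dim(a2)))
    return("allele1 and allele2 must have identical dimensions")
  if (!identical(dimnames(a1), dimnames(a2)))
    return("allele1 and allele2 must have identical dimnames")
  if (is.null(rownames(a1)) || is.null(colnames(a1)))
    return("subject ids (rownames) and rsids (colnames) are required")
  if (anyDuplicated(rownames(a1)))
    return("duplicate subject ids")
  if (anyDuplicated(colnames(a1)))
    return("duplicate rsids")
  if (!identical(is.na(a1), is.na(a2)))
    return("half-calls are not allowed: both alleles must be present or both missing")
  TRUE
})

#' UkpdsCoefficients: the UKPDS CHD risk-engine parameterisation
#'
#' The multiplicative-hazard parameterisation of the UKPDS 10-year CHD risk
#' equation for subjects with type 2 diabetes: a baseline annual hazard
#' intercept \code{q0}, a per-year hazard time-evolution ratio \code{d},
#' and one positive multiplier per risk factor with its reference-centring
#' constant and scale.
#'
#' @slot q0 Baseline annual hazard (positive scalar).
#' @slot d Per-year hazard ratio (positive scalar, not equal to 1; the
#'   analytic limit at 1 is handled explicitly by [cumulativeRisk()]).
#' @slot factors A \code{data.frame} with columns \code{name},
#'   \code{coefficient}, \code{center}, \code{scale}, \code{type}
#'   (\code{"continuous"} or \code{"binary"}). The hazard contribution of a
#'   factor with exposure x is \code{coefficient^((x - center)/scale)} for
#'   continuous factors and \code{coefficient^x} (x in 0/1) for binary ones.
#'
#' @details The factor names are fixed: \code{age_at_diagnosis},
#'   \code{female}, \code{afro_caribbean}, \code{smoker}, \code{hba1c},
#'   \code{sbp}, \code{lipid_ratio} (the lipid exposure is
#'   \code{log(total_cholesterol / hdl_cholesterol)}).
#'
#' @seealso [defaultUkpdsCoefficients()], [computeQ()], [ukpdsRisk()]
#' @export
setClass("UkpdsCoefficients",
         representation(q0 = "numeric", d = "numeric", factors = "data.frame"))

.ukpds_factor_names <- c("age_at_diagnosis", "female", "afro_caribbean",
                         "smoker", "hba1c", "sbp", "lipid_ratio")

setValidity("UkpdsCoefficients", function(object) {
  if (length(object@q0) != 1L || !is.finite(object@q0) || object@q0 <= 0)
    return("q0 must be a single positive number")
  if (length(object@d) != 1L || !is.finite(object@d) || object@d <= 0)
    return("d must be a single positive number")
  f <- object@factors
  req <- c("name", "coefficient", "center", "scale", "type")
  if (!all(req %in% names(f)))
    return(paste("factors needs columns:", paste(req, collapse = ", ")))
  if (!setequal(f$name, .ukpds_factor_names) || anyDuplicated(f$name))
    return(paste("factors must contain exactly:",
                 paste(.ukpds_factor_names, collapse = ", ")))
  if (any(!is.finite(f$coefficient)) || any(f$coefficient <= 0))
    return("all factor coefficients must be positive")
  if (any(!is.finite(f$center)) || any(!is.finite(f$scale)) || any(f$scale == 0))
    return("centers must be finite and scales finite non-zero")
  if (!all(f$type %in% c("continuous", "binary")))
    return("factor type must be 'continuous' or 'binary'")
  TRUE
})

#' ConcordanceTable: per-SNP genotyping concordance between two call sources
#'
#' Cross-tabulation of genotype calls from two sources (e.g. a genotyping
#' array validated against previously determined reference genotypes), with
#' per-SNP comparison counts and the reference-source genotype distribution
#' (common homozygote / heterozygote / rare homozygote).
#'
#' @slot records A \code{data.frame} with columns \code{rsid},
#'   \code{n_compared}, \code{n_concordant}, \code{n_discordant},
#'   \code{hom_common}, \code{het}, \code{hom_rare}.
#' @slot overall_compared,overall_concordant Integer totals; validity
#'   requires them to equal the column sums of the records.
#'
#' @details The genotype-distribution columns are not required to sum to
#'   \code{n_compared}: published tables occasionally print inconsistent
#'   rows, and [summarizeConcordance()] flags such rows rather than
#'   rejecting them.
#'
#' @seealso [compareCallSets()], [summarizeConcordance()]
#' @export
setClass("ConcordanceTable",
         representation(records = "data.frame",
                        overall_compared = "integer",
                        overall_concordant = "integer"))

setValidity("ConcordanceTable", function(object) {
  r <- object@records
  req <- c("rsid", "n_compared", "n_concordant", "n_discordant",
           "hom_common", "het", "hom_rare")
  if (!all(req %in% names(r)))
    return(paste("records needs columns:", paste(req, collapse = ", ")))
  if (anyDuplicated(r$rsid)) return("duplicate rsid in records")
  cnt <- c(r$n_compared, r$n_concordant, r$n_discordant,
           r$hom_common, r$het, r$hom_rare)
  if (any(!is.finite(cnt)) || any(cnt < 0)) return("counts must be non-negative")
  if (any(r$n_concordant + r$n_discordant != r$n_compared))
    return("n_concordant + n_discordant must equal n_compared")
  if (object@overall_compared != sum(r$n_compared))
    return("overall_compared must equal sum of per-SNP n_compared")
  if (object@overall_concordant != sum(r$n_concordant))
    return("overall_concordant must equal sum of per-SNP n_concordant")
  TRUE
})

#' CombinationConfig: how genetic and clinical risk are fused
#'
#' Configuration for combining the gene score with the UKPDS engine: the
#' baseline ten-year CHD incidence \code{p0} anchoring the odds-ratio to
#' relative-risk conversion, and the reference gene score at which the
#' relative odds ratio equals 1.
#'
#' @slot p0 Baseline incidence, in (0, 1). Default 0.3.
#' @slot reference_gene_score The centring score. If \code{NULL} at
#'   combination time, the panel's Hardy-Weinberg population expectation
#'   ([expectedGeneScore()]) is used.
#'
#' @seealso [combinationConfig()], [combinedRisk()]
#' @export
setClass("CombinationConfig",
         representation(p0 = "numeric", reference_gene_score = "numericOrNULL"))

setValidity("CombinationConfig", function(object) {
  if (length(object@p0) != 1L || !is.finite(object@p0) ||
      object@p0 <= 0 || object@p0 >= 1)
    return("p0 must be a single number strictly between 0 and 1")
  r <- object@reference_gene_score
  if (!is.null(r) && (length(r) != 1L || !is.finite(r)))
    return("reference_gene_score must be a single finite number or NULL")
  TRUE
})
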