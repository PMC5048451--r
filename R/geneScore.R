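#' Weighted CHD gene score per subject
#'
#' The gene score is the weighted sum of risk-allele carriage across the
#' panel: for additive SNPs the dosage g (0/1/2) times the per-allele
#' weight w (natural-log odds ratio); for recessive SNPs (NOS3 rs1799983 in
#' the default panel) a homozygous-risk indicator times the weight, so that
#' heterozygotes contribute nothing.
#'
#' @param gs A \linkS4class{GenotypeSet}.
#' @param panel A \linkS4class{SnpPanel} with all weights set.
#' @param missing Missing-call policy: \code{"error"} (default) requires a
#'   complete panel; \code{"impute"} substitutes the HWE expectation
#'   (dosage \code{2 * raf} for additive SNPs, homozygote probability
#'   \code{raf^2} for recessive ones).
#' @param recessiveContribution For a recessive SNP, a homozygote
#'   contributes the weight once (\code{"single"}, the default) or twice
#'   (\code{"double"}, i.e. per allele as for additive SNPs).
#' @return A data.frame with columns \code{subject_id},
#'   \code{n_risk_alleles}, \code{gene_score}.
#' @examples
#' panel <- defaultPanel(weights = placeholderWeights())
#' g <- simulateGenotypes(panel, n = 5, seed = 1)
#' computeGeneScore(g, panel)
#' @export
computeGeneScore <- function(gs, panel, missing = c("error", "impute"),
                             recessiveContribution = c("single", "double")) {
  missing <- match.arg(missing)
  recessiveContribution <- match.arg(recessiveContribution)
  s <- snpInfo(panel)
  if (anyNA(s$weight))
    stop("panel weights are not set for: ",
         paste(s$rsid[is.na(s$weight)], collapse = ", "),
         "; supply weights (see panelWeights<-)")
  d <- dosageMatrix(gs, panel,
                    missing = if (missing == "error") "error" else "na")
  k <- match(colnames(d), s$rsid)
  w <- s$weight[k]
  model <- s$model[k]
  raf <- s$raf[k]
  contrib <- d
  rec <- model == "recessive"
  if (any(rec)) {
    mult <- if (recessiveContribution == "double") 2 else 1
    contrib[, rec] <- mult * (d[, rec, drop = FALSE] == 2)
  }
  if (missing == "impute" && anyNA(contrib)) {
    exp_contrib <- ifelse(rec,
                          (if (recessiveContribution == "double") 2 else 1) * raf^2,
                          2 * raf)
    for (j in which(colSums(is.na(contrib)) > 0))
      contrib[is.na(contrib[, j]), j] <- exp_contrib[j]
    exp_dos <- 2 * raf
    for (j in which(colSums(is.na(d)) > 0))
      d[is.na(d[, j]), j] <- exp_dos[j]
  }
  score <- as.vector(contrib %*% w)
  data.frame(subject_id = rownames(d),
             n_risk_alleles = rowSums(d),
             gene_score = score,
             stringsAsFactors = FALSE)
}

#' Population-expected gene score under Hardy-Weinberg equilibrium
#'
#' The expectation of the gene score for a subject drawn from a population
#' at the panel's risk allele frequencies: additive SNPs contribute
#' \code{w * 2 * raf}, recessive SNPs \code{w * raf^2} (homozygote
#' probability). Used as the default centring point when converting a gene
#' score to a relative odds ratio.
#'
#' @param panel A \linkS4class{SnpPanel} with all weights set.
#' @param recessiveContribution As in [computeGeneScore()].
#' @return A single number.
#' @export
expectedGeneScore <- function(panel,
                              recessiveContribution = c("single", "double")) {
  recessiveContribution <- match.arg(recessiveContribution)
  s <- snpInfo(panel)
  if (anyNA(s$weight))
    stop("panel weights are not set for: ",
         paste(s$rsid[is.na(s$weight)], collapse = ", "))
  mult <- if (recessiveContribution == "double") 2 else 1
  per_snp <- ifelse(s$model == "recessive",
                    mult * s$weight * s$raf^2,
                    s$weight * 2 * s$raf)
  sum(per_snp)
}

#' Rank-based tertile assignment
#'
#' Splits values into three groups of as-equal-as-possible size by rank,
#' with ties broken by stable input order.
#'
#' @param x Numeric vector.
#' @return Integer vector in \{1, 2, 3\}; group sizes differ by at most 1.
#' @export
assignTertiles <- function(x) {
  if (length(x) == 0) stop("cannot assign tertiles of an empty vector")
  r <- rank(x, ties.method = "first")
  as.integer(floor((r - 1) * 3 / length(x)) + 1L)
}

#' Summarise a cohort's gene scores
#'
#' Mean, median, range, empirical tertile cut-points (1/3 and 2/3
#' quantiles) and per-subject tertile assignment.
#'
#' @param scores A data.frame as returned by [computeGeneScore()], or a
#'   numeric vector of gene scores.
#' @return A list with elements \code{n}, \code{mean}, \code{median},
#'   \code{range}, \code{tertile_cutpoints}, \code{tertile_sizes} and
#'   \code{tertile} (per-subject assignment in input order).
#' @export
geneScoreDistribution <- function(scores) {
  x <- if (is.data.frame(scores)) scores$gene_score else as.numeric(scores)
  if (length(x) == 0) stop("empty gene-score collection")
  if (anyNA(x)) stop("gene scores contain NA")
  tert <- assignTertiles(x)
  list(n = length(x),
       mean = mean(x),
       median = stats::median(x),
       range = range(x),
       tertile_cutpoints = unname(stats::quantile(x, c(1, 2) / 3)),
       tertile_sizes = as.integer(table(factor(tert, levels = 1:3))),
       tertile = tert)
}
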