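#' Construct a ConcordanceTable from per-SNP counts
#'
#' @param records data.frame with columns \code{rsid}, \code{n_compared},
#'   \code{n_discordant} (or \code{n_concordant}), and genotype-distribution
#'   columns \code{hom_common}, \code{het}, \code{hom_rare}.
#' @return A validated \linkS4class{ConcordanceTable}.
#' @export
ConcordanceTable <- function(records) {
  r <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"n_concordant" %in% names(r)) {
    if (!"n_discordant" %in% names(r))
      stop("records need n_concordant or n_discordant")
    r$n_concordant <- r$n_compared - r$n_discordant
  }
  if (!"n_discordant" %in% names(r))
    r$n_discordant <- r$n_compared - r$n_concordant
  for (col in c("hom_common", "het", "hom_rare"))
    if (!col %in% names(r)) r[[col]] <- NA_integer_
  int_cols <- c("n_compared", "n_concordant", "n_discordant",
                "hom_common", "het", "hom_rare")
  for (col in int_cols) r[[col]] <- as.integer(r[[col]])
  r <- r[c("rsid", int_cols)]
  rownames(r) <- NULL
  new("ConcordanceTable", records = r,
      overall_compared = sum(r$n_compared),
      overall_concordant = sum(r$n_concordant))
}

#' @rdname ConcordanceTable-class
#' @export
setMethod("concordanceRecords", "ConcordanceTable", function(x) x@records)

setMethod("show", "ConcordanceTable", function(object) {
  cat("ConcordanceTable:", nrow(object@records), "SNPs;",
      object@overall_concordant, "/", object@overall_compared,
      "concordant calls\n")
  invisible(NULL)
})

#' Read a per-SNP concordance-count table
#'
#' Reads a TSV of per-SNP comparison counts (columns \code{rsid},
#' \code{n_compared}, \code{n_discordant}, \code{hom_common}, \code{het},
#' \code{hom_rare}). With \code{path} omitted, loads the bundled published
#' validation counts for the default 19-SNP panel (an array validated
#' against previously determined genotypes; 3158 comparisons).
#'
#' @param path TSV path, or \code{NULL} for the bundled table.
#' @return A \linkS4class{ConcordanceTable}.
#' @export
readConcordanceCounts <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "array_validation_counts.tsv",
                        package = "chdrisk", mustWork = TRUE)
  if (!file.exists(path)) stop("concordance count file not found: ", path)
  ConcordanceTable(utils::read.delim(path, comment.char = "#",
                                     stringsAsFactors = FALSE))
}

## Classify each reference call as common homozygote / heterozygote / rare
## homozygote, where "common" is the more frequent allele among the
## reference calls at that SNP (ties broken toward the panel risk allele).
.genotypeClassCounts <- function(r1, r2, risk_allele, other_allele) {
  n_risk <- sum(r1 == risk_allele, na.rm = TRUE) +
            sum(r2 == risk_allele, na.rm = TRUE)
  n_other <- sum(r1 == other_allele, na.rm = TRUE) +
             sum(r2 == other_allele, na.rm = TRUE)
  common <- if (n_risk >= n_other) risk_allele else other_allele
  dos <- (r1 == common) + (r2 == common)
  c(hom_common = sum(dos == 2, na.rm = TRUE),
    het = sum(dos == 1, na.rm = TRUE),
    hom_rare = sum(dos == 0, na.rm = TRUE))
}

#' Compare two genotype call sets SNP by SNP
#'
#' Cross-tabulates calls from two sources over their shared subjects. A
#' pair is compared only where BOTH sources have a non-missing call, so
#' per-SNP n varies with missingness; genotypes are compared as unordered
#' allele pairs. The genotype-distribution columns describe the
#' reference-source calls among the compared pairs.
#'
#' @param array_calls,reference_calls \linkS4class{GenotypeSet}s sharing at
#'   least one subject id.
#' @param panel The companion \linkS4class{SnpPanel}.
#' @return A \linkS4class{ConcordanceTable}. The result is symmetric in the
#'   two sources up to the genotype-distribution columns.
#' @export
compareCallSets <- function(array_calls, reference_calls, panel) {
  stopifnot(is(array_calls, "GenotypeSet"), is(reference_calls, "GenotypeSet"),
            is(panel, "SnpPanel"))
  .checkAllelesAgainstPanel(array_calls, panel)
  .checkAllelesAgainstPanel(reference_calls, panel)
  shared <- intersect(subjectIds(array_calls), subjectIds(reference_calls))
  if (length(shared) == 0)
    stop("no overlapping subjects between the two call sets")
  s <- snpInfo(panel)
  rs_shared <- intersect(rsids(array_calls), rsids(reference_calls))
  rs <- s$rsid[s$rsid %in% rs_shared]
  a1 <- array_calls@allele1[shared, rs, drop = FALSE]
  a2 <- array_calls@allele2[shared, rs, drop = FALSE]
  r1 <- reference_calls@allele1[shared, rs, drop = FALSE]
  r2 <- reference_calls@allele2[shared, rs, drop = FALSE]
  records <- lapply(seq_along(rs), function(j) {
    ok <- !is.na(a1[, j]) & !is.na(r1[, j])
    ## unordered-pair equality
    same <- (a1[ok, j] == r1[ok, j] & a2[ok, j] == r2[ok, j]) |
            (a1[ok, j] == r2[ok, j] & a2[ok, j] == r1[ok, j])
    k <- match(rs[j], s$rsid)
    cls <- .genotypeClassCounts(r1[ok, j], r2[ok, j],
                                s$risk_allele[k], s$other_allele[k])
    data.frame(rsid = rs[j], n_compared = sum(ok),
               n_concordant = sum(same),
               n_discordant = sum(ok) - sum(same),
               hom_common = cls[["hom_common"]], het = cls[["het"]],
               hom_rare = cls[["hom_rare"]], stringsAsFactors = FALSE)
  })
  ConcordanceTable(do.call(rbind, records))
}

#' Summarise a concordance table
#'
#' Overall and per-SNP concordance percentages (round-half-even to 1
#' decimal, the convention of published validation tables), the list of
#' SNPs with discordant calls, and a flag for records whose printed
#' genotype-distribution counts do not sum to their number of comparisons
#' (published tables occasionally contain such rows; they are reported, not
#' corrected).
#'
#' @param table A \linkS4class{ConcordanceTable}.
#' @return A list with \code{overall_compared}, \code{overall_concordant},
#'   \code{overall_pct}, \code{per_snp} (data.frame with \code{pct}),
#'   \code{discordant} (data.frame of SNPs with discordances) and
#'   \code{inconsistent_rows} (rsids whose genotype counts do not sum to
#'   n_compared).
#' @export
summarizeConcordance <- function(table) {
  stopifnot(is(table, "ConcordanceTable"))
  r <- table@records
  if (table@overall_compared == 0)
    stop("no comparisons: overall concordance undefined")
  per <- r
  per$pct <- round(100 * per$n_concordant / per$n_compared, 1)
  gsum <- r$hom_common + r$het + r$hom_rare
  inconsistent <- r$rsid[!is.na(gsum) & gsum != r$n_compared]
  list(overall_compared = table@overall_compared,
       overall_concordant = table@overall_concordant,
       overall_pct = round(100 * table@overall_concordant /
                             table@overall_compared, 1),
       per_snp = per,
       discordant = per[per$n_discordant > 0,
                        c("rsid", "n_compared", "n_discordant", "pct")],
       inconsistent_rows = inconsistent)
}

#' Per-SNP genotype distribution and observed risk allele frequency
#'
#' For each panel SNP, counts of common homozygotes, heterozygotes and rare
#' homozygotes among non-missing calls (common/rare labelled by the allele
#' counts in these calls, ties toward the risk allele), the observed risk
#' allele frequency \code{(2 * hom_risk + het) / (2n)}, and the exact
#' Hardy-Weinberg expected class counts at that observed frequency.
#'
#' @param gs A \linkS4class{GenotypeSet}.
#' @param panel The companion \linkS4class{SnpPanel}.
#' @return A data.frame with one row per panel SNP: \code{rsid}, \code{n},
#'   \code{hom_common}, \code{het}, \code{hom_rare}, \code{raf_observed},
#'   \code{hwe_hom_common}, \code{hwe_het}, \code{hwe_hom_rare}.
#' @export
genotypeFrequencyReport <- function(gs, panel) {
  stopifnot(is(gs, "GenotypeSet"), is(panel, "SnpPanel"))
  d <- dosageMatrix(gs, panel, missing = "na")
  s <- snpInfo(panel)
  rows <- lapply(colnames(d), function(rs) {
    k <- match(rs, s$rsid)
    x <- d[, rs]
    x <- x[!is.na(x)]
    n <- length(x)
    raf_obs <- if (n > 0) (2 * sum(x == 2) + sum(x == 1)) / (2 * n) else NA_real_
    common_is_risk <- is.na(raf_obs) || raf_obs >= 0.5
    counts <- if (common_is_risk)
      c(sum(x == 2), sum(x == 1), sum(x == 0))
    else
      c(sum(x == 0), sum(x == 1), sum(x == 2))
    p_common <- if (common_is_risk) raf_obs else 1 - raf_obs
    data.frame(rsid = rs, n = n,
               hom_common = counts[1], het = counts[2], hom_rare = counts[3],
               raf_observed = raf_obs,
               hwe_hom_common = n * p_common^2,
               hwe_het = n * 2 * p_common * (1 - p_common),
               hwe_hom_rare = n * (1 - p_common)^2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
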