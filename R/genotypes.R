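#' Construct a GenotypeSet from allele matrices
#'
#' @param allele1,allele2 Character matrices (subjects x SNPs) of allele
#'   codes, with subject ids as rownames and rsIDs as colnames. Missing
#'   calls are \code{NA} in both.
#' @return A validated \linkS4class{GenotypeSet}.
#' @export
GenotypeSet <- function(allele1, allele2) {
  storage.mode(allele1) <- "character"
  storage.mode(allele2) <- "character"
  new("GenotypeSet", allele1 = allele1, allele2 = allele2)
}

#' @rdname GenotypeSet-class
#' @param x A \linkS4class{GenotypeSet}.
#' @export
setMethod("subjectIds", "GenotypeSet", function(x) rownames(x@allele1))

#' @rdname GenotypeSet-class
#' @export
setMethod("nSnps", "GenotypeSet", function(x) ncol(x@allele1))

#' @rdname GenotypeSet-class
#' @export
setMethod("rsids", "GenotypeSet", function(x) colnames(x@allele1))

setMethod("show", "GenotypeSet", function(object) {
  n_missing <- sum(is.na(object@allele1))
  cat("GenotypeSet:", nrow(object@allele1), "subjects x",
      ncol(object@allele1), "SNPs;", n_missing, "missing call(s)\n")
  invisible(NULL)
})

## Letter-exact validation against the panel; no strand flipping or allele
## harmonisation is attempted — a foreign letter signals a data error.
.checkAllelesAgainstPanel <- function(gs, panel) {
  s <- snpInfo(panel)
  unknown <- setdiff(rsids(gs), s$rsid)
  if (length(unknown) > 0)
    stop("genotype calls at rsid(s) not in panel: ",
         paste(unknown, collapse = ", "))
  for (j in seq_len(ncol(gs@allele1))) {
    rs <- colnames(gs@allele1)[j]
    k <- match(rs, s$rsid)
    legal <- c(s$risk_allele[k], s$other_allele[k])
    obs <- c(gs@allele1[, j], gs@allele2[, j])
    bad <- setdiff(obs[!is.na(obs)], legal)
    if (length(bad) > 0)
      stop("allele(s) ", paste(bad, collapse = ", "), " at ", rs,
           " are not among the panel alleles {", legal[1], ", ", legal[2],
           "}; no strand flipping is attempted")
  }
  invisible(TRUE)
}

.genotypeSetFromLong <- function(df, panel) {
  req <- c("subject_id", "rsid", "allele1", "allele2")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    stop("genotype table lacks column(s): ", paste(missing_cols, collapse = ", "))
  half <- xor(is.na(df$allele1) | df$allele1 == "",
              is.na(df$allele2) | df$allele2 == "")
  if (any(half))
    stop("half-calls (one allele missing) at row(s): ",
         paste(utils::head(which(half), 5), collapse = ", "))
  subj <- unique(as.character(df$subject_id))
  rs <- rsids(panel)
  a1 <- matrix(NA_character_, length(subj), length(rs),
               dimnames = list(subj, rs))
  a2 <- a1
  i <- match(as.character(df$subject_id), subj)
  j <- match(as.character(df$rsid), rs)
  if (anyNA(j))
    stop("genotype calls at rsid(s) not in panel: ",
         paste(unique(df$rsid[is.na(j)]), collapse = ", "))
  if (anyDuplicated(cbind(i, j)))
    stop("duplicate (subject_id, rsid) rows in genotype table")
  idx <- cbind(i, j)
  v1 <- as.character(df$allele1); v2 <- as.character(df$allele2)
  v1[v1 == ""] <- NA_character_; v2[v2 == ""] <- NA_character_
  a1[idx] <- v1
  a2[idx] <- v2
  gs <- GenotypeSet(a1, a2)
  .checkAllelesAgainstPanel(gs, panel)
  gs
}

.genotypeSetFromVcf <- function(path, panel) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, names(gt)))
  s <- snpInfo(panel)
  keep <- which(fix$ID %in% s$rsid)
  if (length(keep) == 0) stop("VCF contains no panel SNPs")
  subj <- colnames(gt)
  rs <- rsids(panel)
  a1 <- matrix(NA_character_, length(subj), length(rs),
               dimnames = list(subj, rs))
  a2 <- a1
  for (r in keep) {
    rs_id <- fix$ID[r]
    k <- match(rs_id, s$rsid)
    ref <- fix$REF[r]; alt <- fix$ALT[r]
    if (grepl(",", alt))
      stop("multi-allelic VCF record at ", rs_id, ": only biallelic records are supported")
    legal <- c(s$risk_allele[k], s$other_allele[k])
    if (!setequal(c(ref, alt), legal) && !all(c(ref, alt) %in% legal))
      stop("VCF alleles ", ref, "/", alt, " at ", rs_id,
           " do not match panel alleles {", legal[1], ", ", legal[2], "}")
    alleles <- c(ref, alt)
    g <- gt[r, ]
    g[g %in% c(".", "./.", ".|.")] <- NA_character_
    called <- !is.na(g)
    parts <- strsplit(g[called], "[/|]")
    bad <- vapply(parts, function(p) length(p) != 2L || anyNA(suppressWarnings(as.integer(p))),
                  logical(1))
    if (any(bad)) stop("unparseable GT at ", rs_id)
    i1 <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    i2 <- vapply(parts, function(p) as.integer(p[2]), integer(1))
    if (any(i1 > 1L) || any(i2 > 1L))
      stop("GT allele index > 1 at ", rs_id, ": only biallelic records are supported")
    j <- match(rs_id, rs)
    a1[which(called), j] <- alleles[i1 + 1L]
    a2[which(called), j] <- alleles[i2 + 1L]
  }
  gs <- GenotypeSet(a1, a2)
  .checkAllelesAgainstPanel(gs, panel)
  gs
}

#' Read subject genotypes against a panel
#'
#' Two formats are supported: a long-format CSV with header
#' \code{subject_id,rsid,allele1,allele2} (one row per call; SNPs absent
#' for a subject are recorded as missing), and a minimal VCF (GT field,
#' biallelic records; records whose ID is not a panel rsID are ignored).
#' Any called allele letter that is not one of the panel's two alleles for
#' that SNP is a hard error — no strand flipping or harmonisation is
#' attempted.
#'
#' @param path Path to the genotype file.
#' @param panel A \linkS4class{SnpPanel}.
#' @param format \code{"csv"}, \code{"vcf"} or \code{"auto"} (extension).
#' @return A \linkS4class{GenotypeSet} over all panel SNPs.
#' @export
readGenotypes <- function(path, panel, format = c("auto", "csv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "csv"
  if (format == "vcf") return(.genotypeSetFromVcf(path, panel))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        colClasses = "character")
  .genotypeSetFromLong(df, panel)
}

#' Write genotypes as long-format CSV
#'
#' Missing calls are omitted; [readGenotypes()] restores them as missing,
#' so a write/read round trip reproduces the dosage matrix exactly.
#'
#' @param gs A \linkS4class{GenotypeSet}.
#' @param path Output path.
#' @param comment Optional character vector of comment lines (written with
#'   a leading \code{#}).
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(gs, path, comment = NULL) {
  stopifnot(is(gs, "GenotypeSet"))
  a1 <- gs@allele1; a2 <- gs@allele2
  df <- data.frame(
    subject_id = rep(rownames(a1), times = ncol(a1)),
    rsid = rep(colnames(a1), each = nrow(a1)),
    allele1 = as.vector(a1),
    allele2 = as.vector(a2),
    stringsAsFactors = FALSE)
  df <- df[!is.na(df$allele1), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Risk-allele dosage of genotype calls
#'
#' Counts how many of the two called alleles equal the SNP's risk allele.
#' Symmetric in allele order; missing calls give \code{NA}; any other
#' letter is an error.
#'
#' @param allele1,allele2 Character vectors of allele codes (recycled to a
#'   common length).
#' @param risk_allele,other_allele The SNP's two allele codes.
#' @return Integer vector of dosages in \{0, 1, 2\} with \code{NA} for
#'   missing calls.
#' @examples
#' riskAlleleDosage(c("G", "G", "T"), c("G", "T", "T"), "G", "T")
#' @export
riskAlleleDosage <- function(allele1, allele2, risk_allele, other_allele) {
  n <- max(length(allele1), length(allele2))
  allele1 <- rep_len(allele1, n); allele2 <- rep_len(allele2, n)
  obs <- c(allele1, allele2)
  bad <- setdiff(obs[!is.na(obs)], c(risk_allele, other_allele))
  if (length(bad) > 0)
    stop("allele(s) not among the SNP's defined alleles: ",
         paste(bad, collapse = ", "))
  out <- (allele1 == risk_allele) + (allele2 == risk_allele)
  as.integer(out)
}

#' Risk-allele dosage matrix
#'
#' Reduces a \linkS4class{GenotypeSet} to a subjects-by-SNPs matrix of
#' risk-allele dosages (0, 1 or 2 copies).
#'
#' @param gs A \linkS4class{GenotypeSet}.
#' @param panel The companion \linkS4class{SnpPanel}.
#' @param missing Missing-call policy: \code{"na"} keeps \code{NA} dosages,
#'   \code{"error"} fails naming the offending rsid(s), \code{"impute"}
#'   substitutes the Hardy-Weinberg expectation \code{2 * raf} (an
#'   exploratory option; scoring defaults to complete panels).
#' @return Numeric matrix (integer-valued unless imputed) with the
#'   GenotypeSet's dimnames.
#' @export
dosageMatrix <- function(gs, panel, missing = c("na", "error", "impute")) {
  missing <- match.arg(missing)
  stopifnot(is(gs, "GenotypeSet"), is(panel, "SnpPanel"))
  .checkAllelesAgainstPanel(gs, panel)
  s <- snpInfo(panel)
  k <- match(rsids(gs), s$rsid)
  risk <- s$risk_allele[k]
  d <- (gs@allele1 == rep(risk, each = nrow(gs@allele1))) +
       (gs@allele2 == rep(risk, each = nrow(gs@allele2)))
  storage.mode(d) <- "double"
  if (anyNA(d)) {
    if (missing == "error") {
      bad <- colnames(d)[colSums(is.na(d)) > 0]
      stop("missing genotype call(s) at: ", paste(bad, collapse = ", "))
    }
    if (missing == "impute") {
      exp_d <- 2 * s$raf[k]
      for (j in which(colSums(is.na(d)) > 0))
        d[is.na(d[, j]), j] <- exp_d[j]
    }
  }
  d
}

#' Total risk alleles carried per subject
#'
#' Sums the per-SNP risk-allele dosages across the panel. With a 19-SNP
#' panel the total lies in [0, 38].
#'
#' @inheritParams dosageMatrix
#' @param missing \code{"error"} (default: scoring requires complete
#'   panels) or \code{"impute"} (HWE expectation \code{2 * raf}).
#' @return Named numeric vector (integer-valued unless imputed), one entry
#'   per subject.
#' @export
countRiskAlleles <- function(gs, panel, missing = c("error", "impute")) {
  missing <- match.arg(missing)
  d <- dosageMatrix(gs, panel, missing = missing)
  rowSums(d)
}
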