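#' Construct a SnpPanel
#'
#' @param snps A data.frame with columns \code{rsid}, \code{gene},
#'   \code{chromosome}, \code{risk_allele}, \code{other_allele}, \code{raf},
#'   \code{weight}, \code{model}. \code{weight} may be \code{NA}.
#' @return A validated \linkS4class{SnpPanel}.
#' @export
SnpPanel <- function(snps) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (!"weight" %in% names(snps)) snps$weight <- NA_real_
  for (col in c("rsid", "gene", "chromosome", "risk_allele", "other_allele", "model"))
    if (col %in% names(snps)) snps[[col]] <- as.character(snps[[col]])
  snps$raf <- as.numeric(snps$raf)
  snps$weight <- as.numeric(snps$weight)
  rownames(snps) <- NULL
  new("SnpPanel", snps = snps)
}

#' Read a SNP panel definition from TSV or JSON
#'
#' The TSV dialect is tab-separated with a header row; JSON is an array of
#' objects, one per SNP. Both carry the columns documented in
#' \linkS4class{SnpPanel}. Validation errors (duplicate rsid, RAF outside
#' [0, 1], unknown inheritance model, identical alleles) are raised, not
#' repaired.
#'
#' @param path Path to the panel file.
#' @param format \code{"tsv"} or \code{"json"}; guessed from the file
#'   extension by default.
#' @return A \linkS4class{SnpPanel}.
#' @examples
#' p <- defaultPanel()
#' nSnps(p)
#' @export
readPanel <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("panel file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  snps <- if (format == "json") {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, comment.char = "#")
  }
  req <- c("rsid", "gene", "chromosome", "risk_allele", "other_allele",
           "raf", "model")
  missing_cols <- setdiff(req, names(snps))
  if (length(missing_cols) > 0)
    stop("panel file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  SnpPanel(snps)
}

#' Write a SNP panel to TSV
#'
#' @param panel A \linkS4class{SnpPanel}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writePanel <- function(panel, path) {
  stopifnot(is(panel, "SnpPanel"))
  utils::write.table(panel@snps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The bundled default 19-SNP CHD panel
#'
#' The 19-SNP coronary heart disease panel (rsIDs, gene loci, chromosomes
#' and risk allele frequencies from a published sample of healthy UK men;
#' NOS3 rs1799983 scored recessively, all others additively). Allele codes
#' were compiled from public dbSNP annotations and are illustrative: all
#' scoring behaviour depends only on letter-exact matching within the panel
#' and on the RAF column. Per-allele weights are not part of the published
#' table, so the bundled panel ships with \code{weight = NA}; supply your
#' own weights, or use [placeholderWeights()] for a clearly synthetic
#' demonstration set.
#'
#' @param weights Optional named numeric vector of per-allele log odds
#'   ratios, named by rsid (a full or partial replacement of the NA
#'   weights).
#' @return A \linkS4class{SnpPanel} with 19 SNPs.
#' @examples
#' p <- defaultPanel(weights = placeholderWeights())
#' sum(snpInfo(p)$raf)
#' @export
defaultPanel <- function(weights = NULL) {
  path <- system.file("extdata", "chd19_panel.tsv", package = "chdrisk",
                      mustWork = TRUE)
  panel <- readPanel(path, format = "tsv")
  if (!is.null(weights)) panelWeights(panel) <- weights
  panel
}

#' Synthetic demonstration weights for the default panel
#'
#' A named vector of per-allele natural-log odds ratios for the 19 default
#' panel SNPs. These are NOT the published score weights (which are not in
#' the public domain); they are a synthetic set with literature-plausible
#' magnitudes, provided so that scoring, combination and simulation can be
#' exercised end to end. Any analysis intended for interpretation must
#' substitute real weights.
#'
#' @return Named numeric vector of length 19 (names are rsIDs).
#' @export
placeholderWeights <- function() {
  c(rs11591147 = 0.49, rs17465637 = 0.10, rs646776 = 0.12,
    rs1042031 = 0.10, rs9818870 = 0.08, rs3798220 = 0.46,
    rs10455872 = 0.31, rs1799983 = 0.08, rs328 = 0.17,
    rs1801177 = 0.33, rs7025486 = 0.08, rs10757274 = 0.20,
    rs1746048 = 0.08, rs662799 = 0.17, rs17228212 = 0.07,
    rs708272 = 0.16, rs4341 = 0.14, rs7412 = 0.30, rs429358 = 0.26)
}

#' @rdname SnpPanel-class
#' @export
setMethod("nSnps", "SnpPanel", function(x) nrow(x@snps))

#' @rdname SnpPanel-class
#' @export
setMethod("rsids", "SnpPanel", function(x) x@snps$rsid)

#' @rdname SnpPanel-class
#' @export
setMethod("snpInfo", "SnpPanel", function(x) x@snps)

#' @rdname SnpPanel-class
#' @export
setMethod("panelWeights", "SnpPanel", function(x) {
  stats::setNames(x@snps$weight, x@snps$rsid)
})

#' @rdname SnpPanel-class
#' @export
setReplaceMethod("panelWeights", "SnpPanel", function(x, value) {
  if (is.null(names(value))) {
    if (length(value) != nrow(x@snps))
      stop("unnamed weights must have length nSnps(panel)")
    x@snps$weight <- as.numeric(value)
  } else {
    unknown <- setdiff(names(value), x@snps$rsid)
    if (length(unknown) > 0)
      stop("weights named for rsids not in panel: ",
           paste(unknown, collapse = ", "))
    idx <- match(names(value), x@snps$rsid)
    x@snps$weight[idx] <- as.numeric(value)
  }
  validObject(x)
  x
})

setMethod("show", "SnpPanel", function(object) {
  s <- object@snps
  cat("SnpPanel with", nrow(s), "SNPs on",
      length(unique(s$chromosome)), "chromosomes\n")
  cat("  recessive:", paste(s$rsid[s$model == "recessive"], collapse = ", "),
      "\n")
  cat("  weights:",
      if (all(is.na(s$weight))) "none set" else
        if (anyNA(s$weight)) "partially set" else "set", "\n")
  invisible(NULL)
})
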