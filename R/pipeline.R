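.setSubjectIds <- function(gs, ids) {
  a1 <- gs@allele1; a2 <- gs@allele2
  stopifnot(length(ids) == nrow(a1))
  rownames(a1) <- ids; rownames(a2) <- ids
  GenotypeSet(a1, a2)
}

.writeStage <- function(df, path, seed, config_hash, sep = ",") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d config_md5=%s", seed, config_hash), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full genetic + clinical risk pipeline
#'
#' Wires the stages end to end: load (or simulate) a cohort, compute gene
#' scores, UKPDS clinical risk, combined risk, a concordance QC report
#' (against an error-injected copy when no second call source is given),
#' and a baseline comparison across arms. All outputs are plain text with a
#' header comment carrying the seed and a config hash; a JSON manifest
#' lists the inputs and outputs so a run can be reproduced exactly.
#'
#' @param config A list: \code{out_dir} (required), \code{seed} (required
#'   integer), and optionally \code{panel} / \code{clinical} /
#'   \code{genotypes} / \code{coeffs} / \code{reference_genotypes} (file
#'   paths; unset inputs are simulated or taken from the bundled defaults),
#'   \code{p0} (default 0.3), \code{error_rate} (per-call rate for the
#'   concordance demonstration when no reference call set is supplied;
#'   default 6/3158).
#' @return Invisibly, the manifest list (also written to
#'   \code{out_dir/manifest.json}). Stops with a message naming the path on
#'   any missing input file.
#' @export
runPipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  if (is.null(config$seed)) stop("config$seed is required")
  seed <- as.integer(config$seed)
  p0 <- if (is.null(config$p0)) 0.3 else as.numeric(config$p0)
  error_rate <- if (is.null(config$error_rate)) 6 / 3158 else config$error_rate
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  for (key in c("panel", "clinical", "genotypes", "coeffs", "reference_genotypes"))
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      stop("config$", key, " does not exist: ", config[[key]])

  ## the hash identifies the analytic configuration; where outputs land is
  ## not part of it, so runs into different directories stay comparable
  hashed <- config[setdiff(names(config), "out_dir")]
  cfg_json <- tempfile(fileext = ".json")
  jsonlite::write_json(hashed[order(names(hashed))], cfg_json,
                       auto_unbox = TRUE, digits = NA)
  config_hash <- unname(tools::md5sum(cfg_json))
  unlink(cfg_json)

  panel <- if (is.null(config$panel)) defaultPanel() else readPanel(config$panel)
  placeholder_weights <- FALSE
  if (anyNA(panelWeights(panel))) {
    if (!identical(sort(rsids(panel)), sort(names(placeholderWeights()))))
      stop("panel has unset weights and is not the default panel: supply weights")
    panelWeights(panel) <- placeholderWeights()
    placeholder_weights <- TRUE
  }
  coeffs <- if (is.null(config$coeffs)) defaultUkpdsCoefficients()
            else readUkpdsCoefficients(config$coeffs)

  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4)

  clinical <- if (is.null(config$clinical))
    simulateClinicalCohort(defaultCohortSpec(), seed = stage_seeds[1])
  else {
    cl <- readClinical(config$clinical)
    if (!"arm" %in% names(cl)) cl$arm <- "all"
    cl
  }

  genotypes <- if (is.null(config$genotypes)) {
    g <- simulateGenotypes(panel, n = nrow(clinical), seed = stage_seeds[2])
    .setSubjectIds(g, clinical$subject_id)
  } else readGenotypes(config$genotypes, panel)

  out <- function(name) file.path(config$out_dir, name)
  outputs <- character(0)

  .writeStage(clinical, out("clinical.csv"), seed, config_hash)
  writeGenotypes(genotypes, out("genotypes.csv"),
                 comment = sprintf("seed=%d config_md5=%s", seed, config_hash))
  outputs <- c(outputs, out("clinical.csv"), out("genotypes.csv"))

  scores <- computeGeneScore(genotypes, panel)
  scores$tertile <- assignTertiles(scores$gene_score)
  .writeStage(scores, out("gene_scores.csv"), seed, config_hash)
  outputs <- c(outputs, out("gene_scores.csv"))

  shared <- intersect(clinical$subject_id, scores$subject_id)
  if (length(shared) == 0)
    stop("no subjects shared between clinical and genotype inputs")
  clin_shared <- clinical[clinical$subject_id %in% shared, , drop = FALSE]

  risks <- ukpdsRisk(clin_shared, coeffs)
  .writeStage(risks, out("ukpds_risk.csv"), seed, config_hash)
  outputs <- c(outputs, out("ukpds_risk.csv"))

  comb <- combinedRisk(clin_shared, scores, coeffs,
                       config = combinationConfig(p0 = p0), panel = panel)
  .writeStage(comb, out("combined_risk.csv"), seed, config_hash)
  outputs <- c(outputs, out("combined_risk.csv"))

  reference <- if (is.null(config$reference_genotypes)) {
    injectGenotypeErrors(genotypes, panel, rate = error_rate,
                         seed = stage_seeds[3])$calls
  } else readGenotypes(config$reference_genotypes, panel)
  conc <- summarizeConcordance(compareCallSets(genotypes, reference, panel))
  .writeStage(conc$per_snp, out("concordance_report.tsv"), seed, config_hash,
              sep = "\t")
  outputs <- c(outputs, out("concordance_report.tsv"))

  trait_spec <- data.frame(
    trait = c("age_at_diagnosis", "duration_t2d", "total_cholesterol",
              "hdl_cholesterol", "hba1c", "sbp", "sex", "smoker"),
    transform = c("none", "sqrt", "log", "log", "log", "none", "none", "none"),
    type = c(rep("numeric", 6), "categorical", "categorical"),
    stringsAsFactors = FALSE)
  baseline <- if (length(unique(clinical$arm)) >= 2)
    baselineComparison(clinical, trait_spec, group = "arm") else NULL
  if (!is.null(baseline)) {
    .writeStage(baseline, out("baseline.tsv"), seed, config_hash, sep = "\t")
    outputs <- c(outputs, out("baseline.tsv"))
  }

  manifest <- list(
    package = "chdrisk",
    version = as.character(utils::packageVersion("chdrisk")),
    seed = seed,
    config = config,
    config_md5 = config_hash,
    p0 = p0,
    placeholder_weights = placeholder_weights,
    overall_concordance_pct = conc$overall_pct,
    outputs = basename(outputs))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
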