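.withSeed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' For each panel SNP, genotypes are drawn independently across subjects
#' and SNPs with class probabilities (raf^2, 2 raf (1 - raf), (1 - raf)^2)
#' — equivalently, risk-allele dosage ~ Binomial(2, raf). Linkage
#' disequilibrium is deliberately not modelled: the default panel spans 13
#' chromosomes and the score treats alleles as independent contributors.
#' Reproducible under a fixed seed.
#'
#' @param panel A \linkS4class{SnpPanel}.
#' @param n Number of subjects (>= 1).
#' @param seed Optional integer seed (scoped: the global RNG state is
#'   restored afterwards).
#' @param id_prefix Prefix for generated subject ids.
#' @return A \linkS4class{GenotypeSet} of n subjects over the panel SNPs.
#' @examples
#' g <- simulateGenotypes(defaultPanel(), n = 10, seed = 1)
#' table(countRiskAlleles(g, defaultPanel()))
#' @export
simulateGenotypes <- function(panel, n, seed = NULL, id_prefix = "S") {
  stopifnot(is(panel, "SnpPanel"))
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be a positive integer")
  s <- snpInfo(panel)
  .withSeed(seed, {
    subj <- sprintf("%s%0*d", id_prefix, nchar(as.character(n)), seq_len(n))
    a1 <- matrix(NA_character_, n, nrow(s), dimnames = list(subj, s$rsid))
    a2 <- a1
    for (j in seq_len(nrow(s))) {
      dos <- stats::rbinom(n, 2L, s$raf[j])
      a1[, j] <- ifelse(dos >= 1, s$risk_allele[j], s$other_allele[j])
      a2[, j] <- ifelse(dos == 2, s$risk_allele[j], s$other_allele[j])
    }
    GenotypeSet(a1, a2)
  })
}

#' Histogram of total risk alleles carried
#'
#' @param gs A \linkS4class{GenotypeSet}.
#' @param panel The companion \linkS4class{SnpPanel}.
#' @return A \code{table} keyed by total risk alleles.
#' @export
riskAlleleHistogram <- function(gs, panel) {
  table(countRiskAlleles(gs, panel))
}

.knownFamilies <- c("normal", "lognormal", "sqrtnormal", "bernoulli")

.checkTraitModel <- function(name, tm) {
  if (!is.list(tm) || !all(c("family", "location") %in% names(tm)))
    stop("trait '", name, "' needs fields family and location")
  if (!tm$family %in% .knownFamilies)
    stop("trait '", name, "': unknown family '", tm$family, "'")
  if (is.null(tm$scale)) tm$scale <- 0
  if (!is.finite(tm$location) || !is.finite(tm$scale) || tm$scale < 0)
    stop("trait '", name, "': location must be finite, scale finite and >= 0")
  if (tm$family == "bernoulli" && (tm$location < 0 || tm$location > 1))
    stop("trait '", name, "': bernoulli location must be a probability")
  if (tm$family %in% c("lognormal", "sqrtnormal") && tm$location <= 0)
    stop("trait '", name, "': ", tm$family, " location must be positive")
  tm
}

## One draw of n values from a trait model. Parameters are on the reporting
## scale: lognormal location = geometric mean, scale = approximate SD
## (geometric mean x SD of logs, the delta-method back-transform);
## sqrtnormal location = back-transformed mean (i.e. mean on the sqrt scale
## squared), scale = SD on the sqrt scale, normal truncated at 0 there.
.drawTrait <- function(tm, n) {
  switch(tm$family,
         normal = stats::rnorm(n, tm$location, tm$scale),
         lognormal = {
           sdlog <- if (tm$location > 0) tm$scale / tm$location else 0
           stats::rlnorm(n, meanlog = log(tm$location), sdlog = sdlog)
         },
         sqrtnormal = {
           m <- sqrt(tm$location); s <- tm$scale
           y <- if (s == 0) rep(m, n) else {
             lo <- stats::pnorm(0, m, s)
             stats::qnorm(stats::runif(n, lo, 1), m, s)
           }
           y^2
         },
         bernoulli = stats::runif(n) < tm$location)
}

#' Default synthetic-cohort specification
#'
#' The study conditions of a three-arm T2D self-management trial baseline:
#' arm sizes 67 / 74 / 70 (control, SMI only, SMI plus risk report) and
#' per-arm trait distributions with the published baseline moments — age at
#' T2D diagnosis and systolic blood pressure normal; total cholesterol,
#' HDL cholesterol and HbA1c log-normal (parameterised by geometric mean
#' and approximate SD); T2D duration square-root-normal truncated at 0
#' (back-transformed means 5.60 / 5.60 / 6.33 years; the published table
#' reports no SD on the transformed scale, so the generator uses 1.0
#' sqrt-years); sex, smoking and Afro-Caribbean ethnicity Bernoulli at the
#' published percentages (Afro-Caribbean prevalence is not printed and is
#' set to a small plausible value per arm).
#'
#' @return A list with one element per arm: \code{n} and a named list of
#'   trait models (\code{family}, \code{location}, \code{scale}).
#' @export
defaultCohortSpec <- function() {
  arm <- function(n, age_loc, age_sd, dur, tc, tc_sd, hdl, hdl_sd,
                  a1c, a1c_sd, sbp, sbp_sd, female, smoker, afro) {
    list(n = n, traits = list(
      age_at_diagnosis = list(family = "normal", location = age_loc, scale = age_sd),
      duration_t2d = list(family = "sqrtnormal", location = dur, scale = 1.0),
      total_cholesterol = list(family = "lognormal", location = tc, scale = tc_sd),
      hdl_cholesterol = list(family = "lognormal", location = hdl, scale = hdl_sd),
      hba1c = list(family = "lognormal", location = a1c, scale = a1c_sd),
      sbp = list(family = "normal", location = sbp, scale = sbp_sd),
      female = list(family = "bernoulli", location = female, scale = 0),
      smoker = list(family = "bernoulli", location = smoker, scale = 0),
      afro_caribbean = list(family = "bernoulli", location = afro, scale = 0)))
  }
  list(
    control = arm(67, 55.00, 10.87, 5.60, 4.18, 0.97, 1.27, 0.29,
                  7.73, 1.29, 133.93, 12.56, 0.48, 0.07, 0.04),
    smi_only = arm(74, 54.99, 10.17, 5.60, 4.36, 0.89, 1.23, 0.37,
                   7.60, 1.03, 134.36, 14.41, 0.46, 0.05, 0.04),
    smi_rr = arm(70, 54.90, 8.36, 6.33, 4.29, 1.03, 1.16, 0.29,
                 7.58, 0.99, 133.44, 12.97, 0.34, 0.16, 0.03))
}

#' Read a cohort specification from JSON
#'
#' @param path JSON file with the structure of [defaultCohortSpec()].
#' @return The validated spec list.
#' @export
readCohortSpec <- function(path) {
  if (!file.exists(path)) stop("cohort spec file not found: ", path)
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  for (arm in names(spec)) {
    if (is.null(spec[[arm]]$n) || spec[[arm]]$n < 1)
      stop("arm '", arm, "' needs a positive n")
    for (tr in names(spec[[arm]]$traits))
      spec[[arm]]$traits[[tr]] <- .checkTraitModel(tr, spec[[arm]]$traits[[tr]])
  }
  spec
}

#' Simulate a clinical cohort
#'
#' Draws per-subject clinical profiles arm by arm from the trait models of
#' a cohort spec, then assigns subject identifiers by a seeded permutation
#' (mirroring trial randomisation: arm sizes are exact, not multinomial).
#' Current age is derived as age at diagnosis + duration and never drawn
#' independently.
#'
#' @param spec A cohort spec (see [defaultCohortSpec()]).
#' @param seed Optional integer seed (scoped).
#' @param id_prefix Prefix for generated subject ids.
#' @return A data.frame with columns \code{subject_id}, \code{arm},
#'   \code{sex}, \code{afro_caribbean}, \code{smoker},
#'   \code{age_at_diagnosis}, \code{duration_t2d}, \code{hba1c},
#'   \code{sbp}, \code{total_cholesterol}, \code{hdl_cholesterol},
#'   \code{age}.
#' @examples
#' cohort <- simulateClinicalCohort(defaultCohortSpec(), seed = 1)
#' table(cohort$arm)
#' @export
simulateClinicalCohort <- function(spec, seed = NULL, id_prefix = "P") {
  for (arm in names(spec))
    for (tr in names(spec[[arm]]$traits))
      spec[[arm]]$traits[[tr]] <- .checkTraitModel(tr, spec[[arm]]$traits[[tr]])
  .withSeed(seed, {
    arms <- lapply(names(spec), function(arm) {
      n <- as.integer(spec[[arm]]$n)
      tm <- spec[[arm]]$traits
      draw <- function(name) {
        if (is.null(tm[[name]])) stop("arm '", arm, "' lacks trait '", name, "'")
        .drawTrait(tm[[name]], n)
      }
      data.frame(
        arm = arm,
        sex = ifelse(draw("female"), "female", "male"),
        afro_caribbean = as.logical(draw("afro_caribbean")),
        smoker = as.logical(draw("smoker")),
        age_at_diagnosis = draw("age_at_diagnosis"),
        duration_t2d = draw("duration_t2d"),
        hba1c = draw("hba1c"),
        sbp = draw("sbp"),
        total_cholesterol = draw("total_cholesterol"),
        hdl_cholesterol = draw("hdl_cholesterol"),
        stringsAsFactors = FALSE)
    })
    cohort <- do.call(rbind, arms)
    n_total <- nrow(cohort)
    cohort <- cohort[sample.int(n_total), , drop = FALSE]
    cohort <- cbind(
      subject_id = sprintf("%s%0*d", id_prefix,
                           nchar(as.character(n_total)), seq_len(n_total)),
      cohort, stringsAsFactors = FALSE)
    cohort$age <- cohort$age_at_diagnosis + cohort$duration_t2d
    rownames(cohort) <- NULL
    cohort
  })
}

#' Inject genotyping errors at a per-call rate
#'
#' Each non-missing call is independently replaced, with the given
#' probability, by a different legal genotype at that SNP (the two
#' alternatives among homozygote-risk / heterozygote / homozygote-other are
#' equally likely). Every perturbation is recorded in a ledger, so
#' downstream concordance counts can be checked call for call.
#'
#' @param gs A \linkS4class{GenotypeSet}.
#' @param panel The companion \linkS4class{SnpPanel}.
#' @param rate Per-call error probability in [0, 1).
#' @param seed Optional integer seed (scoped).
#' @return A list with \code{calls} (the perturbed
#'   \linkS4class{GenotypeSet}) and \code{ledger} (data.frame
#'   \code{subject_id}, \code{rsid}, \code{original}, \code{perturbed};
#'   genotypes written as sorted allele pairs).
#' @export
injectGenotypeErrors <- function(gs, panel, rate, seed = NULL) {
  stopifnot(is(gs, "GenotypeSet"), is(panel, "SnpPanel"))
  if (length(rate) != 1L || !is.finite(rate) || rate < 0 || rate >= 1)
    stop("rate must be a single probability in [0, 1)")
  s <- snpInfo(panel)
  a1 <- gs@allele1; a2 <- gs@allele2
  .withSeed(seed, {
    hit <- !is.na(a1) & (stats::runif(length(a1)) < rate)
    idx <- which(hit, arr.ind = TRUE)
    ledger <- data.frame(subject_id = character(0), rsid = character(0),
                         original = character(0), perturbed = character(0),
                         stringsAsFactors = FALSE)
    if (nrow(idx) > 0) {
      pick <- stats::runif(nrow(idx)) # which of the 2 alternative genotypes
      rows <- lapply(seq_len(nrow(idx)), function(k) {
        i <- idx[k, 1]; j <- idx[k, 2]
        rs <- colnames(a1)[j]
        m <- match(rs, s$rsid)
        risk <- s$risk_allele[m]; other <- s$other_allele[m]
        geno <- function(d) switch(as.character(d),
                                   "2" = c(risk, risk),
                                   "1" = c(risk, other),
                                   "0" = c(other, other))
        cur <- (a1[i, j] == risk) + (a2[i, j] == risk)
        alternatives <- setdiff(0:2, cur)
        new_d <- alternatives[1 + (pick[k] >= 0.5)]
        g_new <- geno(new_d)
        fmt <- function(x, y) paste(sort(c(x, y)), collapse = "/")
        orig <- fmt(a1[i, j], a2[i, j])
        a1[i, j] <<- g_new[1]
        a2[i, j] <<- g_new[2]
        data.frame(subject_id = rownames(a1)[i], rsid = rs,
                   original = orig, perturbed = fmt(g_new[1], g_new[2]),
                   stringsAsFactors = FALSE)
      })
      ledger <- do.call(rbind, rows)
    }
    list(calls = GenotypeSet(a1, a2), ledger = ledger)
  })
}
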