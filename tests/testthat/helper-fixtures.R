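## Small synthetic fixtures shared across the suite. Everything is built in
## code so tests carry no binary data.

# a compact panel with controllable RAFs/weights/models; alleles alternate
makeTestPanel <- function(rafs = c(0.5, 0.2, 0.8, 0.33),
                          weights = c(0.10, 0.25, 0.05, 0.15),
                          models = NULL) {
  n <- length(rafs)
  if (is.null(models)) models <- rep("additive", n)
  SnpPanel(data.frame(
    rsid = paste0("rs", seq_len(n)),
    gene = paste0("GENE", seq_len(n)),
    chromosome = as.character(rep_len(1:22, n)),
    risk_allele = rep_len(c("A", "G", "C", "T"), n),
    other_allele = rep_len(c("G", "A", "T", "C"), n),
    raf = rafs, weight = rep_len(weights, n), model = models,
    stringsAsFactors = FALSE))
}

# build a GenotypeSet from a dosage matrix (subjects x panel SNPs)
genotypesFromDosage <- function(dos, panel) {
  s <- snpInfo(panel)
  stopifnot(ncol(dos) == nrow(s))
  subj <- rownames(dos)
  if (is.null(subj)) subj <- paste0("s", seq_len(nrow(dos)))
  a1 <- matrix(NA_character_, nrow(dos), ncol(dos),
               dimnames = list(subj, s$rsid))
  a2 <- a1
  for (j in seq_len(ncol(dos))) {
    d <- dos[, j]
    a1[, j] <- ifelse(is.na(d), NA, ifelse(d >= 1, s$risk_allele[j], s$other_allele[j]))
    a2[, j] <- ifelse(is.na(d), NA, ifelse(d == 2, s$risk_allele[j], s$other_allele[j]))
  }
  GenotypeSet(a1, a2)
}

# a synthetic coefficient set so engine tests never depend on the published
# reference values
makeTestCoeffs <- function(q0 = 0.02, d = 1.05) {
  UkpdsCoefficients(q0 = q0, d = d, factors = data.frame(
    name = c("age_at_diagnosis", "female", "afro_caribbean", "smoker",
             "hba1c", "sbp", "lipid_ratio"),
    coefficient = c(1.04, 0.60, 0.45, 1.30, 1.15, 1.07, 2.50),
    center = c(50, 0, 0, 0, 7, 130, 1.5),
    scale = c(1, 1, 1, 1, 1, 10, 1),
    type = c("continuous", "binary", "binary", "binary",
             "continuous", "continuous", "continuous"),
    stringsAsFactors = FALSE))
}

randomProfiles <- function(n, seed = 1) {
  withr::with_seed(seed, data.frame(
    subject_id = paste0("p", seq_len(n)),
    age_at_diagnosis = runif(n, 35, 70),
    duration_t2d = runif(n, 0, 25),
    sex = sample(c("male", "female"), n, replace = TRUE),
    afro_caribbean = runif(n) < 0.1,
    smoker = runif(n) < 0.2,
    hba1c = runif(n, 5.5, 11),
    sbp = runif(n, 105, 180),
    total_cholesterol = runif(n, 3, 8),
    hdl_cholesterol = runif(n, 0.7, 2.4),
    stringsAsFactors = FALSE))
}

# independent scalar oracle for q: a literal one-line product per subject
oracleQ <- function(row, coeffs) {
  f <- function(nm) {
    fx <- coeffs@factors
    fx[fx$name == nm, ]
  }
  a <- f("age_at_diagnosis"); h <- f("hba1c"); s <- f("sbp"); l <- f("lipid_ratio")
  coeffs@q0 *
    a$coefficient^((row$age_at_diagnosis - a$center) / a$scale) *
    f("female")$coefficient^(row$sex == "female") *
    f("afro_caribbean")$coefficient^(row$afro_caribbean) *
    f("smoker")$coefficient^(row$smoker) *
    h$coefficient^((row$hba1c - h$center) / h$scale) *
    s$coefficient^((row$sbp - s$center) / s$scale) *
    l$coefficient^((log(row$total_cholesterol / row$hdl_cholesterol) - l$center) / l$scale)
}

# brute-force yearly-hazard survival product
oracleYearlyRisk <- function(q, duration, horizon, d) {
  if (horizon == 0) return(0)
  t <- seq_len(horizon) - 1
  1 - prod(exp(-q * d^(duration + t)))
}

# term-by-term gene-score recomputation, one subject at a time
oracleGeneScore <- function(gs, panel) {
  s <- snpInfo(panel)
  d <- dosageMatrix(gs, panel)
  vapply(seq_len(nrow(d)), function(i) {
    total <- 0
    for (j in seq_len(ncol(d))) {
      g <- d[i, j]
      total <- total + if (s$model[j] == "recessive") {
        if (g == 2) s$weight[j] else 0
      } else s$weight[j] * g
    }
    total
  }, numeric(1))
}
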