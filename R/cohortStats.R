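## Trait transforms used throughout the cohort statistics: skewed positive
## traits (lipids, HbA1c) are log transformed and reported as geometric
## means; T2D duration is square-root transformed and reported back on the
## original scale.
.applyTransform <- function(x, transform) {
  switch(transform,
         none = x,
         log = {
           if (any(x <= 0, na.rm = TRUE)) stop("log transform needs positive values")
           log(x)
         },
         sqrt = {
           if (any(x < 0, na.rm = TRUE)) stop("sqrt transform needs non-negative values")
           sqrt(x)
         },
         stop("unknown transform: ", transform))
}

## One printed summary per group, matching the reporting conventions of
## baseline tables: mean (SD); geometric mean (approximate SD, the
## delta-method back-transform GM * SD of logs); back-transformed mean with
## range for sqrt-transformed traits; % (n) for categorical traits.
.summariseTrait <- function(x, transform, type) {
  if (type == "categorical") {
    xl <- as.logical(x)
    return(sprintf("%.0f%% (n = %d)", 100 * mean(xl), sum(xl)))
  }
  switch(transform,
         none = sprintf("%.2f (%.2f)", mean(x), stats::sd(x)),
         log = {
           gm <- exp(mean(log(x)))
           sprintf("%.2f (%.2f)", gm, gm * stats::sd(log(x)))
         },
         sqrt = sprintf("%.2f (%.2f-%.2f)", mean(sqrt(x))^2, min(x), max(x)))
}

.checkTraitSpec <- function(trait_spec) {
  req <- c("trait", "transform", "type")
  if (!all(req %in% names(trait_spec)))
    stop("trait spec needs columns: ", paste(req, collapse = ", "))
  if (!all(trait_spec$transform %in% c("none", "log", "sqrt")))
    stop("transform must be one of none, log, sqrt")
  if (!all(trait_spec$type %in% c("numeric", "categorical")))
    stop("type must be numeric or categorical")
  trait_spec
}

#' Baseline comparison of traits across cohort groups
#'
#' The randomisation check of a trial baseline table: numeric traits are
#' compared across groups with one-way ANOVA on the (optionally
#' transformed) values; categorical traits with a Pearson chi-squared test
#' on the group-by-level contingency table (no continuity correction).
#' Log-transformed traits are summarised as geometric mean with an
#' approximate SD (delta method); square-root-transformed traits as the
#' back-transformed mean with the observed range.
#'
#' @param cohort data.frame with a grouping column and the trait columns.
#' @param trait_spec data.frame with columns \code{trait} (column name),
#'   \code{transform} (\code{"none"}, \code{"log"}, \code{"sqrt"}) and
#'   \code{type} (\code{"numeric"}, \code{"categorical"}).
#' @param group Name of the grouping column (default \code{"arm"}).
#' @return data.frame with one row per trait: \code{trait},
#'   \code{transform}, \code{type}, \code{test}, \code{statistic},
#'   \code{df}, \code{p_value}, \code{note}, and one formatted summary
#'   column per group. A numeric trait with zero within-group variance is
#'   flagged in \code{note} with \code{NA} statistics rather than an
#'   infinite F.
#' @export
baselineComparison <- function(cohort, trait_spec, group = "arm") {
  trait_spec <- .checkTraitSpec(as.data.frame(trait_spec))
  if (!group %in% names(cohort)) stop("grouping column not found: ", group)
  g <- factor(cohort[[group]])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) == 0)) stop("every group must be non-empty")
  rows <- lapply(seq_len(nrow(trait_spec)), function(i) {
    tr <- trait_spec$trait[i]
    if (!tr %in% names(cohort)) stop("trait column not found: ", tr)
    x <- cohort[[tr]]
    transform <- trait_spec$transform[i]
    type <- trait_spec$type[i]
    note <- ""
    if (type == "numeric") {
      y <- .applyTransform(as.numeric(x), transform)
      a <- stats::anova(stats::lm(y ~ g))
      within_ms <- a$`Mean Sq`[2]
      if (!is.finite(within_ms) || within_ms <= .Machine$double.eps * max(1, abs(mean(y)))^2) {
        stat <- NA_real_; p <- NA_real_; df <- NA_real_
        note <- "zero within-group variance: F undefined"
      } else {
        stat <- a$`F value`[1]; p <- a$`Pr(>F)`[1]; df <- a$Df[1]
      }
      test <- "anova"
    } else {
      tab <- table(g, factor(x))
      if (ncol(tab) < 2) {
        stat <- 0; df <- 0; p <- 1
        note <- "trait is constant: chi-squared degenerate"
      } else {
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        stat <- unname(ct$statistic); df <- unname(ct$parameter)
        p <- ct$p.value
      }
      test <- "chi_squared"
    }
    out <- data.frame(trait = tr, transform = transform, type = type,
                      test = test, statistic = stat, df = df, p_value = p,
                      note = note, stringsAsFactors = FALSE)
    for (lev in levels(g)) {
      xg <- x[g == lev]
      out[[paste0("summary_", lev)]] <- .summariseTrait(
        if (type == "numeric") as.numeric(xg) else xg, transform, type)
    }
    out
  })
  do.call(rbind, rows)
}

#' Two-sample comparison of gene scores
#'
#' A two-sample t-test on gene scores (Welch by default; set
#' \code{var_equal = TRUE} for the pooled-variance test).
#'
#' @param scores_a,scores_b Numeric vectors of gene scores (or data.frames
#'   from [computeGeneScore()]).
#' @param var_equal Assume equal variances (default FALSE, Welch).
#' @return data.frame with means, group sizes, \code{statistic}, \code{df}
#'   and \code{p_value}.
#' @export
geneScoreGroupTest <- function(scores_a, scores_b, var_equal = FALSE) {
  a <- if (is.data.frame(scores_a)) scores_a$gene_score else as.numeric(scores_a)
  b <- if (is.data.frame(scores_b)) scores_b$gene_score else as.numeric(scores_b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 scores")
  tt <- stats::t.test(a, b, var.equal = var_equal)
  data.frame(trait = "gene_score", test = "t_test",
             mean_a = mean(a), mean_b = mean(b),
             n_a = length(a), n_b = length(b),
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, stringsAsFactors = FALSE)
}

## Merge histogram cells until every expected count (under homogeneity of
## the two groups) reaches min_expected: repeatedly merge the column with
## the smallest expected total into its smaller-total neighbour.
.poolCells <- function(m, min_expected) {
  repeat {
    if (ncol(m) < 2) break
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    if (all(e >= min_expected)) break
    j <- which.min(colSums(m))
    neighbours <- c(j - 1, j + 1)
    neighbours <- neighbours[neighbours >= 1 & neighbours <= ncol(m)]
    tgt <- neighbours[which.min(colSums(m)[neighbours])]
    lo <- min(j, tgt); hi <- max(j, tgt)
    merged <- m[, lo] + m[, hi]
    keep_names <- colnames(m)
    new_name <- paste(keep_names[lo], keep_names[hi], sep = "+")
    m <- cbind(m[, seq_len(lo - 1), drop = FALSE], merged,
               m[, setdiff(seq_len(ncol(m)), c(seq_len(lo), hi)), drop = FALSE])
    colnames(m)[lo] <- new_name
  }
  m
}

#' Compare two risk-allele count distributions
#'
#' Pearson chi-squared homogeneity test between two histograms of total
#' risk alleles carried (e.g. a trial arm vs a healthy reference cohort).
#' Adjacent cells are pooled from the tails inward until every expected
#' cell count reaches \code{min_expected} (the standard validity rule), and
#' no continuity correction is applied.
#'
#' @param counts_a,counts_b Named numeric vectors or \code{table}s: counts
#'   of subjects keyed by total risk alleles carried.
#' @param min_expected Minimum expected cell count after pooling (default 5).
#' @return data.frame with \code{statistic}, \code{df}, \code{p_value},
#'   \code{n_cells} (after pooling); the pooled 2 x k table is attached as
#'   attribute \code{"pooled_table"}.
#' @export
riskAlleleDistributionTest <- function(counts_a, counts_b, min_expected = 5) {
  ca <- as.table(counts_a); cb <- as.table(counts_b)
  if (sum(ca) == 0 || sum(cb) == 0) stop("empty histogram")
  support <- sort(unique(as.numeric(c(names(ca), names(cb)))))
  if (anyNA(support)) stop("histogram names must be numeric risk-allele counts")
  a <- stats::setNames(rep(0, length(support)), support)
  b <- a
  a[as.character(as.numeric(names(ca)))] <- as.numeric(ca)
  b[as.character(as.numeric(names(cb)))] <- as.numeric(cb)
  m <- rbind(a = a, b = b)
  m <- m[, colSums(m) > 0, drop = FALSE]
  m <- .poolCells(m, min_expected)
  if (ncol(m) < 2)
    stop("fewer than 2 cells remain after pooling: samples too small for a ",
         "chi-squared comparison")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  out <- data.frame(trait = "risk_allele_count", test = "chi_squared",
                    statistic = unname(ct$statistic),
                    df = unname(ct$parameter), p_value = ct$p.value,
                    n_cells = ncol(m), stringsAsFactors = FALSE)
  attr(out, "pooled_table") <- m
  out
}

#' Association of traits with gene-score tertiles
#'
#' Splits subjects into gene-score tertiles (rank-based, sizes differing by
#' at most 1) and regresses each trait on the ordinal tertile index
#' (1/2/3): linear regression for numeric traits (on the transformed scale
#' where one is specified), logistic regression for categorical traits. A
#' single trend slope and two-sided p-value are reported per trait, with
#' per-tertile summaries. Logistic fits with an empty outcome cell in some
#' tertile are flagged as separation rather than silently reported as
#' converged.
#'
#' @param cohort data.frame with a \code{gene_score} column and the trait
#'   columns.
#' @param trait_spec As in [baselineComparison()].
#' @return data.frame, one row per trait: \code{trait}, \code{transform},
#'   \code{type}, \code{test}, \code{slope}, \code{statistic},
#'   \code{p_value}, \code{note}, and per-tertile summary columns.
#' @export
tertileAssociation <- function(cohort, trait_spec) {
  trait_spec <- .checkTraitSpec(as.data.frame(trait_spec))
  if (!"gene_score" %in% names(cohort)) stop("cohort needs a gene_score column")
  gs <- cohort$gene_score
  if (length(unique(gs)) < 3) stop("need at least 3 distinct gene scores")
  tert <- assignTertiles(gs)
  rows <- lapply(seq_len(nrow(trait_spec)), function(i) {
    tr <- trait_spec$trait[i]
    if (!tr %in% names(cohort)) stop("trait column not found: ", tr)
    x <- cohort[[tr]]
    transform <- trait_spec$transform[i]
    type <- trait_spec$type[i]
    note <- ""
    if (type == "numeric") {
      y <- .applyTransform(as.numeric(x), transform)
      fit <- stats::lm(y ~ tert)
      cf <- summary(fit)$coefficients
      slope <- cf["tert", "Estimate"]
      stat <- cf["tert", "t value"]
      p <- cf["tert", "Pr(>|t|)"]
      test <- "linear_regression"
    } else {
      xl <- as.logical(x)
      tab <- table(factor(tert, levels = 1:3), factor(xl, levels = c(FALSE, TRUE)))
      fit <- suppressWarnings(stats::glm(xl ~ tert, family = stats::binomial()))
      cf <- summary(fit)$coefficients
      slope <- cf["tert", "Estimate"]
      stat <- cf["tert", "z value"]
      p <- cf["tert", "Pr(>|z|)"]
      if (any(tab == 0)) {
        note <- "possible separation: zero cell in tertile x outcome table"
        p <- NA_real_
      }
      test <- "logistic_regression"
    }
    out <- data.frame(trait = tr, transform = transform, type = type,
                      test = test, slope = slope, statistic = stat,
                      p_value = p, note = note, stringsAsFactors = FALSE)
    for (t in 1:3) {
      xg <- x[tert == t]
      out[[paste0("summary_tertile", t)]] <- .summariseTrait(
        if (type == "numeric") as.numeric(xg) else xg, transform, type)
    }
    out
  })
  do.call(rbind, rows)
}
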