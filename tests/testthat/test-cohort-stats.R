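make_cohort <- function(n_per_arm = 20, seed = 1, identical_arms = FALSE) {
  withr::with_seed(seed, {
    base <- data.frame(
      age = rnorm(n_per_arm, 60, 8),
      hba1c = rlnorm(n_per_arm, log(7.6), 0.12),
      duration = pmax(rnorm(n_per_arm, 2.4, 1), 0)^2,
      smoker = runif(n_per_arm) < 0.3)
    arms <- lapply(c("control", "smi_only", "smi_rr"), function(a) {
      d <- if (identical_arms) base else data.frame(
        age = rnorm(n_per_arm, 60, 8),
        hba1c = rlnorm(n_per_arm, log(7.6), 0.12),
        duration = pmax(rnorm(n_per_arm, 2.4, 1), 0)^2,
        smoker = runif(n_per_arm) < 0.3)
      d$arm <- a
      d
    })
    do.call(rbind, arms)
  })
}

trait_spec <- data.frame(
  trait = c("age", "hba1c", "duration", "smoker"),
  transform = c("none", "log", "sqrt", "none"),
  type = c("numeric", "numeric", "numeric", "categorical"),
  stringsAsFactors = FALSE)

test_that("identical groups give ANOVA F = 0 (p = 1) and chi-squared 0", {
  cohort <- make_cohort(identical_arms = TRUE)
  res <- baselineComparison(cohort, trait_spec)
  num <- res[res$test == "anova", ]
  expect_equal(num$statistic, rep(0, 3), tolerance = 1e-12)
  expect_equal(num$p_value, rep(1, 3), tolerance = 1e-12)
  cat_row <- res[res$test == "chi_squared", ]
  expect_equal(cat_row$statistic, 0, tolerance = 1e-12)
})

test_that("ANOVA and chi-squared match hand-computed textbook formulas", {
  cohort <- data.frame(
    y = c(1, 2, 3, 2, 4, 6, 5, 6, 10),
    flag = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    arm = rep(c("a", "b", "c"), each = 3))
  spec <- data.frame(trait = c("y", "flag"), transform = "none",
                     type = c("numeric", "categorical"))
  res <- baselineComparison(cohort, spec)

  # hand ANOVA: group means 2, 4, 7; grand mean 13/3
  ss_between <- 3 * sum((c(2, 4, 7) - 13 / 3)^2)
  ss_within <- sum((c(1, 2, 3) - 2)^2) + sum((c(2, 4, 6) - 4)^2) +
    sum((c(5, 6, 10) - 7)^2)
  f_hand <- (ss_between / 2) / (ss_within / 6)
  expect_equal(res$statistic[1], f_hand, tolerance = 1e-12)
  expect_equal(res$p_value[1], pf(f_hand, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)

  # hand chi-squared on the 3x2 table (expected = 3 * 4/9 etc.)
  tab <- table(cohort$arm, cohort$flag)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi_hand <- sum((tab - e)^2 / e)
  expect_equal(res$statistic[2], chi_hand, tolerance = 1e-12)
})

test_that("transform summaries follow the geometric-mean and back-transform rules", {
  cohort <- make_cohort()
  res <- baselineComparison(cohort, trait_spec)
  x <- cohort$hba1c[cohort$arm == "control"]
  gm <- exp(mean(log(x)))
  expect_equal(res[res$trait == "hba1c", "summary_control"],
               sprintf("%.2f (%.2f)", gm, gm * sd(log(x))))
  d <- cohort$duration[cohort$arm == "smi_rr"]
  expect_equal(res[res$trait == "duration", "summary_smi_rr"],
               sprintf("%.2f (%.2f-%.2f)", mean(sqrt(d))^2, min(d), max(d)))

  # ANOVA p on a log-transformed trait is invariant to unit rescaling
  cohort2 <- cohort; cohort2$hba1c <- cohort2$hba1c * 10.5
  res2 <- baselineComparison(cohort2, trait_spec)
  expect_equal(res2[res2$trait == "hba1c", "p_value"],
               res[res$trait == "hba1c", "p_value"], tolerance = 1e-10)
})

test_that("zero within-group variance is flagged, not an infinite F", {
  cohort <- data.frame(y = rep(c(1, 2, 3), each = 4),
                       arm = rep(c("a", "b", "c"), each = 4))
  res <- suppressWarnings(baselineComparison(cohort, data.frame(
    trait = "y", transform = "none", type = "numeric")))
  expect_true(is.na(res$statistic))
  expect_match(res$note, "zero within-group variance")
  expect_error(baselineComparison(cohort[cohort$arm == "a", ],
                                  trait_spec[1, ]), "2 groups")
})

test_that("gene-score t-test: self-comparison is null, hand formula matches", {
  a <- c(3.1, 3.4, 2.9, 3.3)
  self <- geneScoreGroupTest(a, a)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)

  b <- c(2.7, 3.0, 3.6, 3.9, 3.2)
  welch <- geneScoreGroupTest(a, b)
  se <- sqrt(var(a) / 4 + var(b) / 5)
  expect_equal(welch$statistic, (mean(a) - mean(b)) / se, tolerance = 1e-12)
  pooled <- geneScoreGroupTest(a, b, var_equal = TRUE)
  sp2 <- (3 * var(a) + 4 * var(b)) / 7
  expect_equal(pooled$statistic,
               (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 5)),
               tolerance = 1e-12)
  expect_error(geneScoreGroupTest(3, b), "at least 2")
})

test_that("p decreases monotonically with a location shift (simulated grid)", {
  base <- withr::with_seed(22, rnorm(200, 3.15, 0.5))
  ps <- vapply(c(0, 0.1, 0.25, 0.5),
               function(delta) geneScoreGroupTest(base, base + delta)$p_value,
               numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("risk-allele histogram test handles identical, disjoint and pooled cases", {
  h <- table(factor(rep(14:18, times = c(5, 10, 20, 10, 5))))
  same <- riskAlleleDistributionTest(h, h)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  h2 <- table(factor(rep(24:28, times = c(5, 10, 20, 10, 5))))
  disjoint <- riskAlleleDistributionTest(h, h2)
  expect_lt(disjoint$p_value, 1e-10)

  # pooling: manual chi-squared on the pooled table must match
  ca <- c(`10` = 2, `11` = 3, `12` = 40, `13` = 30, `14` = 2)
  cb <- c(`10` = 1, `11` = 6, `12` = 35, `13` = 28, `14` = 4)
  res <- riskAlleleDistributionTest(ca, cb)
  m <- attr(res, "pooled_table")
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_true(all(e >= 5))
  expect_equal(res$statistic, sum((m - e)^2 / e), tolerance = 1e-12)
  expect_error(riskAlleleDistributionTest(table(numeric(0)), h), "empty")
})

test_that("tertile trend regressions recover exact and closed-form slopes", {
  n <- 66
  gs <- seq_len(n) / 10
  cohort <- data.frame(gene_score = gs, exact = assignTertiles(gs))
  res <- suppressWarnings(tertileAssociation(cohort, data.frame(
    trait = "exact", transform = "none", type = "numeric")))
  expect_equal(res$slope, 1, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-12)

  # tiny dataset: slope equals the normal-equations OLS solution
  cohort2 <- data.frame(gene_score = c(1, 2, 3, 4, 5, 6),
                        y = c(2.0, 1.5, 3.1, 2.8, 4.0, 3.5))
  t_idx <- assignTertiles(cohort2$gene_score)
  beta <- cov(t_idx, cohort2$y) / var(t_idx)
  res2 <- tertileAssociation(cohort2, data.frame(
    trait = "y", transform = "none", type = "numeric"))
  expect_equal(res2$slope, beta, tolerance = 1e-12)

  expect_error(tertileAssociation(data.frame(gene_score = c(1, 1, 1)),
                                  trait_spec[1, ]), "distinct")
})

test_that("logistic tertile trend flags separation instead of converging silently", {
  n <- 30
  gs <- seq_len(n)
  tert <- assignTertiles(gs)
  cohort <- data.frame(gene_score = gs, outcome = tert == 3)
  res <- tertileAssociation(cohort, data.frame(
    trait = "outcome", transform = "none", type = "categorical"))
  expect_match(res$note, "separation")
  expect_true(is.na(res$p_value))

  # a well-behaved binary trait is fitted by logistic regression
  cohort$ok <- withr::with_seed(5, runif(n) < 0.5)
  while (length(unique(table(assignTertiles(cohort$gene_score), cohort$ok))) < 2 ||
         any(table(assignTertiles(cohort$gene_score), cohort$ok) == 0)) {
    cohort$ok <- runif(n) < 0.5
  }
  res2 <- tertileAssociation(cohort, data.frame(
    trait = "ok", transform = "none", type = "categorical"))
  expect_equal(res2$test, "logistic_regression")
  expect_true(res2$p_value > 0 && res2$p_value <= 1)
})
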