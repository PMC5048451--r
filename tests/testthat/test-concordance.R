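test_that("identical call sets are 100% concordant at every SNP", {
  panel <- defaultPanel()
  g <- simulateGenotypes(panel, n = 10, seed = 14)
  tab <- compareCallSets(g, g, panel)
  s <- summarizeConcordance(tab)
  expect_equal(s$overall_pct, 100)
  expect_true(all(s$per_snp$pct == 100))
  expect_equal(s$overall_compared, 10L * 19L)
  expect_equal(nrow(s$discordant), 0L)
})

test_that("flipped genotypes are counted as discordant exactly where injected", {
  panel <- makeTestPanel(rafs = c(0.5, 0.3, 0.7, 0.2))
  g <- simulateGenotypes(panel, n = 158, seed = 15)
  inj <- injectGenotypeErrors(g, panel, rate = 0, seed = 1)
  expect_equal(nrow(inj$ledger), 0L)
  expect_identical(inj$calls@allele1, g@allele1)

  # flip two calls by hand at one SNP: 156/158 = 98.7%
  d <- dosageMatrix(g, panel)
  d[1, 1] <- (d[1, 1] + 1) %% 3
  d[2, 1] <- (d[2, 1] + 2) %% 3
  g2 <- genotypesFromDosage(d, panel)
  s <- summarizeConcordance(compareCallSets(g2, g, panel))
  row1 <- s$per_snp[s$per_snp$rsid == "rs1", ]
  expect_equal(row1$n_concordant, 156L)
  expect_equal(row1$n_compared, 158L)
  expect_equal(row1$pct, 98.7)
})

test_that("injected-error ledger matches the computed discordances", {
  panel <- defaultPanel()
  g <- simulateGenotypes(panel, n = 60, seed = 16)
  inj <- injectGenotypeErrors(g, panel, rate = 0.02, seed = 17)
  tab <- compareCallSets(inj$calls, g, panel)
  r <- concordanceRecords(tab)
  expect_equal(sum(r$n_discordant), nrow(inj$ledger))
  led <- table(factor(inj$ledger$rsid, levels = r$rsid))
  expect_equal(as.integer(led), r$n_discordant)
})

test_that("comparison is symmetric and restricted to pairwise-complete calls", {
  panel <- defaultPanel()
  g <- simulateGenotypes(panel, n = 30, seed = 18)
  d <- dosageMatrix(g, panel)
  d[3, 2] <- NA; d[5, 7] <- NA
  g_a <- genotypesFromDosage(d, panel)
  d2 <- dosageMatrix(g, panel)
  d2[9, 2] <- NA
  g_b <- genotypesFromDosage(d2, panel)
  ab <- concordanceRecords(compareCallSets(g_a, g_b, panel))
  ba <- concordanceRecords(compareCallSets(g_b, g_a, panel))
  expect_equal(ab[c("rsid", "n_compared", "n_concordant", "n_discordant")],
               ba[c("rsid", "n_compared", "n_concordant", "n_discordant")])
  expect_equal(ab$n_compared[ab$rsid == rsids(panel)[2]], 28L)  # two missing pairs
  tab <- compareCallSets(g_a, g_b, panel)
  expect_equal(tab@overall_compared, sum(ab$n_compared))
  expect_equal(tab@overall_concordant, sum(ab$n_concordant))

  empty <- genotypesFromDosage(matrix(1, 1, 19, dimnames = list("zz", NULL)), panel)
  expect_error(compareCallSets(g_a, empty, panel), "overlapping")
})

test_that("per-SNP percentages equal an independent ratio recomputation", {
  ct <- readConcordanceCounts()
  s <- summarizeConcordance(ct)
  r <- concordanceRecords(ct)
  expect_equal(s$per_snp$pct, round(100 * r$n_concordant / r$n_compared, 1))
  expect_equal(s$overall_pct,
               round(100 * sum(r$n_concordant) / sum(r$n_compared), 1))
})

test_that("genotype frequency report recovers observed RAF and HWE expectations", {
  panel <- makeTestPanel(rafs = 0.9)
  # 139 hom-risk / 5 het / 0 other-hom: observed RAF = 283/288
  d <- matrix(c(rep(2, 139), rep(1, 5)), ncol = 1)
  rownames(d) <- paste0("s", 1:144)
  rep1 <- genotypeFrequencyReport(genotypesFromDosage(d, panel), panel)
  expect_equal(rep1$n, 144L)
  expect_equal(rep1$raf_observed, 283 / 288, tolerance = 1e-12)
  expect_equal(unlist(rep1[, c("hom_common", "het", "hom_rare")], use.names = FALSE),
               c(139, 5, 0))
  expect_equal(rep1$hwe_het, 144 * 2 * (283 / 288) * (5 / 288), tolerance = 1e-12)

  # all heterozygotes: RAF 0.5
  d2 <- matrix(1, nrow = 8, ncol = 1, dimnames = list(paste0("t", 1:8), NULL))
  rep2 <- genotypeFrequencyReport(genotypesFromDosage(d2, panel), panel)
  expect_equal(rep2$raf_observed, 0.5)

  # HWE cohort: observed RAF within 3 binomial SE of the truth
  p3 <- makeTestPanel(rafs = 0.3)
  g3 <- simulateGenotypes(p3, n = 1e5, seed = 19)
  rep3 <- genotypeFrequencyReport(g3, p3)
  se <- sqrt(0.3 * 0.7 / (2 * 1e5))
  expect_lt(abs(rep3$raf_observed - 0.3), 3 * se)
})

test_that("error injection at rate eps converges to eps discordance (3-SE band)", {
  panel <- makeTestPanel(rafs = c(0.5, 0.2, 0.8, 0.33))
  g <- simulateGenotypes(panel, n = 5000, seed = 20)
  eps <- 0.05
  inj <- injectGenotypeErrors(g, panel, rate = eps, seed = 21)
  tab <- compareCallSets(inj$calls, g, panel)
  n <- tab@overall_compared
  disc <- n - tab@overall_concordant
  se <- sqrt(eps * (1 - eps) / n)
  expect_lt(abs(disc / n - eps), 3 * se)
})

test_that("count-table constructor enforces the conservation invariants", {
  r <- data.frame(rsid = c("a", "b"), n_compared = c(10, 20),
                  n_discordant = c(1, 0), hom_common = c(5, 10),
                  het = c(4, 8), hom_rare = c(1, 2))
  ct <- ConcordanceTable(r)
  expect_equal(ct@overall_compared, 30L)
  expect_equal(ct@overall_concordant, 29L)
  bad <- r; bad$n_concordant <- c(5, 20); bad$n_discordant <- c(1, 0)
  expect_error(ConcordanceTable(bad), "equal")
})
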