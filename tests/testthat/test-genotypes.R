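test_that("long-format CSV reads into a complete GenotypeSet", {
  panel <- defaultPanel()
  g <- simulateGenotypes(panel, n = 2, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  writeGenotypes(g, path)
  g2 <- readGenotypes(path, panel)
  expect_equal(length(subjectIds(g2)), 2L)
  expect_equal(sum(is.na(dosageMatrix(g2, panel))), 0L)
  expect_equal(dosageMatrix(g2, panel)[subjectIds(g), ],
               dosageMatrix(g, panel))
})

test_that("a subject missing one rsid gets exactly one missing call", {
  panel <- defaultPanel()
  g <- simulateGenotypes(panel, n = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  writeGenotypes(g, path)
  df <- read.csv(path, colClasses = "character")
  df <- df[!(df$subject_id == df$subject_id[1] & df$rsid == "rs4341"), ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path2, row.names = FALSE, quote = FALSE)
  g2 <- readGenotypes(path2, panel)
  d <- dosageMatrix(g2, panel)
  expect_equal(sum(is.na(d)), 1L)
  expect_true(is.na(d[df$subject_id[1], "rs4341"]))
})

test_that("allele letters outside the panel are a hard error (no strand flipping)", {
  panel <- makeTestPanel()
  df <- data.frame(subject_id = "s1", rsid = "rs1",
                   allele1 = "T", allele2 = "A", stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(readGenotypes(path, panel), "no strand flipping")
  expect_error(riskAlleleDosage("T", "A", "A", "G"), "defined alleles")
})

test_that("half-calls and unknown rsids are rejected", {
  panel <- makeTestPanel()
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(subject_id = "s1", rsid = "rs1",
                       allele1 = "A", allele2 = ""), path, row.names = FALSE)
  expect_error(readGenotypes(path, panel), "half-call")
  write.csv(data.frame(subject_id = "s1", rsid = "rs99",
                       allele1 = "A", allele2 = "A"), path, row.names = FALSE)
  expect_error(readGenotypes(path, panel), "rs99")
})

test_that("minimal VCF reads GT calls and rejects non-panel ALT alleles", {
  panel <- defaultPanel()
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("7", "150696111", "rs1799983", "G", "T", ".", "PASS", ".",
          "GT", "0/1", "1/1", sep = "\t"),
    paste("16", "56989590", "rs708272", "G", "A", ".", "PASS", ".",
          "GT", "0/0", "./.", sep = "\t")), vcf)
  g <- readGenotypes(vcf, panel, format = "vcf")
  d <- dosageMatrix(g, panel)
  expect_equal(unname(d[c("s1", "s2"), "rs1799983"]), c(1, 2))
  expect_equal(unname(d["s1", "rs708272"]), 2)   # risk allele G is REF here
  expect_true(is.na(d["s2", "rs708272"]))
  expect_true(all(is.na(d[, "rs328"])))          # panel SNP absent from file

  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t"),
    paste("7", "150696111", "rs1799983", "G", "C", ".", "PASS", ".",
          "GT", "0/1", sep = "\t")), bad)
  expect_error(readGenotypes(bad, panel, format = "vcf"), "panel alleles")
})

test_that("dosage reduction is symmetric in allele order and bounded", {
  expect_equal(riskAlleleDosage(c("A", "G"), c("G", "A"), "A", "G"), c(1L, 1L))
  expect_equal(riskAlleleDosage("A", "A", "A", "G"), 2L)
  expect_equal(riskAlleleDosage("G", "G", "A", "G"), 0L)
  expect_true(is.na(riskAlleleDosage(NA_character_, NA_character_, "A", "G")))
})

test_that("total risk alleles equals a brute-force per-SNP recount", {
  panel <- defaultPanel()
  g <- simulateGenotypes(panel, n = 50, seed = 7)
  total <- countRiskAlleles(g, panel)
  s <- snpInfo(panel)
  recount <- vapply(subjectIds(g), function(id) {
    sum(vapply(s$rsid, function(rs) {
      a <- c(g@allele1[id, rs], g@allele2[id, rs])
      sum(a == s$risk_allele[match(rs, s$rsid)])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(total, recount)
  expect_true(all(total >= 0 & total <= 38))
})

test_that("missing-call policy: strict error names the rsid, imputation uses 2*RAF", {
  panel <- makeTestPanel(rafs = c(0.5, 0.2, 0.8, 0.33))
  dos <- matrix(c(1, NA, 2, 0), 1, 4, dimnames = list("s1", NULL))
  g <- genotypesFromDosage(dos, panel)
  expect_error(countRiskAlleles(g, panel), "rs2")
  imput <- countRiskAlleles(g, panel, missing = "impute")
  expect_equal(unname(imput), 1 + 2 * 0.2 + 2 + 0)
})
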